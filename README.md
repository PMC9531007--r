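# cmpad

Unsupervised anomaly detection for in-home movement data, built around the
**Contextual Matrix Profile (CMP)** and its multidimensional extension.

Households of people living with dementia can be monitored with passive
infrared (PIR) motion sensors in the bathroom, bedroom, kitchen, lounge and
hallway. Adverse health events — urinary tract infections (UTIs) and
hospitalizations above all — show up as disturbances of daily movement
routine: multiplied night-time bathroom trips, fragmented sleep, or a house
that suddenly falls quiet. cmpad turns a raw PIR event log into daily
behavioural features, scores each time segment against the patient's own
history, raises alerts by sliding-window thresholding, validates them
against weakly dated clinical labels, and explains them through digital
biomarkers. It is aimed at researchers in sensor-based remote health
monitoring who need a lightweight, streaming, training-free detector with
clinically interpretable output.

## The method

For a daily feature series, every `m`-day subsequence (default `m = 3`) is
z-normalized and compared with every other by Euclidean distance, the
exclusion zone `|i - j| < ceiling(m/2)` masking trivial self-matches. The
series is tiled into **contexts** of `c = 3` subsequence starts, and the
CMP stores per context pair the *block minimum*

    CMP[i, j] = min over a in context i, b in context j of d_z(x_a, x_b),

a denoised, segment-level self-similarity matrix. For multivariate data,
the 11 per-feature CMPs are stacked, each cell is sorted ascending across
features, and layer `k` of the **multidimensional CMP** averages the
`k + 1` smallest distances per cell — scoring each segment pair on the
patient's most stable features, with `k` either fixed or chosen by knee
detection on the per-layer median curve. The anomaly score of a context is
the mean of its cells against strictly earlier contexts (streaming), scores
are broadcast to days, and days are flagged by robust-z / Tukey IQR /
quantile rules in 7–90-day sliding windows. Alerts validate a label when
they fall within −10/+7 days of it; the modal feature at the bottom of the
sorted stack is the patient's top digital biomarker.

Because the motivating cohort data are private, the package includes a
seeded simulator (`simulate_cohort()`) producing Poisson visit processes
with circadian hourly profiles, lognormal day-to-day noise, burst-expanded
firings, and injected UTI-like (night bathroom ×3, 3–8 days) and
hospitalization-like (all activity ×0.1, 2–10 days) episodes with
ground-truth labels.

## Worked example

```r
library(cmpad)

cohort <- simulate_cohort(synth_config(n_patients = 10, n_days = 365, seed = 2))
res <- run_pipeline(cohort$events, cohort$labels,
                    config = list(model = "mdcmp_equal", k = 1,
                                  method = "robust_z", window_days = 7,
                                  threshold = 1.65))
glance(res$evaluation)
#> # A tibble: 1 × 9
#>   mean_recall mean_alerts mean_alert_rate patients_above_threshold n_evaluable
#>         <dbl>       <dbl>           <dbl>                    <int>       <int>
#> 1          80        46.3            12.7                        9          10
#> # precision total_labels total_days label_rate_pct
#> #      16.0           30       3645          0.823

head(res$biomarkers_cohort, 3)
#> # A tibble: 3 × 3
#>   feature     median_contribution n_top_patients
#>   <chr>                     <dbl>          <int>
#> 1 bathroom_em               0.252             10
#> 2 kitchen_em                0.181              0
#> 3 bedroom_em                0.146              0
```

Reading: at the equal-weighted multidimensional setting (`k = 1`, robust
z 1.65, 7-day windows) the pipeline recalls 80% of the injected episodes,
flags 12.7% of patient days, and gives 9 of 10 patients better than
one-third recall (results vary by simulation seed). Early-morning
(midnight–6 AM) bathroom activity is the top-ranked digital biomarker —
the dominant behavioural signature of UTI-like episodes — for all 10
patients, contributing about a quarter of the dimension-0 slots.
`autoplot()` on a `cmp` object draws the segment-similarity heat map;
`plot_scores()` overlays scores, alerts and labels; `grid_search()` sweeps
the full thresholding grid.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cmpad.R", package="cmpad"))')" \
    simulate --patients 10 --days 365 --seed 2 --out sim/
```

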