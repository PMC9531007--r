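# Independent brute-force oracles used to pin down the fast implementations.
# These deliberately use naive loops and textbook definitions only.

# z-normalized Euclidean distance, scalar definition
bf_znorm <- function(a, b) {
  m <- length(a)
  sda <- sqrt(mean((a - mean(a))^2))
  sdb <- sqrt(mean((b - mean(b))^2))
  if (sda == 0 && sdb == 0) return(0)
  if (sda == 0 || sdb == 0) return(sqrt(m))
  sqrt(sum(((a - mean(a)) / sda - (b - mean(b)) / sdb)^2))
}

# all-pairs distance matrix by double loop
bf_distance_matrix <- function(x, m, band = ceiling(m / 2)) {
  ns <- length(x) - m + 1
  D <- matrix(Inf, ns, ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (abs(i - j) >= band) {
        D[i, j] <- bf_znorm(x[i:(i + m - 1)], x[j:(j + m - 1)])
      }
    }
  }
  D
}

# block-minimum CMP straight from the definition
bf_cmp <- function(x, m, c, band = ceiling(m / 2)) {
  D <- bf_distance_matrix(x, m, band)
  ns <- nrow(D)
  C <- ns %/% c
  V <- matrix(Inf, C, C)
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      blk <- D[((i - 1) * c + 1):(i * c), ((j - 1) * c + 1):(j * c)]
      fin <- blk[is.finite(blk)]
      if (length(fin)) V[i, j] <- min(fin)
    }
  }
  V
}

# textbook double-loop ApEn (self-matches included, Chebyshev distance)
bf_apen <- function(x, m, tol) {
  N <- length(x)
  phi <- function(mm) {
    nt <- N - mm + 1
    logC <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= tol) cnt <- cnt + 1
      }
      logC[i] <- log(cnt / nt)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

# double-loop FuzzyEn: mean-subtracted templates, Chebyshev, exponential
# membership, self-matches excluded, N - m templates for both orders
bf_fuzzyen <- function(x, m, tol, n_fuzzy) {
  N <- length(x)
  phi <- function(mm) {
    nt <- N - m
    s <- 0
    for (i in seq_len(nt)) {
      ti <- x[i:(i + mm - 1)]
      ti <- ti - mean(ti)
      for (j in seq_len(nt)) {
        if (j == i) next
        tj <- x[j:(j + mm - 1)]
        tj <- tj - mean(tj)
        d <- max(abs(ti - tj))
        s <- s + exp(-(d / tol)^n_fuzzy)
      }
    }
    s / (nt * (nt - 1))
  }
  -log(phi(m + 1) / phi(m))
}

# knee as the maximum vertical distance from the chord of the min-max
# normalized curve (first index on ties); NA when the curve is flat/linear
bf_knee <- function(y) {
  n <- length(y)
  if (diff(range(y)) <= 0) return(NA_integer_)
  xn <- (seq_len(n) - 1) / (n - 1)
  yn <- (y - min(y)) / diff(range(y))
  d <- yn - xn
  if (max(d) <= 1e-12) return(NA_integer_)
  which.max(d) - 1L
}

# direct-definition threshold flags
bf_robust_z <- function(w, cur, thr) {
  med <- median(w)
  mad0 <- median(abs(w - med))
  if (mad0 == 0) cur > med else 0.6745 * (cur - med) / mad0 > thr
}
bf_iqr <- function(w, cur, thr) {
  q1 <- quantile(w, 0.25, names = FALSE)
  q3 <- quantile(w, 0.75, names = FALSE)
  cur > q3 + thr * (q3 - q1)
}
bf_quantile <- function(w, cur, q) cur > quantile(w, q, names = FALSE)

# small deterministic event stream builder for feature tests
mk_events <- function(times, locations, day0 = "2021-01-01") {
  tibble::tibble(
    timestamp = as.POSIXct(paste(day0), tz = "UTC") + times,
    location = locations
  )
}

# a compact synthetic cohort for pipeline-level tests
small_cohort <- function(n_patients = 2, n_days = 150, seed = 7, ...) {
  simulate_cohort(synth_config(n_patients = n_patients, n_days = n_days,
                               seed = seed, ...))
}
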