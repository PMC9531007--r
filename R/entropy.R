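# Chebyshev distance matrix between all length-m templates of x
# (rows i = x[i..i+m-1]); optionally mean-subtracted templates
.template_cheb <- function(x, m, n_templates, center = FALSE) {
  idx <- outer(seq_len(n_templates), 0:(m - 1L), "+")
  S <- matrix(x[idx], nrow = n_templates)
  if (center) S <- S - rowMeans(S)
  D <- matrix(0, n_templates, n_templates)
  for (k in seq_len(m)) {
    D <- pmax(D, abs(outer(S[, k], S[, k], "-")))
  }
  D
}

#' Approximate entropy (ApEn)
#'
#' Regularity statistic of a series: the negative average log conditional
#' probability that runs of length `m_e` that match within tolerance still
#' match when extended by one point. Template similarity is hard
#' (Heaviside): two templates match when their Chebyshev distance is at most
#' the tolerance. Self-matches are included (the classical ApEn
#' convention), so a constant series has ApEn exactly 0; values run from
#' about 0 (perfectly regular) to about 2 (noise).
#'
#' @param x Numeric series; the trailing `min(n_max, length(x))` points are
#'   used.
#' @param m_e Template length (default 7).
#' @param r Tolerance as a multiple of the series SD (default 0.2). Ignored
#'   when `tolerance` is given.
#' @param tolerance Optional absolute tolerance. When the series SD is zero
#'   and no absolute tolerance is given, the tolerance is floored at 1e-6.
#' @param n_max Maximum number of trailing points used (default 500).
#'
#' @return ApEn value (Phi^m - Phi^(m+1)).
#' @export
approximate_entropy <- function(x, m_e = 7, r = 0.2, tolerance = NULL,
                                n_max = 500) {
  x <- as.numeric(tail(x, n_max))
  N <- length(x)
  if (N < m_e + 2) abort("series too short for ApEn", class = "cmpad_input_error")
  tol <- if (!is.null(tolerance)) tolerance else r * sd(x)
  if (!is.finite(tol) || tol <= 0) tol <- .cmpad_eps
  phi <- function(m) {
    nt <- N - m + 1L
    D <- .template_cheb(x, m, nt)
    Ci <- rowSums(D <= tol) / nt     # self-match included
    mean(log(Ci))
  }
  phi(m_e) - phi(m_e + 1)
}

#' Fuzzy entropy (FuzzyEn)
#'
#' Like sample entropy but with graded template similarity: templates are
#' mean-subtracted and compared by Chebyshev distance d, and similarity is
#' the fuzzy membership `exp(-(d/tol)^n_fuzzy)` in (0, 1]. Self-matches are
#' excluded. A constant series has FuzzyEn 0.
#'
#' @inheritParams approximate_entropy
#' @param n_fuzzy Gradient of the exponential membership boundary
#'   (default 2).
#'
#' @return FuzzyEn value `-log(phi^(m+1) / phi^m)`, non-negative up to
#'   floating point.
#' @export
fuzzy_entropy <- function(x, m_e = 7, r = 0.2, n_fuzzy = 2, tolerance = NULL,
                          n_max = 500) {
  x <- as.numeric(tail(x, n_max))
  N <- length(x)
  if (N < m_e + 2) abort("series too short for FuzzyEn", class = "cmpad_input_error")
  tol <- if (!is.null(tolerance)) tolerance else r * sd(x)
  if (!is.finite(tol) || tol <= 0) tol <- .cmpad_eps
  phi <- function(m) {
    nt <- N - m_e         # same template count for orders m and m+1
    D <- .template_cheb(x, m, nt, center = TRUE)
    mu <- exp(-(D / tol)^n_fuzzy)
    diag(mu) <- 0         # exclude self-matches
    mean(rowSums(mu) / (nt - 1))
  }
  p_m <- phi(m_e)
  p_m1 <- phi(m_e + 1)
  -log(p_m1 / p_m)
}

#' Inverse-entropy feature weights
#'
#' Weights each feature inversely to the entropy of its raw daily series
#' (trailing `n_max` days): noisier, less predictable features carry less
#' weight in the fused anomaly score. Entropies are floored at 1e-6 so a
#' perfectly regular feature cannot produce an infinite weight.
#'
#' @param features Feature tibble for one patient (columns
#'   [cmpad_features()]).
#' @param kind `"apen"` or `"fuzzyen"`.
#' @param m_e,r,n_fuzzy,n_max Entropy parameters (see
#'   [approximate_entropy()] and [fuzzy_entropy()]).
#'
#' @return Named numeric vector of weights over the feature columns, summing
#'   to 1.
#' @export
entropy_weights <- function(features, kind = c("apen", "fuzzyen"),
                            m_e = 7, r = 0.2, n_fuzzy = 2, n_max = 500) {
  kind <- match.arg(kind)
  cols <- intersect(.cmpad_features, names(features))
  stopifnot(length(cols) >= 1)
  H <- vapply(cols, function(f) {
    v <- features[[f]]
    if (kind == "apen") approximate_entropy(v, m_e = m_e, r = r, n_max = n_max)
    else fuzzy_entropy(v, m_e = m_e, r = r, n_fuzzy = n_fuzzy, n_max = n_max)
  }, numeric(1))
  w <- 1 / pmax(H, .cmpad_eps)
  w / sum(w)
}
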