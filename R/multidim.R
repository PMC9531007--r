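#' Stack per-feature CMPs and sort each cell by distance
#'
#' Stacks the feature-specific CMP matrices into an F x C x C array and
#' sorts each (C, C) cell ascending along the feature axis, recording the
#' per-cell feature order. Ties are broken by lexicographic feature name (so
#' biomarker attribution is reproducible); `Inf` cells sort last.
#'
#' @param cmps Named list of `cmp` objects (one per feature, F >= 2) sharing
#'   one context grid. Unnamed lists use each `cmp`'s `feature` field.
#'
#' @return Object of class `cmp_stack`: list with `values` (F x C x C sorted
#'   array), `feature_order` (F x C x C character array of feature names,
#'   ascending by distance), `features` (lexicographically sorted), and
#'   `contexts`.
#' @export
stack_cmps <- function(cmps) {
  stopifnot(length(cmps) >= 2)
  feats <- names(cmps)
  if (is.null(feats)) feats <- purrr::map_chr(cmps, "feature")
  stopifnot(!anyNA(feats), !any(duplicated(feats)))
  Cs <- purrr::map_int(cmps, ~ nrow(.x$values))
  if (length(unique(Cs)) != 1) abort("CMPs have mismatched context grids",
                                     class = "cmpad_input_error")
  C <- Cs[[1]]
  for (cm in cmps) {
    if (!identical(dim(cm$values), c(C, C)) ||
        !identical(cm$contexts$context_id, cmps[[1]]$contexts$context_id)) {
      abort("CMPs have mismatched context grids", class = "cmpad_input_error")
    }
  }
  ord_feats <- sort(feats, method = "radix")
  cmps <- cmps[match(ord_feats, feats)]
  F <- length(ord_feats)
  raw <- array(NA_real_, dim = c(F, C, C))
  for (f in seq_len(F)) raw[f, , ] <- cmps[[f]]$values
  vals <- array(NA_real_, dim = c(F, C, C))
  featord <- array(NA_character_, dim = c(F, C, C))
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      v <- raw[, i, j]
      o <- order(v, method = "radix")  # stable: ties keep lexicographic order
      vals[, i, j] <- v[o]
      featord[, i, j] <- ord_feats[o]
    }
  }
  structure(list(values = vals, feature_order = featord,
                 features = ord_feats, contexts = cmps[[1]]$contexts),
            class = "cmp_stack")
}

#' k-dimensional CMP tensor
#'
#' Layer k (zero-based) of the k-dimensional CMP holds, for every cell, the
#' mean of the k+1 smallest per-feature distances, i.e. the running prefix
#' mean along the sorted feature axis of the stack. `Inf` entries propagate
#' into every layer that includes them; layers are cellwise non-decreasing
#' in k.
#'
#' @param stacked A `cmp_stack`.
#'
#' @return Object of class `cmp_kdim`: list with `values` (F x C x C array,
#'   layer k at index k+1), `features`, `contexts`.
#' @export
kdim_cmp <- function(stacked) {
  stopifnot(inherits(stacked, "cmp_stack"))
  dm <- dim(stacked$values)
  F <- dm[1]
  cs <- apply(stacked$values, c(2, 3), cumsum)     # F x C x C prefix sums
  vals <- cs / array(seq_len(F), dim = dm)
  structure(list(values = vals, features = stacked$features,
                 contexts = stacked$contexts),
            class = "cmp_kdim")
}

#' Extract one layer of the k-dimensional CMP
#'
#' @param kdim A `cmp_kdim`.
#' @param k Zero-based layer index in `[0, F-1]`. `k = 0` is the elementwise
#'   minimum over features; `k = 1` averages the two best features per cell;
#'   `k = F-1` is the plain cross-feature mean.
#'
#' @return A `cmp` object holding the layer and the shared context grid.
#' @export
select_layer <- function(kdim, k) {
  stopifnot(inherits(kdim, "cmp_kdim"))
  F <- dim(kdim$values)[1]
  if (k < 0 || k >= F) abort("k out of range", class = "cmpad_input_error")
  new_cmp(kdim$values[k + 1, , ], kdim$contexts,
          feature = paste0("kdim_", k))
}

# Knee of an increasing curve, kneedle-style: min-max normalize, take the
# difference curve d = y_norm - x_norm, locate its first global maximum, and
# confirm a knee only if d later drops at least S * mean(diff(x_norm)) below
# that maximum. Returns the zero-based index, or NA when no knee exists
# (flat or linear curves).
.kneedle <- function(y, S = 1) {
  n <- length(y)
  if (n < 3) return(NA_integer_)
  rng <- diff(range(y))
  if (rng <= 0) return(NA_integer_)
  xn <- (seq_len(n) - 1) / (n - 1)
  yn <- (y - min(y)) / rng
  d <- yn - xn
  i <- which.max(d)
  if (d[i] <= 1e-12 || i == n) return(NA_integer_)
  thr <- d[i] - S * mean(diff(xn))
  if (any(d[(i + 1):n] < thr)) return(i - 1L) else return(NA_integer_)
}

#' Automatic dimension selection for the k-dimensional CMP
#'
#' Computes, for each layer k, the median of the finite upper-triangle cells
#' (a non-decreasing curve in k by construction) and finds its knee with the
#' kneedle procedure (sensitivity `S`, min-max normalized curve). When no
#' knee is detected (flat or effectively linear median curves), falls back
#' to `k = 1`, the best fixed setting for this kind of data.
#'
#' @param kdim A `cmp_kdim` with F >= 3 layers.
#' @param S Kneedle sensitivity (default 1).
#'
#' @return Zero-based optimal layer index in `[0, F-1]`.
#' @export
optimal_k <- function(kdim, S = 1) {
  stopifnot(inherits(kdim, "cmp_kdim"))
  F <- dim(kdim$values)[1]
  stopifnot(F >= 3)
  C <- dim(kdim$values)[2]
  ut <- upper.tri(matrix(0, C, C))
  med <- vapply(seq_len(F), function(k) {
    v <- kdim$values[k, , ][ut]
    v <- v[is.finite(v)]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  if (anyNA(med) || diff(range(med)) <= 0) return(1L)
  k <- .kneedle(med, S = S)
  if (is.na(k)) 1L else as.integer(k)
}
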