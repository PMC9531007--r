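#' z-normalized Euclidean distance between two subsequences
#'
#' Each vector is standardized to zero mean and unit population standard
#' deviation before the Euclidean distance is taken, so the comparison is
#' shape-based (offset- and scale-invariant). Zero-variance conventions:
#' two flat subsequences are at distance 0; a flat versus a non-flat
#' subsequence is at distance `sqrt(m)` (the distance from the origin to any
#' z-normalized vector).
#'
#' @param a,b Numeric vectors of equal length m >= 2.
#'
#' @return Non-negative distance.
#' @export
znorm_distance <- function(a, b) {
  if (length(a) != length(b)) abort("length mismatch", class = "cmpad_input_error")
  m <- length(a)
  stopifnot(m >= 2)
  sda <- sqrt(sum((a - mean(a))^2) / m)
  sdb <- sqrt(sum((b - mean(b))^2) / m)
  if (sda == 0 && sdb == 0) return(0)
  if (sda == 0 || sdb == 0) return(sqrt(m))
  za <- (a - mean(a)) / sda
  zb <- (b - mean(b)) / sdb
  sqrt(sum((za - zb)^2))
}

# rows = z-normalized subsequences of x with length m (population sd);
# flat rows flagged
.znorm_subsequences <- function(x, m) {
  n <- length(x)
  ns <- n - m + 1L
  idx <- outer(seq_len(ns), 0:(m - 1L), "+")
  S <- matrix(x[idx], nrow = ns)
  mu <- rowMeans(S)
  v <- rowMeans(S^2) - mu^2
  v[v < 0] <- 0     # guard cancellation
  sdv <- sqrt(v)
  flat <- sdv <= 1e-12
  Z <- (S - mu) / ifelse(flat, 1, sdv)
  Z[flat, ] <- 0
  list(Z = Z, flat = flat, ns = ns)
}

#' All-pairs z-normalized distance matrix (self-join)
#'
#' Distances between every pair of length-m subsequences of `x`, with an
#' exclusion zone of width `ceiling(m/2)` around the diagonal set to `Inf`
#' so that trivially overlapping subsequences never count as matches.
#'
#' @param x Numeric series of length n >= m + c - 1.
#' @param m Subsequence length in days (>= 2).
#' @param exclusion `"mp_half_m"` (default) masks `|i - j| < ceiling(m/2)`;
#'   `"none"` masks only the diagonal.
#'
#' @return An (n-m+1) x (n-m+1) symmetric matrix with `Inf` inside the
#'   exclusion zone.
#' @export
distance_matrix <- function(x, m = 3, exclusion = c("mp_half_m", "none")) {
  exclusion <- match.arg(exclusion)
  n <- length(x)
  if (n < m + 1) abort("series too short", class = "cmpad_input_error")
  zs <- .znorm_subsequences(x, m)
  Z <- zs$Z
  flat <- zs$flat
  ns <- zs$ns
  # exact per-coordinate accumulation: the Gram identity 2m - 2*Z %*% t(Z)
  # loses ~sqrt(eps) absolute precision exactly where it matters (near-zero
  # block minima), so sum squared differences directly
  D2 <- matrix(0, ns, ns)
  for (k in seq_len(m)) {
    dk <- outer(Z[, k], Z[, k], "-")
    D2 <- D2 + dk * dk
  }
  if (any(flat)) {
    # flat-vs-flat -> 0; flat-vs-nonflat -> m (squared)
    D2[flat, ] <- m
    D2[, flat] <- m
    D2[flat, flat] <- 0
  }
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  band <- if (exclusion == "mp_half_m") ceiling(m / 2) else 1L
  ij <- abs(row(D) - col(D))
  D[ij < band] <- Inf
  D
}

#' Tile a series into contexts (time segments)
#'
#' A context is a block of `c` consecutive subsequence start positions; the
#' series is tiled by disjoint blocks (stride = `c`) and trailing
#' subsequences that do not fill a whole context are dropped. Neighbouring
#' contexts' day spans overlap by m - 1 days.
#'
#' @param n Series length in days.
#' @param m Subsequence length (days).
#' @param c Context window (subsequences per context).
#' @param dates Optional Date vector of length `n` used to attach calendar
#'   end dates.
#'
#' @return Tibble with one row per context: `context_id` (1-based),
#'   `start_idx`/`end_idx` (1-based subsequence start range), `first_day`/
#'   `last_day` (1-based day indices of the span) and `end_date` (`NA` if
#'   `dates` is missing).
#' @export
build_contexts <- function(n, m = 3, c = 3, dates = NULL) {
  stopifnot(m >= 2, c >= 1)
  ns <- n - m + 1L
  C <- ns %/% c
  if (C < 1) abort("series too short for one context", class = "cmpad_input_error")
  start <- (seq_len(C) - 1L) * c + 1L
  end <- start + c - 1L
  last_day <- end + m - 1L
  tibble::tibble(
    context_id = seq_len(C),
    start_idx = start, end_idx = end,
    first_day = start, last_day = last_day,
    end_date = if (is.null(dates)) as.Date(NA) else as.Date(dates)[last_day]
  )
}

new_cmp <- function(values, contexts, feature = NA_character_, m = NA_integer_,
                    c = NA_integer_) {
  structure(list(values = values, contexts = contexts, feature = feature,
                 m = m, c = c),
            class = "cmp")
}

#' Contextual Matrix Profile self-join
#'
#' Computes the CMP of a single series: the distance matrix is tiled into
#' context-pair blocks and each CMP cell holds the minimum z-normalized
#' distance between any subsequence of one context and any subsequence of
#' the other, ignoring exclusion-zone entries. A cell whose block is
#' entirely excluded is `Inf` (scoring skips such cells).
#'
#' @param x Numeric series.
#' @param m Subsequence length in days (default 3).
#' @param c Context window in subsequences (default 3).
#' @param dates Optional Date vector aligned with `x`.
#' @param exclusion Passed to [distance_matrix()].
#' @param feature Optional feature name carried in the result.
#'
#' @return An object of class `cmp`: a list with `values` (C x C symmetric
#'   matrix), `contexts` (see [build_contexts()]), `feature`, `m`, `c`.
#' @export
cmp_self_join <- function(x, m = 3, c = 3, dates = NULL,
                          exclusion = c("mp_half_m", "none"),
                          feature = NA_character_) {
  exclusion <- match.arg(exclusion)
  ctx <- build_contexts(length(x), m, c, dates)
  if (nrow(ctx) < 2) abort("need at least 2 contexts", class = "cmpad_input_error")
  D <- distance_matrix(x, m, exclusion)
  C <- nrow(ctx)
  V <- matrix(Inf, C, C)
  for (i in seq_len(C)) {
    ri <- ctx$start_idx[i]:ctx$end_idx[i]
    for (j in i:C) {
      blk <- D[ri, ctx$start_idx[j]:ctx$end_idx[j], drop = FALSE]
      fin <- blk[is.finite(blk)]
      V[i, j] <- V[j, i] <- if (length(fin)) min(fin) else Inf
    }
  }
  new_cmp(V, ctx, feature = feature, m = as.integer(m), c = as.integer(c))
}

#' @export
print.cmp <- function(x, ...) {
  cat("<cmp> ", nrow(x$values), "x", ncol(x$values), " contexts",
      if (!is.na(x$feature)) paste0(" [", x$feature, "]"), "\n", sep = "")
  invisible(x)
}

#' Tidy a CMP matrix into long form
#'
#' @param x A `cmp` object.
#' @param ... Unused.
#'
#' @return Tibble `context_i`, `context_j`, `end_date_i`, `end_date_j`,
#'   `distance` (one row per cell, `Inf` cells included).
#' @exportS3Method generics::tidy
tidy.cmp <- function(x, ...) {
  C <- nrow(x$values)
  tibble::tibble(
    context_i = rep(seq_len(C), times = C),
    context_j = rep(seq_len(C), each = C),
    end_date_i = rep(x$contexts$end_date, times = C),
    end_date_j = rep(x$contexts$end_date, each = C),
    distance = as.vector(x$values)
  )
}

#' Heat-map of a CMP matrix
#'
#' Renders the context-by-context minimum-distance matrix; bands of
#' consistently large distance mark anomalous time segments.
#'
#' @param object A `cmp` object.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cmp <- function(object, ...) {
  df <- tidy(object)
  df$distance[!is.finite(df$distance)] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$context_j, y = .data$context_i,
                                   fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "context", y = "context", fill = "min distance",
                  title = if (!is.na(object$feature)) object$feature else NULL) +
    ggplot2::theme_minimal()
}

#' Write a CMP matrix as CSV
#'
#' C x C matrix with ISO end-date row/column headers, suitable for external
#' heat-map rendering.
#'
#' @param cmp A `cmp` object.
#' @param path Output file.
#' @export
write_cmp_csv <- function(cmp, path) {
  hdr <- as.character(cmp$contexts$end_date)
  df <- as.data.frame(cmp$values)
  names(df) <- hdr
  df <- cbind(end_date = hdr, df)
  readr::write_csv(tibble::as_tibble(df), path)
}
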