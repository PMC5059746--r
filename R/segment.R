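## Multivariate changepoint segmentation of windowed evidence tracks.

## Nearest-non-NaN imputation, for segmentation only (reported tracks keep
## their NaNs).
impute_nearest <- function(x) {
  bad <- which(is.na(x))
  good <- which(!is.na(x))
  if (!length(good)) stop_input("track is entirely missing")
  if (length(bad)) {
    nearest <- vapply(bad, function(i) good[which.min(abs(good - i))],
                      integer(1))
    x[bad] <- x[nearest]
  }
  x
}

## Tracks -> z-scored matrix on a verified shared grid.
track_matrix <- function(tracks) {
  if (inherits(tracks, "zw_window_track")) tracks <- list(tracks)
  g <- tracks[[1]]$starts
  for (t in tracks) {
    if (length(t$starts) != length(g) || any(t$starts != g))
      stop_input("tracks must share one window grid")
  }
  X <- vapply(tracks, function(t) impute_nearest(t$values),
              numeric(length(g)))
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) {
    s <- stats::sd(X[, j])
    X[, j] <- if (isTRUE(s > 0)) (X[, j] - mean(X[, j])) / s else X[, j] * 0
  }
  X
}

## Within-segment squared error, all dimensions, via cumulative sums.
seg_cost_fun <- function(X) {
  cs <- apply(X, 2, cumsum)
  cs2 <- apply(X^2, 2, cumsum)
  cs <- rbind(0, cs)
  cs2 <- rbind(0, cs2)
  function(i, j) {   # cost of segment [i, j] inclusive, 1-based
    n <- j - i + 1
    s <- cs[j + 1, ] - cs[i, ]
    s2 <- cs2[j + 1, ] - cs2[i, ]
    sum(s2 - s^2 / n)
  }
}

binseg_breakpoints <- function(X, k) {
  cost <- seg_cost_fun(X)
  n <- nrow(X)
  segs <- list(c(1L, n))
  bps <- integer(0)
  for (step in seq_len(k)) {
    best <- NULL
    for (si in seq_along(segs)) {
      a <- segs[[si]][1]; b <- segs[[si]][2]
      if (b - a < 1L) next
      base <- cost(a, b)
      for (m in a:(b - 1L)) {
        gain <- base - cost(a, m) - cost(m + 1L, b)
        if (is.null(best) || gain > best$gain + 1e-12) {
          best <- list(gain = gain, si = si, m = m)
        }
      }
    }
    if (is.null(best)) break
    a <- segs[[best$si]][1]; b <- segs[[best$si]][2]
    segs[[best$si]] <- c(a, best$m)
    segs[[length(segs) + 1L]] <- c(best$m + 1L, b)
    bps <- sort(c(bps, best$m))
  }
  refine_breakpoints(X, bps)
}

## Cyclic single-breakpoint re-optimization: holding its neighbors fixed,
## each breakpoint is moved to the least-squares optimum of its flanking
## pair of segments, until no move improves the fit.  Greedy binary
## segmentation can misplace an early split on staircase signals; this
## local refinement recovers the exact optimum in such cases.
refine_breakpoints <- function(X, bps, max_iter = 25L) {
  if (!length(bps)) return(bps)
  cost <- seg_cost_fun(X)
  n <- nrow(X)
  for (iter in seq_len(max_iter)) {
    moved <- FALSE
    for (j in seq_along(bps)) {
      lo <- if (j == 1L) 1L else bps[j - 1L] + 1L
      hi <- if (j == length(bps)) n else bps[j + 1L]
      cand <- lo:(hi - 1L)
      cc <- vapply(cand, function(m) cost(lo, m) + cost(m + 1L, hi),
                   numeric(1))
      best <- cand[which.min(cc)]
      if (best != bps[j]) {
        bps[j] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  sort(bps)
}

dp_breakpoints <- function(X, k) {
  cost <- seg_cost_fun(X)
  n <- nrow(X)
  C <- matrix(Inf, k + 1L, n)       # C[m, j]: best cost of X[1..j] in m segs
  back <- matrix(0L, k + 1L, n)
  for (j in 1:n) C[1, j] <- cost(1L, j)
  if (k >= 1L) {
    for (m in 2:(k + 1L)) {
      for (j in m:n) {
        prev <- (m - 1L):(j - 1L)
        vals <- C[m - 1L, prev] + vapply(prev, function(t) cost(t + 1L, j),
                                         numeric(1))
        best <- which.min(vals)
        C[m, j] <- vals[best]
        back[m, j] <- prev[best]
      }
    }
  }
  bps <- integer(0)
  j <- n
  for (m in (k + 1L):2L) {
    bps <- c(back[m, j], bps)
    j <- back[m, j]
  }
  bps
}

segment_total_cost <- function(X, bps) {
  cost <- seg_cost_fun(X)
  edges <- c(0L, sort(bps), nrow(X))
  sum(vapply(seq_len(length(edges) - 1L),
             function(i) cost(edges[i] + 1L, edges[i + 1L]), numeric(1)))
}

#' Segment evidence tracks into strata
#'
#' Multivariate least-squares changepoint detection over one or more
#' windowed tracks sharing a grid.  Each track is z-scored (equal weight)
#' and NaN windows are imputed from their nearest neighbor for the fit
#' only.  Detection is by binary segmentation (default) or an exact
#' dynamic program (`method = "dp"`, the oracle for moderate problem
#' sizes); binary segmentation is followed by cyclic single-breakpoint
#' refinement, which repairs the occasional greedy misplacement on
#' staircase signals.  The number of breakpoints is either fixed (`k`) or
#' chosen by a BIC-style penalty: minimize total cost + `penalty * k'`
#' over `k' <= k_max`.  The default penalty is `3 * log(n) * sum(sigma2)`
#' where each track's noise variance is estimated robustly from the
#' median absolute first difference, so model selection responds to the
#' noise floor rather than to the signal amplitude that z-scoring folds
#' in.
#'
#' @param tracks a [window_track()] or list of them on one grid.
#' @param k fixed number of breakpoints; NULL to select by penalty.
#' @param penalty penalty per breakpoint when `k` is NULL.
#' @param k_max largest breakpoint count considered under the penalty.
#' @param method `"binseg"` or `"dp"`.
#' @return list of class `zw_segmentation`: `breakpoints` (bp positions on
#'   the chromosome, at window boundaries), `window_index` (last window of
#'   each left segment), `cost`, `chrom`, `window_size`, `n_windows`.
#' @export
segment_strata <- function(tracks, k = 2L, penalty = NULL, k_max = 6L,
                           method = c("binseg", "dp")) {
  method <- match.arg(method)
  if (inherits(tracks, "zw_window_track")) tracks <- list(tracks)
  X <- track_matrix(tracks)
  n <- nrow(X)
  find <- function(kk) if (kk == 0L) integer(0) else
    switch(method, binseg = binseg_breakpoints(X, kk),
           dp = dp_breakpoints(X, kk))
  if (!is.null(k)) {
    if (n < k + 1L) stop_input("fewer windows (%d) than breakpoints+1", n)
    bps <- find(as.integer(k))
  } else {
    ## noise variance per (z-scored) track from median absolute first
    ## differences, so the penalty scales with the noise rather than with
    ## the signal the z-scoring folds in
    sigma2 <- vapply(seq_len(ncol(X)), function(j)
      (stats::mad(diff(X[, j])) / sqrt(2))^2, numeric(1))
    pen <- penalty %||% (3 * log(n) * sum(sigma2))
    cand <- lapply(0:min(k_max, n - 1L), find)
    tot <- vapply(seq_along(cand), function(i)
      segment_total_cost(X, cand[[i]]) + pen * (i - 1L), numeric(1))
    bps <- cand[[which.min(tot)]]
  }
  t1 <- tracks[[1]]
  out <- list(breakpoints = t1$starts[bps] + t1$window_size,
              window_index = bps,
              cost = segment_total_cost(X, bps),
              chrom = t1$chrom, window_size = t1$window_size, n_windows = n)
  class(out) <- "zw_segmentation"
  out
}

#' @export
print.zw_segmentation <- function(x, ...) {
  cat(sprintf("zw_segmentation: %s, %d breakpoint(s) at %s (cost %.3g)\n",
              x$chrom, length(x$breakpoints),
              paste(format(x$breakpoints, big.mark = ",",
                           scientific = FALSE, trim = TRUE),
                    collapse = ", "),
              x$cost))
  invisible(x)
}

#' Label segments as PAR and age-ranked strata
#'
#' Segments whose mean female:autosome depth ratio is close to 1 (within
#' `par_band`) are recombining pseudoautosomal regions; the remaining
#' segments are ranked by mean Z/W divergence, descending, as S1 (oldest),
#' S2, ... .  Segments with no divergence evidence at all are labelled
#' UNRANKED.
#'
#' @param segmentation a [segment_strata()] result (or numeric breakpoint
#'   bp positions plus `chrom_len`).
#' @param divergence a divergence [window_track()].
#' @param depth_ratio a depth-ratio [window_track()] on the same grid, or
#'   NULL to skip PAR detection.
#' @param par_band depth-ratio band treated as recombining.
#' @param chrom_len chromosome length, required when `segmentation` is a
#'   bare breakpoint vector.
#' @return data frame of class `zw_strata`: start, end, label,
#'   mean_divergence, mean_depth_ratio.
#' @export
label_strata <- function(segmentation, divergence, depth_ratio = NULL,
                         par_band = c(0.85, 1.15), chrom_len = NULL) {
  if (inherits(segmentation, "zw_segmentation")) {
    bps <- segmentation$breakpoints
    chrom_len <- chrom_len %||%
      (divergence$starts[length(divergence$starts)] + divergence$window_size)
  } else {
    bps <- as.numeric(segmentation)
    if (is.null(chrom_len)) stop_input("chrom_len required with bare breakpoints")
  }
  edges <- c(0, sort(bps), chrom_len)
  seg_mean <- function(track, lo, hi) {
    if (is.null(track)) return(NA_real_)
    sel <- track$starts >= lo & track$starts < hi
    v <- track$values[sel]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  n_seg <- length(edges) - 1L
  mdiv <- mdr <- numeric(n_seg)
  for (i in seq_len(n_seg)) {
    mdiv[i] <- seg_mean(divergence, edges[i], edges[i + 1])
    mdr[i] <- seg_mean(depth_ratio, edges[i], edges[i + 1])
  }
  is_par <- !is.na(mdr) & mdr >= par_band[1] & mdr <= par_band[2]
  label <- rep(NA_character_, n_seg)
  label[is_par] <- "PAR"
  strat <- which(!is_par)
  ranked <- strat[order(-mdiv[strat], na.last = TRUE)]
  label[ranked] <- paste0("S", seq_along(ranked))
  label[!is_par & is.na(mdiv)] <- "UNRANKED"
  out <- data.frame(start = edges[-length(edges)], end = edges[-1],
                    label = label, mean_divergence = mdiv,
                    mean_depth_ratio = mdr)
  class(out) <- c("zw_strata", "data.frame")
  out
}

## Grid-halving/restoring helpers: refine a track to half-size windows
## (each value duplicated) and aggregate pairs back by mean.
track_refine2 <- function(track) {
  w <- track$window_size / 2
  window_track(track$chrom, w,
               rep(track$starts, each = 2) + c(0, w),
               rep(track$values, each = 2))
}

track_coarsen2 <- function(track) {
  n <- length(track$starts)
  stopifnot(n %% 2 == 0)
  v <- track$values
  pair <- matrix(v, nrow = 2)
  window_track(track$chrom, track$window_size * 2,
               track$starts[seq(1, n, by = 2)], colMeans(pair))
}
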