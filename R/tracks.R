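#' Windowed value track along a chromosome
#'
#' A fixed-grid track: consecutive windows of `window_size` starting at 0,
#' values possibly NaN where no evidence falls in a window.
#'
#' @param chrom chromosome name.
#' @param window_size window size in bp.
#' @param starts 0-based half-open window starts (strictly increasing,
#'   constant step `window_size`).
#' @param values numeric values, one per window (NaN = missing).
#' @return object of class `zw_window_track`.
#' @export
window_track <- function(chrom, window_size, starts, values) {
  if (length(starts) != length(values))
    stop_input("starts and values must have equal length")
  if (length(starts) > 1L && any(diff(starts) != window_size))
    stop_input("starts must advance by exactly window_size")
  structure(list(chrom = chrom, window_size = window_size,
                 starts = as.numeric(starts), values = as.numeric(values)),
            class = "zw_window_track")
}

#' @export
print.zw_window_track <- function(x, ...) {
  cat(sprintf("zw_window_track: %s, %d windows of %.3g bp, %d missing\n",
              x$chrom, length(x$starts), x$window_size,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
as.data.frame.zw_window_track <- function(x, ...) {
  data.frame(chrom = x$chrom, start = x$starts,
             end = x$starts + x$window_size, value = x$values)
}

track_grid <- function(chrom_len, window) {
  seq(0, chrom_len - 1, by = window)
}

## Length-weighted mean of interval values per window of a fixed grid.
weighted_track <- function(starts, ends, values, chrom_len, window, chrom) {
  grid <- track_grid(chrom_len, window)
  num <- numeric(length(grid))
  den <- numeric(length(grid))
  if (length(starts)) {
    ends <- pmin(ends, chrom_len)
    w1 <- findInterval(starts, grid)
    w2 <- findInterval(ends - 1e-9, grid)
    same <- w1 == w2          # vectorized fast path: interval within a window
    if (any(same)) {
      ov <- (ends - starts)[same]
      num_add <- tapply(ov * values[same], w1[same], sum)
      den_add <- tapply(ov, w1[same], sum)
      idx <- as.integer(names(num_add))
      num[idx] <- num[idx] + as.numeric(num_add)
      den[idx] <- den[idx] + as.numeric(den_add)
    }
    for (i in which(!same)) {
      for (w in w1[i]:w2[i]) {
        ov <- overlap_bp(grid[w], grid[w] + window, starts[i], ends[i])
        num[w] <- num[w] + ov * values[i]
        den[w] <- den[w] + ov
      }
    }
  }
  vals <- ifelse(den > 0, num / den, NaN)
  window_track(chrom, window, grid, vals)
}

#' Relative depth track along a chromosome
#'
#' Window mean depth divided by the median depth of autosomal scaffolds:
#' ~1 on autosomes and recombining PARs, ~0.5 on the female side of a fully
#' differentiated sex-linked region.
#'
#' @param depth a depth table (scaffold, start, end, depth).
#' @param calls a `zw_sex_calls` frame (or data frame scaffold/label)
#'   providing the autosomal scaffold set for normalization.
#' @param layout data frame scaffold/chrom/chrom_start placing scaffolds on
#'   chromosomes (e.g. `model$scaffolds` or a pseudo-chromosome map).
#' @param chrom chromosome to build the track for.
#' @param window window size in bp.
#' @return a [window_track()].
#' @export
depth_ratio_track <- function(depth, calls, layout, chrom = "chrZ",
                              window = 1e6) {
  auto <- calls$scaffold[calls$label == "AUTO"]
  if (!length(auto)) stop_input("no autosomal scaffolds to normalize against")
  med <- stats::median(depth$depth[depth$scaffold %in% auto])
  if (!isTRUE(med > 0)) stop_input("autosomal median depth is zero")
  li <- match(depth$scaffold, layout$scaffold)
  on_chrom <- !is.na(li) & layout$chrom[li] == chrom
  d <- depth[on_chrom, , drop = FALSE]
  if (!nrow(d)) stop_input("no depth windows on chromosome '%s'", chrom)
  gs <- layout$chrom_start[li[on_chrom]] + d$start
  ge <- layout$chrom_start[li[on_chrom]] + d$end
  chrom_len <- if ("chrom_end" %in% names(layout))
    max(layout$chrom_end[layout$chrom == chrom]) else max(ge)
  weighted_track(gs, ge, d$depth / med, chrom_len, window, chrom)
}

#' Z/W divergence track
#'
#' Per-window length-weighted mean pairwise divergence of Z/W alignment
#' fragments anchored on the Z.  Fragments either carry sequences (columns
#' z_seq/w_seq) or precomputed counts (n_diff/n_sites).  Windows without
#' any fragment are NaN.
#'
#' @param alignments data frame with z_start, z_end and either z_seq/w_seq
#'   or n_diff/n_sites.
#' @param chrom_len Z chromosome length in bp.
#' @param window window size in bp.
#' @param model divergence model, `"p"` (default) or `"K2P"`.
#' @param chrom chromosome name for the track.
#' @return a [window_track()].
#' @export
divergence_track <- function(alignments, chrom_len, window = 1e6,
                             model = c("p", "K2P"), chrom = "chrZ") {
  model <- match.arg(model)
  a <- alignments
  if (nrow(a) && (any(a$z_start < 0) || any(a$z_end > chrom_len)))
    stop_input("alignment anchor outside the chromosome")
  div <- if (all(c("n_diff", "n_sites") %in% names(a))) {
    a$n_diff / pmax(a$n_sites, 1)
  } else {
    vapply(seq_len(nrow(a)), function(i)
      pairwise_divergence(c(a$z_seq[i], a$w_seq[i]), model = model),
      numeric(1))
  }
  weighted_track(a$z_start, a$z_end, div, chrom_len, window, chrom)
}

#' W-fragment density track
#'
#' Fraction of each Z window covered by identifiable W-derived fragments
#' (intervals merged before counting coverage).  High density marks
#' recently recombination-suppressed regions where the W still aligns.
#'
#' @param placements data frame of W placements on the Z (z_start, z_end
#'   or start, end).
#' @param chrom_len Z chromosome length in bp.
#' @param window window size in bp (1 Mb by convention).
#' @param chrom chromosome name.
#' @return a [window_track()].
#' @export
wfragment_density_track <- function(placements, chrom_len, window = 1e6,
                                    chrom = "chrZ") {
  s <- placements$z_start %||% placements$start
  e <- placements$z_end %||% placements$end
  grid <- track_grid(chrom_len, window)
  vals <- numeric(length(grid))
  if (length(s)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = round(s) + 1L,
                                           end = round(e)))
    ms <- IRanges::start(ir) - 1L
    me <- IRanges::end(ir)
    for (w in seq_along(grid)) {
      vals[w] <- sum(overlap_bp(grid[w], grid[w] + window, ms, me))
    }
  }
  window_track(chrom, window, grid, pmin(vals / window, 1))
}

#' Toy pairwise alignment score
#'
#' Per-bp score of an existing (gapped) pairwise alignment: match +1,
#' mismatch -1, gap -2, divided by alignment length.  Used to score
#' synthetic cross-species sequence pairs in place of an external
#' whole-genome aligner, whose score tables are otherwise ingested as-is.
#'
#' @param seq_a,seq_b aligned sequences of equal length (may contain `-`).
#' @return the normalized per-bp score; NaN for zero-length input.
#' @export
toy_align_score <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop_input("sequences must be aligned (equal length)")
  if (!length(a)) return(NaN)
  gap <- a == "-" | b == "-"
  sum(ifelse(gap, -2, ifelse(a == b, 1, -1))) / length(a)
}

#' Cross-species conservation track
#'
#' Grids an ingested per-window alignment-score table (columns start, end,
#' score) onto the track grid, length-weighting scores that span windows.
#'
#' @param scores data frame: start, end, score.
#' @param chrom_len chromosome length in bp.
#' @param window window size in bp.
#' @param chrom chromosome name.
#' @return a [window_track()].
#' @export
conservation_track <- function(scores, chrom_len, window = 1e6,
                               chrom = "chrZ") {
  weighted_track(scores$start, scores$end, scores$score, chrom_len, window,
                 chrom)
}

#' Repeat density track
#'
#' Fraction of each window covered by repeat intervals of one family
#' (overlaps merged before counting), by convention in 100-kb windows.
#'
#' @param bed repeat frame from [read_repeat_bed()] or
#'   [simulate_repeats()].
#' @param chrom_len chromosome length in bp.
#' @param window window size in bp.
#' @param family restrict to one repeat family (NULL = all).
#' @param chrom chromosome to build the track for.
#' @return a [window_track()].
#' @export
repeat_density_track <- function(bed, chrom_len, window = 1e5,
                                 family = NULL, chrom = "chrZ") {
  b <- bed[bed$chrom == chrom, , drop = FALSE]
  if (!is.null(family)) b <- b[b$family == family, , drop = FALSE]
  wfragment_density_track(
    data.frame(start = b$start, end = pmin(b$end, chrom_len)),
    chrom_len, window, chrom)
}

#' Repeat divergence profile per stratum segment
#'
#' Bins the percent divergence of repeat copies (from their family
#' consensus) into 2%-wide bins within each stratum segment; old strata
#' show older, more diverged copies.  Intervals are assigned to the
#' segment containing their midpoint.
#'
#' @param bed repeat frame with a divergence column.
#' @param segments data frame start/end/label (e.g. from [label_strata()]
#'   or a ground-truth stratum map with column `stratum`).
#' @param bin_width divergence bin width in percent.
#' @param family optional family restriction.
#' @param chrom chromosome name.
#' @return list: `histogram` (data frame label/bin_lo/bin_hi/n) and
#'   `means` (data frame label/mean_divergence/n).
#' @export
repeat_divergence_profile <- function(bed, segments, bin_width = 2,
                                      family = NULL, chrom = "chrZ") {
  lab <- segments$label %||% segments$stratum
  b <- bed[bed$chrom == chrom, , drop = FALSE]
  if (!is.null(family)) b <- b[b$family == family, , drop = FALSE]
  mid <- (b$start + b$end) / 2
  seg_of <- rep(NA_character_, nrow(b))
  for (j in seq_along(lab))
    seg_of[mid >= segments$start[j] & mid < segments$end[j]] <- lab[j]
  hist_rows <- list()
  mean_rows <- list()
  for (l in lab) {
    d <- b$divergence[!is.na(seg_of) & seg_of == l]
    mean_rows[[l]] <- data.frame(
      label = l, mean_divergence = if (length(d)) mean(d) else NA_real_,
      n = length(d))
    if (!length(d)) next
    lo <- floor(d / bin_width) * bin_width
    tab <- table(lo)
    hist_rows[[l]] <- data.frame(label = l,
                                 bin_lo = as.numeric(names(tab)),
                                 bin_hi = as.numeric(names(tab)) + bin_width,
                                 n = as.integer(tab))
  }
  list(histogram = if (length(hist_rows)) do.call(rbind, hist_rows) else
         data.frame(label = character(), bin_lo = numeric(),
                    bin_hi = numeric(), n = integer()),
       means = do.call(rbind, mean_rows))
}
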