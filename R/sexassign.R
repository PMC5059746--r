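#' Per-scaffold coverage statistics from two-sex depth tables
#'
#' Computes, for each scaffold, the fraction of non-gap length covered by at
#' least one read and the mean depth, separately for the female and male
#' libraries.  Depth tables are windowed (`scaffold start end depth`); a
#' window counts as covered when its depth is positive.  Assembly gaps can
#' be excluded from the denominators via `gap_bp`.
#'
#' @param depth_f,depth_m depth tables as from [read_depth_table()] or
#'   [simulate_depth()].
#' @param lengths named numeric vector of scaffold lengths, or a data frame
#'   with columns scaffold and length.
#' @param gap_bp optional named vector of assembly-gap bp per scaffold.
#' @return data frame of class `zw_coverage_stats`: scaffold, length,
#'   covered_frac_f, covered_frac_m, mean_depth_f, mean_depth_m.
#' @export
summarize_coverage <- function(depth_f, depth_m, lengths, gap_bp = NULL) {
  if (is.data.frame(lengths))
    lengths <- stats::setNames(lengths$length, lengths$scaffold)
  per_sex <- function(depth) {
    miss <- setdiff(unique(depth$scaffold), names(lengths))
    if (length(miss))
      stop_input("scaffold '%s' present in depth table but not in lengths",
                 miss[1])
    w <- depth$end - depth$start
    cov_bp <- tapply(w * (depth$depth > 0), depth$scaffold, sum)
    dp_bp <- tapply(w * depth$depth, depth$scaffold, sum)
    tot_bp <- tapply(w, depth$scaffold, sum)
    data.frame(scaffold = names(cov_bp), cov_bp = as.numeric(cov_bp),
               dp_bp = as.numeric(dp_bp), tot_bp = as.numeric(tot_bp))
  }
  f <- per_sex(depth_f)
  m <- per_sex(depth_m)
  scafs <- names(lengths)
  gaps <- if (is.null(gap_bp)) stats::setNames(numeric(length(scafs)), scafs)
          else gap_bp
  eff_len <- pmax(lengths - gaps[scafs], 0)
  fi <- match(scafs, f$scaffold)
  mi <- match(scafs, m$scaffold)
  val <- function(tab, idx, col) ifelse(is.na(idx), 0, tab[[col]][idx])
  out <- data.frame(
    scaffold = scafs,
    length = as.numeric(lengths),
    covered_frac_f = pmin(val(f, fi, "cov_bp") / pmax(eff_len, 1), 1),
    covered_frac_m = pmin(val(m, mi, "cov_bp") / pmax(eff_len, 1), 1),
    mean_depth_f = val(f, fi, "dp_bp") / pmax(val(f, fi, "tot_bp"), 1),
    mean_depth_m = val(m, mi, "dp_bp") / pmax(val(m, mi, "tot_bp"), 1))
  class(out) <- c("zw_coverage_stats", "data.frame")
  out
}

#' Scaled male:female depth ratio
#'
#' Each sex's scaffold depth is normalized by that sex's autosomal
#' reference depth (`norm_m`, `norm_f`; typically the median depth over
#' autosomal scaffolds), removing library-size differences.  A fully
#' Z-linked scaffold (two male copies, one female copy) then expects a
#' ratio of 2, an autosome 1 and a W scaffold 0.  A scaffold with zero
#' female depth returns `Inf`.
#'
#' @param stats a `zw_coverage_stats` data frame (or any frame with
#'   mean_depth_f / mean_depth_m).
#' @param norm_f,norm_m positive per-sex normalization depths.
#' @return numeric vector of scaled M:F ratios, one per scaffold.
#' @export
scaled_mf_ratio <- function(stats, norm_f, norm_m) {
  if (!is.numeric(norm_f) || !is.numeric(norm_m) || norm_f <= 0 || norm_m <= 0)
    stop_input("normalization depths must be positive")
  m <- stats$mean_depth_m / norm_m
  f <- stats$mean_depth_f / norm_f
  ifelse(f == 0 & m == 0, NaN, ifelse(f == 0, Inf, m / f))
}

#' Default classification thresholds
#'
#' The standard rule set: scaffolds shorter than 500 bp or with less than
#' 80% alignment coverage are ineligible; a Z call requires the scaled M:F
#' ratio within 20% of 2 (1.6--2.4, boundaries inclusive); a W call
#' requires >80% female coverage and <20% male coverage; the autosomal
#' window mirrors the Z tolerance around 1 (0.8--1.2).
#'
#' @return named list of thresholds.
#' @export
sex_thresholds <- function() {
  list(min_len = 500, min_cov = 0.8,
       z_window = c(1.6, 2.4), auto_window = c(0.8, 1.2),
       w_f_cov = 0.8, w_m_cov = 0.2)
}

#' Classify one or more scaffolds from coverage evidence
#'
#' Rules fire in order: (1) the W rule -- covered by female reads over
#' `w_f_cov` of the length and by male reads below `w_m_cov` -- is tested
#' before the eligibility filter because W scaffolds fail male coverage by
#' construction; (2) scaffolds shorter than `min_len` or with coverage (in
#' the better-covered sex) below `min_cov` are excluded; (3) the Z window,
#' then (4) the autosomal window on the scaled ratio; anything else is
#' UNASSIGNED.
#'
#' @param stats a `zw_coverage_stats` data frame.
#' @param ratio scaled M:F ratios from [scaled_mf_ratio()].
#' @param thresholds see [sex_thresholds()].
#' @return data frame of class `zw_sex_calls`: scaffold, length, label
#'   (Z/W/AUTO/UNASSIGNED), mf_scaled_ratio, evidence.
#' @export
classify_scaffold <- function(stats, ratio, thresholds = sex_thresholds()) {
  th <- utils::modifyList(sex_thresholds(), thresholds)
  n <- nrow(stats)
  label <- rep("UNASSIGNED", n)
  evidence <- rep("no rule matched", n)

  is_w <- stats$covered_frac_f > th$w_f_cov & stats$covered_frac_m < th$w_m_cov
  cov_best <- pmax(stats$covered_frac_f, stats$covered_frac_m)
  too_short <- stats$length < th$min_len
  low_cov <- cov_best < th$min_cov
  is_z <- !is.na(ratio) & is.finite(ratio) &
    ratio >= th$z_window[1] & ratio <= th$z_window[2]
  is_auto <- !is.na(ratio) & is.finite(ratio) &
    ratio >= th$auto_window[1] & ratio <= th$auto_window[2]

  label[is_w] <- "W"
  evidence[is_w] <- sprintf("W rule: f_cov>%.2g, m_cov<%.2g",
                            th$w_f_cov, th$w_m_cov)
  rest <- !is_w
  excl <- rest & (too_short | low_cov)
  label[excl] <- "UNASSIGNED"
  evidence[excl & too_short] <- sprintf("excluded: length < %d bp", th$min_len)
  evidence[excl & !too_short] <- sprintf("excluded: coverage < %.2g", th$min_cov)
  ok <- rest & !excl
  label[ok & is_z] <- "Z"
  evidence[ok & is_z] <- sprintf("Z window [%.2g, %.2g]",
                                 th$z_window[1], th$z_window[2])
  oa <- ok & !is_z & is_auto
  label[oa] <- "AUTO"
  evidence[oa] <- sprintf("AUTO window [%.2g, %.2g]",
                          th$auto_window[1], th$auto_window[2])

  out <- data.frame(scaffold = stats$scaffold, length = stats$length,
                    label = label, mf_scaled_ratio = ratio,
                    evidence = evidence)
  class(out) <- c("zw_sex_calls", "data.frame")
  out
}

## Length-weighted median.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

## Exact 1-D 2-means: best split of sorted values minimizing within-SS.
## Returns the threshold (midpoint) and the two cluster means.
best_split_1d <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 2L) return(list(threshold = Inf, lo = mean(x), hi = mean(x)))
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(a, b) {      # within-SS of x[a..b]
    s <- cs[b] - if (a > 1) cs[a - 1] else 0
    s2 <- cs2[b] - if (a > 1) cs2[a - 1] else 0
    s2 - s^2 / (b - a + 1)
  }
  tot <- vapply(1:(n - 1), function(m) sse(1, m) + sse(m + 1, n), numeric(1))
  m <- which.min(tot)
  list(threshold = (x[m] + x[m + 1]) / 2,
       lo = mean(x[1:m]), hi = mean(x[(m + 1):n]))
}

#' Classify all scaffolds with two-pass normalization, and summarize
#'
#' The scaled-ratio normalization depth of each sex is not known a priori:
#' sex-linked content skews genome-wide totals, and when sex-linked bp
#' rivals autosomal bp a plain median falls between the autosomal and
#' Z-linked depth modes.  Pass 1 therefore identifies a provisional
#' autosomal set structurally: raw M:F ratios (library-size normalized by
#' each sex's length-weighted mean depth, W-rule scaffolds excluded) are
#' split on the log2 scale by an exact two-means partition, and the
#' lower-ratio cluster -- autosomes always sit below Z-linked scaffolds --
#' is taken as provisionally autosomal (when the two cluster centres lie
#' within 0.5 log2 units there is no Z-linked cluster and everything is
#' provisional-autosomal).  Pass 2 normalizes each sex by the
#' length-weighted median depth of that set, applies the absolute windows
#' via [classify_scaffold()], then re-derives the norms from the final
#' AUTO calls.  The summary reports scaffold count, total bp and N50 per
#' label.
#'
#' @inheritParams classify_scaffold
#' @return list of class `zw_classification`: `calls` (a `zw_sex_calls`
#'   frame), `summary` (data frame label/n/total_bp/n50) and `norms`
#'   (final per-sex normalization depths).
#' @export
classify_all <- function(stats, thresholds = sex_thresholds()) {
  if (!nrow(stats)) stop_input("no scaffolds to classify")
  th <- utils::modifyList(sex_thresholds(), thresholds)
  w_rule <- stats$covered_frac_f > th$w_f_cov &
    stats$covered_frac_m < th$w_m_cov
  eligible <- !w_rule & stats$length >= th$min_len &
    pmax(stats$covered_frac_f, stats$covered_frac_m) >= th$min_cov &
    stats$mean_depth_f > 0 & stats$mean_depth_m > 0
  base <- if (any(eligible)) stats[eligible, , drop = FALSE] else
    stats[stats$mean_depth_f > 0 & stats$mean_depth_m > 0, , drop = FALSE]
  if (!nrow(base))
    stop_input("cannot derive normalization depths: no covered scaffolds")

  ## pass 1: provisional autosomes from the log-ratio structure
  lib_f <- sum(base$mean_depth_f * base$length) / sum(base$length)
  lib_m <- sum(base$mean_depth_m * base$length) / sum(base$length)
  lr <- log2(scaled_mf_ratio(base, lib_f, lib_m))
  sp <- best_split_1d(lr)
  provisional <- if (sp$hi - sp$lo >= 0.5) lr <= sp$threshold else
    rep(TRUE, nrow(base))
  norm_f <- weighted_median(base$mean_depth_f[provisional],
                            base$length[provisional])
  norm_m <- weighted_median(base$mean_depth_m[provisional],
                            base$length[provisional])

  ## pass 2: absolute windows, then re-derive norms from the AUTO calls
  pass2 <- classify_scaffold(stats, scaled_mf_ratio(stats, norm_f, norm_m), th)
  auto <- pass2$label == "AUTO"
  if (any(auto)) {
    norm_f <- weighted_median(stats$mean_depth_f[auto], stats$length[auto])
    norm_m <- weighted_median(stats$mean_depth_m[auto], stats$length[auto])
  } else {
    warning("no autosomal calls; keeping provisional-cluster normalization")
  }
  calls <- classify_scaffold(stats, scaled_mf_ratio(stats, norm_f, norm_m), th)

  labs <- c("Z", "W", "AUTO", "UNASSIGNED")
  summ <- do.call(rbind, lapply(labs, function(l) {
    len <- calls$length[calls$label == l]
    data.frame(label = l, n = length(len), total_bp = sum(len),
               n50 = if (length(len)) compute_n50(len) else NA_real_)
  }))
  out <- list(calls = calls, summary = summ,
              norms = c(norm_f = norm_f, norm_m = norm_m))
  class(out) <- "zw_classification"
  out
}

#' @export
print.zw_classification <- function(x, ...) {
  cat("scaffold sex-linkage classification\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Assembly N50
#'
#' The largest length L such that pieces of length >= L together cover at
#' least half the total.
#'
#' @param lengths positive lengths.
#' @return the N50 in the input's units.
#' @export
compute_n50 <- function(lengths) {
  if (!length(lengths)) stop_input("empty length set")
  if (any(!is.finite(lengths) | lengths <= 0))
    stop_input("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Link scaffolds into a pseudo-chromosome
#'
#' Concatenates ordered, oriented scaffolds with 600 `N`s between adjacent
#' scaffolds, the convention used when anchoring scaffolds to a reference
#' karyotype.  `-`-oriented scaffolds are reverse-complemented.
#'
#' @param order_tbl data frame with columns scaffold and orientation
#'   (`"+"`/`"-"`).
#' @param sequences a named [Biostrings::DNAStringSet] (or named character
#'   vector) holding every ordered scaffold.
#' @param gap_n number of `N`s between adjacent scaffolds.
#' @return list: `seq` (a [Biostrings::DNAString]) and `map` (data frame
#'   scaffold/start/end/orientation, 0-based half-open, non-overlapping and
#'   sorted).
#' @export
build_pseudochromosome <- function(order_tbl, sequences, gap_n = 600) {
  if (anyDuplicated(order_tbl$scaffold))
    stop_input("duplicate scaffold id '%s' in order table",
               order_tbl$scaffold[duplicated(order_tbl$scaffold)][1])
  if (!all(order_tbl$orientation %in% c("+", "-")))
    stop_input("orientation must be '+' or '-'")
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  miss <- setdiff(order_tbl$scaffold, names(sequences))
  if (length(miss)) stop_input("no sequence for scaffold '%s'", miss[1])

  seqs <- sequences[order_tbl$scaffold]
  flip <- order_tbl$orientation == "-"
  if (any(flip)) seqs[flip] <- Biostrings::reverseComplement(seqs[flip])
  lens <- Biostrings::width(seqs)
  starts <- cumsum(c(0, lens[-length(lens)] + gap_n))
  gap <- paste(rep("N", gap_n), collapse = "")
  seq <- Biostrings::DNAString(
    paste(as.character(seqs), collapse = gap))
  map <- data.frame(scaffold = order_tbl$scaffold, start = starts,
                    end = starts + lens, orientation = order_tbl$orientation)
  list(seq = seq, map = map)
}
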