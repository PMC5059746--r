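#' Read a variant table from a VCF
#'
#' Parses CHROM, POS, QUAL, INFO DP (falling back to the first sample's
#' FORMAT DP) and the first sample's GT.  Genotypes with two identical
#' alleles are homozygous; any two different alleles (0/1, 1/2, phased or
#' not) are heterozygous.  Records with missing or malformed genotypes are
#' dropped and counted in the `n_malformed` attribute.
#'
#' @param path VCF file (plain text).
#' @return data frame: scaffold, pos, qual, depth, genotype ("het"/"hom"),
#'   with attribute `n_malformed`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop_input("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  if (all(is.na(dp)) && ncol(v@gt) > 1L) {
    dpg <- tryCatch(vcfR::extract.gt(v, "DP"), error = function(e) NULL)
    if (!is.null(dpg)) dp <- suppressWarnings(as.numeric(dpg[, 1]))
  }
  gt <- tryCatch(vcfR::extract.gt(v, "GT")[, 1], error = function(e)
    rep(NA_character_, nrow(fix)))
  alleles <- strsplit(gt, "[/|]")
  genotype <- vapply(alleles, function(a) {
    if (length(a) != 2L || anyNA(a) || any(a == ".")) return(NA_character_)
    if (a[1] == a[2]) "hom" else "het"
  }, character(1))
  out <- data.frame(scaffold = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                    depth = dp, genotype = genotype)
  bad <- is.na(out$genotype)
  attr_n <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- attr_n
  out
}

#' Filter variants on depth and quality
#'
#' Keeps variants whose read depth lies within `depth_range` (inclusive at
#' both bounds) and whose quality is at least `min_qual` -- the standard
#' criteria for excluding collapsed repeats, low-coverage noise and
#' low-confidence calls before heterozygosity estimation.  Records with
#' missing depth or quality are dropped and counted in the `n_malformed`
#' attribute.  The filter is idempotent.
#'
#' @param variants data frame with columns depth and qual.
#' @param depth_range inclusive depth bounds, default `c(10, 120)`.
#' @param min_qual minimum quality, default 100.
#' @return the filtered data frame.
#' @export
filter_variants <- function(variants, depth_range = c(10, 120),
                            min_qual = 100) {
  bad <- is.na(variants$depth) | is.na(variants$qual)
  v <- variants[!bad, , drop = FALSE]
  keep <- v$depth >= depth_range[1] & v$depth <= depth_range[2] &
    v$qual >= min_qual
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Callable sites from a depth table
#'
#' The heterozygosity denominator: bp whose depth lies within the same
#' bounds used by the variant filter, counted per scaffold from the
#' windowed depth table.
#'
#' @param depth a depth table (scaffold, start, end, depth).
#' @param depth_range inclusive depth bounds.
#' @return data frame: scaffold, n_callable.
#' @export
callable_sites <- function(depth, depth_range = c(10, 120)) {
  w <- depth$end - depth$start
  ok <- depth$depth >= depth_range[1] & depth$depth <= depth_range[2]
  n <- tapply(w * ok, depth$scaffold, sum)
  data.frame(scaffold = names(n), n_callable = as.numeric(n))
}

#' Heterozygosity per chromosome class
#'
#' Aggregates filtered heterozygous calls and callable sites over a region
#' map assigning scaffolds to classes (AUTO/Z/W), yielding one rate per
#' class.  A class with zero callable sites gets an NA rate and is flagged
#' in the `flagged` column.
#'
#' @param variants filtered variant frame (with `genotype`).
#' @param callable data frame scaffold/n_callable from [callable_sites()].
#' @param region_map data frame with columns scaffold and region_class (or
#'   a `zw_sex_calls` frame, whose `label` is used).
#' @return data frame: region_class, n_callable, n_het, rate, rate_percent,
#'   flagged.
#' @export
het_rate <- function(variants, callable, region_map) {
  if (inherits(region_map, "zw_sex_calls") ||
      (!"region_class" %in% names(region_map) && "label" %in% names(region_map)))
    region_map <- data.frame(scaffold = region_map$scaffold,
                             region_class = region_map$label)
  cls <- function(scafs) region_map$region_class[
    match(scafs, region_map$scaffold)]
  het <- variants[variants$genotype == "het", , drop = FALSE]
  n_het <- tapply(rep(1, nrow(het)), cls(het$scaffold), sum)
  n_call <- tapply(callable$n_callable, cls(callable$scaffold), sum)
  classes <- sort(unique(stats::na.omit(region_map$region_class)))
  nh <- ifelse(is.na(match(classes, names(n_het))), 0,
               as.numeric(n_het[match(classes, names(n_het))]))
  nc <- ifelse(is.na(match(classes, names(n_call))), 0,
               as.numeric(n_call[match(classes, names(n_call))]))
  rate <- ifelse(nc > 0, nh / nc, NA_real_)
  data.frame(region_class = classes, n_callable = nc, n_het = nh,
             rate = rate, rate_percent = 100 * rate, flagged = nc == 0)
}

#' Windowed heterozygosity rates
#'
#' Per-window rates along scaffolds, the pairing unit for the signed-rank
#' comparison between sexes.  Windows with no callable sites get NA.
#'
#' @param variants filtered variant frame.
#' @param depth the same-sex depth table (for callable sites per window).
#' @param window window size in bp.
#' @param depth_range inclusive callable-depth bounds.
#' @param scaffolds optional restriction to a scaffold subset.
#' @return data frame: scaffold, start, end, n_callable, n_het, rate.
#' @export
windowed_het_rates <- function(variants, depth, window = 1e6,
                               depth_range = c(10, 120), scaffolds = NULL) {
  if (!is.null(scaffolds)) {
    variants <- variants[variants$scaffold %in% scaffolds, , drop = FALSE]
    depth <- depth[depth$scaffold %in% scaffolds, , drop = FALSE]
  }
  out <- list()
  for (sc in unique(depth$scaffold)) {
    d <- depth[depth$scaffold == sc, , drop = FALSE]
    v <- variants[variants$scaffold == sc & variants$genotype == "het", ,
                  drop = FALSE]
    len <- max(d$end)
    t <- tile_intervals(len, window)
    wi_d <- findInterval(d$start, t$start)
    ok <- d$depth >= depth_range[1] & d$depth <= depth_range[2]
    ncall <- tapply((d$end - d$start) * ok, factor(wi_d, seq_len(nrow(t))),
                    sum, default = 0)
    wi_v <- findInterval(v$pos - 1L, t$start)
    nhet <- tapply(rep(1, nrow(v)), factor(wi_v, seq_len(nrow(t))),
                   sum, default = 0)
    out[[sc]] <- data.frame(scaffold = sc, start = t$start, end = t$end,
                            n_callable = as.numeric(ncall),
                            n_het = as.numeric(nhet),
                            rate = ifelse(ncall > 0,
                                          as.numeric(nhet) / as.numeric(ncall),
                                          NA_real_))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired signed-rank comparison of windowed heterozygosity
#'
#' Two-sided Wilcoxon signed-rank test on paired window rates.
#' Zero differences are excluded (Wilcoxon's original rule); when every
#' pair is tied the comparison is vacuous and p = 1 with a warning.  The
#' exact null distribution is used up to `exact_n` informative pairs, the
#' normal approximation with continuity correction beyond.
#'
#' @param rates_a,rates_b paired per-window rates (same length/order).
#' @param exact_n largest n for the exact distribution.
#' @return list: statistic (V), p_value, n_pairs (informative pairs),
#'   method.
#' @export
compare_het <- function(rates_a, rates_b, exact_n = 25L) {
  if (length(rates_a) != length(rates_b))
    stop_input("rate vectors must be paired (equal length)")
  keep <- !is.na(rates_a) & !is.na(rates_b)
  d <- rates_a[keep] - rates_b[keep]
  d <- d[d != 0]
  n <- length(d)
  if (length(rates_a[keep]) < 6L)
    stop_input("need at least 6 paired windows")
  if (n == 0L) {
    warning("all paired differences are zero; test is vacuous")
    return(list(statistic = NA_real_, p_value = 1, n_pairs = 0L,
                method = "degenerate"))
  }
  exact <- n <= exact_n
  ht <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n_pairs = n,
       method = if (exact) "exact" else "normal approximation")
}
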