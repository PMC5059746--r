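#' Configuration for the synthetic ZW genome generator
#'
#' Builds and validates the parameter set driving all `simulate_*()`
#' generators.  The defaults constitute the "viper-like" preset: a 77-Mb Z
#' chromosome carrying three evolutionary strata with recombination-
#' suppression boundaries at 42 and 56 Mb, no pseudoautosomal region, 80-fold
#' sequencing depth per sex, 0.1% autosomal heterozygosity and a degenerate,
#' fragmented W whose identifiable fragments are densest in the youngest
#' stratum.  Per-segment vectors are given in genomic order along the Z
#' (0--42, 42--56, 56--77 Mb by default); stratum age is *derived* from Z--W
#' divergence, so the middle segment (highest divergence) is the oldest
#' stratum S1 and the distal segment the youngest S3.
#'
#' @param n_autosomes number of autosomes to simulate.
#' @param autosome_len length of each autosome in bp.
#' @param z_len Z chromosome length in bp.
#' @param strata_boundaries increasing bp positions on the Z where
#'   recombination-suppression events changed; `length(strata_boundaries)+1`
#'   strata tile the non-PAR portion.
#' @param stratum_divergence per-segment target Z--W p-distance
#'   (substitutions/site realised as mismatch fraction), genomic order.
#' @param w_retention per-segment fraction of the homologous Z interval still
#'   covered by identifiable (assemblable) W-derived fragments.  Old strata
#'   retain little; the youngest retains most.
#' @param cons_divergence per-segment divergence of the viper Z from its
#'   recombining homolog in an outgroup (drives the conservation-score
#'   track); oldest stratum most diverged.
#' @param repeat_density,repeat_divergence per-segment fraction of the Z
#'   covered by the focal transposable-element family and its mean percent
#'   divergence from the family consensus (old strata accumulate older
#'   copies).
#' @param auto_repeat_density,auto_repeat_divergence the same two quantities
#'   for autosomes.
#' @param par_fraction fraction of the Z (at the distal end) retained as a
#'   recombining pseudoautosomal region; 0 for the default preset.
#' @param mean_depth_f,mean_depth_m mean per-base fold coverage of the
#'   female and male libraries on a diploid (two-copy) region.
#' @param het_auto per-site autosomal heterozygosity (both sexes).
#' @param het_z_male per-site heterozygosity of the male Z (two copies).
#' @param seq_error per-base sequencing error rate; drives spurious
#'   low-quality variant calls and the error spike of the k-mer spectrum.
#' @param w_disruption_rate expected ORF disruptions per W gametolog per
#'   unit Z--W p-distance.
#' @param n_gametolog_genes number of gametolog genes to simulate.
#' @param gene_len_range CDS length range in bp (rounded to codons).
#' @param species character vector of species labels sharing the strata.
#' @param species_split_div Jukes--Cantor distance between species within a
#'   chromosome lineage; smaller than the stratum Z--W distance means the
#'   stratum predates the species split (shared stratum).
#' @param scaffold_len assembly scaffold size used to tile chromosomes, bp.
#' @param w_tile size of candidate W fragments/scaffolds, bp.
#' @param depth_window granularity at which read depth is simulated, bp.
#' @param frag_aln_len length of the simulated Z/W intergenic alignment
#'   sampled per W fragment, bp.
#' @param cons_seg_len length of the sequence pair sampled per window for
#'   the conservation track, bp.
#' @param mismap_rate fraction of the per-copy depth observed on a
#'   chromosome absent from an individual (e.g. male reads mismapping to W);
#'   0 disables.
#' @param k k-mer length for the simulated k-mer spectrum.
#' @param seed integer seed; a fixed config is fully deterministic.
#'
#' @return an object of class `zw_sim_config` (a validated list).
#' @export
sim_config <- function(n_autosomes = 5,
                       autosome_len = 2e7,
                       z_len = 7.7e7,
                       strata_boundaries = c(4.2e7, 5.6e7),
                       stratum_divergence = c(0.15, 0.25, 0.05),
                       w_retention = c(0.15, 0.08, 0.75),
                       cons_divergence = c(0.15, 0.20, 0.08),
                       repeat_density = c(0.12, 0.22, 0.06),
                       repeat_divergence = c(14, 20, 8),
                       auto_repeat_density = 0.05,
                       auto_repeat_divergence = 10,
                       par_fraction = 0,
                       mean_depth_f = 80,
                       mean_depth_m = 80,
                       het_auto = 0.001,
                       het_z_male = 8e-4,
                       seq_error = 1e-4,
                       w_disruption_rate = 3,
                       n_gametolog_genes = 40,
                       gene_len_range = c(900, 1800),
                       species = c("viper", "cobra"),
                       species_split_div = 0.02,
                       scaffold_len = 1e6,
                       w_tile = 5e4,
                       depth_window = 1000,
                       frag_aln_len = 1000,
                       cons_seg_len = 500,
                       mismap_rate = 0,
                       k = 17,
                       seed = 1L) {
  cfg <- list(
    n_autosomes = n_autosomes, autosome_len = autosome_len, z_len = z_len,
    strata_boundaries = as.numeric(strata_boundaries),
    stratum_divergence = as.numeric(stratum_divergence),
    w_retention = as.numeric(w_retention),
    cons_divergence = as.numeric(cons_divergence),
    repeat_density = as.numeric(repeat_density),
    repeat_divergence = as.numeric(repeat_divergence),
    auto_repeat_density = auto_repeat_density,
    auto_repeat_divergence = auto_repeat_divergence,
    par_fraction = par_fraction,
    mean_depth_f = mean_depth_f, mean_depth_m = mean_depth_m,
    het_auto = het_auto, het_z_male = het_z_male, seq_error = seq_error,
    w_disruption_rate = w_disruption_rate,
    n_gametolog_genes = n_gametolog_genes,
    gene_len_range = gene_len_range,
    species = species, species_split_div = species_split_div,
    scaffold_len = scaffold_len, w_tile = w_tile,
    depth_window = depth_window, frag_aln_len = frag_aln_len,
    cons_seg_len = cons_seg_len, mismap_rate = mismap_rate,
    k = k, seed = as.integer(seed))
  class(cfg) <- "zw_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop_input("invalid sim_config: field '%s' %s", field, why)
  }
  if (!is_count(cfg$n_autosomes)) fail("n_autosomes", "must be a count")
  for (f in c("autosome_len", "z_len", "scaffold_len", "w_tile",
              "depth_window", "frag_aln_len", "cons_seg_len")) {
    if (!is_count(cfg[[f]]) || cfg[[f]] <= 0) fail(f, "must be a positive count")
  }
  b <- cfg$strata_boundaries
  non_par <- cfg$z_len * (1 - cfg$par_fraction)
  if (length(b) && (any(diff(b) <= 0) || any(b <= 0) || any(b >= non_par)))
    fail("strata_boundaries",
         "must be strictly increasing and inside the non-PAR Z")
  n_seg <- length(b) + 1L
  for (f in c("stratum_divergence", "w_retention", "cons_divergence",
              "repeat_density")) {
    if (length(cfg[[f]]) != n_seg) fail(f, sprintf("needs %d values", n_seg))
    if (!is_prob(cfg[[f]])) fail(f, "must hold rates in [0,1]")
  }
  if (length(cfg$repeat_divergence) != n_seg)
    fail("repeat_divergence", sprintf("needs %d values", n_seg))
  for (f in c("par_fraction", "het_auto", "het_z_male", "seq_error",
              "auto_repeat_density", "mismap_rate"))
    if (!is_prob(cfg[[f]]) || length(cfg[[f]]) != 1L)
      fail(f, "must be a single rate in [0,1]")
  if (!is.numeric(cfg$mean_depth_f) || cfg$mean_depth_f < 0)
    fail("mean_depth_f", "must be non-negative")
  if (!is.numeric(cfg$mean_depth_m) || cfg$mean_depth_m < 0)
    fail("mean_depth_m", "must be non-negative")
  if (!is_count(cfg$n_gametolog_genes)) fail("n_gametolog_genes", "must be a count")
  if (length(cfg$gene_len_range) != 2L || any(cfg$gene_len_range < 9) ||
      diff(cfg$gene_len_range) < 0)
    fail("gene_len_range", "must be an increasing pair >= 9 bp")
  if (length(cfg$species) < 1L) fail("species", "needs at least one label")
  if (!is.numeric(cfg$species_split_div) || cfg$species_split_div < 0)
    fail("species_split_div", "must be non-negative")
  if (!is_count(cfg$k) || cfg$k < 2) fail("k", "must be a count >= 2")
  if (!is_count(abs(cfg$seed))) fail("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.zw_sim_config <- function(x, ...) {
  n_seg <- length(x$strata_boundaries) + 1L
  cat(sprintf(
    "zw_sim_config: %d autosome(s) x %.3g Mb, Z %.3g Mb, %d strata, seed %d\n",
    x$n_autosomes, x$autosome_len / 1e6, x$z_len / 1e6, n_seg, x$seed))
  invisible(x)
}

## Non-PAR stratum segments in genomic order, with derived age-rank labels
## (S1 = highest Z-W divergence = oldest).  PAR appended last when present.
strata_segments <- function(cfg) {
  non_par <- round(cfg$z_len * (1 - cfg$par_fraction))
  edges <- c(0, cfg$strata_boundaries, non_par)
  seg <- data.frame(start = edges[-length(edges)], end = edges[-1])
  seg$divergence <- cfg$stratum_divergence
  seg$stratum <- paste0("S", rank(-seg$divergence, ties.method = "first"))
  if (non_par < cfg$z_len) {
    seg <- rbind(seg, data.frame(start = non_par, end = cfg$z_len,
                                 divergence = 0, stratum = "PAR"))
  }
  seg
}
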