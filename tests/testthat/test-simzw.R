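test_that("config validation names the offending field", {
  expect_error(sim_config(het_auto = 2), "het_auto")
  expect_error(sim_config(strata_boundaries = c(5e7, 4e7)),
               "strata_boundaries")
  expect_error(sim_config(stratum_divergence = c(0.1, 0.2)),
               "stratum_divergence")
  expect_error(sim_config(mean_depth_f = -1), "mean_depth_f")
})

test_that("genome layout tiles chromosomes and strata deterministically", {
  cfg <- sim_config(n_autosomes = 2, autosome_len = 2e6, z_len = 7e7,
                    strata_boundaries = c(4.2e7, 5.6e7), scaffold_len = 1e6,
                    seed = 1)
  m <- simulate_genome(cfg)
  seg <- m$strata_map
  expect_equal(seg$start, c(0, 4.2e7, 5.6e7))
  expect_equal(seg$end, c(4.2e7, 5.6e7, 7e7))
  expect_equal(seg$end - seg$start, c(42e6, 14e6, 14e6))
  # strata tile the Z without gaps or overlap
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  # no PAR when par_fraction = 0; W fragments span all strata
  expect_false(any(seg$stratum == "PAR"))
  expect_setequal(unique(m$w_fragments$stratum), seg$stratum)
  # scaffold coordinates lie within their chromosome
  z <- m$scaffolds[m$scaffolds$true_label == "Z", ]
  expect_equal(min(z$chrom_start), 0)
  expect_equal(max(z$chrom_end), cfg$z_len)
  expect_true(all(z$chrom_end - z$chrom_start == z$length))
  # identical config => identical model
  expect_identical(m, simulate_genome(cfg))
})

test_that("window depth follows the copy-number Poisson means", {
  b <- toy_bundle()
  cfg <- b$config
  lab <- b$model$scaffolds$true_label[
    match(b$depth_f$scaffold, b$model$scaffolds$scaffold)]
  mean_se <- function(x) c(mean(x), sd(x) / sqrt(length(x)))
  # female W: one copy => half depth
  w <- mean_se(b$depth_f$depth[lab == "W"])
  expect_lt(abs(w[1] - cfg$mean_depth_f / 2), 3 * w[2])
  # female Z (hemizygous) vs female autosome: ratio ~ 0.5
  zf <- mean_se(b$depth_f$depth[lab == "Z"])
  af <- mean_se(b$depth_f$depth[lab == "AUTO"])
  expect_lt(abs(zf[1] / af[1] - 0.5), 0.02)
  # male Z and male autosome both diploid-depth
  labm <- b$model$scaffolds$true_label[
    match(b$depth_m$scaffold, b$model$scaffolds$scaffold)]
  zm <- mean_se(b$depth_m$depth[labm == "Z"])
  expect_lt(abs(zm[1] - cfg$mean_depth_m), 3 * zm[2])
  # male W: chromosome absent => all zero without mismapping noise
  expect_true(all(b$depth_m$depth[labm == "W"] == 0))
  expect_error(simulate_depth(b$model, "X"), "sex")
})

test_that("variant tables respect heterozygosity and hemizygosity", {
  cfg <- sim_config(n_autosomes = 1, autosome_len = 1e6, z_len = 1e6,
                    strata_boundaries = c(4e5, 7e5), scaffold_len = 1e6,
                    seq_error = 0, seed = 21)
  m <- simulate_genome(cfg)
  vf <- simulate_variants(m, "F")
  vm <- simulate_variants(m, "M")
  lab <- function(v) m$scaffolds$true_label[
    match(v$scaffold, m$scaffolds$scaffold)]
  # ~ het_auto * L autosomal het sites, within 3 binomial SD
  n_expect <- cfg$het_auto * cfg$autosome_len
  sd3 <- 3 * sqrt(n_expect * (1 - cfg$het_auto))
  nf <- sum(vf$genotype == "het" & lab(vf) == "AUTO")
  nm <- sum(vm$genotype == "het" & lab(vm) == "AUTO")
  expect_lt(abs(nf - n_expect), sd3)
  expect_lt(abs(nm - n_expect), sd3)
  # sexes agree in expectation
  expect_lt(abs(nf - nm), 3 * sqrt(2 * n_expect))
  # female Z is hemizygous: no true heterozygotes when errors are off
  expect_equal(sum(vf$genotype == "het" & lab(vf) == "Z"), 0)
  # male Z carries two copies and does vary
  expect_gt(sum(vm$genotype == "het" & lab(vm) == "Z"), 0)
})

test_that("gametolog divergence is calibrated and degenerate cases hold", {
  # zero divergence and zero disruption: Z and W identical, ORFs intact
  cfg0 <- sim_config(stratum_divergence = c(0, 0, 0), species_split_div = 0,
                     w_disruption_rate = 0, n_gametolog_genes = 4, seed = 3)
  g0 <- simulate_gametologs(cfg0)
  for (g in g0$genes) {
    expect_identical(g$aln[["viper_Z"]], g$aln[["viper_W"]])
    expect_equal(nrow(g$disruptions), 0)
  }
  # realized Z-W p-distance within 20% of target, averaged per stratum
  cfg <- sim_config(n_gametolog_genes = 60, w_disruption_rate = 0, seed = 4)
  gs <- simulate_gametologs(cfg)
  rep <- gametolog_report(gs)
  div <- tapply(rep$pairs$divergence,
                vapply(gs$genes, `[[`, "", "stratum")[
                  match(rep$pairs$gene_id,
                        vapply(gs$genes, `[[`, "", "gene_id"))],
                mean, na.rm = TRUE)
  target <- c(S1 = 0.25, S2 = 0.15, S3 = 0.05)
  for (s in names(target)) {
    expect_lt(abs(div[[s]] - target[[s]]) / target[[s]], 0.2)
  }
  # configured stratum age ranking is recovered in the divergences
  expect_true(div[["S1"]] > div[["S2"]], )
  expect_true(div[["S2"]] > div[["S3"]])
})

test_that("k-mer spectrum conserves instances and shows the error spike", {
  cfg0 <- sim_config(seq_error = 0, seed = 5)
  h0 <- simulate_kmer_histogram(cfg0, genome_size = 1e6, depth = 30)
  total <- sum(h0$entries$depth * h0$entries$count)
  expect_lt(abs(total - 3e7) / 3e7, 0.01)
  # no error spike without errors; spike appears with errors
  expect_lt(h0$entries$count[h0$entries$depth == 1], 50)
  h1 <- simulate_kmer_histogram(sim_config(seq_error = 1e-3, seed = 5),
                                genome_size = 1e6, depth = 30)
  expect_gt(h1$entries$count[h1$entries$depth == 1],
            max(h1$entries$count[h1$entries$depth >= 10]))
  # same seed, same histogram
  expect_identical(h0, simulate_kmer_histogram(cfg0, genome_size = 1e6,
                                               depth = 30))
  expect_error(simulate_kmer_histogram(cfg0, 1e6, depth = 0), "depth")
})

test_that("bundle writing is byte-deterministic and round-trips", {
  cfg <- toy_config(seed = 5)
  b <- simulate_bundle(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  files <- write_bundle(b, d1)
  write_bundle(simulate_bundle(cfg), d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # round trips reproduce the in-memory objects
  df <- read_depth_table(files[["depth_f"]])
  expect_equal(df$depth, b$depth_f$depth)
  bed <- read_repeat_bed(files[["repeats"]])
  expect_equal(nrow(bed), nrow(b$repeats))
  expect_equal(bed$divergence, b$repeats$divergence)
  h <- read_histogram(files[["histo"]])
  expect_equal(h$entries, b$kmer_histogram$entries)
  v <- read_variants(files[["vcf_f"]])
  expect_equal(nrow(v), nrow(b$variants_f))
  expect_equal(v$genotype, b$variants_f$genotype)
  expect_equal(v$depth, b$variants_f$depth)
  aln <- read_gametolog_alignments(files[["gametolog_dir"]])
  expect_equal(unname(aln[["gene001"]]),
               unname(b$gametologs$genes[[1]]$aln))
  # ground truth lists labels for every scaffold
  tr <- read_truth(files[["truth"]])
  expect_setequal(tr$scaffolds$scaffold, b$model$scaffolds$scaffold)
  expect_setequal(unique(tr$scaffolds$true_label), c("AUTO", "Z", "W"))
})
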