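test_that("window tracks validate their grid", {
  expect_error(window_track("z", 10, c(0, 10), 1), "equal length")
  expect_error(window_track("z", 10, c(0, 15), c(1, 2)), "window_size")
  tr <- window_track("z", 10, c(0, 10, 20), c(1, NaN, 3))
  df <- as.data.frame(tr)
  expect_equal(df$end, c(10, 20, 30))
  expect_equal(sum(is.na(df$value)), 1)
})

test_that("depth-ratio track reads 1 on autosomes/PAR and 0.5 on female Z", {
  cfg <- sim_config(n_autosomes = 3, autosome_len = 3e6, z_len = 4e6,
                    strata_boundaries = c(1.5e6, 2.25e6), par_fraction = 0.25,
                    stratum_divergence = c(0.25, 0.15, 0.05),
                    w_retention = c(0.1, 0.1, 0.7),
                    cons_divergence = c(0.2, 0.15, 0.08),
                    repeat_density = c(0.2, 0.12, 0.06),
                    repeat_divergence = c(20, 14, 8),
                    scaffold_len = 2.5e5, w_tile = 2e4, seed = 31)
  m <- simulate_genome(cfg)
  expect_true("PAR" %in% m$strata_map$stratum)
  df <- simulate_depth(m, "F")
  dm <- simulate_depth(m, "M")
  st <- summarize_coverage(df, dm, stats::setNames(m$scaffolds$length,
                                                   m$scaffolds$scaffold))
  cl <- classify_all(st)
  tr <- depth_ratio_track(df, cl$calls, m$scaffolds, chrom = "chrZ",
                          window = 2.5e5)
  non_par <- tr$starts < 3e6
  expect_lt(abs(mean(tr$values[non_par]) - 0.5), 0.03)
  expect_lt(abs(mean(tr$values[!non_par]) - 1.0), 0.05)
  # autosomal track sits at 1
  ta <- depth_ratio_track(df, cl$calls, m$scaffolds, chrom = "chrA1",
                          window = 2.5e5)
  expect_lt(abs(mean(ta$values) - 1.0), 0.05)
  expect_error(depth_ratio_track(df, data.frame(scaffold = "x",
                                                label = "Z"),
                                 m$scaffolds), "autosomal")
})

test_that("divergence track averages fragment p-distances per window", {
  aln <- data.frame(z_start = c(0, 100), z_end = c(100, 200),
                    z_seq = c("ACGTACGTAC", "ACGTACGTAC"),
                    w_seq = c("ACGTACGTAC", "TCGTACGTAG"))
  tr <- divergence_track(aln, 400, window = 200)
  expect_equal(tr$values[1], mean(c(0, 0.2)))
  expect_true(is.na(tr$values[2]))   # no fragments there
  # 5 mismatches over 100 sites -> 0.05
  z <- strrep("ACGT", 25)
  w <- paste0(strrep("T", 5), substr(z, 6, 100))
  n_mm <- sum(strsplit(z, "")[[1]] != strsplit(w, "")[[1]])
  tr2 <- divergence_track(data.frame(z_start = 0, z_end = 100,
                                     z_seq = z, w_seq = w), 100, 100)
  expect_equal(tr2$values[1], n_mm / 100)
  expect_error(divergence_track(data.frame(z_start = 0, z_end = 500,
                                           z_seq = "A", w_seq = "A"),
                                400, 200), "outside")
})

test_that("simulated stratum divergences are recovered within 20%", {
  b <- toy_bundle()
  cfg <- b$config
  tr <- divergence_track(b$zw_alignments, cfg$z_len, window = 1e5)
  seg <- b$model$strata_map
  target <- c(S2 = 0.15, S1 = 0.25, S3 = 0.05)
  for (j in seq_len(nrow(seg))) {
    sel <- tr$starts >= seg$start[j] & tr$starts < seg$end[j]
    got <- mean(tr$values[sel], na.rm = TRUE)
    want <- target[[seg$stratum[j]]]
    expect_lt(abs(got - want) / want, 0.2)
  }
})

test_that("W-fragment density merges intervals and matches a direct merge", {
  # no placements -> all zero
  t0 <- wfragment_density_track(data.frame(start = numeric(),
                                           end = numeric()), 2e6, 1e6)
  expect_equal(t0$values, c(0, 0))
  # one 500-kb fragment in one 1-Mb window -> 0.5
  t1 <- wfragment_density_track(data.frame(start = 0, end = 5e5), 2e6, 1e6)
  expect_equal(t1$values, c(0.5, 0))
  # overlapping fragments are merged before coverage
  t2 <- wfragment_density_track(data.frame(start = c(0, 2e5),
                                           end = c(5e5, 6e5)), 1e6, 1e6)
  expect_equal(t2$values, 0.6)
  # random intervals: total covered bp equals a brute-force merge
  set.seed(5)
  s <- sort(sample.int(1e6, 50))
  e <- pmin(s + sample.int(5e4, 50, replace = TRUE), 1e6)
  tr <- wfragment_density_track(data.frame(start = s, end = e), 1e6, 1e5)
  cov <- logical(1e6)
  for (i in seq_along(s)) cov[(s[i] + 1):e[i]] <- TRUE
  expect_equal(sum(tr$values) * 1e5, sum(cov))
})

test_that("toy alignment scores decrease with divergence", {
  expect_equal(toy_align_score(strrep("A", 1000), strrep("A", 1000)), 1)
  expect_equal(toy_align_score(strrep("A", 100), strrep("C", 100)), -1)
  expect_equal(toy_align_score("AC-G", "ACTG"), (2 - 2 + 1) / 4)
  expect_error(toy_align_score("AA", "AAA"), "equal")
  set.seed(8)
  base <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                collapse = "")
  scores <- vapply(c(0, 0.05, 0.1, 0.2), function(d) {
    v <- strsplit(base, "")[[1]]
    hit <- which(runif(length(v)) < d)
    v[hit] <- vapply(v[hit],
                     function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                     "")
    toy_align_score(base, paste(v, collapse = ""))
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("conservation track grids scores and tracks stratum age", {
  # ingested score table: length-weighted gridding
  sc <- data.frame(start = c(0, 5e5, 1e6), end = c(5e5, 1e6, 2e6),
                   score = c(1, 0, -1))
  tr <- conservation_track(sc, 2e6, window = 1e6)
  expect_equal(tr$values, c(0.5, -1))
  # simulated outgroup scores: the oldest stratum is least conserved
  b <- toy_bundle()
  cons <- simulate_conservation_scores(b$model, window = 1e5)
  trc <- conservation_track(cons, b$config$z_len, window = 1e5)
  seg <- b$model$strata_map
  seg_mean <- function(s) mean(trc$values[trc$starts >= seg$start[
    seg$stratum == s] & trc$starts < seg$end[seg$stratum == s]])
  expect_lt(seg_mean("S1"), seg_mean("S2"))
  expect_lt(seg_mean("S2"), seg_mean("S3"))
  # scores fall with divergence: ~ 1 - 2d for substitution-only pairs
  expect_lt(abs(seg_mean("S1") - (1 - 2 * 0.20)), 0.05)
})

test_that("repeat tracks filter by family and honour merged coverage", {
  bed <- data.frame(chrom = "chrZ", start = c(0, 2e4, 1.5e5),
                    end = c(5e4, 5e4, 1.8e5),
                    name = c("r1", "r2", "r3"), score = 0, strand = "+",
                    family = c("Gypsy", "Gypsy", "CR1"),
                    divergence = c(20, 18, 5))
  tr <- repeat_density_track(bed, 2e5, window = 1e5, family = "Gypsy")
  expect_equal(tr$values, c(0.5, 0))         # overlaps merged
  tr_all <- repeat_density_track(bed, 2e5, window = 1e5)
  expect_equal(tr_all$values, c(0.5, 0.3))
  # malformed BED rejected with a line number
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrZ\t0\t10\tr\t0\t+\tGypsy\t5", "chrZ\t5\tbad"), f)
  expect_error(read_repeat_bed(f), "line 2")
})

test_that("repeat divergence profiles separate old from young strata", {
  b <- toy_bundle()
  seg <- b$model$strata_map
  prof <- repeat_divergence_profile(b$repeats, seg, family = "Gypsy")
  means <- stats::setNames(prof$means$mean_divergence, prof$means$label)
  expect_gt(means[["S1"]], means[["S3"]])
  # bin totals count every assigned interval
  expect_equal(sum(prof$histogram$n), sum(prof$means$n))
  # empty segment yields an empty histogram
  empty <- repeat_divergence_profile(
    b$repeats[0, ], data.frame(start = 0, end = 1e6, label = "S1"))
  expect_equal(nrow(empty$histogram), 0)
})

test_that("segmentation recovers noiseless and noisy changepoints", {
  # piecewise-constant noiseless two-level track: exact breakpoint forced
  tr <- window_track("z", 1e6, seq(0, 19e6, by = 1e6),
                     c(rep(1, 12), rep(3, 8)))
  seg <- segment_strata(tr, k = 1)
  expect_equal(seg$breakpoints, 12e6)
  # error when more breakpoints than windows allow
  expect_error(segment_strata(window_track("z", 1, 0:1, c(1, 2)), k = 5),
               "fewer windows")
  # exact DP agrees with binary segmentation on clear 100-window signals
  set.seed(13)
  for (i in 1:8) {
    bps_true <- sort(sample(10:90, 2))
    mu <- c(0, 3, 6)[c(rep(1, bps_true[1]),
                       rep(2, bps_true[2] - bps_true[1]),
                       rep(3, 100 - bps_true[2]))]
    x <- rnorm(100, mu, 1)            # SNR = 3
    trk <- window_track("z", 1, 0:99, x)
    sb <- segment_strata(trk, k = 2, method = "binseg")
    sd_ <- segment_strata(trk, k = 2, method = "dp")
    expect_equal(sb$window_index, sd_$window_index)
    expect_true(all(abs(sb$window_index - bps_true) <= 2))
  }
})

test_that("segmentation cost never increases with more breakpoints", {
  set.seed(3)
  trk <- window_track("z", 1, 0:59, rnorm(60, rep(c(0, 2, 4), each = 20)))
  costs <- vapply(0:4, function(k) segment_strata(trk, k = k)$cost,
                  numeric(1))
  expect_true(all(diff(costs) <= 1e-9))
  # penalty-based selection lands on the true 2 breakpoints
  auto <- segment_strata(trk, k = NULL)
  expect_equal(length(auto$breakpoints), 2L)
})

test_that("strata labelling ranks by divergence and spots the PAR", {
  grid <- seq(0, 29e6, by = 1e6)
  div <- window_track("chrZ", 1e6, grid,
                      c(rep(0.15, 10), rep(0.25, 10), rep(0.05, 10)))
  seg <- list(breakpoints = c(10e6, 20e6))
  lab <- label_strata(seg$breakpoints, div, chrom_len = 30e6)
  expect_equal(lab$label, c("S2", "S1", "S3"))
  expect_equal(lab$mean_divergence, c(0.15, 0.25, 0.05))
  # PAR: depth ratio ~1 beats divergence ranking
  dr <- window_track("chrZ", 1e6, grid, c(rep(0.5, 20), rep(1.0, 10)))
  lab2 <- label_strata(seg$breakpoints, div, dr, chrom_len = 30e6)
  expect_equal(lab2$label, c("S2", "S1", "PAR"))
  # a segment with no divergence evidence is UNRANKED
  div_na <- window_track("chrZ", 1e6, grid,
                         c(rep(0.15, 10), rep(0.25, 10), rep(NaN, 10)))
  lab3 <- label_strata(seg$breakpoints, div_na, chrom_len = 30e6)
  expect_equal(lab3$label, c("S2", "S1", "UNRANKED"))
})

test_that("viper-like preset recovers its strata geometry", {
  cfg <- sim_config(seed = 2)
  m <- simulate_genome(cfg)
  div <- divergence_track(simulate_zw_alignments(m), cfg$z_len, 1e6)
  dens <- wfragment_density_track(m$w_fragments, cfg$z_len, 1e6)
  seg <- segment_strata(list(dens, div), k = 2)
  bp <- sort(seg$breakpoints)
  expect_lte(abs(bp[1] - 42e6), 1e6)
  expect_lte(abs(bp[2] - 56e6), 1e6)
  lab <- label_strata(seg, div, chrom_len = cfg$z_len)
  # oldest stratum in the middle, youngest at the distal end
  expect_equal(lab$label[lab$start < 42e6][1], "S2")
  expect_equal(lab$label[abs(lab$start - bp[1]) <= 1e6], "S1")
  expect_equal(lab$label[abs(lab$start - bp[2]) <= 1e6], "S3")
})

test_that("tracks survive a refine/coarsen round trip", {
  tr <- window_track("z", 2e5, seq(0, 19e5, by = 2e5), rnorm(10))
  rt <- zwstrata:::track_coarsen2(zwstrata:::track_refine2(tr))
  expect_equal(rt$starts, tr$starts)
  expect_equal(rt$values, tr$values, tolerance = 1e-12)
  expect_equal(rt$window_size, tr$window_size)
})
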