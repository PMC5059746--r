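test_that("alignment cleaning drops gapped columns and applies the 300-bp rule", {
  aln <- c(a = "ACGTACGT", b = "ACGTACGT")
  cl <- clean_alignment(aln)
  expect_equal(unname(cl), unname(aln), ignore_attr = TRUE)
  expect_equal(attr(cl, "cleaned_len"), 8L)
  # 400-bp alignment with 150 gapped columns: 250 <= 300 -> rejected
  a <- strrep("A", 400)
  b2 <- paste0(strrep("-", 150), strrep("A", 250))
  cl2 <- clean_alignment(c(a = a, b = b2))
  expect_equal(attr(cl2, "cleaned_len"), 250L)
  expect_false(attr(cl2, "kept"))
  # column count equals a brute-force per-column scan
  set.seed(17)
  mk <- function() paste(sample(c("A", "C", "G", "T", "-", "N"), 200,
                                replace = TRUE, prob = c(rep(0.22, 4), 0.06,
                                                         0.06)),
                         collapse = "")
  aln3 <- c(x = mk(), y = mk(), z = mk())
  m <- do.call(rbind, strsplit(aln3, ""))
  n_clean <- sum(apply(m, 2, function(col)
    all(col %in% c("A", "C", "G", "T"))))
  expect_equal(attr(clean_alignment(aln3), "cleaned_len"), n_clean)
  expect_error(clean_alignment(c(a = "ACG", b = "AC")), "equal length")
})

test_that("divergence models behave: p simple counts, K2P corrects upward", {
  expect_equal(pairwise_divergence(c(a = "ACGT", b = "ACGT")), 0)
  z <- strrep("ACGT", 25)
  w <- paste0("TTTTT", substr(z, 6, 100))
  p <- pairwise_divergence(c(z = z, w = w))
  expect_equal(p, sum(strsplit(z, "")[[1]] != strsplit(w, "")[[1]]) / 100)
  # K2P >= p wherever defined (multiple-hit correction)
  set.seed(23)
  for (d in c(0.02, 0.1, 0.2, 0.3)) {
    base <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                  collapse = "")
    v <- strsplit(base, "")[[1]]
    hit <- which(runif(1500) < d)
    v[hit] <- vapply(v[hit],
                     function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                     "")
    pair <- c(a = base, b = paste(v, collapse = ""))
    pp <- pairwise_divergence(pair, "p")
    kk <- pairwise_divergence(pair, "K2P")
    expect_gte(kk, pp)
  }
  # saturation flagged
  expect_warning(
    expect_true(is.na(pairwise_divergence(
      c(a = strrep("AG", 50), b = strrep("GA", 50)), "K2P"))),
    "saturat")
})

test_that("ORF scanning pinpoints constructed disruptions", {
  z <- make_orf(20)                       # 60 bp, codons 1..20
  # intact W: no events
  expect_equal(nrow(scan_orf(z, z)), 0L)
  # single-base deletion in codon 10 -> one frameshift at that codon
  w_del <- gap_base(z, 28)
  sc <- scan_orf(z, w_del)
  expect_equal(sc$type, "frameshift")
  expect_true(sc$pos >= 28 && sc$pos <= 30)
  # TAA substituted mid-frame -> one premature stop at the codon start
  w_stop <- set_codon(z, 10, "TAA")
  sc2 <- scan_orf(z, w_stop)
  expect_equal(sc2$type, "premature_stop")
  expect_equal(sc2$pos, 28L)
  # a 3-bp deletion keeps the frame: no frameshift
  w_del3 <- gap_base(gap_base(gap_base(z, 28), 29), 30)
  expect_equal(nrow(scan_orf(z, w_del3)), 0L)
  # terminal stop codon is not premature
  expect_equal(nrow(scan_orf(z, set_codon(z, 20, "TGA"))), 0L)
  # broken reference is refused
  expect_error(scan_orf(set_codon(z, 5, "TAA"), z), "reference ORF")
  expect_error(scan_orf(sub("^ATG", "CCC", z), z), "reference ORF")
})

test_that("simulated disruptions are recovered exactly", {
  gs <- toy_bundle()$gametologs
  for (g in gs$genes) {
    for (s in gs$species) {
      got <- scan_orf(g$aln[[paste0(s, "_Z")]], g$aln[[paste0(s, "_W")]])
      want <- g$disruptions[g$disruptions$species == s, c("type", "pos")]
      want <- want[order(want$pos), ]
      expect_equal(got$type, want$type)
      expect_equal(got$pos, want$pos)
    }
  }
  # reverting all disruptions restores an intact ORF: regenerate without
  cfg0 <- toy_config(w_disruption_rate = 0)
  for (g in simulate_gametologs(cfg0)$genes) {
    for (s in cfg0$species) {
      expect_equal(nrow(scan_orf(g$aln[[paste0(s, "_Z")]],
                                 g$aln[[paste0(s, "_W")]])), 0L)
    }
  }
})

test_that("pseudogene fractions reduce to exact printed arithmetic", {
  res <- pseudogene_fraction(c(rep(TRUE, 62), rep(FALSE, 137 - 62)))
  expect_equal(res$percent, 45.26)
  expect_equal(pseudogene_fraction(rep(FALSE, 10))$percent, 0)
  expect_error(pseudogene_fraction(logical()), "no gametolog")
})

test_that("neighbor joining recovers additive and ultrametric topologies", {
  # additive 4-taxon matrix from ((A,B),(C,D)) with internal branch 0.3
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 0.2
  D["C", "D"] <- D["D", "C"] <- 0.2
  for (i in c("A", "B")) for (j in c("C", "D"))
    D[i, j] <- D[j, i] <- 0.1 + 0.3 + 0.1
  tr <- nj_tree(D)
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
  # permuting taxa yields the same unrooted topology
  perm <- c(3, 1, 4, 2)
  tr2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))[1], 0)
  # cophenetic distances of random trees are additive: NJ recovers them
  set.seed(29)
  for (n in c(5, 8)) {
    t0 <- ape::rtree(n)
    got <- nj_tree(stats::cophenetic(t0))
    expect_equal(ape::dist.topo(ape::unroot(t0), ape::unroot(got))[1], 0)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "3 sequences|symmetric")
})

test_that("chromosome- versus species-clustering is read off the tree", {
  by_chr <- ape::read.tree(text = "((A_Z:1,B_Z:1):2,(A_W:1,B_W:1):2);")
  expect_equal(cluster_by_chromosome_test(by_chr)$clustering,
               "by_chromosome")
  by_sp <- ape::read.tree(text = "((A_Z:1,A_W:1):2,(B_Z:1,B_W:1):2);")
  expect_equal(cluster_by_chromosome_test(by_sp)$clustering, "by_species")
  crossed <- ape::read.tree(text = "((A_Z:1,B_W:1):2,(B_Z:1,A_W:1):2);")
  expect_equal(cluster_by_chromosome_test(crossed)$clustering, "unresolved")
  bad <- ape::read.tree(text = "((A_Z:1,B_Q:1):2,(B_Z:1,A_W:1):2);")
  expect_error(cluster_by_chromosome_test(bad), "_Z/_W")
})

test_that("shared strata cluster by chromosome across the gene set", {
  # species split younger than every stratum: all genes should cluster by
  # chromosome when the divergence gap is at least twofold
  rep <- gametolog_report(toy_bundle()$gametologs)
  expect_gte(mean(rep$trees$clustering == "by_chromosome"), 0.95)
  # lineage-specific preset: species split far older than the stratum
  cfg <- toy_config(species_split_div = 0.3,
                    stratum_divergence = c(0.05, 0.08, 0.02),
                    n_gametolog_genes = 8, seed = 33)
  rep2 <- gametolog_report(simulate_gametologs(cfg))
  expect_gte(mean(rep2$trees$clustering == "by_species"), 0.95)
})
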