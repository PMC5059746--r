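# Shared fixtures: small configurations and a cached toy bundle so that
# multiple test files can reuse one simulation.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, make(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## Toy genome: 3 autosomes x 3 Mb (autosome-majority), 7.7-Mb Z with the
## three-strata geometry scaled 1:10.
toy_config <- function(seed = 7, ...) {
  args <- list(n_autosomes = 3, autosome_len = 3e6, z_len = 7.7e6,
               strata_boundaries = c(4.2e6, 5.6e6), scaffold_len = 2e5,
               w_tile = 2e4, n_gametolog_genes = 12, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

toy_bundle <- function() {
  cache_get("toy_bundle", function() simulate_bundle(toy_config()))
}

toy_calls <- function() {
  cache_get("toy_calls", function() {
    b <- toy_bundle()
    st <- summarize_coverage(
      b$depth_f, b$depth_m,
      stats::setNames(b$model$scaffolds$length, b$model$scaffolds$scaffold))
    classify_all(st)
  })
}

## A hand-built intact ORF of n_codon codons: ATG + fixed non-stop codons
## + TAA, as a single string.
make_orf <- function(n_codon = 20) {
  paste0("ATG", paste(rep("GCT", n_codon - 2), collapse = ""), "TAA")
}

## Replace the i-th codon (1-based) of a sequence string.
set_codon <- function(seq, i, codon) {
  v <- strsplit(seq, "")[[1]]
  v[(3 * i - 2):(3 * i)] <- strsplit(codon, "")[[1]]
  paste(v, collapse = "")
}

## Delete (gap out) a single base at position pos in a sequence string.
gap_base <- function(seq, pos) {
  v <- strsplit(seq, "")[[1]]
  v[pos] <- "-"
  paste(v, collapse = "")
}

## Exact two-sided signed-rank p-value by enumeration of all 2^n sign
## assignments (independent oracle; requires no zeros and no tied |d|).
signed_rank_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vstar <- as.numeric(signs %*% r)
  M <- n * (n + 1) / 4
  p_one <- if (V > M) mean(Vstar >= V) else mean(Vstar <= V)
  min(1, 2 * p_one)
}

## Brute-force N50 oracle: scan candidate lengths directly.
n50_oracle <- function(lengths) {
  half <- sum(lengths) / 2
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= half) return(L)
  }
  stop("unreachable")
}
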