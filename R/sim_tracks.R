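## Generators for the windowed-evidence inputs of the strata module and the
## k-mer spectrum of the genome-size module.

## Substitute each base with prob p to a different base; p IS the expected
## observed mismatch fraction for a single-step pair.
mutate_string <- function(x, p) {
  v <- strsplit(x, "")[[1]]
  hit <- which(stats::runif(length(v)) < p)
  if (length(hit))
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(BASES, b), 1L),
                     character(1))
  paste(v, collapse = "")
}

#' Simulate Z/W intergenic alignment fragments
#'
#' For every identifiable W fragment of the model, samples an alignment of
#' up to `frag_aln_len` bp between the Z and its W homolog, mutated to the
#' fragment's stratum-specific Z--W divergence.  These anchor the
#' [divergence_track()] along the Z.
#'
#' @inheritParams simulate_depth
#' @return data frame: z_start, z_end, stratum, z_seq, w_seq.
#' @export
simulate_zw_alignments <- function(model, config = model$config) {
  seg <- strata_segments(config)
  wf <- model$w_fragments
  with_sim_seed(config$seed, 601L, {
    if (!nrow(wf)) {
      return(data.frame(z_start = numeric(), z_end = numeric(),
                        stratum = character(), z_seq = character(),
                        w_seq = character()))
    }
    p <- seg$divergence[match(wf$stratum, seg$stratum)]
    len <- pmin(wf$z_end - wf$z_start, config$frag_aln_len)
    z_seq <- vapply(len, random_dna, character(1))
    w_seq <- vapply(seq_along(z_seq),
                    function(i) mutate_string(z_seq[i], p[i]), character(1))
    data.frame(z_start = wf$z_start, z_end = wf$z_end, stratum = wf$stratum,
               z_seq = z_seq, w_seq = w_seq)
  })
}

#' Simulate cross-species conservation scores along the Z
#'
#' Emulates an ingested alignment-score table between the focal Z and the
#' homologous (recombining) chromosome of an outgroup: per window a sequence
#' pair of `cons_seg_len` bp diverged by the window's stratum-specific
#' outgroup divergence (oldest strata most diverged, by male-driven
#' evolution of the Z) is scored with [toy_align_score()].  PAR windows use
#' the smallest configured divergence.
#'
#' @inheritParams simulate_depth
#' @param window window size in bp.
#' @return data frame: start, end, score (per-bp).
#' @export
simulate_conservation_scores <- function(model, config = model$config,
                                         window = 1e6) {
  seg <- strata_segments(config)
  div <- rep(min(config$cons_divergence), nrow(seg))
  div[seg$stratum != "PAR"] <- config$cons_divergence
  with_sim_seed(config$seed, 701L, {
    t <- tile_intervals(config$z_len, window)
    mid <- (t$start + t$end) / 2
    d <- div[findInterval(mid, seg$start)]
    score <- vapply(d, function(di) {
      a <- random_dna(config$cons_seg_len)
      toy_align_score(a, mutate_string(a, di))
    }, numeric(1))
    data.frame(start = t$start, end = t$end, score = score)
  })
}

#' Simulate a repeat annotation
#'
#' Transposable-element intervals with family and percent-divergence
#' columns.  On the Z the focal family ("Gypsy") is laid down at the
#' per-stratum `repeat_density` with per-stratum mean divergence from the
#' family consensus (`repeat_divergence`); a background family ("CR1") gets
#' half that density.  Autosomes use the autosomal density/divergence.
#'
#' @inheritParams simulate_depth
#' @return BED-like data frame: chrom, start, end, name, score, strand,
#'   family, divergence; 0-based half-open.
#' @export
simulate_repeats <- function(model, config = model$config) {
  seg <- strata_segments(config)
  mean_len <- 1100
  with_sim_seed(config$seed, 801L, {
    place <- function(chrom, lo, hi, density, div_mean, family) {
      n <- round(density * (hi - lo) / mean_len)
      if (n <= 0) return(NULL)
      len <- pmax(100, round(stats::rgamma(n, shape = 2, scale = 500)))
      start <- floor(stats::runif(n, lo, hi - len))
      data.frame(chrom = chrom, start = start, end = start + len,
                 family = family,
                 divergence = round(pmax(0.5,
                   stats::rnorm(n, div_mean, 3)), 1))
    }
    out <- list()
    for (j in seq_len(nrow(seg))) {
      dens <- if (seg$stratum[j] == "PAR") config$auto_repeat_density else
        config$repeat_density[match(seg$stratum[j],
                                    seg$stratum[seg$stratum != "PAR"])]
      divm <- if (seg$stratum[j] == "PAR") config$auto_repeat_divergence else
        config$repeat_divergence[match(seg$stratum[j],
                                       seg$stratum[seg$stratum != "PAR"])]
      out[[length(out) + 1L]] <- place("chrZ", seg$start[j], seg$end[j],
                                       dens, divm, "Gypsy")
      out[[length(out) + 1L]] <- place("chrZ", seg$start[j], seg$end[j],
                                       dens / 2, divm, "CR1")
    }
    for (i in seq_len(config$n_autosomes)) {
      out[[length(out) + 1L]] <- place(sprintf("chrA%d", i), 0,
                                       config$autosome_len,
                                       config$auto_repeat_density,
                                       config$auto_repeat_divergence, "Gypsy")
    }
    out <- do.call(rbind, Filter(Negate(is.null), out))
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    out$name <- sprintf("rep%05d", seq_len(nrow(out)))
    out$score <- 0L
    out$strand <- "+"
    rownames(out) <- NULL
    out[, c("chrom", "start", "end", "name", "score", "strand",
            "family", "divergence")]
  })
}

#' Simulate a k-mer depth histogram
#'
#' A mixture of (i) a Poisson-like main peak: `genome_size` distinct genomic
#' k-mers whose observed depth is Poisson with mean
#' `depth * (1 - seq_error)^k` (reads carrying an error inside the k-mer are
#' lost to it), sampled multinomially so k-mer instances are conserved, and
#' (ii) an error spike at depth 1--3 holding the erroneous instances, each
#' error k-mer being essentially unique.  Total k-mer instances across the
#' histogram are `genome_size * depth` in expectation.
#'
#' @param config a [sim_config()] object (supplies `seq_error`, `k`, seed,
#'   and defaults for size/depth).
#' @param genome_size haploid genome size in bp; defaults to the config's
#'   total chromosome length.
#' @param depth sequencing depth; defaults to `mean_depth_m`.
#' @return object of class `zw_kmer_histogram`: list(k, entries) where
#'   entries is a data frame (depth, count).
#' @export
simulate_kmer_histogram <- function(config, genome_size = NULL, depth = NULL) {
  G <- round(genome_size %||%
               (config$n_autosomes * config$autosome_len + config$z_len))
  depth <- depth %||% config$mean_depth_m
  if (depth <= 0) stop_input("depth must be positive")
  err_k <- 1 - (1 - config$seq_error)^config$k
  lambda <- depth * (1 - err_k)

  with_sim_seed(config$seed, 901L, {
    dmax <- stats::qpois(1 - 1e-12, lambda) + 3L
    pr <- stats::dpois(seq_len(dmax), lambda)
    pr <- pr / sum(pr)
    counts <- as.numeric(stats::rmultinom(1L, G, pr))
    err_inst <- stats::rpois(1L, G * depth * err_k)
    counts[1] <- counts[1] + round(0.90 * err_inst)
    counts[2] <- counts[2] + round(0.05 * err_inst)   # 2 x 0.05 instances
    entries <- data.frame(depth = seq_len(dmax), count = counts)
    entries <- entries[entries$count > 0 |
                         seq_len(dmax) <= which.max(counts), , drop = FALSE]
    rownames(entries) <- NULL
    out <- list(k = config$k, entries = entries)
    class(out) <- "zw_kmer_histogram"
    out
  })
}

#' @export
print.zw_kmer_histogram <- function(x, ...) {
  cat(sprintf("zw_kmer_histogram: k=%d, %d depth bins, %.3g k-mer instances\n",
              x$k, nrow(x$entries), sum(x$entries$depth * x$entries$count)))
  invisible(x)
}
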