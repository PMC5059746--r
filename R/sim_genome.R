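#' Simulate a ZW genome model with known ground truth
#'
#' Lays out autosomal, Z-linked and W-linked scaffolds.  Chromosomes are
#' tiled into scaffolds of `scaffold_len`; the Z carries a stratum map tiling
#' `[0, z_len)` (non-PAR strata plus an optional distal PAR).  W scaffolds
#' are the "identifiable W fragments": for each non-PAR stratum the
#' homologous Z interval is tiled into `w_tile` pieces of which a
#' stratum-specific fraction (`w_retention`) is retained, emulating the
#' progressive loss of alignable W sequence in older strata.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `zw_genome`: a list with elements
#'   `scaffolds` (data frame: scaffold, length, true_label in AUTO/Z/W,
#'   chrom, chrom_start, chrom_end, stratum), `strata_map` (start, end,
#'   stratum), `w_fragments` (Z-homologous intervals of the W scaffolds)
#'   and `config`.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  seg <- strata_segments(config)

  with_sim_seed(config$seed, 101L, {
    scaf <- list()
    for (i in seq_len(config$n_autosomes)) {
      t <- tile_intervals(config$autosome_len, config$scaffold_len)
      scaf[[length(scaf) + 1L]] <- data.frame(
        scaffold = sprintf("A%d_%04d", i, seq_len(nrow(t))),
        length = t$end - t$start, true_label = "AUTO",
        chrom = sprintf("chrA%d", i), chrom_start = t$start,
        chrom_end = t$end, stratum = NA_character_)
    }
    t <- tile_intervals(config$z_len, config$scaffold_len)
    mid <- (t$start + t$end) / 2
    z_stratum <- seg$stratum[findInterval(mid, seg$start)]
    scaf[[length(scaf) + 1L]] <- data.frame(
      scaffold = sprintf("Z_%04d", seq_len(nrow(t))),
      length = t$end - t$start, true_label = "Z",
      chrom = "chrZ", chrom_start = t$start, chrom_end = t$end,
      stratum = z_stratum)

    wfrag <- list()
    non_par <- seg[seg$stratum != "PAR", , drop = FALSE]
    for (j in seq_len(nrow(non_par))) {
      tiles <- tile_intervals(non_par$end[j] - non_par$start[j], config$w_tile)
      keep <- stats::runif(nrow(tiles)) < config$w_retention[
        match(non_par$stratum[j], seg$stratum[seg$stratum != "PAR"])]
      if (!any(keep)) next
      tiles <- tiles[keep, , drop = FALSE]
      wfrag[[length(wfrag) + 1L]] <- data.frame(
        z_start = tiles$start + non_par$start[j],
        z_end = tiles$end + non_par$start[j],
        stratum = non_par$stratum[j])
    }
    wfrag <- if (length(wfrag)) do.call(rbind, wfrag) else
      data.frame(z_start = numeric(), z_end = numeric(),
                 stratum = character())
    wfrag <- wfrag[order(wfrag$z_start), , drop = FALSE]
    rownames(wfrag) <- NULL
    if (nrow(wfrag)) {
      scaf[[length(scaf) + 1L]] <- data.frame(
        scaffold = sprintf("W_%04d", seq_len(nrow(wfrag))),
        length = wfrag$z_end - wfrag$z_start, true_label = "W",
        chrom = "chrW", chrom_start = wfrag$z_start,
        chrom_end = wfrag$z_end, stratum = wfrag$stratum)
    }
    scaffolds <- do.call(rbind, scaf)
    rownames(scaffolds) <- NULL

    model <- list(scaffolds = scaffolds,
                  strata_map = seg[, c("start", "end", "stratum")],
                  w_fragments = wfrag,
                  config = config)
    class(model) <- "zw_genome"
    model
  })
}

#' @export
print.zw_genome <- function(x, ...) {
  tab <- table(x$scaffolds$true_label)
  cat("zw_genome:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
      sprintf("| %d strata segment(s)\n", nrow(x$strata_map)))
  invisible(x)
}

## Copy number carried by `sex` for a scaffold window.  PAR windows on the Z
## are diploid in both sexes.
copy_number <- function(label, sex, in_par) {
  ifelse(label == "AUTO", 2,
  ifelse(label == "Z", ifelse(sex == "M", 2, ifelse(in_par, 2, 1)),
  ifelse(sex == "F", 1, 0)))  # W
}

#' Simulate windowed read depth for one sex
#'
#' Depth is drawn per `depth_window` as Poisson with mean
#' `copy_number/2 * mean_depth`, i.e. autosomes see the full per-sex depth,
#' the hemizygous female Z half of it, and the male W nothing (unless
#' `mismap_rate > 0`).  Values are per-base mean depth estimates for the
#' window; the Poisson approximation at window granularity is what every
#' downstream consumer (scaffold means, ratio tracks) uses.
#'
#' @param model a [simulate_genome()] result.
#' @param sex `"M"` or `"F"`.
#' @param config optionally override `model$config`.
#' @return data frame with columns scaffold, start, end (0-based half-open,
#'   scaffold-local), depth.
#' @export
simulate_depth <- function(model, sex, config = model$config) {
  if (!inherits(model, "zw_genome")) stop_input("model must be a zw_genome")
  if (!is.character(sex) || length(sex) != 1L || !sex %in% c("M", "F"))
    stop_input("unknown sex label '%s' (use \"M\" or \"F\")", as.character(sex)[1])
  lambda <- if (sex == "M") config$mean_depth_m else config$mean_depth_f
  par_start <- round(config$z_len * (1 - config$par_fraction))

  with_sim_seed(config$seed, if (sex == "M") 211L else 212L, {
    sc <- model$scaffolds
    out <- vector("list", nrow(sc))
    for (i in seq_len(nrow(sc))) {
      t <- tile_intervals(sc$length[i], config$depth_window)
      in_par <- sc$true_label[i] == "Z" &
        (sc$chrom_start[i] + t$start) >= par_start
      cn <- copy_number(sc$true_label[i], sex, in_par)
      mu <- cn / 2 * lambda
      mu[cn == 0] <- config$mismap_rate * lambda
      out[[i]] <- data.frame(scaffold = sc$scaffold[i], start = t$start,
                             end = t$end, depth = stats::rpois(nrow(t), mu))
    }
    do.call(rbind, out)
  })
}

#' Simulate a variant table for one sex
#'
#' True heterozygous sites arise on diploid compartments only: autosomes in
#' both sexes at `het_auto`, the male Z at `het_z_male` and the female PAR at
#' `het_auto`.  The hemizygous female Z and the single-copy W can never be
#' truly heterozygous; any heterozygous call there is error-driven.
#' Sequencing errors produce spurious low-quality heterozygous calls at
#' `seq_error` per base on every compartment present in the individual.
#' Homozygous-alternative sites (fixed differences from the reference) are
#' added at `het_auto/2` for realism.  Site depth is Poisson with the
#' compartment's total copy depth; quality scales with depth for genuine
#' calls and is exponentially distributed (mean 15) for error calls, so the
#' standard quality filter separates them.
#'
#' @inheritParams simulate_depth
#' @return data frame with columns scaffold, pos (1-based), ref, alt, qual,
#'   depth, gt (VCF genotype string), genotype ("het"/"hom") and origin
#'   ("het"/"hom"/"error"; simulator ground truth).
#' @export
simulate_variants <- function(model, sex, config = model$config) {
  if (!inherits(model, "zw_genome")) stop_input("model must be a zw_genome")
  if (!sex %in% c("M", "F")) stop_input("unknown sex label '%s'", sex)
  lambda <- if (sex == "M") config$mean_depth_m else config$mean_depth_f
  par_start <- round(config$z_len * (1 - config$par_fraction))
  bases <- c("A", "C", "G", "T")

  with_sim_seed(config$seed, if (sex == "M") 311L else 312L, {
    sc <- model$scaffolds
    out <- list()
    for (i in seq_len(nrow(sc))) {
      lab <- sc$true_label[i]
      in_par_scaf <- lab == "Z" && sc$chrom_start[i] >= par_start
      cn <- copy_number(lab, sex, in_par_scaf)
      if (cn == 0) next                     # chromosome absent in this sex
      p_het <- if (lab == "AUTO" || in_par_scaf) config$het_auto
               else if (lab == "Z" && sex == "M") config$het_z_male
               else 0                        # hemizygous female Z, W
      L <- sc$length[i]
      draw <- function(n_rate, origin, gt, qual_fun) {
        n <- stats::rbinom(1L, L, n_rate)
        if (n == 0) return(NULL)
        dp <- stats::rpois(n, cn / 2 * lambda)
        data.frame(scaffold = sc$scaffold[i],
                   pos = sort(sample.int(L, n)),
                   ref = sample(bases, n, replace = TRUE),
                   alt = sample(bases, n, replace = TRUE),
                   qual = qual_fun(n, dp), depth = dp, gt = gt,
                   genotype = if (gt == "1/1") "hom" else "het",
                   origin = origin)
      }
      qual_true <- function(n, dp) round(pmax(stats::rnorm(n, 4 * dp, 25), 1), 1)
      qual_err  <- function(n, dp) round(stats::rexp(n, 1 / 15), 1)
      parts <- list(
        draw(p_het, "het", "0/1", qual_true),
        draw(config$het_auto / 2, "hom", "1/1", qual_true),
        draw(config$seq_error, "error", "0/1", qual_err))
      parts <- Filter(Negate(is.null), parts)
      if (length(parts)) out[[length(out) + 1L]] <- do.call(rbind, parts)
    }
    if (!length(out)) {
      return(data.frame(scaffold = character(), pos = integer(),
                        ref = character(), alt = character(),
                        qual = numeric(), depth = integer(), gt = character(),
                        genotype = character(), origin = character()))
    }
    v <- do.call(rbind, out)
    v <- v[order(v$scaffold, v$pos), , drop = FALSE]
    v <- v[!duplicated(v[, c("scaffold", "pos")]), , drop = FALSE]
    rownames(v) <- NULL
    v
  })
}

#' Generate scaffold sequences for a simulated genome
#'
#' Random uniform DNA, deterministic under the config seed.  Intended for
#' small demonstration genomes (pseudo-chromosome assembly, bundle FASTA);
#' sequence content carries no signal for the coverage-based modules.
#'
#' @inheritParams simulate_depth
#' @return a [Biostrings::DNAStringSet] named by scaffold.
#' @export
simulate_sequences <- function(model, config = model$config) {
  with_sim_seed(config$seed, 401L, {
    seqs <- vapply(model$scaffolds$length, random_dna, character(1))
    names(seqs) <- model$scaffolds$scaffold
    Biostrings::DNAStringSet(seqs)
  })
}
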