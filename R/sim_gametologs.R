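## Jukes-Cantor helpers.  Distances d are expected substitutions/site;
## p is the corresponding expected proportion of observed differences.
jc_p_from_d <- function(d) 3 / 4 * (1 - exp(-4 * d / 3))
jc_d_from_p <- function(p) {
  if (any(p >= 0.75)) stop_input("p-distance %.3f is saturated under JC", max(p))
  -3 / 4 * log(1 - 4 * p / 3)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_str <- function(x, i) paste(x[(3 * i - 2):(3 * i)], collapse = "")

## Substitute each mutable site with prob p (uniform over the 3 other
## bases), then re-draw any codon that became a stop so ORFs stay readable.
## First and last codons (start ATG, terminal stop) are never touched.
mutate_cds <- function(x, p) {
  if (p <= 0) return(x)
  L <- length(x)
  mutable <- 4:(L - 3)
  hit <- mutable[stats::runif(length(mutable)) < p]
  if (!length(hit)) return(x)
  y <- x
  y[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1L),
                   character(1))
  for (ci in unique(ceiling(hit / 3))) {
    tries <- 0L
    while (codon_str(y, ci) %in% STOP_CODONS && tries < 20L) {
      idx <- (3 * ci - 2):(3 * ci)
      ch <- intersect(idx, hit)
      y[ch] <- vapply(x[ch], function(b) sample(setdiff(BASES, b), 1L),
                      character(1))
      tries <- tries + 1L
    }
    if (codon_str(y, ci) %in% STOP_CODONS) {
      idx <- (3 * ci - 2):(3 * ci)
      y[idx] <- x[idx]              # give up: revert the codon
    }
  }
  y
}

## Random intact CDS: ATG + random non-stop codons + TAA, as base vector.
random_cds <- function(len_bp) {
  n_codon <- len_bp %/% 3
  mid <- n_codon - 2L
  codons <- character(mid)
  for (i in seq_len(mid)) {
    repeat {
      cd <- paste(sample(BASES, 3, replace = TRUE), collapse = "")
      if (!cd %in% STOP_CODONS) break
    }
    codons[i] <- cd
  }
  strsplit(paste0("ATG", paste(codons, collapse = ""), "TAA"), "")[[1]]
}

#' Simulate gametolog gene alignments across species
#'
#' For each gene an ancestral intact CDS evolves along a tree in which the
#' Z--W split occurred at the age of the gene's stratum (total Z--W
#' p-distance = the stratum's configured divergence, via exact Jukes--Cantor
#' calibration) and the species split at `species_split_div` (a JC
#' distance).  When the species split is younger than the stratum the
#' stratum is shared: Z copies of all species are mutually closer than any
#' Z--W pair.  When it is older, each lineage suppressed recombination
#' independently.  W copies then acquire ORF disruptions at
#' `w_disruption_rate` expected events per unit divergence, inserted as
#' single-base deletions (frameshift) or in-frame stop-codon substitutions
#' with equal probability, at uniform interior codons.  Mutated codons are
#' never allowed to become stops, so the recorded disruption list is the
#' complete ground truth recoverable by [scan_orf()].
#'
#' Genes are assigned to strata proportionally to stratum length.
#'
#' @param config a [sim_config()] object.
#' @return object of class `zw_gametolog_set`: list with `genes` (a list;
#'   each element has gene_id, stratum, target_divergence, aln -- a named
#'   character vector of aligned sequences `<species>_Z` / `<species>_W` --
#'   and `disruptions`, a data frame with species, type, pos in Z
#'   coordinates), plus `species` and `config`.
#' @export
simulate_gametologs <- function(config) {
  validate_sim_config(config)
  seg <- strata_segments(config)
  seg <- seg[seg$stratum != "PAR", , drop = FALSE]
  sp <- config$species
  d_sp <- config$species_split_div

  with_sim_seed(config$seed, 501L, {
    n <- config$n_gametolog_genes
    strata_of <- sample(seg$stratum, n, replace = TRUE,
                        prob = seg$end - seg$start)
    lens <- 3L * round(stats::runif(n, config$gene_len_range[1],
                                    config$gene_len_range[2]) / 3)
    genes <- vector("list", n)
    for (g in seq_len(n)) {
      p_s <- seg$divergence[match(strata_of[g], seg$stratum)]
      D_s <- if (p_s > 0) jc_d_from_p(p_s) else 0
      anc <- random_cds(lens[g])
      tips <- list()
      if (d_sp <= D_s) {            # shared stratum: ZW split predates species
        z_anc <- mutate_cds(anc, jc_p_from_d((D_s - d_sp) / 2))
        w_anc <- mutate_cds(anc, jc_p_from_d((D_s - d_sp) / 2))
        for (s in sp) {
          tips[[paste0(s, "_Z")]] <- mutate_cds(z_anc, jc_p_from_d(d_sp / 2))
          tips[[paste0(s, "_W")]] <- mutate_cds(w_anc, jc_p_from_d(d_sp / 2))
        }
      } else {                      # lineage-specific stratum
        for (s in sp) {
          s_anc <- mutate_cds(anc, jc_p_from_d((d_sp - D_s) / 2))
          tips[[paste0(s, "_Z")]] <- mutate_cds(s_anc, jc_p_from_d(D_s / 2))
          tips[[paste0(s, "_W")]] <- mutate_cds(s_anc, jc_p_from_d(D_s / 2))
        }
      }

      n_codon <- lens[g] %/% 3
      disr <- list()
      for (s in sp) {
        w <- tips[[paste0(s, "_W")]]
        n_d <- stats::rpois(1L, config$w_disruption_rate * p_s)
        n_d <- min(n_d, (n_codon - 2L) %/% 2L)
        if (n_d > 0) {
          ## non-adjacent interior codons, so indel runs never merge and the
          ## recorded disruption list stays exactly recoverable
          repeat {
            codons <- sample(2:(n_codon - 1L), n_d)
            if (n_d == 1L || all(diff(sort(codons)) >= 2L)) break
          }
          types <- sample(c("premature_stop", "frameshift"), n_d,
                          replace = TRUE)
          for (j in seq_len(n_d)) {
            idx <- (3 * codons[j] - 2):(3 * codons[j])
            if (types[j] == "premature_stop") {
              w[idx] <- strsplit(sample(STOP_CODONS, 1L), "")[[1]]
              pos <- idx[1]
            } else {
              pos <- sample(idx, 1L)
              w[pos] <- "-"
            }
            disr[[length(disr) + 1L]] <- data.frame(
              species = s, type = types[j], pos = pos)
          }
          tips[[paste0(s, "_W")]] <- w
        }
      }
      disr <- if (length(disr)) do.call(rbind, disr) else
        data.frame(species = character(), type = character(), pos = integer())
      disr <- disr[order(disr$species, disr$pos), , drop = FALSE]
      rownames(disr) <- NULL

      genes[[g]] <- list(
        gene_id = sprintf("gene%03d", g), stratum = strata_of[g],
        target_divergence = p_s,
        aln = vapply(tips, paste, character(1), collapse = ""),
        disruptions = disr)
    }
    out <- list(genes = genes, species = sp, config = config)
    class(out) <- "zw_gametolog_set"
    out
  })
}

#' @export
print.zw_gametolog_set <- function(x, ...) {
  cat(sprintf("zw_gametolog_set: %d gene(s), %d species (%s)\n",
              length(x$genes), length(x$species),
              paste(x$species, collapse = ", ")))
  invisible(x)
}
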