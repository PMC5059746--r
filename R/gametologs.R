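## Alignments are handled as named character vectors of equal-length
## strings, or equivalently character matrices (rows = sequences).

aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  v <- lapply(aln, function(s) strsplit(toupper(s), "")[[1]])
  lens <- lengths(v)
  if (length(unique(lens)) != 1L)
    stop_input("aligned sequences must have equal length")
  m <- do.call(rbind, v)
  rownames(m) <- names(aln)
  m
}

aln_strings <- function(m) {
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

#' Clean an alignment and apply the length rule
#'
#' Removes every column containing a gap or an ambiguous (non-ACGT)
#' character -- a strict stand-in for block-based alignment cleaning --
#' then flags alignments whose cleaned length is not greater than
#' `min_len` bp as rejected (they should not enter divergence or tree
#' estimation).
#'
#' @param aln named character vector of aligned sequences (equal length).
#' @param min_len minimum cleaned alignment length in bp (exclusive).
#' @return named character vector of cleaned sequences with attributes
#'   `kept` (logical: passes the length rule) and `cleaned_len`.
#' @export
clean_alignment <- function(aln, min_len = 300) {
  m <- aln_matrix(aln)
  ok_col <- apply(m, 2, function(col) all(col %in% BASES))
  m2 <- m[, ok_col, drop = FALSE]
  out <- aln_strings(m2)
  attr(out, "cleaned_len") <- ncol(m2)
  attr(out, "kept") <- ncol(m2) > min_len
  out
}

#' Pairwise sequence divergence
#'
#' p-distance (mismatches over ungapped shared sites) or Kimura
#' two-parameter distance from transition/transversion counts.  K2P is
#' flagged saturated (NA with a warning) when its logarithms are
#' undefined.
#'
#' @param aln two aligned sequences (named character vector of length 2,
#'   or a 2-row matrix).
#' @param model `"p"` or `"K2P"`.
#' @return the divergence in substitutions/site.
#' @export
pairwise_divergence <- function(aln, model = c("p", "K2P")) {
  model <- match.arg(model)
  m <- aln_matrix(aln)
  if (nrow(m) != 2L) stop_input("pairwise divergence needs exactly 2 sequences")
  ok <- m[1, ] %in% BASES & m[2, ] %in% BASES
  a <- m[1, ok]; b <- m[2, ok]
  n <- length(a)
  if (!n) return(NaN)
  if (model == "p") return(sum(a != b) / n)
  purine <- c("A", "G")
  transition <- (a != b) & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(a != b & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P distance saturated; returning NA")
    return(NA_real_)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Scan a W gametolog for ORF disruptions against its intact Z partner
#'
#' The Z sequence (gaps removed) must be an intact ORF: starts with ATG,
#' length a multiple of three, no internal stop codon.  Walking the
#' alignment in the Z reading frame, a premature stop is an in-frame stop
#' codon in the W (all three of a Z codon's columns present in W) before
#' the terminal Z codon; an insertion or deletion run whose length is not
#' divisible by three is a frameshift.  Frameshift accounting is by runs,
#' so paired indels whose net length restores the frame do not flag
#' downstream codons.  Positions are 1-based Z coordinates (codon start
#' for stops, first affected base for indel runs).
#'
#' @param z_seq,w_seq aligned sequences (equal length, `-` for gaps).
#' @return data frame of class `zw_orf_scan` with columns type
#'   ("premature_stop"/"frameshift") and pos; zero rows = intact ORF.
#' @export
scan_orf <- function(z_seq, w_seq) {
  m <- aln_matrix(c(z = z_seq, w = w_seq))
  z <- m[1, ]; w <- m[2, ]
  shared_gap <- z == "-" & w == "-"
  z <- z[!shared_gap]; w <- w[!shared_gap]

  z_ungapped <- z[z != "-"]
  L <- length(z_ungapped)
  if (L < 6L || L %% 3L != 0L ||
      paste(z_ungapped[1:3], collapse = "") != "ATG")
    stop_input("reference ORF invalid: Z is not an intact reading frame")
  n_codon <- L %/% 3L
  z_codons <- vapply(seq_len(n_codon),
                     function(i) paste(z_ungapped[(3 * i - 2):(3 * i)],
                                       collapse = ""), character(1))
  if (any(z_codons[-n_codon] %in% STOP_CODONS))
    stop_input("reference ORF invalid: internal stop codon in Z")

  zpos <- cumsum(z != "-")          # Z coordinate of each column (1-based)
  events <- list()

  ## indel runs: W gap at a Z base (deletion) or W base at a Z gap (insertion)
  run_type <- ifelse(z != "-" & w == "-", "del",
                     ifelse(z == "-" & w != "-", "ins", "none"))
  r <- rle(run_type)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] == "none") next
    if (r$lengths[j] %% 3L == 0L) next
    col0 <- idx_start[j]
    pos <- if (r$values[j] == "del") zpos[col0] else max(zpos[col0], 1L)
    events[[length(events) + 1L]] <- data.frame(type = "frameshift",
                                                pos = as.integer(pos))
  }

  ## premature stops, assessed per Z codon in the reference frame
  col_of <- which(z != "-")
  for (i in seq_len(n_codon - 1L)) {
    cols <- col_of[(3 * i - 2):(3 * i)]
    wc <- w[cols]
    if (any(wc == "-")) next
    if (paste(wc, collapse = "") %in% STOP_CODONS)
      events[[length(events) + 1L]] <- data.frame(
        type = "premature_stop", pos = as.integer(3L * i - 2L))
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), pos = integer())
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("zw_orf_scan", "data.frame")
  out
}

#' Pseudogene fraction among gametolog pairs
#'
#' @param status logical vector (TRUE = pseudogene, i.e. at least one ORF
#'   disruption) or a data frame with a `w_status` column holding
#'   "intact"/"pseudogene".
#' @return list: n_total, n_pseudo, percent (2 decimals).
#' @export
pseudogene_fraction <- function(status) {
  if (is.data.frame(status)) status <- status$w_status == "pseudogene"
  if (!length(status)) stop_input("no gametolog pairs")
  n <- length(status)
  k <- sum(status)
  list(n_total = n, n_pseudo = k, percent = round(100 * k / n, 2))
}

#' Pairwise distance matrix for a set of aligned sequences
#'
#' @param aln named character vector of aligned sequences (>= 3).
#' @param model `"p"` or `"K2P"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, model = c("p", "K2P")) {
  model <- match.arg(model)
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 3L) stop_input("need at least 3 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- pairwise_divergence(m[c(i, j), , drop = FALSE],
                                              model = model)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration with negative branch lengths clamped to zero.
#' Taxa are ordered by name before agglomeration so that ties resolve
#' deterministically regardless of input order.
#'
#' @param D symmetric distance matrix with row/column names.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop_input("distance matrix needs taxon names")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop_input("distance matrix must be symmetric")
  if (any(!is.finite(D))) stop_input("distance matrix must be finite")
  o <- order(rownames(D))
  tr <- ape::nj(D[o, o])
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## Is tip set `tips` separable by a single edge of the unrooted tree?
edge_separable <- function(tree, tips) {
  all_tips <- tree$tip.label
  tips <- intersect(tips, all_tips)
  n <- length(all_tips)
  k <- length(tips)
  if (k == 0L || k == n) return(FALSE)
  if (k == 1L || k == n - 1L) return(TRUE)   # pendant edges always separate
  parts <- ape::prop.part(ape::unroot(tree))
  labs <- attr(parts, "labels")
  target <- sort(match(tips, labs))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, target) ||
        identical(sort(setdiff(seq_len(n), sp)), target)) return(TRUE)
  }
  FALSE
}

#' Test whether a gametolog tree clusters by chromosome or by species
#'
#' On the unrooted gene tree, `by_chromosome` requires the Z-tip set (and
#' hence the W-tip set) to be separable by a single edge: all species' Z
#' copies cluster together, apart from all W copies, implying that
#' recombination suppression (the stratum) predates the species splits.
#' `by_species` requires each species' {Z, W} pair to be edge-separable:
#' suppression happened independently after the splits.  Anything else is
#' unresolved.
#'
#' @param tree a `phylo` tree whose tips are labelled `<species>_Z` /
#'   `<species>_W`, or supply `labels`.
#' @param labels optional data frame tip/species/chromosome overriding the
#'   label convention.
#' @return list of class `zw_dating`: clustering ("by_chromosome",
#'   "by_species" or "unresolved"), tree (newick string), species.
#' @export
cluster_by_chromosome_test <- function(tree, labels = NULL) {
  tips <- tree$tip.label
  if (is.null(labels)) {
    if (!all(grepl("_[ZW]$", tips)))
      stop_input("tip '%s' lacks a _Z/_W chromosome label",
                 tips[!grepl("_[ZW]$", tips)][1])
    labels <- data.frame(tip = tips,
                         species = sub("_[ZW]$", "", tips),
                         chromosome = sub("^.*_", "", tips))
  }
  miss <- setdiff(tips, labels$tip)
  if (length(miss)) stop_input("missing label for tip '%s'", miss[1])
  sp <- unique(labels$species)
  if (length(sp) < 2L) stop_input("need at least 2 species")
  z_tips <- labels$tip[labels$chromosome == "Z"]

  clustering <- if (edge_separable(tree, z_tips)) {
    "by_chromosome"
  } else if (all(vapply(sp, function(s)
    edge_separable(tree, labels$tip[labels$species == s]), logical(1)))) {
    "by_species"
  } else {
    "unresolved"
  }
  out <- list(clustering = clustering, tree = ape::write.tree(tree),
              species = sp)
  class(out) <- "zw_dating"
  out
}

#' Full degeneration report for a simulated or ingested gametolog set
#'
#' For every gene and species: cleans the Z/W pair alignment, computes
#' divergence (genes failing the length rule get NA), scans the W ORF, and
#' classifies the gene tree topology across species.
#'
#' @param alignments named list (gene id) of named character vectors of
#'   aligned sequences (`<species>_Z`/`<species>_W`), e.g. from
#'   [read_gametolog_alignments()] or a `zw_gametolog_set`'s genes.
#' @param model divergence model.
#' @param min_len cleaned-alignment length rule.
#' @return list: `pairs` (data frame gene_id, species, aligned_len,
#'   divergence, w_status, n_disruptions), `trees` (data frame gene_id,
#'   clustering), `pseudogene` (the [pseudogene_fraction()] over pairs).
#' @export
gametolog_report <- function(alignments, model = "p", min_len = 300) {
  if (inherits(alignments, "zw_gametolog_set")) {
    alignments <- stats::setNames(
      lapply(alignments$genes, `[[`, "aln"),
      vapply(alignments$genes, `[[`, "", "gene_id"))
  }
  pair_rows <- list()
  tree_rows <- list()
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    species <- unique(sub("_[ZW]$", "", names(aln)))
    for (s in species) {
      zi <- paste0(s, "_Z"); wi <- paste0(s, "_W")
      if (!all(c(zi, wi) %in% names(aln))) next
      cl <- clean_alignment(aln[c(zi, wi)], min_len = min_len)
      div <- if (attr(cl, "kept")) pairwise_divergence(cl, model = model)
             else NA_real_
      scan <- scan_orf(aln[[zi]], aln[[wi]])
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        gene_id = g, species = s, aligned_len = attr(cl, "cleaned_len"),
        divergence = div,
        w_status = if (nrow(scan)) "pseudogene" else "intact",
        n_disruptions = nrow(scan))
    }
    if (length(species) >= 2L) {
      cl <- clean_alignment(aln, min_len = min_len)
      if (attr(cl, "kept")) {
        res <- cluster_by_chromosome_test(nj_tree(distance_matrix(
          cl, model = model)))
        tree_rows[[length(tree_rows) + 1L]] <- data.frame(
          gene_id = g, clustering = res$clustering)
      }
    }
  }
  pairs <- do.call(rbind, pair_rows)
  trees <- if (length(tree_rows)) do.call(rbind, tree_rows) else
    data.frame(gene_id = character(), clustering = character())
  list(pairs = pairs, trees = trees,
       pseudogene = pseudogene_fraction(pairs$w_status == "pseudogene"))
}
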