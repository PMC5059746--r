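#' Run every generator for a configuration
#'
#' Convenience orchestration: genome model, per-sex depth and variant
#' tables, gametolog set, Z/W alignment fragments, conservation scores,
#' repeat annotation and k-mer histogram, all deterministic under the
#' config seed.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `zw_bundle` holding all simulated objects.
#' @export
simulate_bundle <- function(config) {
  model <- simulate_genome(config)
  out <- list(
    config = config,
    model = model,
    depth_f = simulate_depth(model, "F"),
    depth_m = simulate_depth(model, "M"),
    variants_f = simulate_variants(model, "F"),
    variants_m = simulate_variants(model, "M"),
    gametologs = simulate_gametologs(config),
    zw_alignments = simulate_zw_alignments(model),
    conservation = simulate_conservation_scores(model),
    repeats = simulate_repeats(model),
    kmer_histogram = simulate_kmer_histogram(config))
  class(out) <- "zw_bundle"
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_minimal_vcf <- function(variants, path, sample = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)),
    con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%d\tGT\t%s",
                       variants$scaffold, variants$pos, variants$ref,
                       variants$alt, format(variants$qual, trim = TRUE),
                       variants$depth, variants$gt), con)
  }
  invisible(path)
}

write_aligned_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(aln)) writeLines(c(paste0(">", nm), aln[[nm]]), con)
  invisible(path)
}

#' Write a simulated bundle to disk
#'
#' Emits every downstream input in its standard text format: depth TSVs,
#' VCFs (1-based), repeat BED (0-based half-open), per-gene aligned
#' gametolog FASTAs, Z/W alignment fragment TSV, conservation TSV, k-mer
#' histogram (two-column text) and a ground-truth JSON with true scaffold
#' labels, the stratum map and the disruption list.  Scaffold FASTA is
#' written when the genome is small enough to be practical as text
#' (`write_fasta = NULL` auto-decides at 30 Mb).
#'
#' @param bundle a [simulate_bundle()] result.
#' @param dir output directory (created if needed).
#' @param write_fasta logical or NULL (auto).
#' @return invisibly, a named character vector of file paths.
#' @export
write_bundle <- function(bundle, dir, write_fasta = NULL) {
  if (!inherits(bundle, "zw_bundle")) stop_input("not a zw_bundle")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop_input("cannot create output directory '%s'", dir)
  p <- function(f) file.path(dir, f)

  write_tsv(bundle$depth_f, p("depth_F.tsv"))
  write_tsv(bundle$depth_m, p("depth_M.tsv"))
  write_minimal_vcf(bundle$variants_f, p("variants_F.vcf"), "female")
  write_minimal_vcf(bundle$variants_m, p("variants_M.vcf"), "male")
  write_tsv(bundle$repeats, p("repeats.bed"))
  write_tsv(bundle$zw_alignments, p("zw_alignments.tsv"))
  write_tsv(bundle$conservation, p("conservation.tsv"))
  utils::write.table(bundle$kmer_histogram$entries, p("kmer.histo"),
                     sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  gdir <- p("gametologs")
  if (!dir.exists(gdir)) dir.create(gdir)
  for (g in bundle$gametologs$genes)
    write_aligned_fasta(as.list(g$aln), file.path(gdir, paste0(g$gene_id, ".fa")))

  total_bp <- sum(bundle$model$scaffolds$length)
  if (is.null(write_fasta)) write_fasta <- total_bp <= 3e7
  if (write_fasta) {
    seqs <- simulate_sequences(bundle$model)
    Biostrings::writeXStringSet(seqs, p("scaffolds.fa"))
  }

  truth <- list(
    scaffolds = bundle$model$scaffolds,
    strata_map = bundle$model$strata_map,
    w_fragments = bundle$model$w_fragments,
    disruptions = do.call(rbind, lapply(bundle$gametologs$genes, function(g) {
      if (!nrow(g$disruptions)) return(NULL)
      cbind(gene_id = g$gene_id, g$disruptions)
    })),
    gene_strata = data.frame(
      gene_id = vapply(bundle$gametologs$genes, `[[`, "", "gene_id"),
      stratum = vapply(bundle$gametologs$genes, `[[`, "", "stratum"),
      target_divergence = vapply(bundle$gametologs$genes, `[[`,
                                 numeric(1), "target_divergence")),
    seed = bundle$config$seed)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       digits = NA, auto_unbox = TRUE, null = "null")

  files <- c(depth_f = p("depth_F.tsv"), depth_m = p("depth_M.tsv"),
             vcf_f = p("variants_F.vcf"), vcf_m = p("variants_M.vcf"),
             repeats = p("repeats.bed"), zw_alignments = p("zw_alignments.tsv"),
             conservation = p("conservation.tsv"), histo = p("kmer.histo"),
             gametolog_dir = gdir, truth = p("truth.json"))
  if (write_fasta) files["fasta"] <- p("scaffolds.fa")
  invisible(files)
}

#' Read a depth table
#'
#' Accepts either the windowed form (`scaffold start end depth`, 0-based
#' half-open) or samtools-depth-like per-base form (`scaffold pos depth`,
#' 1-based), which is converted to 1-bp windows.
#'
#' @param path TSV path (header optional for the 3-column form).
#' @return data frame: scaffold, start, end, depth.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop_input("depth table not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("scaffold|chrom", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) == 4L) {
    names(df) <- c("scaffold", "start", "end", "depth")
  } else if (ncol(df) == 3L) {
    names(df) <- c("scaffold", "pos", "depth")
    df <- data.frame(scaffold = df$scaffold, start = df$pos - 1L,
                     end = df$pos, depth = df$depth)
  } else {
    stop_input("depth table must have 3 or 4 columns, got %d", ncol(df))
  }
  df
}

#' Read a repeat annotation BED
#'
#' BED6+2 with family and percent divergence in columns 7 and 8.
#'
#' @param path BED path (header optional).
#' @return data frame: chrom, start, end, name, score, strand, family,
#'   divergence.
#' @export
read_repeat_bed <- function(path) {
  if (!file.exists(path)) stop_input("BED not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^(chrom|#)", lines[1])) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_bad <- which(lengths(fields) < 8L)
  if (length(n_bad))
    stop_input("malformed BED line %d: expected >=8 fields", n_bad[1])
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)[, 1:8]
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "family", "divergence")
  for (cc in c("start", "end", "score", "divergence")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stop_input("malformed BED line %d: non-numeric '%s'",
                 which(is.na(v))[1], cc)
    df[[cc]] <- v
  }
  df
}

#' Read a directory of aligned gametolog FASTAs
#'
#' @param dir directory of per-gene aligned FASTA files (`<gene>.fa`).
#' @return named list (by gene id) of named character vectors of aligned
#'   sequences.
#' @export
read_gametolog_alignments <- function(dir) {
  if (!dir.exists(dir)) stop_input("gametolog directory not found: %s", dir)
  files <- list.files(dir, pattern = "\\.fa(sta)?$", full.names = TRUE)
  out <- lapply(files, function(f) {
    ss <- Biostrings::readBStringSet(f)
    stats::setNames(as.character(ss), names(ss))
  })
  names(out) <- tools::file_path_sans_ext(basename(files))
  out
}

#' Read a bundle's ground-truth JSON
#'
#' @param path path to `truth.json`.
#' @return list with scaffolds, strata_map, w_fragments, disruptions,
#'   gene_strata as data frames.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop_input("truth file not found: %s", path)
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("scaffolds", "strata_map", "w_fragments", "disruptions",
               "gene_strata"))
    if (!is.null(tr[[nm]])) tr[[nm]] <- as.data.frame(tr[[nm]])
  tr
}
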