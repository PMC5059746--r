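#' Read a k-mer depth histogram
#'
#' Two-column whitespace-separated text (as produced by jellyfish-style
#' counters): depth and distinct-k-mer count per line.
#'
#' @param path histogram file.
#' @param k k-mer length the histogram was computed with (metadata only).
#' @return object of class `zw_kmer_histogram`.
#' @export
read_histogram <- function(path, k = 17L) {
  if (!file.exists(path)) stop_input("histogram file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_input("histogram file is empty: %s", path)
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop_input("parse error at line %d: expected 2 fields", bad[1])
  depth <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  count <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(depth) | is.na(count) | depth != floor(depth) |
                 count != floor(count))
  if (length(bad))
    stop_input("parse error at line %d: non-integer field", bad[1])
  if (any(depth < 1)) stop_input("depths must be >= 1")
  if (anyDuplicated(depth)) stop_input("duplicate depth bins in histogram")
  o <- order(depth)
  hist <- list(k = as.integer(k),
               entries = data.frame(depth = depth[o], count = count[o]))
  class(hist) <- "zw_kmer_histogram"
  hist
}

#' Locate the error cutoff and the main peak of a k-mer spectrum
#'
#' Counts are smoothed with a 3-bin moving average to suppress
#' noise-induced spurious extrema.  Scanning from the lowest depth, the
#' error cutoff is the first local minimum of the smoothed counts (the
#' trough between the sequencing-error spike and the main peak); when the
#' spectrum starts by rising (no error spike) the cutoff sits below the
#' first depth bin.  The peak depth is the argmax of the smoothed counts
#' over depths above the cutoff, ties broken toward the lower depth.  A
#' monotonically decreasing spectrum has no main peak and is an error.
#'
#' @param hist a `zw_kmer_histogram`.
#' @return list(error_cutoff, peak_depth) (integer depths).
#' @export
find_peak <- function(hist) {
  e <- hist$entries
  if (nrow(e) < 3L) stop_input("need at least 3 depth bins")
  ## place counts on a dense grid so smoothing sees missing bins as zeros
  depth <- seq(min(e$depth), max(e$depth))
  count <- numeric(length(depth))
  count[match(e$depth, depth)] <- e$count
  n <- length(count)
  s <- (c(count[1], count[-n]) + count + c(count[-1], count[n])) / 3

  if (count[1] < count[2]) {
    ## rises from the start: no error spike to exclude
    cutoff <- if (count[1] == 0) depth[1] else depth[1] - 1L
  } else {
    i <- 2L
    while (i < n && s[i] <= s[i - 1]) i <- i + 1L
    if (i == n && s[n] <= s[n - 1])
      stop_input("no main peak: spectrum decreases monotonically")
    cutoff <- depth[i - 1L]       # first local minimum of the smoothed counts
  }
  above <- which(depth > cutoff)
  if (!length(above)) stop_input("no main peak above the error cutoff")
  peak <- depth[above[which.max(s[above])]]
  list(error_cutoff = as.integer(cutoff), peak_depth = as.integer(peak))
}

#' Estimate genome size from a k-mer spectrum
#'
#' Implements `G = K_num / Peak_depth`: the total number of k-mer instances
#' in the main distribution divided by the expected (per-copy) k-mer depth.
#' `K_num` sums `depth x count` over bins above the error cutoff, so the
#' sequencing-error spike never inflates the estimate.  `Peak_depth` is the
#' expected value of the k-mer depth over the same bins
#' (`sum(d*c)/sum(c)`), rounded to the nearest integer; the modal depth
#' from [find_peak()] is retained for diagnostics but is quantized too
#' coarsely (a per-copy depth just below an integer shifts the mode a full
#' unit, a ~1/depth relative error in G).
#'
#' @param hist a `zw_kmer_histogram`.
#' @return object of class `zw_genome_size`: list(G, peak_depth,
#'   modal_depth, error_cutoff, k_num_used).
#' @export
estimate_genome_size <- function(hist) {
  pk <- find_peak(hist)
  e <- hist$entries
  keep <- e$depth > pk$error_cutoff
  k_num <- sum(e$depth[keep] * e$count[keep])
  peak <- as.integer(round(k_num / sum(e$count[keep])))
  out <- list(G = k_num / peak, peak_depth = peak,
              modal_depth = pk$peak_depth,
              error_cutoff = pk$error_cutoff, k_num_used = k_num)
  class(out) <- "zw_genome_size"
  out
}

#' @export
print.zw_genome_size <- function(x, ...) {
  cat(sprintf(paste0("genome size estimate: G = %.4g bp ",
                     "(K_num = %.4g, peak depth = %d, error cutoff <= %d)\n"),
              x$G, x$k_num_used, x$peak_depth, x$error_cutoff))
  invisible(x)
}
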