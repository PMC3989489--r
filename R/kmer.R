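# k-mer multiplicity spectrum and genome-size estimation by peak selection.

#' Count the canonical k-mer multiplicity spectrum of a read set
#'
#' k-mers are canonicalized (lexicographic minimum of the k-mer and its reverse
#' complement); k-mers containing N are skipped.
#'
#' @param reads A read table (data.frame with a `seq` column) or a character
#'   vector of sequences.
#' @param k Odd k-mer size, 11 <= k <= 31 (default 17).
#' @return An object of class `kmer_spectrum`: list with `k`, `counts` (a
#'   data.frame of multiplicity and n_kmers) and `total_occurrences`.
#'   Invariant: sum(multiplicity * n_kmers) == total_occurrences.
#' @export
count_kmer_spectrum <- function(reads, k = 17) {
  if (k %% 2 != 1 || k < 11 || k > 31) stop("k must be odd and in [11, 31]")
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0) {
    out <- list(k = k, counts = data.frame(multiplicity = integer(),
                                           n_kmers = numeric()),
                total_occurrences = 0, empty = TRUE)
    return(structure(out, class = "kmer_spectrum"))
  }
  sp <- kmer_spectrum_cpp(seqs, as.integer(k))
  counts <- data.frame(multiplicity = sp$multiplicity, n_kmers = sp$n_kmers)
  mass <- sum(counts$multiplicity * counts$n_kmers)
  stopifnot(isTRUE(all.equal(mass, sp$total_occurrences)))
  structure(list(k = k, counts = counts,
                 total_occurrences = sp$total_occurrences,
                 empty = nrow(counts) == 0),
            class = "kmer_spectrum")
}

# Histogram over the full 1..max multiplicity grid, smoothed by a centered
# moving average of window 3.
smoothed_histogram <- function(spectrum) {
  mx <- max(spectrum$counts$multiplicity)
  h <- numeric(mx)
  h[spectrum$counts$multiplicity] <- spectrum$counts$n_kmers
  if (mx >= 3) {
    sm <- h
    sm[2:(mx - 1)] <- (h[1:(mx - 2)] + h[2:(mx - 1)] + h[3:mx]) / 3
    sm
  } else h
}

#' Detect coverage peaks in a k-mer spectrum
#'
#' Local maxima of the smoothed histogram above the error region. The error
#' region boundary defaults to the first local minimum after multiplicity 1,
#' capped at 10.
#'
#' Minor local maxima (e.g. from doubled repeat k-mers) are suppressed by a
#' relative height floor: a peak must reach `min_height_frac` of the tallest
#' post-cutoff height.
#'
#' @param spectrum A [count_kmer_spectrum()] result.
#' @param error_cutoff Multiplicities <= this value are treated as sequencing
#'   error; NULL to auto-detect.
#' @param min_height_frac Minimum peak height relative to the tallest peak.
#' @return data.frame of peaks (multiplicity, height), ordered by multiplicity,
#'   with attribute `error_cutoff`. Zero rows (flagged via attribute
#'   `no_peak = TRUE`) when no peak lies above the cutoff.
#' @export
detect_peaks <- function(spectrum, error_cutoff = NULL, min_height_frac = 0.05) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (isTRUE(spectrum$empty) || nrow(spectrum$counts) == 0)
    stop("empty spectrum: no k-mers were counted")
  h <- smoothed_histogram(spectrum)
  mx <- length(h)
  if (is.null(error_cutoff)) {
    error_cutoff <- min(10, mx)
    if (mx >= 3) {
      for (m in 2:(mx - 1)) {
        if (m >= 10) break
        if (h[m] <= h[m - 1] && h[m] <= h[m + 1]) {
          error_cutoff <- m
          break
        }
      }
    }
  }
  peaks <- data.frame(multiplicity = integer(), height = numeric())
  if (mx >= 2 && error_cutoff < mx) {
    for (m in seq(max(2, error_cutoff + 1), mx)) {
      left <- h[m - 1]
      right <- if (m < mx) h[m + 1] else -Inf
      if (h[m] > 0 && h[m] >= left && h[m] > right)
        peaks <- rbind(peaks, data.frame(multiplicity = m, height = h[m]))
    }
    if (nrow(peaks))
      peaks <- peaks[peaks$height >= min_height_frac * max(peaks$height), ,
                     drop = FALSE]
    rownames(peaks) <- NULL
  }
  attr(peaks, "error_cutoff") <- error_cutoff
  attr(peaks, "no_peak") <- nrow(peaks) == 0
  peaks
}

#' Estimate genome size from a k-mer spectrum
#'
#' The estimate divides the k-mer mass above the error cutoff by the depth of
#' the highest-multiplicity (homozygous) peak; a lower-multiplicity peak, when
#' present, is reported as the heterozygous peak.
#'
#' @param spectrum A [count_kmer_spectrum()] result.
#' @param peaks Peak table from [detect_peaks()]; NULL to detect here.
#' @return List of class `genome_size_estimate` with `homozygous_peak_depth`,
#'   `heterozygous_peak_depth` (NA when absent), `estimated_size`, `peaks` and
#'   `error_cutoff`.
#' @export
estimate_genome_size <- function(spectrum, peaks = NULL) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (is.null(peaks)) peaks <- detect_peaks(spectrum)
  if (nrow(peaks) == 0)
    stop("no coverage peak above the error cutoff; cannot estimate genome size")
  cutoff <- attr(peaks, "error_cutoff")
  mx <- max(spectrum$counts$multiplicity)
  if (any(peaks$multiplicity > mx))
    stop("peak multiplicity beyond histogram support")
  hom <- peaks$multiplicity[which.max(peaks$multiplicity)]
  het <- if (nrow(peaks) > 1) {
    low <- peaks[peaks$multiplicity < hom, , drop = FALSE]
    low$multiplicity[which.max(low$height)]
  } else NA_integer_
  keep <- spectrum$counts$multiplicity > cutoff
  mass <- sum(spectrum$counts$multiplicity[keep] * spectrum$counts$n_kmers[keep])
  structure(list(
    homozygous_peak_depth = hom,
    heterozygous_peak_depth = het,
    estimated_size = round(mass / hom),
    peaks = peaks,
    error_cutoff = cutoff
  ), class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat("Genome size estimate:", format(x$estimated_size, big.mark = ","), "bp\n")
  cat("  homozygous peak depth:", x$homozygous_peak_depth, "\n")
  if (!is.na(x$heterozygous_peak_depth))
    cat("  heterozygous peak depth:", x$heterozygous_peak_depth, "\n")
  cat("  error cutoff: m <=", x$error_cutoff, "\n")
  invisible(x)
}
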