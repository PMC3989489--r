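# Microsatellite (SSR) detection and summaries.

#' Minimum repeat counts per SSR motif length
#'
#' Defaults: mono 12, di 6, tri 7, tetra 5, penta 5, hexa 5.
#'
#' @param mono,di,tri,tetra,penta,hexa Minimum number of whole repeat units.
#' @return Integer vector of length 6 (names "1".."6").
#' @export
ssr_thresholds <- function(mono = 12, di = 6, tri = 7, tetra = 5, penta = 5,
                           hexa = 5) {
  v <- as.integer(c(mono, di, tri, tetra, penta, hexa))
  if (any(v < 2)) stop("all minimum repeat counts must be >= 2")
  stats::setNames(v, as.character(1:6))
}

#' Canonical SSR motif class
#'
#' The canonical motif is the lexicographic minimum over all rotations of the
#' unit and of its reverse complement, so a locus and its reverse complement on
#' the opposite strand share one class (e.g. (AT)n, (AG)n).
#'
#' @param motif Character vector of repeat units.
#' @return Character vector of canonical motifs.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(u) {
    n <- nchar(u)
    rots <- vapply(seq_len(n) - 1L, function(i)
      paste0(substr(u, i + 1, n), substr(u, 1, i)), character(1))
    rc <- revcomp(u)
    rots_rc <- vapply(seq_len(n) - 1L, function(i)
      paste0(substr(rc, i + 1, n), substr(rc, 1, i)), character(1))
    min(c(rots, rots_rc))
  }, character(1), USE.NAMES = FALSE)
}

#' Find perfect SSR loci
#'
#' Detects all maximal perfect tandem repeats with unit length 1-6 meeting the
#' minimum repeat counts. A run reportable under several unit lengths is
#' reported once, under its smallest (primitive) unit; overlapping loci of
#' distinct motifs are all reported. Coordinates are 0-based, half-open, and
#' cover whole units only.
#'
#' @param sequences Named character vector.
#' @param thresholds Minimum repeats per motif length, from [ssr_thresholds()].
#' @return data.frame: seq_id, start, end, motif (unit as it occurs),
#'   canonical_motif, motif_length, repeat_count.
#' @export
find_ssrs <- function(sequences, thresholds = ssr_thresholds()) {
  if (length(sequences) == 0)
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      motif = character(), canonical_motif = character(),
                      motif_length = integer(), repeat_count = integer(),
                      stringsAsFactors = FALSE))
  hits <- find_ssrs_cpp(unname(sequences), unname(thresholds))
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  out <- data.frame(
    seq_id = ids[hits$seq_index],
    start = hits$start, end = hits$end,
    motif = hits$motif,
    canonical_motif = canonical_motif(hits$motif),
    motif_length = hits$motif_length,
    repeat_count = hits$repeat_count,
    stringsAsFactors = FALSE
  )
  out[order(match(out$seq_id, ids), out$start, out$motif_length), , drop = FALSE]
}

#' Summarize an SSR census
#'
#' @param loci Locus table from [find_ssrs()].
#' @param genome_length Total surveyed length in bases (> 0).
#' @return List with `by_motif_length` (count and fraction per unit length),
#'   `by_canonical_motif` (counts per motif class, most frequent first),
#'   `density_per_100kb` (all loci) and `density_di_to_hexa_per_100kb`
#'   (excluding mononucleotide loci).
#' @export
summarize_ssrs <- function(loci, genome_length) {
  stopifnot(genome_length > 0)
  counts <- integer(6)
  names(counts) <- as.character(1:6)
  if (nrow(loci)) {
    tb <- table(factor(loci$motif_length, levels = 1:6))
    counts[] <- as.integer(tb)
  }
  total <- sum(counts)
  by_len <- data.frame(
    motif_length = 1:6,
    n_loci = unname(counts),
    fraction = if (total > 0) unname(counts) / total else rep(0, 6)
  )
  by_motif <- if (nrow(loci)) {
    tb <- sort(table(loci$canonical_motif), decreasing = TRUE)
    data.frame(canonical_motif = names(tb), n_loci = as.integer(tb),
               stringsAsFactors = FALSE)
  } else data.frame(canonical_motif = character(), n_loci = integer(),
                    stringsAsFactors = FALSE)
  list(
    by_motif_length = by_len,
    by_canonical_motif = by_motif,
    n_loci = total,
    n_loci_di_to_hexa = total - counts[["1"]],
    density_per_100kb = total / genome_length * 1e5,
    density_di_to_hexa_per_100kb = (total - counts[["1"]]) / genome_length * 1e5
  )
}
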