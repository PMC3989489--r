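# Read-level QC, assembly length filtering, contamination screening and
# assembly statistics.

#' QC rules for short-read preprocessing
#'
#' @param min_quality Phred threshold: trailing 3' bases below it are trimmed.
#' @param adaptor_min_match 3'-terminal adaptor matches of MORE than this many
#'   bases are trimmed.
#' @param drop_reads_with_N Remove reads containing N.
#' @param min_sequence_length Assembly length filter threshold (inclusive).
#' @return List of class `qc_rules`.
#' @export
qc_rules <- function(min_quality = 10, adaptor_min_match = 5,
                     drop_reads_with_N = TRUE, min_sequence_length = 300) {
  stopifnot(min_quality > 0, adaptor_min_match > 0, min_sequence_length > 0)
  structure(list(min_quality = min_quality,
                 adaptor_min_match = adaptor_min_match,
                 drop_reads_with_N = drop_reads_with_N,
                 min_sequence_length = min_sequence_length),
            class = "qc_rules")
}

#' Quality-control a read set
#'
#' Reads containing N are removed; trailing 3' bases with phred below
#' `min_quality` are trimmed; a 3'-terminal exact match to the start of an
#' adaptor longer than `adaptor_min_match` bases is trimmed; reads emptied by
#' trimming are removed. Rejection causes are tallied.
#'
#' @param reads data.frame with columns id, seq, qual (phred+33).
#' @param rules A [qc_rules()] object.
#' @param adaptors Character vector of adaptor sequences (may be empty to skip
#'   adaptor trimming).
#' @return List with `reads` (the kept, possibly trimmed read table) and `log`
#'   (named counts: input, contains_N, quality_trimmed, adaptor_trimmed,
#'   emptied, kept).
#' @export
qc_reads <- function(reads, rules = qc_rules(), adaptors = character(0)) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    stop("sequence/quality length mismatch in record ", bad[1],
         " (id ", reads$id[bad[1]], ")")
  n_in <- nrow(reads)
  log <- c(input = n_in, contains_N = 0L, quality_trimmed = 0L,
           adaptor_trimmed = 0L, emptied = 0L, kept = 0L)
  if (rules$drop_reads_with_N) {
    has_n <- grepl("N", reads$seq, fixed = TRUE)
    log["contains_N"] <- sum(has_n)
    reads <- reads[!has_n, , drop = FALSE]
  }
  if (nrow(reads)) {
    # maximal trailing run of bases with phred < min_quality
    pat <- sprintf("[\\x21-\\x%x]+$", 33 + rules$min_quality - 1)
    m <- regexpr(pat, reads$qual, perl = TRUE)
    trim_at <- ifelse(m > 0, m - 1L, nchar(reads$qual))
    log["quality_trimmed"] <- sum(m > 0)
    reads$seq <- substr(reads$seq, 1, trim_at)
    reads$qual <- substr(reads$qual, 1, trim_at)
  }
  if (nrow(reads) && length(adaptors)) {
    trimmed <- logical(nrow(reads))
    for (ad in adaptors) {
      maxj <- min(nchar(ad), max(nchar(reads$seq)))
      if (maxj <= rules$adaptor_min_match) next
      for (j in rev(seq(rules$adaptor_min_match + 1, maxj))) {
        suf <- substr(ad, 1, j)
        hit <- !trimmed & nchar(reads$seq) >= j &
          substr(reads$seq, nchar(reads$seq) - j + 1, nchar(reads$seq)) == suf
        if (any(hit)) {
          reads$seq[hit] <- substr(reads$seq[hit], 1, nchar(reads$seq[hit]) - j)
          reads$qual[hit] <- substr(reads$qual[hit], 1, nchar(reads$seq[hit]))
          trimmed <- trimmed | hit
        }
      }
    }
    log["adaptor_trimmed"] <- sum(trimmed)
  }
  empty <- nchar(reads$seq) == 0
  log["emptied"] <- sum(empty)
  reads <- reads[!empty, , drop = FALSE]
  log["kept"] <- nrow(reads)
  list(reads = reads, log = log)
}

#' Filter sequences by minimum length
#'
#' @param sequences Named character vector.
#' @param min_len Inclusive length threshold (default 300).
#' @return List with `kept` (sequences of length >= min_len), `dropped_total_length`
#'   and `n_dropped`.
#' @export
filter_by_length <- function(sequences, min_len = 300) {
  lens <- nchar(sequences)
  keep <- lens >= min_len
  list(kept = sequences[keep],
       dropped_total_length = sum(lens[!keep]),
       n_dropped = sum(!keep))
}

#' Contamination screening policy
#'
#' @param evalue_cutoff Maximum E-value for a contaminant hit.
#' @param min_coverage Minimum aligned fraction of the query length.
#' @return List of class `contamination_policy`.
#' @export
contamination_policy <- function(evalue_cutoff = 1e-10, min_coverage = 0.10) {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  structure(list(evalue_cutoff = evalue_cutoff, min_coverage = min_coverage),
            class = "contamination_policy")
}

#' Screen sequences against contaminant collections
#'
#' A sequence is contaminated iff some alignment to a contaminant has
#' E <= `evalue_cutoff` and the aligned query span covers at least
#' `min_coverage` of the query length; attribution goes to the best-scoring
#' contaminant set.
#'
#' @param sequences Named character vector to screen.
#' @param contaminant_sets Named list of named character vectors (e.g.
#'   chloroplast, mitochondrial, bacterial, vector collections).
#' @param policy A [contamination_policy()].
#' @return List with `clean` (sequences kept), `contaminated` (a data.frame of
#'   removed ids, attributed source and best score).
#' @export
screen_contamination <- function(sequences, contaminant_sets,
                                 policy = contamination_policy()) {
  stopifnot(length(contaminant_sets) > 0, !is.null(names(contaminant_sets)))
  best_src <- rep(NA_character_, length(sequences))
  best_score <- rep(-Inf, length(sequences))
  names(best_src) <- names(best_score) <- names(sequences)
  for (src in names(contaminant_sets)) {
    hits <- align_sequences(sequences, contaminant_sets[[src]],
                            mode = "megablast_like",
                            evalue_max = policy$evalue_cutoff)
    if (nrow(hits) == 0) next
    cov <- (hits$q_end - hits$q_start) / hits$q_size
    hits <- hits[cov >= policy$min_coverage, , drop = FALSE]
    if (nrow(hits) == 0) next
    agg <- tapply(hits$score, hits$q_name, max)
    upd <- names(agg)[agg > best_score[names(agg)]]
    best_score[upd] <- agg[upd]
    best_src[upd] <- src
  }
  contaminated <- !is.na(best_src)
  list(clean = sequences[!contaminated],
       contaminated = data.frame(
         id = names(sequences)[contaminated],
         source = best_src[contaminated],
         score = best_score[contaminated],
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Assembly statistics (counts, N50, base composition)
#'
#' N50 is the length of the sequence at which the cumulative length, taking
#' sequences longest first, first reaches half the assembly total. GC% excludes
#' N from the denominator.
#'
#' @param sequences Named character vector (non-empty).
#' @return List of class `assembly_stats` with n_sequences, total_length,
#'   average_length, maximum_length, n50, base counts A/T/G/C/N, total_atgc and
#'   gc_percent.
#' @export
compute_assembly_stats <- function(sequences) {
  if (length(sequences) == 0) stop("cannot compute statistics of an empty set")
  lens <- nchar(sequences)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- unname(sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1]])
  dss <- Biostrings::DNAStringSet(unname(sequences))
  freq <- Biostrings::letterFrequency(dss, letters = c("A", "T", "G", "C", "N"))
  tot <- colSums(freq)
  atgc <- sum(tot[c("A", "T", "G", "C")])
  structure(list(
    n_sequences = length(sequences),
    total_length = sum(lens),
    average_length = mean(lens),
    maximum_length = max(lens),
    n50 = n50,
    A = unname(tot["A"]), T = unname(tot["T"]),
    G = unname(tot["G"]), C = unname(tot["C"]), N = unname(tot["N"]),
    total_atgc = atgc,
    gc_percent = 100 * sum(tot[c("G", "C")]) / atgc
  ), class = "assembly_stats")
}

#' Assembly statistics as a one-column table
#'
#' Rows mirror the conventional assembly report order (number of sequences,
#' total/average/maximum length, N50, base counts, total ATGC, GC%).
#'
#' @param stats An `assembly_stats` object.
#' @return data.frame with columns statistic and value.
#' @export
assembly_stats_table <- function(stats) {
  stopifnot(inherits(stats, "assembly_stats"))
  data.frame(
    statistic = c("Number of sequences", "Total length (bp)",
                  "Average length (bp)", "Maximum length (bp)",
                  "N50 length (bp)", "A", "T", "G", "C", "N",
                  "Total (A+T+G+C)", "GC% (GC/ATGC)"),
    value = c(stats$n_sequences, stats$total_length,
              round(stats$average_length, 1), stats$maximum_length, stats$n50,
              stats$A, stats$T, stats$G, stats$C, stats$N, stats$total_atgc,
              round(stats$gc_percent, 1)),
    stringsAsFactors = FALSE
  )
}
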