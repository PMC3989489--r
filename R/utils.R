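# Shared helpers: RNG scoping, sequence primitives, standard-format I/O.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random DNA sequence with a target GC content
#'
#' @param n Sequence length in bases.
#' @param gc_content Target GC fraction in (0, 1).
#' @return A single character string over A/C/G/T.
#' @export
random_dna <- function(n, gc_content = 0.5) {
  stopifnot(n > 0, gc_content > 0, gc_content < 1)
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2, (1 - gc_content) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

phred_to_ascii <- function(q) {
  vapply(q, function(qq) intToUtf8(qq + 33L, multiple = FALSE), character(1))
}

ascii_to_phred <- function(s) utf8ToInt(s) - 33L

#' Read a FASTA file
#'
#' Sequences are uppercased on input; names are the full description lines.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' Malformed records (missing \code{@}/\code{+} markers, or sequence and
#' quality strings of different lengths) abort with the offending line number.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A data.frame with columns id, seq, qual.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4 != 0)
    stop("truncated FASTQ: ", length(ln), " lines is not a multiple of 4")
  n <- length(ln) / 4
  id_l <- ln[seq(1, length(ln), by = 4)]
  seq_l <- ln[seq(2, length(ln), by = 4)]
  plus_l <- ln[seq(3, length(ln), by = 4)]
  qual_l <- ln[seq(4, length(ln), by = 4)]
  bad <- which(substr(id_l, 1, 1) != "@")
  if (length(bad))
    stop("malformed FASTQ header at line ", (bad[1] - 1) * 4 + 1)
  bad <- which(substr(plus_l, 1, 1) != "+")
  if (length(bad))
    stop("malformed FASTQ separator at line ", (bad[1] - 1) * 4 + 3)
  bad <- which(nchar(seq_l) != nchar(qual_l))
  if (length(bad))
    stop("sequence/quality length mismatch at line ", (bad[1] - 1) * 4 + 2)
  data.frame(id = sub("^@", "", id_l), seq = toupper(seq_l), qual = qual_l,
             stringsAsFactors = FALSE)
}

#' Write a read table to a FASTQ file
#'
#' @param reads data.frame with columns id, seq, qual.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), by = 4)] <- reads$seq
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
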