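# Independent oracles and small fixture builders used across test files.

# Mutate a sequence at exactly n substitution positions; returns the mutant
# and the positions (1-based). Positions avoid the first/last `pad` bases so
# local alignments are not end-trimmed.
mutate_known <- function(seq, n, pad = 0) {
  L <- nchar(seq)
  pos <- sample((1 + pad):(L - pad), n)
  r <- charToRaw(seq)
  b <- charToRaw("ACGT")
  for (i in pos) r[i] <- sample(setdiff(b, r[i]), 1)
  list(seq = rawToChar(r), pos = sort(pos))
}

# Brute-force N50: walk the sorted lengths, accumulating until >= half.
n50_oracle <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
  NA_integer_
}

# Brute-force SSR scan via backreference regexes over every unit length,
# with the same rules as the scanner: whole units only, primitive units,
# smallest-unit reporting.
ssr_regex_oracle <- function(seq, thresholds = polydissect::ssr_thresholds()) {
  out <- list()
  for (u in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1+", u)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      start <- m[k]
      len <- attr(m, "match.length")[k]
      unit <- substr(seq, start, start + u - 1)
      # leftmost-extension: gregexpr can anchor later than the true start
      while (start > 1 &&
             substr(seq, start - 1, start - 1) ==
               substr(seq, start + u - 1, start + u - 1)) {
        start <- start - 1
        len <- len + 1
        unit <- substr(seq, start, start + u - 1)
      }
      reps <- (len %/% u)
      if (reps < thresholds[[u]]) next
      if (!polydissect:::is_primitive_unit(unit)) next
      out[[length(out) + 1]] <- data.frame(
        start = start - 1L, end = start - 1L + u * reps, motif = unit,
        motif_length = u, repeat_count = reps, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      motif_length = integer(), repeat_count = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- unique(res)
  res[order(res$start, res$motif_length), , drop = FALSE]
}

# Full Needleman-Wunsch global alignment score with the aligner's scoring
# (match +1, mismatch -2, linear gap -3); quadratic, for small inputs only.
nw_score_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  prev <- -3 * (0:m)
  for (i in 1:n) {
    cur <- numeric(m + 1)
    cur[1] <- -3 * i
    for (j in 1:m) {
      cur[j + 1] <- max(prev[j] + ifelse(A[i] == B[j], 1, -2),
                        prev[j + 1] - 3, cur[j] - 3)
    }
    prev <- cur
  }
  prev[m + 1]
}

# Identity fraction of two equal-length strings.
pct_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  mean(x == y)
}

# Quality string helper: constant-phred string of length n.
qual_string <- function(phred, n) strrep(intToUtf8(phred + 33), n)

# Embed an SSR tract between pads that neither extend the tract's periodicity
# at its boundaries nor contain SSRs of their own.
embed_tract <- function(unit, reps, pad_len = 60) {
  u <- nchar(unit)
  repeat {
    padL <- polydissect::random_dna(pad_len)
    padR <- polydissect::random_dna(pad_len)
    s <- paste0(padL, strrep(unit, reps), padR)
    left_ok <- substr(s, pad_len, pad_len) != substr(s, pad_len + u, pad_len + u)
    q0 <- pad_len + u * reps + 1
    right_ok <- substr(s, q0, q0) != substr(s, q0 - u, q0 - u)
    pads_clean <- nrow(ssr_regex_oracle(padL)) == 0 &&
      nrow(ssr_regex_oracle(padR)) == 0
    if (left_ok && right_ok && pads_clean) return(s)
  }
}
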