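# Construction of a heterozygosity-collapsed virtual reference: backbone-
# specific sequence selection, window splitting, overlap-layout-consensus at
# 90% identity with heterozygous-base elimination, merging, and integration.

#' Select sequences with no significant similarity to a backbone
#'
#' @param candidates Named character vector.
#' @param backbone Named character vector (non-empty).
#' @param evalue_cutoff Maximum E-value defining similarity (default 1e-10).
#' @param ... Passed to [align_sequences()].
#' @return The candidates having no alignment to the backbone at
#'   E <= `evalue_cutoff`.
#' @export
select_specific_sequences <- function(candidates, backbone,
                                      evalue_cutoff = 1e-10, ...) {
  stopifnot(length(backbone) > 0)
  if (length(candidates) == 0) return(candidates)
  rec <- align_sequences(candidates, backbone, mode = NULL,
                         min_identity = 0, min_score = 20,
                         evalue_max = evalue_cutoff, ...)
  candidates[!(names(candidates) %in% unique(rec$q_name))]
}

#' Split sequences into overlapping windows
#'
#' Parents of length >= `window` yield fragments starting at 0, step,
#' 2*step, ...; when the last regular fragment does not reach the parent's
#' end, one extra right-anchored full window covering the final `window` bases
#' is emitted, so fragments jointly reproduce the parent. Shorter parents are
#' emitted whole.
#'
#' @param sequences Named character vector.
#' @param window Window length in bases (default 300).
#' @param step Start-to-start distance (default 100, i.e. 200 bp overlaps).
#' @return data.frame: frag_id, parent_id, parent_start (0-based), seq.
#' @export
split_windows <- function(sequences, window = 300, step = 100) {
  stopifnot(window > step, step > 0, !is.null(names(sequences)))
  out <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    L <- nchar(s)
    nm <- names(sequences)[i]
    if (L < window) {
      starts <- 0L
    } else {
      starts <- seq(0L, L - window, by = step)
      if (starts[length(starts)] + window < L) starts <- c(starts, L - window)
    }
    out[[i]] <- data.frame(
      frag_id = paste0(nm, "|w", starts),
      parent_id = nm,
      parent_start = as.integer(starts),
      seq = substring(s, starts + 1, pmin(starts + window, L)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

as_fragment_frame <- function(fragments) {
  if (is.data.frame(fragments)) {
    stopifnot(all(c("frag_id", "seq") %in% names(fragments)))
    fragments
  } else {
    stopifnot(!is.null(names(fragments)))
    data.frame(frag_id = names(fragments), seq = unname(fragments),
               stringsAsFactors = FALSE)
  }
}

#' Find pairwise overlaps between fragments
#'
#' Candidate pairs are generated from shared seed k-mers on both strands; the
#' best-voted diagonal gives the relative offset, over which identity is
#' computed base by base. Overlaps of length >= `min_overlap` and identity >=
#' `min_identity` are reported once per unordered pair; `offset` places
#' `frag_b` (its reverse complement for strand "-") in `frag_a` forward
#' coordinates.
#'
#' @param fragments A [split_windows()] frame or a named character vector.
#' @param min_overlap Minimum overlap length in bases (default 100).
#' @param min_identity Minimum overlap identity, fraction (default 0.90;
#'   exactly 0.90 passes).
#' @param seed_len Seed k-mer length.
#' @param max_seed_occ Seeds more frequent than this are ignored.
#' @param min_votes Minimum shared seeds on a diagonal to evaluate it.
#' @return data.frame: frag_a, frag_b, strand, offset, length, matches,
#'   identity.
#' @export
find_overlaps <- function(fragments, min_overlap = 100, min_identity = 0.90,
                          seed_len = 11, max_seed_occ = 200, min_votes = 2) {
  fr <- as_fragment_frame(fragments)
  stopifnot(nrow(fr) > 0)
  ov <- find_overlaps_cpp(fr$seq, as.integer(seed_len),
                          as.integer(min_overlap), as.numeric(min_identity),
                          as.integer(max_seed_occ), as.integer(min_votes))
  data.frame(frag_a = fr$frag_id[ov$a], frag_b = fr$frag_id[ov$b],
             strand = ov$strand, offset = ov$offset, length = ov$length,
             matches = ov$matches, identity = ov$identity,
             stringsAsFactors = FALSE)
}

# Agglomerative layout over the overlap graph with cluster-level identity
# verification (see layout_consensus); returns per-node orientation, offset,
# component id, conflict and rejected-merge counts.
layout_graph <- function(fr, overlaps, min_identity = 0.90, max_conflict = 5) {
  idx <- stats::setNames(seq_len(nrow(fr)), fr$frag_id)
  lay <- agglomerate_layout_cpp(fr$seq,
                                as.integer(idx[overlaps$frag_a]),
                                as.integer(idx[overlaps$frag_b]),
                                ifelse(overlaps$strand == "+", 1L, -1L),
                                as.integer(overlaps$offset),
                                as.numeric(overlaps$identity),
                                as.integer(overlaps$length),
                                as.numeric(min_identity),
                                as.integer(max_conflict))
  list(ori = lay$ori, offset = lay$offset, component = lay$component,
       conflicts = lay$conflicts, rejected = lay$rejected_merges)
}

#' Lay out overlapping fragments and call a collapsed consensus
#'
#' Connected components of the overlap graph are placed by propagating
#' pairwise offsets (conflicting edges beyond 5 bp are counted and ignored)
#' and collapsed column-wise: the consensus base is the weight-majority base
#' (fragment weight defaults to 1), ties breaking A < C < G < T; columns where
#' members disagree are counted as eliminated heterozygous sites. The output
#' contains no ambiguity codes.
#'
#' Fragments are clustered agglomeratively, strongest overlap first, and a
#' merge of two growing clusters is accepted only when the aggregate identity
#' over all overlapping member columns (under the placement the edge implies)
#' still reaches `min_identity`. An isolated near-threshold overlap between
#' otherwise diverged copies is therefore rejected once the copies have grown,
#' while copies whose overall divergence is within the threshold collapse.
#' Overlap edges are additionally required to be transitively supported (a
#' third fragment overlapping both consistently) unless an endpoint has no
#' other overlap; set `require_support = FALSE` to disable.
#'
#' @param fragments A [split_windows()] frame or named character vector.
#' @param overlaps Overlap table from [find_overlaps()].
#' @param weights Optional per-fragment weights (fragment counts).
#' @param min_identity Aggregate identity required to join two clusters.
#' @param require_support Drop overlap edges with no transitive support.
#' @return List of class `consensus_set`: `contigs` (named character vector),
#'   `info` (id, length, n_members, het_sites_collapsed), `depth` (per-contig
#'   integer vectors), `members` (per-contig fragment ids), `conflicts`,
#'   `rejected_merges`.
#' @export
layout_consensus <- function(fragments, overlaps, weights = NULL,
                             min_identity = 0.90, require_support = TRUE) {
  fr <- as_fragment_frame(fragments)
  frag_len <- nchar(fr$seq)
  if (is.null(weights)) weights <- rep(1, nrow(fr))
  if (require_support && nrow(overlaps) > 1) {
    idx <- stats::setNames(seq_len(nrow(fr)), fr$frag_id)
    keep <- overlap_support_cpp(nrow(fr),
                                as.integer(idx[overlaps$frag_a]),
                                as.integer(idx[overlaps$frag_b]),
                                ifelse(overlaps$strand == "+", 1L, -1L),
                                as.integer(overlaps$offset),
                                as.integer(frag_len), 5L)
    overlaps <- overlaps[keep, , drop = FALSE]
  }
  lay <- layout_graph(fr, overlaps, min_identity = min_identity)
  ncomp <- max(lay$component)
  contigs <- character(ncomp)
  ids <- sprintf("consensus_%05d", seq_len(ncomp))
  info <- vector("list", ncomp)
  depth <- vector("list", ncomp)
  members <- vector("list", ncomp)
  for (cc in seq_len(ncomp)) {
    sel <- which(lay$component == cc)
    seqs <- fr$seq[sel]
    flip <- lay$ori[sel] == -1L
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    offs <- lay$offset[sel] - min(lay$offset[sel])
    cons <- consensus_cpp(seqs, as.integer(round(offs)), as.numeric(weights[sel]))
    contigs[cc] <- cons$sequence
    depth[[cc]] <- cons$depth
    members[[cc]] <- fr$frag_id[sel]
    info[[cc]] <- data.frame(id = ids[cc], length = nchar(cons$sequence),
                             n_members = length(sel),
                             het_sites_collapsed = cons$het_sites,
                             stringsAsFactors = FALSE)
  }
  names(contigs) <- names(depth) <- names(members) <- ids
  structure(list(contigs = contigs, info = do.call(rbind, info),
                 depth = depth, members = members,
                 conflicts = lay$conflicts,
                 rejected_merges = lay$rejected),
            class = "consensus_set")
}

# Overlap row seen from b's side (offset of oriented-a in b forward coords).
reverse_overlap_offset <- function(offset, strand, len_a, len_b) {
  ifelse(strand == "+", -offset, offset + len_b - len_a)
}

#' Merge consensus contigs sharing end overlaps
#'
#' Contigs whose ends share an overlap of >= `min_merge_overlap` bases at >=
#' `min_identity` identity are concatenated (the overlap counted once),
#' repeatedly until a fixpoint. Contained contigs are absorbed. Merging is
#' deterministic: longest contig first, ties by id; an end with two or more
#' candidate partners is left unmerged and the ambiguity logged.
#'
#' @param consensus A `consensus_set` or named character vector of contigs.
#' @param min_merge_overlap Minimum end overlap in bases (default 100).
#' @param min_identity Minimum overlap identity (default 0.90).
#' @return List with `contigs` (named character vector) and `ambiguities`
#'   (count of ends left unmerged due to multiple candidates).
#' @export
merge_unjoined <- function(consensus, min_merge_overlap = 100,
                           min_identity = 0.90) {
  contigs <- if (inherits(consensus, "consensus_set")) consensus$contigs
             else consensus
  stopifnot(!is.null(names(contigs)))
  ambiguities <- 0L
  repeat {
    if (length(contigs) < 2) break
    ov <- find_overlaps(contigs, min_overlap = min_merge_overlap,
                        min_identity = min_identity)
    if (nrow(ov) == 0) break
    lens <- nchar(contigs)
    # deterministic processing order: longest first, ties by id
    ord <- names(sort(lens, decreasing = TRUE))
    ord <- ord[order(-lens[ord], ord)]
    merged_any <- FALSE
    used <- character(0)
    for (nm in ord) {
      if (nm %in% used) next
      rows <- ov[ov$frag_a == nm | ov$frag_b == nm, , drop = FALSE]
      rows <- rows[!(rows$frag_a %in% used) & !(rows$frag_b %in% used), ,
                   drop = FALSE]
      if (nrow(rows) == 0) next
      # normalize rows so nm is always 'a'
      swap <- rows$frag_b == nm
      if (any(swap)) {
        o2 <- reverse_overlap_offset(rows$offset[swap], rows$strand[swap],
                                     nchar(contigs[rows$frag_a[swap]]),
                                     nchar(contigs[nm]))
        tmp <- rows$frag_a[swap]
        rows$frag_a[swap] <- nm
        rows$frag_b[swap] <- tmp
        rows$offset[swap] <- o2
      }
      la <- nchar(contigs[nm])
      lb <- nchar(contigs[rows$frag_b])
      right_ext <- rows$offset > 0 & rows$offset + lb > la
      left_ext <- rows$offset < 0 & rows$offset + lb < la
      contained <- rows$offset >= 0 & rows$offset + lb <= la
      contains_a <- rows$offset <= 0 & rows$offset + lb >= la
      pick <- NULL
      if (any(contained)) {
        pick <- which(contained)[1]        # absorb a contained contig
        type <- "absorb"
      } else if (any(contains_a)) {
        pick <- which(contains_a)[1]
        type <- "absorbed_by"
      } else {
        if (sum(right_ext) > 1 || sum(left_ext) > 1) {
          ambiguities <- ambiguities + sum(c(sum(right_ext) > 1,
                                             sum(left_ext) > 1))
          next
        }
        if (any(right_ext)) { pick <- which(right_ext)[1]; type <- "right" }
        else if (any(left_ext)) { pick <- which(left_ext)[1]; type <- "left" }
      }
      if (is.null(pick)) next
      row <- rows[pick, , drop = FALSE]
      b <- row$frag_b
      ob <- if (row$strand == "+") contigs[[b]] else revcomp(contigs[[b]])
      lbv <- nchar(ob)
      newseq <- switch(type,
        absorb = contigs[[nm]],
        absorbed_by = ob,
        right = paste0(contigs[[nm]], substr(ob, la - row$offset + 1, lbv)),
        left = paste0(ob, substr(contigs[[nm]], row$offset + lbv + 1, la))
      )
      contigs[[nm]] <- newseq
      contigs <- contigs[names(contigs) != b]
      used <- c(used, nm, b)
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  list(contigs = contigs, ambiguities = ambiguities)
}

#' Collapse a heterozygous sequence set into consensus contigs
#'
#' Convenience wrapper running [split_windows()], [find_overlaps()],
#' [layout_consensus()] and [merge_unjoined()] with the standard parameters
#' (300-bp windows, 200-bp overlaps, 90% identity).
#'
#' @param sequences Named character vector.
#' @param window,step Window splitting parameters.
#' @param min_overlap,min_identity Overlap detection thresholds.
#' @param min_merge_overlap Merge threshold.
#' @return List with `contigs`, `info`, `conflicts`, `ambiguities`.
#' @export
collapse_assembly <- function(sequences, window = 300, step = 100,
                              min_overlap = 100, min_identity = 0.90,
                              min_merge_overlap = 100) {
  frags <- split_windows(sequences, window = window, step = step)
  ov <- find_overlaps(frags, min_overlap = min_overlap,
                      min_identity = min_identity)
  cons <- layout_consensus(frags, ov, min_identity = min_identity)
  merged <- merge_unjoined(cons, min_merge_overlap = min_merge_overlap,
                           min_identity = min_identity)
  list(contigs = merged$contigs, info = cons$info,
       conflicts = cons$conflicts, rejected_merges = cons$rejected_merges,
       ambiguities = merged$ambiguities)
}

#' Integrate a backbone with collapsed specific sequences
#'
#' @param backbone Named character vector (e.g. long-read scaffolds).
#' @param collapsed_specific Named character vector of collapsed contigs.
#' @return List with `reference` (ids namespaced by source), `report`
#'   (per-source counts and lengths) and `stats` (assembly statistics of the
#'   integrated reference).
#' @export
build_virtual_reference <- function(backbone, collapsed_specific) {
  bb <- backbone
  sp <- collapsed_specific
  if (length(bb)) names(bb) <- paste0("backbone|", names(bb))
  if (length(sp)) names(sp) <- paste0("specific|", names(sp))
  reference <- c(bb, sp)
  if (anyDuplicated(names(reference)))
    stop("duplicate sequence ids in integrated reference")
  report <- data.frame(
    source = c("backbone", "specific"),
    n_sequences = c(length(bb), length(sp)),
    total_length = c(sum(nchar(bb)), sum(nchar(sp)))
  )
  list(reference = reference, report = report,
       stats = if (length(reference)) compute_assembly_stats(reference) else NULL)
}
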