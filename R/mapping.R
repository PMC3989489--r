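# Seed-and-extend local alignment with PSL-record semantics, hit filtering,
# best-hit selection, multiplicity classification, top-hit attribution,
# non-homologous accounting and greedy clustering.

aligner_presets <- list(
  blat_like = list(min_identity = 95, min_score = 100, evalue_max = Inf),
  megablast_like = list(min_identity = 90, min_score = 30, evalue_max = 1e-50)
)

#' Align query sequences against target sequences
#'
#' Seeded (11-mer), chained, banded-DP-extended local alignment on both
#' strands, reported with PSL field semantics (0-based half-open coordinates;
#' query coordinates always on the forward strand). `score` is
#' matches - mismatches - q_gap_count - t_gap_count; E-values use a
#' Karlin-Altschul statistic with blastn-like scoring (+1/-2, lambda = 1.33,
#' K = 0.621). Mode presets: `blat_like` (min_identity 95, min_score 100) and
#' `megablast_like` (min_identity 90, E <= 1e-50).
#'
#' @param queries,targets Named character vectors of DNA sequences (A/C/G/T/N).
#' @param mode Preset name, or NULL to use the explicit thresholds.
#' @param min_identity Minimum percent identity of reported records.
#' @param min_score Minimum PSL-style score.
#' @param evalue_max Maximum E-value.
#' @param seed_len Seed k-mer length.
#' @param band Diagonal band half-width for chaining and DP.
#' @param max_chain_gap Maximum gap when merging colinear seed clusters.
#' @param max_seed_occ Seeds occurring more often than this in the target set
#'   are ignored (repeat masking).
#' @return data.frame of alignment records ordered by (q_name, t_name,
#'   score desc).
#' @export
align_sequences <- function(queries, targets, mode = "blat_like",
                            min_identity = NULL, min_score = NULL,
                            evalue_max = NULL, seed_len = 11, band = 16,
                            max_chain_gap = 100, max_seed_occ = 256) {
  if (length(queries) == 0 || length(targets) == 0)
    stop("queries and targets must be non-empty")
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(targets))) names(targets) <- paste0("t", seq_along(targets))
  bad <- grep("[^ACGTNacgtn]", queries)
  if (length(bad)) {
    p <- regexpr("[^ACGTNacgtn]", queries[bad[1]])
    stop("query ", names(queries)[bad[1]], " has non-ACGTN symbol at position ", p)
  }
  bad <- grep("[^ACGTNacgtn]", targets)
  if (length(bad)) {
    p <- regexpr("[^ACGTNacgtn]", targets[bad[1]])
    stop("target ", names(targets)[bad[1]], " has non-ACGTN symbol at position ", p)
  }
  if (!is.null(mode)) {
    preset <- aligner_presets[[match.arg(mode, names(aligner_presets))]]
    if (is.null(min_identity)) min_identity <- preset$min_identity
    if (is.null(min_score)) min_score <- preset$min_score
    if (is.null(evalue_max)) evalue_max <- preset$evalue_max
  }
  rec <- seed_align_cpp(names(queries), unname(toupper(queries)),
                        names(targets), unname(toupper(targets)),
                        as.integer(seed_len), as.integer(band),
                        as.integer(max_chain_gap),
                        as.numeric(min_identity), as.integer(min_score),
                        as.numeric(evalue_max), 1.33, 0.621,
                        as.integer(max_seed_occ))
  rec <- rec[order(rec$q_name, rec$t_name, -rec$score, rec$t_start), ,
             drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Hit-selection filter thresholds
#'
#' The four selection inequalities applied to PSL records, in percent of the
#' query length: c1 = (matches + q_gap_bases) * 100 / q_size >= `c1_min`;
#' c2 = query span * 100 / q_size >= `c2_min`; c3 = matches * 100 / q_size >=
#' `c3_min`; c4 = target span * 100 / q_size within `c4_range`.
#'
#' @param c1_min,c2_min,c3_min Lower bounds (percent).
#' @param c4_range Two-element numeric range (percent).
#' @return List of class `hit_filter`.
#' @export
hit_filter <- function(c1_min = 80, c2_min = 80, c3_min = 25,
                       c4_range = c(80, 120)) {
  stopifnot(length(c4_range) == 2, c4_range[1] <= c4_range[2])
  structure(list(c1_min = c1_min, c2_min = c2_min, c3_min = c3_min,
                 c4_range = c4_range), class = "hit_filter")
}

#' Apply the four hit-selection inequalities
#'
#' @param records Alignment records from [align_sequences()].
#' @param filter A [hit_filter()].
#' @return The surviving records (idempotent).
#' @export
apply_hit_filters <- function(records, filter = hit_filter()) {
  need <- c("q_size", "q_start", "q_end", "t_start", "t_end", "matches",
            "q_gap_bases")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) == 0) return(records)
  c1 <- (records$matches + records$q_gap_bases) * 100 / records$q_size
  c2 <- (records$q_end - records$q_start) * 100 / records$q_size
  c3 <- records$matches * 100 / records$q_size
  c4 <- (records$t_end - records$t_start) * 100 / records$q_size
  keep <- c1 >= filter$c1_min & c2 >= filter$c2_min & c3 >= filter$c3_min &
    c4 >= filter$c4_range[1] & c4 <= filter$c4_range[2]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the best alignment per query
#'
#' Among records whose query coverage (q_end - q_start)/q_size is at least
#' `min_cover`, the highest-score record wins; ties break by higher matches,
#' then lexicographic target name, then target start. Queries with no
#' qualifying record are reported unmapped.
#'
#' @param records Filtered alignment records.
#' @param min_cover Minimum query coverage fraction (default 0.20).
#' @return data.frame of one best record per mapped query, with attribute
#'   `unmapped` listing queries present in `records` but failing coverage.
#' @export
select_best_alignment <- function(records, min_cover = 0.20) {
  if (nrow(records) == 0) {
    attr(records, "unmapped") <- character(0)
    return(records)
  }
  cov <- (records$q_end - records$q_start) / records$q_size
  ok <- records[cov >= min_cover, , drop = FALSE]
  ord <- order(ok$q_name, -ok$score, -ok$matches, ok$t_name, ok$t_start)
  ok <- ok[ord, , drop = FALSE]
  best <- ok[!duplicated(ok$q_name), , drop = FALSE]
  rownames(best) <- NULL
  attr(best, "unmapped") <- setdiff(unique(records$q_name), best$q_name)
  best
}

multiplicity_class <- function(n) {
  cut(n, breaks = c(0.5, 1.5, 2.5, 3.5, 4.5, Inf),
      labels = c("single", "double", "triple", "quadruple", "five_plus"))
}

#' Classify mapping multiplicity of targets
#'
#' Bins target sequences by the number of distinct queries whose best hit they
#' receive (single, double, triple, quadruple, five_plus). Query fractions are
#' computed over all mapped queries, so they describe how the mapped query set
#' distributes over target multiplicity classes.
#'
#' @param best_hits Best-hit records from [select_best_alignment()].
#' @return List with `per_target` (target, n_queries, class) and `by_class`
#'   (class, n_targets, n_queries, fraction_of_mapped_queries).
#' @export
classify_multiplicity <- function(best_hits) {
  if (nrow(best_hits) == 0) {
    return(list(per_target = data.frame(t_name = character(),
                                        n_queries = integer(),
                                        class = character()),
                by_class = data.frame(class = character(),
                                      n_targets = integer(),
                                      n_queries = integer(),
                                      fraction_of_mapped_queries = numeric())))
  }
  tb <- table(best_hits$t_name)
  per_target <- data.frame(t_name = names(tb), n_queries = as.integer(tb),
                           class = as.character(multiplicity_class(as.integer(tb))),
                           stringsAsFactors = FALSE)
  cls <- c("single", "double", "triple", "quadruple", "five_plus")
  n_targets <- vapply(cls, function(cl) sum(per_target$class == cl), integer(1))
  n_queries <- vapply(cls, function(cl)
    sum(per_target$n_queries[per_target$class == cl]), integer(1))
  total_q <- nrow(best_hits)
  stopifnot(sum(n_queries) == total_q, sum(n_targets) == nrow(per_target))
  list(per_target = per_target,
       by_class = data.frame(class = cls, n_targets = unname(n_targets),
                             n_queries = unname(n_queries),
                             fraction_of_mapped_queries = unname(n_queries) / total_q,
                             stringsAsFactors = FALSE))
}

#' Attribute reference sequences to the top-hit species
#'
#' For each reference (target) sequence the species whose best hit scores
#' highest wins; ties are split deterministically in the order of
#' `best_hits_by_species` and logged.
#'
#' @param best_hits_by_species Named list of best-hit record tables, one per
#'   species, all against the same reference.
#' @return List with `per_target` (target, species, score), `by_species`
#'   (species, n_top_hits, percent) and `ties` (count of tied targets).
#' @export
attribute_top_hits <- function(best_hits_by_species) {
  stopifnot(!is.null(names(best_hits_by_species)))
  species <- names(best_hits_by_species)
  rows <- list()
  for (sp in species) {
    bh <- best_hits_by_species[[sp]]
    if (nrow(bh) == 0) next
    agg <- tapply(bh$score, bh$t_name, max)
    rows[[sp]] <- data.frame(t_name = names(agg), species = sp,
                             score = as.numeric(agg),
                             stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0) {
    return(list(per_target = data.frame(t_name = character(),
                                        species = character(),
                                        score = numeric()),
                by_species = data.frame(species = species, n_top_hits = 0L,
                                        percent = NA_real_),
                ties = 0L))
  }
  # deterministic winner: max score, ties by species order
  all$sp_rank <- match(all$species, species)
  ord <- order(all$t_name, -all$score, all$sp_rank)
  all <- all[ord, , drop = FALSE]
  first <- !duplicated(all$t_name)
  winners <- all[first, , drop = FALSE]
  # count ties: a target whose top score is achieved by >1 species
  key <- paste(all$t_name, all$score)
  top_key <- paste(winners$t_name, winners$score)
  ties <- sum(table(key[key %in% top_key]) > 1)
  counts <- vapply(species, function(sp) sum(winners$species == sp), integer(1))
  list(per_target = winners[, c("t_name", "species", "score")],
       by_species = data.frame(species = species, n_top_hits = unname(counts),
                               percent = 100 * unname(counts) / sum(counts),
                               stringsAsFactors = FALSE),
       ties = as.integer(ties))
}

#' Non-homologous sequence accounting
#'
#' Queries with no alignment to any target at E <= `evalue_cutoff` are listed
#' with their summed length and its fraction of the total query length.
#'
#' @param queries,targets Named character vectors.
#' @param evalue_cutoff Maximum E-value defining homology (default 1e-10).
#' @param ... Passed to [align_sequences()].
#' @return List with `no_hit` (query ids), `no_hit_length`, `total_length` and
#'   `ratio`.
#' @export
compute_nonhomologous <- function(queries, targets, evalue_cutoff = 1e-10, ...) {
  rec <- align_sequences(queries, targets, mode = "megablast_like",
                         evalue_max = evalue_cutoff, ...)
  hit <- unique(rec$q_name)
  no_hit <- setdiff(names(queries), hit)
  list(no_hit = no_hit,
       no_hit_length = sum(nchar(queries[no_hit])),
       total_length = sum(nchar(queries)),
       ratio = sum(nchar(queries[no_hit])) / sum(nchar(queries)))
}

#' Greedy incremental sequence clustering
#'
#' Sequences are processed longest first; each joins the first existing
#' cluster whose representative aligns at >= `identity` with coverage of the
#' shorter sequence >= `short_coverage`, else founds a new cluster.
#'
#' @param sequences Named character vector.
#' @param identity Minimum alignment identity, fraction (default 0.80).
#' @param short_coverage Minimum aligned coverage of the shorter sequence,
#'   fraction (default 0.10).
#' @param species Optional named vector mapping sequence id to species; when
#'   given, clusters with members from a single species are labelled unique.
#' @return List with `clusters` (list of member id vectors, representative
#'   first) and, when `species` is given, `species_unique` counts per species.
#' @export
greedy_cluster <- function(sequences, identity = 0.80, short_coverage = 0.10,
                           species = NULL) {
  stopifnot(length(sequences) > 0, !is.null(names(sequences)))
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- character(0)   # representative sequences
  rep_ids <- character(0)
  clusters <- list()
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    s <- sequences[[i]]
    assigned <- FALSE
    if (length(reps)) {
      rec <- align_sequences(stats::setNames(s, id), stats::setNames(reps, rep_ids),
                             mode = NULL, min_identity = identity * 100,
                             min_score = 20, evalue_max = Inf)
      if (nrow(rec)) {
        shorter <- pmin(rec$q_size, rec$t_size)
        aligned <- rec$q_end - rec$q_start
        rec <- rec[aligned / shorter >= short_coverage, , drop = FALSE]
        if (nrow(rec)) {
          # first existing cluster in founding order
          k <- min(match(rec$t_name, rep_ids))
          clusters[[k]] <- c(clusters[[k]], id)
          assigned <- TRUE
        }
      }
    }
    if (!assigned) {
      reps <- c(reps, s)
      rep_ids <- c(rep_ids, id)
      clusters[[length(clusters) + 1]] <- id
    }
  }
  names(clusters) <- rep_ids
  out <- list(clusters = clusters)
  if (!is.null(species)) {
    cl_species <- lapply(clusters, function(m) unique(species[m]))
    uniq <- vapply(cl_species, function(x) length(x) == 1, logical(1))
    tab <- table(unlist(cl_species[uniq]))
    out$species_unique <- stats::setNames(as.integer(tab), names(tab))
  }
  out
}
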