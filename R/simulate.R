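# Synthetic allo-octoploid genomes, fragmented assemblies, reads and
# SSR-marker genotypes, all with recorded truth for downstream recovery tests.

#' Simulation configuration for an allo-octoploid genome
#'
#' The default model is the AAA'A'BBB'B' composition: two progenitor lineages
#' (P1 carrying subgenomes A and Ap, P2 carrying B and Bp), two haplotypes per
#' subgenome, eight haploid complements in total. Divergence is modelled as
#' i.i.d. substitutions (plus optional short 1-10 bp indels): `d_prog` is the
#' expected total substitution divergence between subgenomes of different
#' lineages, `d_sub` between homoeologs of one lineage, and `h_allelic` between
#' the two haplotypes of one subgenome.
#'
#' @param monoploid_length Length of one haploid complement, in bases.
#' @param gc_content GC fraction of the ancestral sequence, in (0, 1).
#' @param ploidy_model Named character vector mapping subgenome labels to
#'   progenitor lineage labels.
#' @param n_haplotypes Haplotypes per subgenome.
#' @param d_prog Expected substitution divergence between subgenomes of
#'   different progenitor lineages (fraction).
#' @param d_sub Expected divergence between homoeologs within a lineage.
#' @param h_allelic Expected allelic heterozygosity between the two haplotypes
#'   of one subgenome.
#' @param indel_rate Fraction of divergence events realized as 1-10 bp indels.
#' @param ssr_density SSR loci seeded per 100 kb of ancestral sequence.
#' @param contig_n50_target Target N50 for [fragment_assembly()].
#' @param read_coverage Fold coverage for [simulate_reads()].
#' @param read_length Read length in bases.
#' @param error_rate Per-base sequencing error rate.
#' @param seed Integer RNG seed; identical seeds give byte-identical output.
#' @param allow_high_heterozygosity Set TRUE to permit `h_allelic > d_sub`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(monoploid_length = 1e5, gc_content = 0.39,
                       ploidy_model = c(A = "P1", Ap = "P1", B = "P2", Bp = "P2"),
                       n_haplotypes = 2,
                       d_prog = 0.08, d_sub = 0.02, h_allelic = 0.005,
                       indel_rate = 0, ssr_density = 16,
                       contig_n50_target = 3000,
                       read_coverage = 30, read_length = 100,
                       error_rate = 0.005, seed = 1,
                       allow_high_heterozygosity = FALSE) {
  stopifnot(monoploid_length > 0, contig_n50_target > 0, read_length > 0,
            gc_content > 0, gc_content < 1,
            n_haplotypes >= 1, length(ploidy_model) >= 1,
            !is.null(names(ploidy_model)))
  if (!(d_sub >= 0 && d_sub <= d_prog && d_prog <= 0.5))
    stop("divergence rates must satisfy 0 <= d_sub <= d_prog <= 0.5")
  if (h_allelic > d_sub && !allow_high_heterozygosity)
    stop("h_allelic exceeds d_sub; set allow_high_heterozygosity = TRUE to override")
  if (indel_rate < 0 || indel_rate > 1) stop("indel_rate must be in [0, 1]")
  structure(list(
    monoploid_length = as.integer(monoploid_length), gc_content = gc_content,
    ploidy_model = ploidy_model, n_haplotypes = as.integer(n_haplotypes),
    d_prog = d_prog, d_sub = d_sub, h_allelic = h_allelic,
    indel_rate = indel_rate, ssr_density = ssr_density,
    contig_n50_target = as.integer(contig_n50_target),
    read_coverage = read_coverage, read_length = as.integer(read_length),
    error_rate = error_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# Draw substitution/indel events at `rate` per base and apply them.
# Events are recorded in parent coordinates and applied right-to-left, so
# replaying the table on the parent reproduces the child exactly.
mutate_seq <- function(seq, rate, indel_rate = 0) {
  empty <- data.frame(pos = integer(), type = character(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE)
  L <- nchar(seq)
  if (rate <= 0 || L == 0) return(list(seq = seq, events = empty))
  n <- rbinom(1, L, rate)
  if (n == 0) return(list(seq = seq, events = empty))
  pos <- sort(sample.int(L, n))
  type <- ifelse(runif(n) < indel_rate,
                 ifelse(runif(n) < 0.5, "ins", "del"), "sub")
  r <- charToRaw(seq)
  code <- integer(256)
  code[as.integer(charToRaw("ACGT"))] <- 0:3
  bases_raw <- charToRaw("ACGT")
  ref <- alt <- character(n)
  sub_i <- which(type == "sub")
  if (length(sub_i)) {
    cur <- as.integer(r[pos[sub_i]])
    cur_code <- code[cur]
    new_code <- (cur_code + sample.int(3, length(sub_i), replace = TRUE)) %% 4
    ref[sub_i] <- strsplit(rawToChar(r[pos[sub_i]]), "")[[1]]
    alt[sub_i] <- strsplit(rawToChar(bases_raw[new_code + 1]), "")[[1]]
    r[pos[sub_i]] <- bases_raw[new_code + 1]
  }
  indel_i <- which(type != "sub")
  if (length(indel_i)) {
    lens <- sample.int(10, length(indel_i), replace = TRUE)
    # pre-draw insertion payloads in position order for determinism
    ins_payload <- vapply(lens, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1))
    for (k in rev(seq_along(indel_i))) {
      i <- indel_i[k]
      p <- pos[i]
      if (type[i] == "ins") {
        ref[i] <- ""
        alt[i] <- ins_payload[k]
        r <- c(r[seq_len(p)], charToRaw(alt[i]), if (p < length(r)) r[(p + 1):length(r)])
      } else {
        dl <- min(lens[k], length(r) - p + 1)
        ref[i] <- rawToChar(r[p:(p + dl - 1)])
        alt[i] <- ""
        r <- r[-(p:(p + dl - 1))]
      }
    }
  }
  list(seq = rawToChar(r),
       events = data.frame(pos = pos, type = type, ref = ref, alt = alt,
                           stringsAsFactors = FALSE))
}

# Replay an event table (as recorded by mutate_seq) on the parent sequence.
replay_events <- function(seq, events) {
  if (nrow(events) == 0) return(seq)
  r <- charToRaw(seq)
  for (k in rev(seq_len(nrow(events)))) {
    p <- events$pos[k]
    if (events$type[k] == "sub") {
      r[p] <- charToRaw(events$alt[k])
    } else if (events$type[k] == "ins") {
      r <- c(r[seq_len(p)], charToRaw(events$alt[k]),
             if (p < length(r)) r[(p + 1):length(r)])
    } else {
      dl <- nchar(events$ref[k])
      r <- r[-(p:(p + dl - 1))]
    }
  }
  rawToChar(r)
}

# Seed perfect SSR tracts into a sequence at the given density (loci/100 kb).
seed_ssrs <- function(seq, density, thresholds = ssr_thresholds()) {
  L <- nchar(seq)
  n <- round(L / 1e5 * density)
  loci <- data.frame(pos = integer(), motif = character(),
                     repeats = integer(), stringsAsFactors = FALSE)
  if (n == 0) return(list(seq = seq, loci = loci))
  r <- charToRaw(seq)
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      ulen <- sample.int(6, 1)
      unit <- paste(sample(c("A", "C", "G", "T"), ulen, replace = TRUE),
                    collapse = "")
      if (ulen > 1 && !is_primitive_unit(unit)) next
      reps <- thresholds[ulen] + sample.int(8, 1)
      tract <- strrep(unit, reps)
      tl <- nchar(tract)
      if (tl + 2 >= L) next
      p <- sample.int(L - tl - 1, 1) + 1
      if (nrow(occupied) &&
          any(p <= occupied[, 2] + ulen & p + tl >= occupied[, 1] - ulen)) next
      r[p:(p + tl - 1)] <- charToRaw(tract)
      occupied <- rbind(occupied, c(p, p + tl))
      loci <- rbind(loci, data.frame(pos = p, motif = unit,
                                     repeats = as.integer(reps),
                                     stringsAsFactors = FALSE))
      break
    }
  }
  list(seq = rawToChar(r), loci = loci)
}

is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1)) {
    if (u %% d != 0) next
    if (strrep(substr(unit, 1, d), u / d) == unit) return(FALSE)
  }
  TRUE
}

#' Simulate an allo-octoploid genome with recorded truth
#'
#' Builds an ancestral monoploid sequence (with seeded SSR tracts), diverges it
#' into progenitor lineages, homoeologous subgenomes and allelic haplotypes,
#' and records every event so each haplotype can be reproduced from the
#' ancestor. With the default `ploidy_model` the result has eight haploid
#' complements (AAA'A'BBB'B').
#'
#' @param config A [sim_config()].
#' @return An object of class `polyploid_truth`: list with `ancestor`,
#'   `haplotypes` (named character vector), `subgenome_of`, `progenitor`,
#'   `events` (per-level event tables), `ssr_loci`, and `config`.
#' @export
simulate_octoploid <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$monoploid_length
  rl <- (config$d_prog - config$d_sub) / 2 # lineage-private rate
  rs <- config$d_sub / 2                   # subgenome-private rate
  rh <- config$h_allelic / 2               # haplotype-private rate
  for (r in c(lineage = rl, subgenome = rs, haplotype = rh)) {
    if (r > 0 && L * r < 1)
      stop("degenerate configuration: expected number of divergence events ",
           "at rate ", r, " on ", L, " bases is below 1")
  }
  with_seed(config$seed, {
    anc <- random_dna(L, config$gc_content)
    ss <- seed_ssrs(anc, config$ssr_density)
    anc <- ss$seq

    lineages <- unique(unname(config$ploidy_model))
    lin_seq <- list(); lin_ev <- list()
    for (lg in lineages) {
      m <- mutate_seq(anc, rl, config$indel_rate)
      lin_seq[[lg]] <- m$seq; lin_ev[[lg]] <- m$events
    }
    sub_seq <- list(); sub_ev <- list()
    for (sg in names(config$ploidy_model)) {
      m <- mutate_seq(lin_seq[[config$ploidy_model[[sg]]]], rs, config$indel_rate)
      sub_seq[[sg]] <- m$seq; sub_ev[[sg]] <- m$events
    }
    hap_seq <- character(0); hap_ev <- list(); sub_of <- character(0)
    for (sg in names(config$ploidy_model)) {
      for (h in seq_len(config$n_haplotypes)) {
        nm <- paste0(sg, "_h", h)
        m <- mutate_seq(sub_seq[[sg]], rh, config$indel_rate)
        hap_seq[[nm]] <- m$seq; hap_ev[[nm]] <- m$events
        sub_of[[nm]] <- sg
      }
    }
    structure(list(
      ancestor = anc,
      haplotypes = hap_seq,
      subgenome_of = sub_of,
      progenitor = config$ploidy_model,
      events = list(lineage = lin_ev, subgenome = sub_ev, haplotype = hap_ev),
      ssr_loci = ss$loci,
      config = config
    ), class = "polyploid_truth")
  })
}

#' Reconstruct a haplotype by replaying its recorded events
#'
#' @param truth A `polyploid_truth` object.
#' @param haplotype Haplotype name, e.g. `"A_h1"`.
#' @return The reconstructed sequence (character).
#' @export
replay_haplotype <- function(truth, haplotype) {
  stopifnot(inherits(truth, "polyploid_truth"),
            haplotype %in% names(truth$haplotypes))
  sg <- truth$subgenome_of[[haplotype]]
  lg <- truth$progenitor[[sg]]
  s <- replay_events(truth$ancestor, truth$events$lineage[[lg]])
  s <- replay_events(s, truth$events$subgenome[[sg]])
  replay_events(s, truth$events$haplotype[[haplotype]])
}

#' Fragment haplotypes into contigs with a target N50
#'
#' Each haploid sequence is cut at random positions into contigs whose lengths
#' are drawn around the target; the realized N50 lands within 25% of the
#' target. Contig names encode the origin as `haplotype:start-end` (0-based,
#' half-open), so concatenating a haplotype's contigs in order reconstructs it.
#'
#' @param x A `polyploid_truth` object or a named character vector of sequences.
#' @param contig_n50_target Target N50 in bases (>= 600).
#' @param seed Integer RNG seed.
#' @param min_contig Minimum contig length the cutter will emit.
#' @return Named character vector of contigs.
#' @export
fragment_assembly <- function(x, contig_n50_target = NULL, seed = 1,
                              min_contig = 300) {
  seqs <- if (inherits(x, "polyploid_truth")) {
    if (is.null(contig_n50_target)) contig_n50_target <- x$config$contig_n50_target
    x$haplotypes
  } else x
  stopifnot(!is.null(contig_n50_target), !is.null(names(seqs)))
  if (contig_n50_target < 2 * min_contig)
    stop("contig_n50_target (", contig_n50_target, ") must be at least twice ",
         "the minimum contig length (", min_contig, ")")
  with_seed(seed, {
    out <- character(0)
    for (nm in names(seqs)) {
      L <- nchar(seqs[[nm]])
      if (L <= contig_n50_target) {
        out[[paste0(nm, ":0-", L)]] <- seqs[[nm]]
        next
      }
      cuts <- integer(0)
      pos <- 0
      lo <- max(min_contig, round(0.4 * contig_n50_target))
      hi <- round(1.6 * contig_n50_target)
      repeat {
        len <- round(stats::rnorm(1, contig_n50_target, 0.2 * contig_n50_target))
        len <- min(max(len, lo), hi)
        if (pos + len + lo > L) break
        pos <- pos + len
        cuts <- c(cuts, pos)
      }
      starts <- c(0, cuts)
      ends <- c(cuts, L)
      pieces <- substring(seqs[[nm]], starts + 1, ends)
      names(pieces) <- paste0(nm, ":", starts, "-", ends)
      out <- c(out, pieces)
    }
    out
  })
}

#' Parse origin information from contig identifiers
#'
#' @param ids Contig names produced by [fragment_assembly()].
#' @return data.frame with haplotype, subgenome, start, end.
#' @export
parse_contig_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)_h([0-9]+):([0-9]+)-([0-9]+)$", ids))
  bad <- which(vapply(m, length, integer(1)) != 5)
  if (length(bad)) stop("unparseable contig id: ", ids[bad[1]])
  data.frame(
    id = ids,
    haplotype = vapply(m, function(g) paste0(g[2], "_h", g[3]), character(1)),
    subgenome = vapply(m, `[`, character(1), 2),
    start = as.integer(vapply(m, `[`, character(1), 4)),
    end = as.integer(vapply(m, `[`, character(1), 5)),
    stringsAsFactors = FALSE
  )
}

#' Simulate uniform shotgun reads with substitution errors
#'
#' Reads start uniformly on both strands; substitution errors are injected at
#' `error_rate`, and base qualities are set from the error rate
#' (phred = -10 log10 p) with a small per-read jitter. The total number of
#' emitted bases equals `coverage` times the total sequence length to within
#' one read.
#'
#' @param sequences Named character vector of template sequences.
#' @param coverage Fold coverage (> 0).
#' @param read_length Read length in bases (at most the shortest template).
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer RNG seed.
#' @return data.frame with columns id, seq, qual (phred+33); read ids encode
#'   the true origin as `template:start-end:strand`.
#' @export
simulate_reads <- function(sequences, coverage, read_length = 100,
                           error_rate = 0.005, seed = 1) {
  stopifnot(!is.null(names(sequences)))
  if (coverage <= 0) stop("coverage must be positive")
  lens <- nchar(sequences)
  if (read_length > min(lens))
    stop("read_length exceeds the shortest template sequence")
  with_seed(seed, {
    total <- sum(lens)
    n <- max(1L, round(coverage * total / read_length))
    tmpl <- sample.int(length(sequences), n, replace = TRUE,
                       prob = lens - read_length + 1)
    starts <- floor(runif(n) * (lens[tmpl] - read_length + 1)) + 1
    minus <- runif(n) < 0.5
    seqs <- substring(sequences[tmpl], starts, starts + read_length - 1)
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    # substitution errors
    nerr <- rbinom(n, read_length, error_rate)
    which_err <- which(nerr > 0)
    if (length(which_err)) {
      code <- integer(256)
      code[as.integer(charToRaw("ACGT"))] <- 0:3
      bases_raw <- charToRaw("ACGT")
      for (i in which_err) {
        r <- charToRaw(seqs[i])
        p <- sample.int(read_length, nerr[i])
        cur <- code[as.integer(r[p])]
        r[p] <- bases_raw[((cur + sample.int(3, nerr[i], replace = TRUE)) %% 4) + 1]
        seqs[i] <- rawToChar(r)
      }
    }
    qbase <- round(-10 * log10(max(error_rate, 1e-6)))
    q <- pmin(pmax(qbase + sample(-2:2, n, replace = TRUE), 2), 60)
    qual <- strrep(vapply(q, function(x) intToUtf8(x + 33), character(1)),
                   read_length)
    ids <- sprintf("read_%07d %s:%d-%d:%s", seq_len(n),
                   names(sequences)[tmpl], starts - 1,
                   starts - 1 + read_length, ifelse(minus, "-", "+"))
    data.frame(id = ids, seq = unname(seqs), qual = qual,
               stringsAsFactors = FALSE)
  })
}

#' Configuration for the SSR allelic-peak genotype simulator
#'
#' @param n_accessions Number of accessions.
#' @param n_markers Number of SSR markers (>= 10 for simulation).
#' @param cluster_assignment Named vector mapping accession to cluster id;
#'   default splits accessions evenly over `n_clusters`.
#' @param n_clusters Number of clusters when `cluster_assignment` is NULL.
#' @param within_cluster_peak_share Probability, in (0, 1], that an accession
#'   presents each peak of its cluster's characteristic set; 1 makes
#'   same-cluster accessions identical.
#' @param ploidy_per_accession Named vector of peak-count multipliers
#'   (default 1 for all).
#' @param n_linkage_groups Optional number of linkage groups markers are
#'   assigned to (round-robin); NULL for none.
#' @param seed Integer RNG seed.
#' @return An object of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(n_accessions = 20, n_markers = 50,
                                cluster_assignment = NULL, n_clusters = 4,
                                within_cluster_peak_share = 0.9,
                                ploidy_per_accession = NULL,
                                n_linkage_groups = NULL, seed = 1) {
  acc <- sprintf("acc%02d", seq_len(n_accessions))
  if (is.null(cluster_assignment)) {
    cluster_assignment <- stats::setNames(
      paste0("C", sort(rep_len(seq_len(n_clusters), n_accessions))), acc)
  }
  if (is.null(ploidy_per_accession))
    ploidy_per_accession <- stats::setNames(rep(1, length(cluster_assignment)),
                                            names(cluster_assignment))
  stopifnot(length(cluster_assignment) == n_accessions,
            !is.null(names(cluster_assignment)),
            all(names(ploidy_per_accession) %in% names(cluster_assignment)))
  if (within_cluster_peak_share <= 0 || within_cluster_peak_share > 1)
    stop("within_cluster_peak_share must be in (0, 1]")
  structure(list(
    n_accessions = as.integer(n_accessions), n_markers = as.integer(n_markers),
    cluster_assignment = cluster_assignment,
    within_cluster_peak_share = within_cluster_peak_share,
    ploidy_per_accession = ploidy_per_accession,
    n_linkage_groups = n_linkage_groups, seed = as.integer(seed)
  ), class = "genotype_sim_config")
}

#' Simulate a binary SSR allelic-peak genotype matrix
#'
#' Each cluster holds a characteristic ordered peak pool per marker; an
#' accession presents the first `2 * ploidy` peaks of its own cluster's pool,
#' each with probability `within_cluster_peak_share`, plus rare cross-cluster
#' leakage, so within-cluster Jaccard distances are smaller than
#' between-cluster distances in expectation and higher-ploidy accessions
#' present proportionally more peaks.
#'
#' @param config A [genotype_sim_config()].
#' @return Binary matrix (accessions x peaks) with attributes `peak_marker`
#'   (marker of each column), `marker_group` (optional linkage-group map) and
#'   `cluster` (true cluster per accession).
#' @export
simulate_marker_genotypes <- function(config = genotype_sim_config()) {
  stopifnot(inherits(config, "genotype_sim_config"))
  if (config$n_markers < 10) stop("n_markers must be at least 10")
  cl <- config$cluster_assignment
  acc <- names(cl)
  clusters <- sort(unique(unname(cl)))
  pl <- config$ploidy_per_accession[acc]
  ppc <- max(2L, 2L * as.integer(max(pl)))  # peaks per cluster per marker
  share <- config$within_cluster_peak_share
  leak <- (1 - share) / max(1, length(clusters) - 1) * 0.5
  with_seed(config$seed, {
    ncol_total <- config$n_markers * length(clusters) * ppc
    peak_cluster <- rep(rep(clusters, each = ppc), config$n_markers)
    peak_marker <- rep(sprintf("M%03d", seq_len(config$n_markers)),
                       each = length(clusters) * ppc)
    colnames_out <- paste0(peak_marker, "_", peak_cluster, "_p",
                           rep(seq_len(ppc), length(clusters) * config$n_markers))
    mat <- matrix(0L, nrow = length(acc), ncol = ncol_total,
                  dimnames = list(acc, colnames_out))
    for (a in seq_along(acc)) {
      n_pick <- min(2L * as.integer(pl[a]), ppc)
      # first n_pick peaks of the accession's own-cluster pool, per marker
      own_idx <- which(peak_cluster == cl[a])
      own_rank <- stats::ave(own_idx, peak_marker[own_idx], FUN = seq_along)
      sel <- own_idx[own_rank <= n_pick]
      keep <- sel[runif(length(sel)) < share]
      mat[a, keep] <- 1L
      if (leak > 0) {
        other_idx <- which(peak_cluster != cl[a])
        leak_hit <- other_idx[runif(length(other_idx)) < leak * n_pick / ppc]
        mat[a, leak_hit] <- 1L
      }
    }
    if (any(rowSums(mat) == 0))
      stop("simulated accession with zero peaks; increase markers or share")
    attr(mat, "peak_marker") <- peak_marker
    if (!is.null(config$n_linkage_groups)) {
      mk <- sprintf("M%03d", seq_len(config$n_markers))
      attr(mat, "marker_group") <- stats::setNames(
        paste0("LG", rep_len(seq_len(config$n_linkage_groups),
                             config$n_markers)), mk)
    }
    attr(mat, "cluster") <- cl
    mat
  })
}
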