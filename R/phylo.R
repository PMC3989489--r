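# SSR allelic-peak phylogenetics: Jaccard distances, Ward clustering,
# (multiscale) bootstrap support and per-group distance summaries.

#' Jaccard distance matrix from a binary genotype matrix
#'
#' D(x, y) = 1 - |peaks shared| / |peaks in either|; pairs sharing no peaks
#' get distance 1.
#'
#' @param matrix Binary accession x peak matrix (no all-zero rows).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
jaccard_distance <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2) stop("need at least 2 accessions")
  if (any(!(m %in% c(0, 1)))) stop("genotype matrix must be binary")
  if (any(rowSums(m) == 0)) stop("all-zero accession row")
  inter <- m %*% t(m)
  rs <- rowSums(m)
  uni <- outer(rs, rs, "+") - inter
  d <- 1 - ifelse(uni > 0, inter / uni, 0)
  d[uni == 0] <- 1
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with Ward linkage (ward.D2 by default, i.e.
#' Lance-Williams updates on squared distances; switchable to ward.D).
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param method "ward.D2" (default) or "ward.D".
#' @return An `hclust` tree.
#' @export
ward_cluster <- function(d, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isTRUE(all.equal(m, t(m)))) stop("distance matrix must be symmetric")
    d <- stats::as.dist(m)
  }
  stats::hclust(d, method = method)
}

# Bipartitions (leaf-membership keys) of the internal nodes of an hclust tree.
tree_bipartitions <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  keys <- character(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    mem <- integer(0)
    for (j in 1:2) {
      v <- hc$merge[i, j]
      mem <- c(mem, if (v < 0) -v else sets[[v]])
    }
    sets[[i]] <- sort(mem)
    keys[i] <- paste(hc$labels[sets[[i]]][order(hc$labels[sets[[i]]])],
                     collapse = "\r")
  }
  list(sets = sets, keys = keys)
}

#' Bootstrap support for Ward/Jaccard dendrogram nodes
#'
#' Peak columns are resampled with replacement; the bootstrap proportion (BP)
#' of each observed bipartition is the fraction of replicate trees containing
#' it. When `scales` are given, the multiscale bootstrap is run at sample
#' sizes r * n_peaks and approximately unbiased (AU) values are obtained by
#' fitting qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r) per node, with
#' AU = 1 - pnorm(v - c).
#'
#' @param matrix Binary genotype matrix.
#' @param replications Bootstrap replications per scale (>= 100).
#' @param scales Optional numeric vector of resampling scales (e.g.
#'   `seq(0.5, 1.4, by = 0.1)`); NULL for plain bootstrap.
#' @param seed Integer RNG seed.
#' @param method Ward variant, see [ward_cluster()].
#' @return List of class `bootstrap_tree`: `tree` (hclust), `node_support`
#'   (data.frame node, bp, au), `replications`.
#' @export
bootstrap_support <- function(matrix, replications = 1000, scales = NULL,
                              seed = 1, method = "ward.D2") {
  if (replications < 100) stop("use at least 100 replications")
  m <- as.matrix(matrix)
  hc <- ward_cluster(jaccard_distance(m), method = method)
  obs <- tree_bipartitions(hc)
  np <- ncol(m)
  run_scale <- function(size) {
    hits <- numeric(length(obs$keys))
    ok <- 0L
    for (r in seq_len(replications)) {
      cols <- sample.int(np, size, replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      if (any(rowSums(mb) == 0)) next  # resample produced an empty accession
      hcb <- ward_cluster(jaccard_distance(mb), method = method)
      hits <- hits + (obs$keys %in% tree_bipartitions(hcb)$keys)
      ok <- ok + 1L
    }
    if (ok == 0L) stop("no valid bootstrap replicate")
    hits / ok
  }
  with_seed(seed, {
    if (is.null(scales)) {
      bp <- run_scale(np)
      au <- rep(NA_real_, length(bp))
    } else {
      bps <- vapply(scales, function(r) run_scale(max(2, round(r * np))),
                    numeric(length(obs$keys)))
      bp <- bps[, which.min(abs(scales - 1))]
      au <- apply(bps, 1, function(bprow) {
        usable <- bprow > 0 & bprow < 1
        if (sum(usable) < 2) return(NA_real_)
        z <- qnorm(1 - bprow[usable])
        sq <- sqrt(scales[usable])
        fit <- stats::lsfit(cbind(sq, 1 / sq), z, intercept = FALSE)
        v <- fit$coefficients[1]; cc <- fit$coefficients[2]
        1 - pnorm(v - cc)
      })
    }
    structure(list(tree = hc,
                   node_support = data.frame(node = seq_along(bp), bp = bp,
                                             au = au),
                   replications = replications),
              class = "bootstrap_tree")
  })
}

#' Export a supported dendrogram as Newick
#'
#' Node labels carry BP (and AU when present) as `bp|au` percentages.
#'
#' @param bt A [bootstrap_support()] result.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when written to file.
#' @export
tree_to_newick <- function(bt, path = NULL) {
  stopifnot(inherits(bt, "bootstrap_tree"))
  phy <- ape::as.phylo(bt$tree)
  # hclust merge row i corresponds to phylo internal node labelled by height
  # order; map via ape's conversion (internal nodes follow merge order)
  lab <- sprintf("%.0f", 100 * bt$node_support$bp)
  if (!all(is.na(bt$node_support$au)))
    lab <- paste0(lab, "|", sprintf("%.0f", 100 * bt$node_support$au))
  # ape numbers internal nodes (ntip+1) .. (2*ntip-1); hclust merge rows map to
  # them in reverse height order; use ape's stored node order
  phy$node.label <- rep("", phy$Nnode)
  # match bipartitions between hclust and phylo to place labels robustly
  obs <- tree_bipartitions(bt$tree)
  tips <- phy$tip.label
  for (i in seq_along(obs$keys)) {
    mem <- sort(bt$tree$labels[obs$sets[[i]]])
    node <- ape::getMRCA(phy, match(mem, tips))
    if (!is.null(node)) phy$node.label[node - length(tips)] <- lab[i]
  }
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Per-group mean distances from a focal accession
#'
#' Distances are recomputed per marker group (e.g. linkage group) using only
#' that group's peak columns; the mean Jaccard distance from the focal
#' accession to every other accession is reported per group.
#'
#' @param matrix Binary genotype matrix with attributes `peak_marker` and
#'   `marker_group` (as produced by [simulate_marker_genotypes()]), or supply
#'   `peak_group` directly.
#' @param focal Focal accession id (row name).
#' @param peak_group Optional explicit group label per column.
#' @return data.frame: group, n_peaks, mean_distance (NA for groups where the
#'   focal or all others carry no peaks, flagged in `degenerate`).
#' @export
summarize_group_distances <- function(matrix, focal, peak_group = NULL) {
  m <- as.matrix(matrix)
  stopifnot(focal %in% rownames(m))
  if (is.null(peak_group)) {
    pm <- attr(matrix, "peak_marker")
    mg <- attr(matrix, "marker_group")
    if (is.null(pm) || is.null(mg))
      stop("need peak_marker/marker_group attributes or explicit peak_group")
    peak_group <- unname(mg[pm])
  }
  stopifnot(length(peak_group) == ncol(m))
  groups <- sort(unique(peak_group))
  out <- lapply(groups, function(g) {
    sub <- m[, peak_group == g, drop = FALSE]
    ok_rows <- rowSums(sub) > 0
    if (!ok_rows[focal] || sum(ok_rows) < 2)
      return(data.frame(group = g, n_peaks = ncol(sub),
                        mean_distance = NA_real_, degenerate = TRUE))
    sub2 <- sub[ok_rows, , drop = FALSE]
    d <- jaccard_distance(sub2)
    others <- setdiff(rownames(sub2), focal)
    data.frame(group = g, n_peaks = ncol(sub),
               mean_distance = mean(d[focal, others]), degenerate = FALSE)
  })
  do.call(rbind, out)
}
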