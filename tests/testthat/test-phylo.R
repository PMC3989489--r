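# Jaccard distances, Ward clustering, bootstrap support, group summaries.

test_that("Jaccard distances match hand counts and the vegan oracle", {
  m <- rbind(x = c(1, 1, 0, 0), y = c(1, 0, 1, 0), z = c(1, 1, 0, 0),
             w = c(0, 0, 0, 1))
  d <- jaccard_distance(m)
  expect_equal(d["x", "y"], 1 - 1 / 3) # {p1,p2} vs {p1,p3}
  expect_equal(d["x", "z"], 0)
  expect_equal(d["x", "w"], 1)         # disjoint
  skip_if_not_installed("vegan")
  set.seed(51)
  rm2 <- matrix(rbinom(30 * 40, 1, 0.4), nrow = 30)
  rownames(rm2) <- paste0("a", 1:30)
  rm2[rowSums(rm2) == 0, 1] <- 1
  expect_equal(unname(jaccard_distance(rm2)),
               unname(as.matrix(vegan::vegdist(rm2, method = "jaccard",
                                               binary = TRUE))),
               tolerance = 1e-12)
})

test_that("Jaccard distance satisfies the metric axioms", {
  set.seed(52)
  for (i in 1:5) {
    m <- matrix(rbinom(10 * 30, 1, 0.5), nrow = 10)
    rownames(m) <- paste0("a", 1:10)
    m[rowSums(m) == 0, 1] <- 1
    d <- jaccard_distance(m)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    for (k in 1:20) {
      ijk <- sample(10, 3)
      expect_lte(d[ijk[1], ijk[3]],
                 d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)
    }
  }
  expect_error(jaccard_distance(rbind(a = c(0, 0), b = c(1, 0))), "all-zero")
})

test_that("Ward clustering is deterministic and recovers separated pairs", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc <- ward_cluster(d2)
  expect_equal(hc$height, 0.4)
  gm <- simulate_marker_genotypes(genotype_sim_config(
    n_accessions = 4, n_markers = 20, n_clusters = 2, seed = 53))
  hc4 <- ward_cluster(jaccard_distance(gm))
  # the first two merges join the true within-cluster pairs
  truth <- attr(gm, "cluster")
  first_two <- hc4$merge[1:2, ]
  expect_true(all(first_two < 0))
  for (r in 1:2) {
    pair <- hc4$labels[-first_two[r, ]]
    expect_equal(truth[[pair[1]]], truth[[pair[2]]])
  }
  # permuting accession order leaves the topology unchanged
  perm <- sample(nrow(gm))
  hc_p <- ward_cluster(jaccard_distance(gm[perm, ]))
  # same partition (cluster ids are arbitrary labels)
  p1 <- cutree(hc_p, 2)[rownames(gm)]
  p2 <- cutree(hc4, 2)[rownames(gm)]
  expect_equal(length(unique(paste(p1, p2))), 2)
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("bootstrap support is high for real structure, low for noise", {
  # duplicated accessions pair with certainty
  set.seed(54)
  base <- rbinom(100, 1, 0.5)
  m <- rbind(dup1 = base, dup2 = base,
             o1 = rbinom(100, 1, 0.5), o2 = rbinom(100, 1, 0.5),
             o3 = rbinom(100, 1, 0.5))
  bt <- bootstrap_support(m, replications = 200, seed = 1)
  parts <- polydissect:::tree_bipartitions(bt$tree)
  pair_node <- which(vapply(parts$sets, function(s)
    setequal(bt$tree$labels[s], c("dup1", "dup2")), logical(1)))
  expect_equal(bt$node_support$bp[pair_node], 1.0)
  # pure-noise matrices have unstable internal nodes
  meds <- vapply(1:5, function(sd) {
    set.seed(sd)
    nm <- matrix(rbinom(12 * 80, 1, 0.5), nrow = 12,
                 dimnames = list(paste0("a", 1:12), NULL))
    nm[rowSums(nm) == 0, 1] <- 1
    bt <- bootstrap_support(nm, replications = 200, seed = sd)
    stats::median(bt$node_support$bp)
  }, numeric(1))
  expect_lt(stats::median(meds), 0.7)
})

test_that("bootstrap support is invariant to column order and AU is bounded", {
  gm <- simulate_marker_genotypes(genotype_sim_config(
    n_accessions = 12, n_markers = 20, n_clusters = 3, seed = 55))
  bt1 <- bootstrap_support(gm, replications = 150, seed = 9)
  bt2 <- bootstrap_support(gm[, sample(ncol(gm))], replications = 150, seed = 9)
  # the observed bipartitions are identical; BP agrees up to resampling noise
  # and exactly for fully supported nodes
  expect_lt(max(abs(bt1$node_support$bp - bt2$node_support$bp)), 0.2)
  expect_identical(bt1$node_support$bp == 1, bt2$node_support$bp == 1)
  bta <- bootstrap_support(gm, replications = 120,
                           scales = seq(0.6, 1.4, by = 0.2), seed = 10)
  au <- bta$node_support$au
  expect_true(all(is.na(au) | (au >= 0 & au <= 1)))
  expect_true(any(!is.na(au)))
  expect_error(bootstrap_support(gm, replications = 50), "100")
})

test_that("Newick export carries support labels and reparses", {
  gm <- simulate_marker_genotypes(genotype_sim_config(
    n_accessions = 8, n_markers = 15, n_clusters = 2, seed = 56))
  bt <- bootstrap_support(gm, replications = 120, seed = 2)
  nwk <- tree_to_newick(bt)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(gm))
  expect_true(any(grepl("^[0-9]+$", phy$node.label)))
  # topology agrees with the hclust tree
  expect_equal(suppressWarnings(
    ape::dist.topo(phy, ape::as.phylo(bt$tree)))[1], 0)
})

test_that("per-group distances isolate group-specific divergence", {
  gm <- simulate_marker_genotypes(genotype_sim_config(
    n_accessions = 8, n_markers = 20, n_clusters = 2,
    n_linkage_groups = 2, seed = 57))
  # a single group holding every peak reproduces the global distances
  all_one <- summarize_group_distances(gm, "acc01",
                                       peak_group = rep("G", ncol(gm)))
  d <- jaccard_distance(gm)
  expect_equal(all_one$mean_distance,
               mean(d["acc01", setdiff(rownames(gm), "acc01")]))
  # constructed two-group case: zero distance in the identical group only
  m <- cbind(matrix(rep(c(1, 1, 0, 1), 4), nrow = 4, byrow = FALSE),
             rbind(c(1, 0), c(0, 1), c(1, 1), c(0, 1)))
  rownames(m) <- paste0("a", 1:4)
  pg <- c(rep("g1", 4), rep("g2", 2))
  res <- summarize_group_distances(m, "a1", peak_group = pg)
  # a3 carries no g1 peaks and is excluded there; a2 and a4 are identical to a1
  expect_equal(res$mean_distance[res$group == "g1"], 0)
  expect_gt(res$mean_distance[res$group == "g2"], 0)
  # attribute-driven grouping works end to end
  res2 <- summarize_group_distances(gm, "acc01")
  expect_equal(nrow(res2), 2)
})
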