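# Truth-labelled octoploid simulator: divergence calibration, conservation,
# determinism.

test_that("zero-divergence configuration reproduces the ancestor in all copies", {
  tr <- simulate_octoploid(sim_config(monoploid_length = 5000, d_prog = 0,
                                      d_sub = 0, h_allelic = 0, seed = 2))
  expect_length(tr$haplotypes, 8)
  expect_true(all(tr$haplotypes == tr$ancestor))
})

test_that("realized divergence matches the configured rates", {
  cfg <- sim_config(monoploid_length = 1e5, d_prog = 0.08, d_sub = 0.02,
                    h_allelic = 0.005, seed = 1)
  tr <- simulate_octoploid(cfg)
  # cross-lineage homoeologs: identity ~ 1 - d_prog
  expect_equal(pct_identity(tr$haplotypes[["A_h1"]], tr$haplotypes[["B_h1"]]),
               0.92, tolerance = 0.011)
  # within-lineage homoeologs: ~ 1 - d_sub (plus allelic noise)
  expect_equal(pct_identity(tr$haplotypes[["A_h1"]], tr$haplotypes[["Ap_h1"]]),
               0.975, tolerance = 0.01)
  # allelic haplotypes: ~ 1 - h_allelic, within 3 sigma of binomial
  p <- 1 - pct_identity(tr$haplotypes[["A_h1"]], tr$haplotypes[["A_h2"]])
  expect_lt(abs(p - 0.005), 3 * sqrt(0.005 * 0.995 / 1e5))
  # ancestral GC within one percentage point of the target
  gc <- sum(strsplit(tr$ancestor, "")[[1]] %in% c("G", "C")) / 1e5
  expect_lt(abs(gc - cfg$gc_content), 0.01)
})

test_that("identical seeds give identical output and replay reproduces haplotypes", {
  cfg <- sim_config(monoploid_length = 2e4, seed = 7)
  tr1 <- simulate_octoploid(cfg)
  tr2 <- simulate_octoploid(cfg)
  expect_identical(tr1, tr2)
  for (h in c("A_h1", "Bp_h2"))
    expect_identical(replay_haplotype(tr1, h), tr1$haplotypes[[h]])
  # replay also holds with indels enabled
  tri <- simulate_octoploid(sim_config(monoploid_length = 2e4,
                                       indel_rate = 0.1, seed = 8))
  expect_identical(replay_haplotype(tri, "B_h2"), tri$haplotypes[["B_h2"]])
})

test_that("degenerate configurations are rejected with an explanation", {
  expect_error(simulate_octoploid(sim_config(monoploid_length = 30,
                                             d_prog = 0.04, d_sub = 0.01,
                                             h_allelic = 0.005, seed = 1)),
               "degenerate")
  expect_error(sim_config(d_prog = 0.02, d_sub = 0.05), "d_sub")
  expect_error(sim_config(h_allelic = 0.05, d_sub = 0.02), "h_allelic")
})

test_that("fragmentation conserves every base and hits the target N50", {
  tr <- simulate_octoploid(sim_config(monoploid_length = 1e4, seed = 3))
  contigs <- fragment_assembly(tr, contig_n50_target = 3000, seed = 7)
  info <- parse_contig_id(names(contigs))
  expect_identical(sum(nchar(contigs)), sum(nchar(tr$haplotypes)))
  # concatenating one haplotype's contigs in order reconstructs it
  for (h in c("A_h1", "B_h2")) {
    sel <- info$haplotype == h
    ord <- order(info$start[sel])
    expect_identical(paste(contigs[sel][ord], collapse = ""),
                     unname(tr$haplotypes[[h]]))
  }
  n50 <- n50_oracle(nchar(contigs))
  expect_gte(n50, 2250)
  expect_lte(n50, 3750)
  # single-contig boundary: target at least the sequence length
  one <- fragment_assembly(c(x_h1 = random_dna(1e4)),
                           contig_n50_target = 1e4, seed = 1)
  expect_length(one, 1)
  expect_error(fragment_assembly(tr, contig_n50_target = 500, seed = 1),
               "twice")
})

test_that("read simulation conserves coverage and injects calibrated errors", {
  g <- c(tpl = random_dna(5e4))
  rd <- simulate_reads(g, coverage = 10, read_length = 100,
                       error_rate = 0, seed = 4)
  expect_lte(abs(sum(nchar(rd$seq)) - 10 * 5e4), 100)
  # error-free reads are exact substrings of the template or its complement
  idx <- sample(nrow(rd), 50)
  rc <- revcomp(g)
  for (i in idx) {
    expect_true(grepl(rd$seq[i], g, fixed = TRUE) ||
                  grepl(rd$seq[i], rc, fixed = TRUE))
  }
  # realized mismatch count within 3 sigma of Binomial(1e6, 0.01)
  rd2 <- simulate_reads(g, coverage = 20, read_length = 100,
                        error_rate = 0.01, seed = 5)
  rd2 <- rd2[seq_len(10000), ]
  origin <- regmatches(rd2$id, regexec("tpl:(\\d+)-(\\d+):(.)", rd2$id))
  mism <- 0
  for (i in seq_len(nrow(rd2))) {
    s <- as.integer(origin[[i]][2])
    truth <- substr(g, s + 1, s + 100)
    if (origin[[i]][4] == "-") truth <- revcomp(truth)
    mism <- mism + round((1 - pct_identity(rd2$seq[i], truth)) * 100)
  }
  expect_lt(abs(mism - 1e4 * 100 * 0.01), 3 * sqrt(1e6 * 0.01 * 0.99))
  expect_error(simulate_reads(g, coverage = 0, seed = 1), "positive")
})

test_that("genotype simulator produces the configured cluster structure", {
  # share = 1 makes same-cluster accessions identical
  cfg1 <- genotype_sim_config(n_accessions = 4, n_markers = 12, n_clusters = 2,
                              within_cluster_peak_share = 1, seed = 11)
  gm1 <- simulate_marker_genotypes(cfg1)
  d <- jaccard_distance(gm1)
  expect_equal(d["acc01", "acc02"], 0)
  expect_gt(d["acc01", "acc03"], 0.5)
  # ploidy multiplier scales peaks per marker ~ proportionally
  cfg2 <- genotype_sim_config(
    n_accessions = 8, n_markers = 40, n_clusters = 1,
    within_cluster_peak_share = 0.95,
    ploidy_per_accession = stats::setNames(rep(c(1, 4), each = 4),
                                           sprintf("acc%02d", 1:8)),
    seed = 12)
  gm2 <- simulate_marker_genotypes(cfg2)
  mean1 <- mean(rowSums(gm2[1:4, ]) / 40)
  mean4 <- mean(rowSums(gm2[5:8, ]) / 40)
  expect_equal(mean4 / mean1, 4, tolerance = 0.2)
  # Ward/Jaccard recovers 4 configured clusters exactly
  gm3 <- simulate_marker_genotypes(genotype_sim_config(
    n_accessions = 20, n_markers = 50, n_clusters = 4, seed = 3))
  ct <- cutree(ward_cluster(jaccard_distance(gm3)), 4)
  truth <- attr(gm3, "cluster")
  expect_equal(length(unique(paste(ct, truth))), 4)
})
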