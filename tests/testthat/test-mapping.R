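# PSL-semantics alignment, the four-inequality hit filter, best-hit
# selection, multiplicity, attribution, non-homologous accounting, clustering.

test_that("self and reverse-complement alignments are exact", {
  set.seed(41)
  t <- random_dna(500)
  r <- align_sequences(c(q1 = t), c(t1 = t))
  expect_equal(nrow(r), 1)
  expect_equal(r$matches, 500)
  expect_equal(r$mismatches, 0)
  expect_equal(c(r$q_start, r$q_end, r$t_start, r$t_end), c(0, 500, 0, 500))
  expect_equal(r$strand, "+")
  expect_equal(r$identity, 100)
  r2 <- align_sequences(c(q1 = revcomp(t)), c(t1 = t))
  expect_equal(r2$strand, "-")
  expect_equal(r2$matches, 500)
  expect_error(align_sequences(c(q = "ACGTX"), c(t = t)), "non-ACGTN")
})

test_that("identity thresholds suppress diverged alignments", {
  set.seed(42)
  s <- random_dna(1000)
  q3 <- mutate_known(s, 30, pad = 10)
  r3 <- align_sequences(stats::setNames(q3$seq, "q"), c(t = s))
  expect_equal(r3$matches, 970)
  expect_equal(r3$mismatches, 30)
  expect_equal(r3$identity, 97)
  q8 <- mutate_known(s, 80, pad = 10)
  r8 <- align_sequences(stats::setNames(q8$seq, "q"), c(t = s))
  expect_equal(nrow(r8), 0) # below minIdentity 95
  r8m <- align_sequences(stats::setNames(q8$seq, "q"), c(t = s),
                         mode = "megablast_like")
  expect_equal(r8m$mismatches, 80) # megablast preset admits 92%
})

test_that("alignment counts agree with truth and a full-DP oracle", {
  set.seed(43)
  for (i in 1:5) {
    L <- sample(300:1500, 1)
    s <- random_dna(L)
    nmut <- round(L * 0.03)
    q <- mutate_known(s, nmut, pad = 12)
    r <- align_sequences(stats::setNames(q$seq, "q"), c(t = s))
    # substitution-only truth: full-span alignment, exact match counts
    expect_equal(r$q_start, 0)
    expect_equal(r$q_end, L)
    expect_equal(r$matches, L - nmut)
    expect_equal(r$mismatches, nmut)
    # full Needleman-Wunsch oracle on the same pair, same scoring
    expect_equal(r$matches - 2 * r$mismatches -
                   3 * (r$q_gap_bases + r$t_gap_bases),
                 nw_score_oracle(q$seq, s))
  }
  # a 7-bp deletion in the query within the band is recovered as target gap
  s <- random_dna(800)
  q <- paste0(substr(s, 1, 400), substr(s, 408, 800))
  r <- align_sequences(c(q = q), c(t = s))
  expect_equal(r$t_gap_bases, 7)
  expect_equal(r$matches, 793)
})

test_that("the four hit-selection inequalities match hand evaluation", {
  rec <- data.frame(
    q_name = c("a", "b", "c"), q_size = c(1000, 1000, 500),
    q_start = c(50, 50, 0), q_end = c(950, 950, 500),
    t_start = 0, t_end = c(950, 1300, 500),
    matches = c(850, 850, 500), mismatches = c(40, 40, 0),
    q_gap_bases = c(10, 10, 0), stringsAsFactors = FALSE
  )
  # a: c1=86, c2=90, c3=85, c4=95 -> kept; b: c4=130 -> dropped;
  # c: perfect self-hit, all 100 -> kept
  kept <- apply_hit_filters(rec)
  expect_identical(kept$q_name, c("a", "c"))
  # idempotence
  expect_identical(apply_hit_filters(kept), kept)
  # boundary values: exactly 80 / 25 / 120 pass, just beyond fails
  bd <- data.frame(
    q_name = sprintf("r%02d", 1:8), q_size = 1000,
    q_start = 0,
    q_end = c(800, 799, 800, 800, 800, 800, 800, 800),
    t_start = 0,
    t_end = c(800, 800, 800, 800, 1200, 1201, 799, 800),
    matches = c(800, 800, 799, 250, 800, 800, 800, 249),
    mismatches = 0,
    q_gap_bases = c(0, 0, 1, 550, 0, 0, 0, 551),
    stringsAsFactors = FALSE
  )
  kept <- apply_hit_filters(bd)$q_name
  expect_true(all(c("r01", "r03", "r04", "r05") %in% kept))
  expect_false(any(c("r02", "r06", "r07") %in% kept)) # c2=79.9, c4=120.1, c4=79.9
  expect_false("r08" %in% kept)                       # c1=80 ok but c3=24.9
})

test_that("best-hit selection applies minCover and is order-invariant", {
  rec <- data.frame(
    q_name = c("q1", "q2", "q2", "q3"),
    q_size = c(1000, 1000, 1000, 1000),
    q_start = c(0, 0, 0, 0), q_end = c(250, 900, 850, 150),
    t_name = c("tA", "tA", "tB", "tC"),
    t_start = 0, t_end = c(250, 900, 850, 150),
    matches = c(250, 880, 840, 150), score = c(250, 400, 300, 150),
    stringsAsFactors = FALSE
  )
  best <- select_best_alignment(rec)
  expect_equal(best$score[best$q_name == "q2"], 400)
  expect_true("q1" %in% best$q_name)   # coverage 0.25 qualifies
  expect_false("q3" %in% best$q_name)  # coverage 0.15 below minCover
  expect_identical(attr(best, "unmapped"), "q3")
  set.seed(44)
  for (i in 1:5) {
    shuf <- rec[sample(nrow(rec)), ]
    expect_identical(select_best_alignment(shuf)[order(best$q_name), ],
                     best[order(best$q_name), ], ignore_attr = TRUE)
  }
})

test_that("multiplicity classes bin targets by received best hits", {
  bh <- data.frame(q_name = c("q1", "q2", "q3"),
                   t_name = c("t1", "t1", "t2"), stringsAsFactors = FALSE)
  mt <- classify_multiplicity(bh)
  expect_equal(mt$per_target$class[mt$per_target$t_name == "t1"], "double")
  expect_equal(mt$per_target$class[mt$per_target$t_name == "t2"], "single")
  empty <- classify_multiplicity(bh[0, ])
  expect_equal(nrow(empty$per_target), 0)
  # conservation: class-weighted target counts equal mapped queries
  set.seed(45)
  bh2 <- data.frame(q_name = paste0("q", 1:200),
                    t_name = paste0("t", sample(40, 200, replace = TRUE)),
                    stringsAsFactors = FALSE)
  mt2 <- classify_multiplicity(bh2)
  expect_equal(sum(mt2$by_class$n_queries), 200)
  expect_equal(sum(mt2$by_class$fraction_of_mapped_queries), 1)
})

test_that("top-hit attribution picks the best species deterministically", {
  b1 <- data.frame(t_name = c("t1", "t2"), score = c(300, 200),
                   stringsAsFactors = FALSE)
  b2 <- data.frame(t_name = c("t2", "t3"), score = c(250, 100),
                   stringsAsFactors = FALSE)
  at <- attribute_top_hits(list(spA = b1, spB = b2))
  expect_equal(at$per_target$species[at$per_target$t_name == "t1"], "spA")
  expect_equal(at$per_target$species[at$per_target$t_name == "t2"], "spB")
  expect_equal(sum(at$by_species$percent), 100)
  # tie goes to the first-listed species and is logged
  tie <- attribute_top_hits(list(
    spA = data.frame(t_name = "t", score = 100, stringsAsFactors = FALSE),
    spB = data.frame(t_name = "t", score = 100, stringsAsFactors = FALSE)))
  expect_equal(tie$per_target$species, "spA")
  expect_equal(tie$ties, 1L)
})

test_that("non-homologous accounting separates shared from unique queries", {
  set.seed(46)
  shared <- stats::setNames(vapply(1:5, function(i) random_dna(600),
                                   character(1)), paste0("s", 1:5))
  nh <- compute_nonhomologous(shared, shared)
  expect_equal(nh$no_hit_length, 0)
  unrelated <- stats::setNames(vapply(1:10, function(i) random_dna(600),
                                      character(1)), paste0("u", 1:10))
  nh2 <- compute_nonhomologous(unrelated, shared)
  expect_equal(nh2$ratio, 1)
  expect_length(nh2$no_hit, 10)
  # mixed set: simulated unique inserts are flagged, shared ones are not
  mixed <- c(shared, unrelated[1:5])
  nh3 <- compute_nonhomologous(mixed, shared)
  expect_setequal(nh3$no_hit, names(unrelated)[1:5])
  expect_equal(nh3$ratio, 5 * 600 / (10 * 600))
})

test_that("greedy clustering reproduces truth labels for shared genes", {
  set.seed(47)
  expect_length(greedy_cluster(c(a = "ACGTACGTACGTACGTACGTACGTACGT",
                                 b = "ACGTACGTACGTACGTACGTACGTACGT"))$clusters, 1)
  two <- greedy_cluster(c(a = random_dna(300), b = random_dna(300)))
  expect_length(two$clusters, 2)
  # 30 genes shared across two species at ~2% divergence + 10 species-A-only
  genes <- vapply(1:40, function(i) random_dna(500), character(1))
  spA <- stats::setNames(genes, paste0("A_g", 1:40))
  spB <- stats::setNames(
    vapply(genes[1:30], function(g) mutate_known(g, 10, pad = 5)$seq,
           character(1)), paste0("B_g", 1:30))
  seqs <- c(spA, spB)
  species <- stats::setNames(substr(names(seqs), 1, 1), names(seqs))
  cl <- greedy_cluster(seqs, species = species)
  expect_equal(length(cl$clusters), 40)
  expect_equal(unname(cl$species_unique["A"]), 10)
})
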