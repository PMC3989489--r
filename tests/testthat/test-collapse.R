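# Windowed overlap-layout-consensus collapsing of heterozygous sequences.

test_that("backbone-specific selection keeps only novel sequences", {
  set.seed(31)
  backbone <- stats::setNames(vapply(1:5, function(i) random_dna(2000),
                                     character(1)), paste0("bb", 1:5))
  derived <- stats::setNames(
    vapply(1:10, function(i) {
      src <- sample(5, 1)
      mutate_known(substr(backbone[[src]], 1, 800), 16, pad = 5)$seq  # 2% diverged
    }, character(1)), paste0("derived", 1:10))
  novel <- stats::setNames(vapply(1:10, function(i) random_dna(800),
                                  character(1)), paste0("novel", 1:10))
  spec <- select_specific_sequences(c(derived, novel), backbone)
  expect_setequal(names(spec), names(novel))
  # identical copy excluded, seed-free random included
  expect_length(select_specific_sequences(c(x = backbone[[1]]), backbone), 0)
})

test_that("window splitting reproduces parents and handles boundaries", {
  set.seed(32)
  p <- c(p500 = random_dna(500), p300 = random_dna(300), p250 = random_dna(250))
  fr <- split_windows(p, window = 300, step = 100)
  f500 <- fr[fr$parent_id == "p500", ]
  expect_equal(f500$parent_start, c(0, 100, 200))
  expect_true(all(nchar(f500$seq) == 300))
  expect_equal(nrow(fr[fr$parent_id == "p300", ]), 1)
  f250 <- fr[fr$parent_id == "p250", ]
  expect_equal(nchar(f250$seq), 250)
  # reassembly by offsets reproduces each parent exactly
  for (nm in names(p)) {
    sub <- fr[fr$parent_id == nm, ]
    rebuilt <- strrep("?", nchar(p[[nm]]))
    for (i in seq_len(nrow(sub)))
      substr(rebuilt, sub$parent_start[i] + 1,
             sub$parent_start[i] + nchar(sub$seq[i])) <- sub$seq[i]
    expect_identical(rebuilt, unname(p[[nm]]))
  }
  # right-anchored final window when the last step misses the end
  fr2 <- split_windows(c(x = random_dna(550)))
  expect_equal(fr2$parent_start, c(0, 100, 200, 250))
})

test_that("overlap detection honours the 90% identity boundary exactly", {
  set.seed(33)
  ident <- random_dna(300)
  ov <- find_overlaps(c(a = ident, b = ident), min_overlap = 100)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$length, 300)
  expect_equal(ov$identity, 1.0)
  # two 300-mers sharing a 200-bp span: 20 mismatches -> identity exactly
  # 0.90, reported; 21 mismatches -> 0.895, suppressed
  span <- random_dna(200)
  for (nm in c(20, 21)) {
    span_mut <- mutate_known(span, nm, pad = 2)$seq
    a <- paste0(random_dna(100), span)
    b <- paste0(span_mut, random_dna(100))
    ov <- find_overlaps(c(a = a, b = b), min_overlap = 100)
    if (nm == 20) {
      expect_equal(nrow(ov), 1)
      expect_equal(ov$identity, 0.90)
      expect_equal(ov$offset, 100)
    } else {
      expect_equal(nrow(ov), 0)
    }
  }
  # fragments of one parent chain with offset 100 at identity 1
  fr <- split_windows(c(x = random_dna(700)))
  ovc <- find_overlaps(fr)
  adjacent <- ovc[abs(ovc$offset) == 100, ]
  expect_true(all(adjacent$identity == 1))
  expect_gte(nrow(adjacent), 4)
})

test_that("layout consensus collapses haplotypes and counts het sites", {
  set.seed(34)
  h1 <- random_dna(1000)
  m <- mutate_known(h1, 20, pad = 2) # 2% SNPs
  res <- collapse_assembly(c(a = h1, b = m$seq))
  expect_length(res$contigs, 1)
  expect_equal(nchar(res$contigs[[1]]), 1000)
  expect_equal(sum(res$info$het_sites_collapsed), 20)
  expect_false(grepl("N", res$contigs[[1]]))
  # 15% divergence: no overlap passes 90%, copies stay separate
  m15 <- mutate_known(h1, 150, pad = 2)
  res15 <- collapse_assembly(c(a = h1, b = m15$seq))
  expect_length(res15$contigs, 2)
  # a single fragment with no overlaps is returned verbatim
  lone <- layout_consensus(c(solo = "ACGTACGTAC"),
                           find_overlaps(c(solo = "ACGTACGTAC"),
                                         min_overlap = 5))
  expect_equal(unname(lone$contigs[[1]]), "ACGTACGTAC")
})

test_that("consensus takes the weight-majority base with deterministic ties", {
  # three copies, one diverging: majority base wins at the divergent column
  s <- strrep("ACGTT", 60)
  d <- s
  substr(d, 150, 150) <- "A"
  frs <- c(x = s, y = s, z = d)
  cons <- layout_consensus(frs, find_overlaps(frs))
  expect_equal(unname(cons$contigs[[1]]), s)
  expect_equal(cons$info$het_sites_collapsed, 1)
  expect_equal(unique(cons$depth[[1]]), 3L)
  # 1:1 tie -> fixed base order A < C < G < T
  a <- strrep("GGTTC", 60); b <- a
  substr(b, 100, 100) <- "A" # disagree: one G, one A -> A wins
  tie <- layout_consensus(c(p = a, q = b), find_overlaps(c(p = a, q = b)))
  expect_equal(substr(tie$contigs[[1]], 100, 100), "A")
})

test_that("unjoined contigs merge deterministically on end overlaps", {
  set.seed(35)
  x <- random_dna(700)
  m <- merge_unjoined(c(c1 = substr(x, 1, 400), c2 = substr(x, 301, 700)))
  expect_length(m$contigs, 1)
  expect_identical(unname(m$contigs[[1]]), x)
  # unrelated contigs stay apart
  m2 <- merge_unjoined(c(a = random_dna(400), b = random_dna(400)))
  expect_length(m2$contigs, 2)
  # chain of 5 overlapping contigs collapses to the parent exactly
  parent <- random_dna(1400)
  starts <- c(1, 251, 501, 751, 1001)
  chain <- stats::setNames(substring(parent, starts, starts + 399),
                           paste0("k", 1:5))
  m3 <- merge_unjoined(chain)
  expect_length(m3$contigs, 1)
  expect_identical(unname(m3$contigs[[1]]), parent)
})

test_that("virtual reference integrates sources and rejects id clashes", {
  set.seed(36)
  bb <- stats::setNames(vapply(1:10, function(i) random_dna(500),
                               character(1)), paste0("s", 1:10))
  sp <- stats::setNames(vapply(1:5, function(i) random_dna(400),
                               character(1)), paste0("c", 1:5))
  ref <- build_virtual_reference(bb, sp)
  expect_length(ref$reference, 15)
  expect_equal(ref$stats$total_length, sum(nchar(bb)) + sum(nchar(sp)))
  empty <- build_virtual_reference(bb, character(0))
  expect_equal(unname(empty$reference), unname(bb))
  expect_error(build_virtual_reference(c(a = "ACGT"), c(a = "ACGT")), NA)
  expect_error(build_virtual_reference(stats::setNames(c("AC", "GT"), c("a", "a")),
                                       character(0)), "duplicate")
})

test_that("full octoploid collapse lands between 1x and 2x the monoploid", {
  tr <- simulate_octoploid(sim_config(monoploid_length = 3e4, seed = 5))
  res <- collapse_assembly(tr$haplotypes)
  total <- sum(nchar(res$contigs))
  expect_gte(total, 3e4 * 0.99)
  expect_lte(total, 2 * 3e4)
})
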