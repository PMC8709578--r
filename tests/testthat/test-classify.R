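# Decision table, gene aggregation, summaries and gene-set comparison.

test_that("headline decision-table branches match the published patterns", {
  expect_equal(classify_region(TRUE, TRUE, TRUE, TRUE), "cobinding")
  # both factors, one motif: the factor lacking its motif is tethered
  expect_equal(classify_region(TRUE, TRUE, TRUE, FALSE),
               "tethering_HSF1_by_ER")
  expect_equal(classify_region(TRUE, TRUE, FALSE, TRUE),
               "tethering_ER_by_HSF1")
  expect_equal(classify_region(TRUE, TRUE, FALSE, FALSE), "indirect")
  expect_equal(classify_region(TRUE, FALSE, TRUE, FALSE), "canonical_ER")
  expect_equal(classify_region(TRUE, FALSE, TRUE, TRUE), "canonical_ER")
  expect_equal(classify_region(FALSE, TRUE, FALSE, TRUE), "canonical_HSF1")
  # single factor without its own motif, or no factor: unclassified
  expect_equal(classify_region(TRUE, FALSE, FALSE, TRUE), "unclassified")
  expect_equal(classify_region(FALSE, TRUE, TRUE, FALSE), "unclassified")
  expect_equal(classify_region(FALSE, FALSE, TRUE, TRUE), "unclassified")
})

test_that("aggregate_by_gene assigns regions to nearest genes and dedups", {
  tss <- tss_records(c("gA", "gB"), "chr1", c("+", "+"), c(1000, 9000))
  ev <- data.frame(
    region_id = c("r1", "r2", "r3"), chrom = "chr1",
    start = c(1400, 1400, 8000), end = c(1600, 1600, 8200),
    mode = c("cobinding", "cobinding", "unclassified"),
    stringsAsFactors = FALSE)
  gt <- aggregate_by_gene(ev, tss)
  # unclassified regions are excluded; duplicate rows collapse
  expect_equal(nrow(gt), 2L)
  expect_equal(unique(gt$gene_id), "gA")
  expect_equal(gt$distance, c(500, 500))
  ev2 <- ev; ev2$chrom <- c("chr1", "chrX", "chr1")
  expect_warning(aggregate_by_gene(ev2, tss), "dropped")
})

test_that("summarize_modes counts genes and the direct-cooperation union", {
  empty <- data.frame(gene_id = character(0), mode = character(0),
                      region_id = character(0))
  expect_true(all(summarize_modes(empty)$counts == 0))

  gt <- data.frame(
    gene_id = c("A", "B", "C", "C", "D", "D", "E"),
    mode = c("cobinding", "tethering_HSF1_by_ER", "cobinding",
             "tethering_ER_by_HSF1", "canonical_ER", "canonical_HSF1",
             "canonical_ER"),
    region_id = sprintf("r%d", 1:7), stringsAsFactors = FALSE)
  s <- summarize_modes(gt)
  expect_equal(unname(s$counts["cobinding"]), 2L)       # A, C
  expect_equal(unname(s$counts["tethering"]), 2L)       # B, C
  expect_equal(unname(s$counts["direct_cooperation"]), 3L) # A, B, C
  expect_equal(unname(s$counts["canonical_coregulated"]), 1L) # D
  expect_setequal(s$genes$direct_cooperation, c("A", "B", "C"))
})

test_that("compare_gene_sets produces all 7 Venn counts and sums to the union", {
  expect_equal(unname(compare_gene_sets("a", "b", "c")),
               c(1, 1, 1, 0, 0, 0, 0))
  same <- sprintf("g%d", 1:5)
  expect_equal(unname(compare_gene_sets(same, same, same)),
               c(0, 0, 0, 0, 0, 0, 5))
  for (seed in 1:5) {
    sets <- withr::with_seed(seed, lapply(1:3, function(i)
      sample(sprintf("g%02d", 1:30), sample(5:25, 1))))
    got <- compare_gene_sets(sets[[1]], sets[[2]], sets[[3]])
    expect_equal(got, oracle_venn(sets[[1]], sets[[2]], sets[[3]]))
    expect_equal(sum(got),
                 length(unique(unlist(sets))))
  }
})

test_that("three_way_overlap flags anchors and pairs peak-only regions", {
  anchors <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  er <- peak_records("chr1", c(1400, 5000), c(1600, 5200),
                     name = c("er1", "er2"))
  hs <- peak_records("chr1", c(1450, 5050), c(1650, 5150),
                     name = c("h1", "h2"))
  ev <- three_way_overlap(anchors, er, hs)
  a_row <- ev[ev$source == "anchor", ]
  expect_true(a_row$er_present && a_row$hsf1_present)
  pp <- ev[ev$source == "peak_pair", ]
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$start, 5000)
  expect_equal(pp$end, 5200)
  # HSF1-only anchor: ER peak removed
  ev2 <- three_way_overlap(anchors, er[2, ], hs)
  a2 <- ev2[ev2$source == "anchor", ]
  expect_false(a2$er_present)
  expect_true(a2$hsf1_present)
  # overlapping anchors violate the reduce invariant
  bad <- data.frame(chrom = "chr1", start = c(0, 500), end = c(1000, 1500))
  expect_error(three_way_overlap(bad, er, hs), "internal error")
})

test_that("the each/one switch changes peak-only pairing as documented", {
  # centers: er 150 inside hs [100, 400); hs center 250 not inside er
  er <- peak_records("chr1", 100, 200, name = "er1")
  hs <- peak_records("chr1", 100, 400, name = "h1")
  none <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0))
  ev_each <- three_way_overlap(none, er, hs, overlap_rule = "each")
  expect_equal(sort(ev_each$source), c("peak", "peak"))
  ev_one <- three_way_overlap(none, er, hs, overlap_rule = "one")
  expect_equal(ev_one$source, "peak_pair")
})

test_that("loop-mediated cross-anchor pairings are reported separately", {
  pairs <- anchor_pairs("chr1", 1000, 2000, "chr1", 50000, 51000)
  er <- peak_records("chr1", 1400, 1600, name = "er1")
  hs <- peak_records("chr1", 50400, 50600, name = "h1")
  genome_seq <- setNames(random_dna(60000, seed = 404), "chr1")
  tss <- tss_records("gA", "chr1", "+", 3000)
  res <- classify_pipeline(er, hs, pairs, genome_seq,
                           build_pwm(toy_ere_counts()),
                           build_pwm(toy_hse_counts()), tss)
  expect_equal(nrow(res$loop_pairs), 1L)
  # neither anchor region classifies as tethering: single factors only
  expect_false(any(res$evidence$mode %in%
                     c("tethering_HSF1_by_ER", "tethering_ER_by_HSF1")))
})
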