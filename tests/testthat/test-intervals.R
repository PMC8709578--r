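# Interval algebra: centers, the two overlap conventions, reduce,
# nearest-TSS annotation and randomized placement.

test_that("peak_center uses the summit when present, floored midpoint otherwise", {
  pk <- peak_records("chr1", c(100, 100, 100), c(200, 201, 200),
                     summit_offset = c(NA, NA, 30))
  expect_equal(peak_center(pk), c(150, 150, 130))
})

test_that("center_in follows the half-open convention", {
  a <- peak_records(rep("chr1", 3), rep(100, 3), rep(200, 3))
  b <- data.frame(chrom = "chr1", start = c(140, 150, 160),
                  end = c(160, 160, 300))
  # center 150: inside [140,160); boundary start 150 counts; [160,300) no
  expect_equal(center_in(a, b), c(TRUE, TRUE, FALSE))
  b2 <- data.frame(chrom = "chr2", start = 140, end = 160)
  expect_false(center_in(a[1, ], b2))
})

test_that("one-center and each-center rules behave per convention on examples", {
  a <- peak_records("chr1", 100, 200)
  b <- peak_records("chr1", 140, 160)
  expect_equal(nrow(common_sites_one(a, b)), 1L)
  expect_true(common_sites_each(a, b)) # 150 in both
  expect_equal(nrow(common_sites_one(peak_records("chr1", 0, 10),
                                     peak_records("chr1", 100, 110))), 0L)
  # a=100-200 vs b=190-400: neither center falls inside the other
  b2 <- peak_records("chr1", 190, 400)
  expect_false(common_sites_each(a, b2))
  expect_equal(nrow(common_sites_one(a, b2)), 0L)
  # a's center inside a wide b, but not vice versa: one yes, each no
  b3 <- peak_records("chr1", 140, 500)
  expect_false(common_sites_each(a, b3))
  expect_equal(nrow(common_sites_one(a, b3)), 1L)
})

test_that("common_sites_one matches the brute-force oracle on random sets", {
  genome <- toy_genome()
  for (seed in c(1, 2, 3)) {
    a <- random_peak_set(200, genome, seed = seed)
    b <- random_peak_set(200, genome, seed = seed + 100)
    got <- common_sites_one(a, b)
    want <- oracle_common_one(a, b)
    want <- want[order(want$a, want$b), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("each-center implies one-center on random peak pairs", {
  genome <- toy_genome()
  a <- random_peak_set(10000, genome, seed = 9, width = c(20, 500))
  b <- random_peak_set(10000, genome, seed = 10, width = c(20, 500))
  each <- common_sites_each(a, b)
  one_pairs <- common_sites_one(a, b)
  one_diag <- logical(nrow(a))
  one_diag[one_pairs$a[one_pairs$a == one_pairs$b]] <- TRUE
  expect_true(all(!each | one_diag))
})

test_that("reduce_merge merges overlap and adjacency, is idempotent and conserves coverage", {
  x <- data.frame(chrom = "chr1", start = c(10, 50), end = c(60, 100))
  expect_equal(reduce_merge(x),
               data.frame(chrom = "chr1", start = 10, end = 100))
  x2 <- data.frame(chrom = "chr1", start = c(10, 20), end = c(20, 30))
  expect_equal(reduce_merge(x2),
               data.frame(chrom = "chr1", start = 10, end = 30))

  covered_bp <- function(df) {
    sum(vapply(unique(df$chrom), function(ch) {
      sub <- df[df$chrom == ch, ]
      pos <- unique(unlist(mapply(seq, sub$start, sub$end - 1,
                                  SIMPLIFY = FALSE)))
      length(pos)
    }, numeric(1)))
  }
  for (seed in 1:5) {
    r <- withr::with_seed(seed, {
      s <- floor(runif(60) * 3000)
      data.frame(chrom = sample(c("c1", "c2"), 60, TRUE), start = s,
                 end = s + 1 + floor(runif(60) * 200))
    })
    red <- reduce_merge(r)
    expect_equal(reduce_merge(red), red)                  # idempotent
    expect_equal(covered_bp(red), covered_bp(r))          # same union
    expect_true(all(diff(red$start[red$chrom == "c1"]) > 0))
    # matches the reference reduce implementation per chromosome
    by_ch <- lapply(split(r, r$chrom), function(d)
      IRanges::reduce(IRanges::IRanges(d$start + 1, d$end)))
    for (ch in names(by_ch)) {
      sub <- red[red$chrom == ch, ]
      expect_equal(sub$start, IRanges::start(by_ch[[ch]]) - 1)
      expect_equal(sub$end, as.numeric(IRanges::end(by_ch[[ch]])))
    }
  }
})

test_that("nearest_tss handles examples, the tie rule, and errors", {
  tss <- tss_records(c("gA", "gB"), "chr1", c("+", "+"), c(1000, 2100))
  r <- data.frame(chrom = "chr1", start = 1400, end = 1600) # midpoint 1500
  nt <- nearest_tss(r, tss)
  expect_equal(nt$gene_id, "gA")
  expect_equal(nt$distance, 500)
  # equidistant: lexicographically smaller gene id wins
  tss2 <- tss_records(c("gZ", "gB"), "chr1", c("+", "-"), c(1000, 2000))
  nt2 <- nearest_tss(r, tss2)
  expect_equal(nt2$gene_id, "gB")
  expect_equal(nt2$distance, 500) # minus strand: tss - mid = 2000 - 1500
  expect_error(nearest_tss(r, tss_records(character(0), character(0),
                                          character(0), numeric(0))),
               "empty")
  # no same-chromosome TSS -> NA sentinel
  r2 <- data.frame(chrom = "chrX", start = 0, end = 10)
  expect_true(is.na(nearest_tss(r2, tss)$gene_id))
})

test_that("nearest_tss matches the brute-force oracle on random instances", {
  genome <- toy_genome()
  for (seed in c(21, 22, 23)) {
    regions <- withr::with_seed(seed, {
      ci <- sample.int(2, 1000, TRUE)
      s <- floor(runif(1000) * (genome$length[ci] - 500))
      data.frame(chrom = genome$chrom[ci], start = s,
                 end = s + 1 + floor(runif(1000) * 500))
    })
    tss <- random_tss_table(100, genome, seed = seed + 50)
    got <- nearest_tss(regions, tss)
    want <- oracle_nearest_tss(regions, tss)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$distance, want$distance)
  }
})

test_that("randomize_peaks preserves structure and is uniform and seeded", {
  genome <- genome_spec("chr1", 1000)
  # degenerate: width equals chromosome length forces start 0
  deg <- randomize_peaks(peak_records("chr1", 0, 100, name = "x"),
                         genome_spec("chr1", 100), seed = 3)
  expect_equal(deg$start, 0)
  expect_error(randomize_peaks(peak_records("chr1", 0, 200),
                               genome_spec("chr1", 100), seed = 1),
               "longer than")

  many <- peak_records(rep("chr1", 10000), rep(500, 10000), rep(600, 10000),
                       summit_offset = 10)
  r <- randomize_peaks(many, genome, seed = 99)
  expect_equal(r$end - r$start, many$end - many$start)
  expect_equal(r$chrom, many$chrom)
  expect_equal(r$summit_offset, many$summit_offset)
  expect_identical(r, randomize_peaks(many, genome, seed = 99))
  expect_false(identical(r$start, randomize_peaks(many, genome, seed = 100)$start))
  # uniform over the admissible range [0, 900]
  expect_true(all(r$start >= 0 & r$start <= 900))
  bins <- cut(r$start, breaks = seq(-0.5, 900.5, length.out = 11))
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)
})
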