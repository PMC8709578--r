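# PWM construction, scanning, exact null distribution, presence calls
# and central enrichment.

test_that("build_pwm implements the stated log-odds formula", {
  # uniform column: all scores zero regardless of pseudocount
  m <- motif_counts("u", matrix(1, 4, 4))
  pwm <- build_pwm(m, pseudocount = 2.5)
  expect_equal(unname(pwm$log_odds), matrix(0, 4, 4))
  # hand arithmetic: column (4,0,0,0), uniform bg, pseudocount 1
  m2 <- motif_counts("s", matrix(c(4, 0, 0, 0), 4, 4))
  pwm2 <- build_pwm(m2, pseudocount = 1)
  expect_equal(unname(pwm2$log_odds["A", 1]), log2(3.4), tolerance = 1e-12)
  expect_equal(unname(pwm2$log_odds["C", 1]), log2((0 + 0.25) / 5 / 0.25),
               tolerance = 1e-12)
  expect_error(build_pwm(motif_counts("z", matrix(c(1, 0, 0, 0), 4, 4)),
                         pseudocount = 0), "pseudocount")
})

test_that("changing the background shifts scores by -log2(bg/0.25)", {
  m <- random_motif_counts(31, L = 6)
  bg <- c(0.2, 0.3, 0.3, 0.2)
  p_unif <- build_pwm(m, pseudocount = 1)
  p_bg <- build_pwm(m, background = bg, pseudocount = 1)
  # with the background-weighted pseudocount the exact identity holds in
  # the limit of sharp counts; check the dominant algebraic term on a
  # column with all counts equal (numerator shift cancels)
  mu <- motif_counts("u", matrix(5, 4, 5))
  s_unif <- build_pwm(mu, pseudocount = 1)$log_odds
  s_bg <- build_pwm(mu, background = bg, pseudocount = 1)$log_odds
  for (j in 1:4)
    expect_equal(s_bg[j, ] - s_unif[j, ],
                 rep(-log2(bg[j] / 0.25) +
                       log2((5 + bg[j]) / (5 + 0.25)), 5),
                 tolerance = 1e-12)
  expect_equal(dim(p_bg$log_odds), dim(p_unif$log_odds))
})

test_that("scan_sequence finds consensus hits with strand symmetry", {
  pwm <- build_pwm(toy_ere_counts())
  cons <- "GGTCAAAATGACC"
  hits <- scan_sequence(pwm, cons)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$position, 0L)
  expect_equal(best$strand, "+")
  # maximum attainable score: consensus base at every position
  expect_equal(best$score, sum(apply(pwm$log_odds, 2, max)),
               tolerance = 1e-12)
  # the ERE is palindromic: on the reverse complement, the - strand hit
  # at 0 carries the same maximal score
  rc_hits <- scan_sequence(pwm, oracle_revcomp(cons))
  rc_minus <- rc_hits[rc_hits$strand == "-" & rc_hits$position == 0, ]
  expect_equal(rc_minus$score, best$score, tolerance = 1e-12)

  # a non-palindromic motif resolves the strand unambiguously
  m <- motif_counts("np", sapply(strsplit("GGGGAATC", "")[[1]], function(b)
    ifelse(c("A", "C", "G", "T") == b, 12, 0)))
  pwm_np <- build_pwm(m)
  word <- "GGGGAATC"
  fw <- scan_sequence(pwm_np, word)
  expect_equal(fw$strand[which.max(fw$score)], "+")
  rc <- scan_sequence(pwm_np, oracle_revcomp(word))
  expect_equal(rc$strand[which.max(rc$score)], "-")
  expect_equal(max(rc$score), max(fw$score), tolerance = 1e-12)
})

test_that("scanning a random sequence matches naive per-window summation", {
  m <- random_motif_counts(77, L = 7)
  pwm <- build_pwm(m, pseudocount = 1)
  seq <- random_dna(200, seed = 78)
  got <- scan_sequence(pwm, seq)
  want <- oracle_scan(m$counts, rep(0.25, 4), 1, seq)
  expect_equal(got$position, want$position)
  expect_equal(got$strand, want$strand)
  expect_equal(got$score, want$score, tolerance = 1e-9)
})

test_that("strand symmetry holds globally on random sequences", {
  pwm <- build_pwm(random_motif_counts(5, L = 8))
  seq <- random_dna(120, seed = 6)
  fwd <- scan_sequence(pwm, seq)
  rev <- scan_sequence(pwm, oracle_revcomp(seq))
  L <- pwm$length
  n <- nchar(seq)
  # a + hit at p maps to a - hit at n - L - p on the reverse complement
  fwd_plus <- fwd[fwd$strand == "+", ]
  rev_minus <- rev[rev$strand == "-", ]
  rev_minus <- rev_minus[order(n - L - rev_minus$position), ]
  expect_equal(fwd_plus$score, rev_minus$score, tolerance = 1e-9)
})

test_that("windows with N are skipped and short sequences give empty results", {
  pwm <- build_pwm(toy_ere_counts())
  expect_equal(nrow(scan_sequence(pwm, "ACGT")), 0L)
  seq <- paste0("GGTCAAAATGACC", "N", "GGTCAAAATGACC")
  hits <- scan_sequence(pwm, seq)
  # no window crossing the N survives
  expect_false(any(hits$position > 0 & hits$position < 14))
  expect_true(all(c(0, 14) %in% hits$position))
})

test_that("null_pmf is exact: support, normalization and enumeration tails", {
  # single position (4,0,0,0): two support points with masses 1/4, 3/4
  m1 <- motif_counts("one", matrix(c(4, 0, 0, 0), 4, 4))
  pwm1 <- build_pwm(motif_counts("one", matrix(c(4, 0, 0, 0), 4, 4)[, 1,
                                               drop = FALSE]))
  np1 <- null_pmf(pwm1)
  expect_equal(sort(np1$mass[np1$mass > 0]), c(0.25, 0.75))
  expect_equal(sum(np1$mass), 1, tolerance = 1e-9)

  for (seed in c(101, 102, 103)) {
    m <- random_motif_counts(seed, L = sample(4:6, 1))
    pwm <- build_pwm(m, pseudocount = 1)
    np <- null_pmf(pwm, bin_width = 0.01)
    # query within the attainable score range (the tail is clamped
    # outside it)
    rng <- c(sum(apply(pwm$log_odds, 2, min)),
             sum(apply(pwm$log_odds, 2, max)))
    scores <- withr::with_seed(seed, runif(20, rng[1], rng[2]))
    got <- score_pvalue(np, scores)
    lo_tail <- oracle_null_tail(m$counts, rep(0.25, 4), 1, scores + 0.011)
    hi_tail <- oracle_null_tail(m$counts, rep(0.25, 4), 1, scores - 0.011)
    expect_true(all(got >= lo_tail - 1e-9 & got <= hi_tail + 1e-9))
  }
  # normalization for a long random PWM
  np_long <- null_pmf(build_pwm(random_motif_counts(9, L = 20)))
  expect_equal(sum(np_long$mass), 1, tolerance = 1e-9)
})

test_that("motif_present calls planted sites, rejects clean background, is monotone", {
  pwm <- build_pwm(toy_ere_counts())
  np <- null_pmf(pwm)
  # Independent oracle for the toy ERE: its uniform columns score 0 for
  # every base and its 10 sharp columns are two-valued, so the window
  # score increases strictly with the number of consensus matches at the
  # sharp positions and the exact null tail is Binomial(10, 1/4).
  cons <- "GGTCAAAATGACC"
  sharp <- c(1:5, 9:13)
  match_count <- function(word) {
    cb <- strsplit(cons, "")[[1]]; wb <- strsplit(word, "")[[1]]
    sum(wb[sharp] == cb[sharp])
  }
  max_matches <- function(seq) {
    best <- 0L
    for (p in 0:(nchar(seq) - 13)) {
      w <- substr(seq, p + 1, p + 13)
      best <- max(best, match_count(w), match_count(oracle_revcomp(w)))
    }
    best
  }
  # presence at p < 1e-4 needs >= 9 matches: P(X>=8) = 4.2e-4 > 1e-4,
  # P(X>=9) = 3.0e-5 < 1e-4
  expect_lt(1 - pbinom(8, 10, 0.25), 1e-4)
  expect_gt(1 - pbinom(7, 10, 0.25), 1e-4)
  # construct a 150 bp background verified motif-free by the oracle,
  # then plant the consensus
  bg <- NULL
  for (seed in 300:400) {
    cand <- random_dna(150, seed = seed)
    if (max_matches(cand) < 9L) { bg <- cand; break }
  }
  expect_false(motif_present(pwm, bg, 1e-4, np)$present)
  planted <- bg
  substr(planted, 61, 73) <- "GGTCAAAATGACC"
  res <- motif_present(pwm, planted, 1e-4, np)
  expect_true(res$present)
  expect_equal(res$best$position, 60L)
  # monotone in the threshold
  thresholds <- c(1e-12, 1e-8, 1e-4, 1e-2, 1)
  calls <- vapply(thresholds, function(t)
    motif_present(pwm, planted, t, np)$present, logical(1))
  expect_true(all(diff(calls) >= 0))
  # threshold 1: always present when a scorable window exists
  expect_true(motif_present(pwm, bg, 1, np)$present)
  expect_false(motif_present(pwm, "ACGT", 1, np)$present) # no window
})

test_that("central_enrichment matches closed-form binomial arithmetic", {
  # all hits at the exact center, fraction 0.2 -> ratio 5
  all_c <- central_enrichment(rep(75, 40), region_width = 150,
                              central_fraction = 0.2)
  expect_equal(all_c$ratio, 5)
  # n=10, 8 central, fraction 0.5 -> exact binomial tail
  off <- c(rep(75, 8), 1, 149)
  res <- central_enrichment(off, 150, central_fraction = 0.5)
  expect_equal(res$n_central, 8L)
  expect_equal(res$p_value, 0.0546875, tolerance = 1e-9)
  expect_true(is.na(central_enrichment(numeric(0), 150)$ratio))
})
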