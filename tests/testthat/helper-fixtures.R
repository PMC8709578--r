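# Fixture builders used across test files. Everything is generated in
# code under fixed seeds; no binary fixtures.

random_peak_set <- function(n, genome, seed, width = c(50, 300),
                            summit_prob = 0.5, prefix = "p") {
  withr::with_seed(seed, {
    ci <- sample.int(nrow(genome), n, replace = TRUE)
    w <- width[1] + floor(runif(n) * (width[2] - width[1] + 1))
    s <- floor(runif(n) * (genome$length[ci] - w + 1))
    so <- ifelse(runif(n) < summit_prob, floor(runif(n) * w), NA_real_)
    peak_records(genome$chrom[ci], s, s + w,
                 name = sprintf("%s_%03d", prefix, seq_len(n)),
                 summit_offset = so)
  })
}

random_tss_table <- function(m, genome, seed, prefix = "G") {
  withr::with_seed(seed, {
    ci <- sample.int(nrow(genome), m, replace = TRUE)
    tss_records(sprintf("%s%03d", prefix, sample(m)), genome$chrom[ci],
                sample(c("+", "-"), m, replace = TRUE),
                floor(runif(m) * genome$length[ci]))
  })
}

random_motif_counts <- function(seed, L = NULL, id = "M") {
  withr::with_seed(seed, {
    if (is.null(L)) L <- sample(4:10, 1)
    m <- matrix(floor(runif(4 * L) * 20), 4, L)
    m[cbind(sample(1:4, L, replace = TRUE), 1:L)] <- 20 # no dead column
    motif_counts(id, m)
  })
}

random_dna <- function(n, seed, gc = 0.5) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

toy_genome <- function() genome_spec(c("chr1", "chr2"), c(1e5, 5e4))

# A small simulation spec that keeps test runtimes low: 6 regions per
# mode plus 2 co-regulated pairs on a 4 x 1 Mb genome.
small_sim_spec <- function(seed = 7, ...) {
  simulation_spec(
    seed = seed,
    genome = genome_spec(paste0("chrS", 1:4), rep(1e6, 4)),
    n_canonical_er = 6L, n_canonical_hsf1 = 6L, n_cobinding = 6L,
    n_tether_hsf1_by_er = 6L, n_tether_er_by_hsf1 = 6L,
    n_indirect = 6L, n_decoy = 6L, n_coregulated_pairs = 2L, ...)
}

# Match manifest regions to pipeline evidence rows by exact interval.
match_manifest <- function(manifest, evidence) {
  key <- function(c, s, e) paste(c, s, e)
  match(key(manifest$chrom, manifest$start, manifest$end),
        key(evidence$chrom, evidence$start, evidence$end))
}

# Expected gene-level counts computed directly from a truth manifest.
manifest_summary <- function(manifest) {
  g <- function(modes) unique(manifest$gene_id[manifest$mode %in% modes])
  tether <- c("tethering_HSF1_by_ER", "tethering_ER_by_HSF1")
  list(canonical_coregulated =
         length(intersect(g("canonical_ER"), g("canonical_HSF1"))),
       cobinding = length(g("cobinding")),
       tethering = length(g(tether)),
       direct_cooperation = length(union(g("cobinding"), g(tether))))
}
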