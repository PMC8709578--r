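# Synthetic-data generator: genomes, TSS tables, peak sets with summits
# and negative-binomial tag counts, ChIA-PET-style anchor pairs and
# sequences with planted ERE/HSE sites, all reproducible from one seed
# and accompanied by a ground-truth manifest.
#
# Layout strategy: each planted region occupies one exclusive "slot" of
# slot_size bp, so overlap calls between regions are unambiguous by
# construction. Loop partner anchors are placed beyond the slot zone
# (loop_span >= zone length) so they never touch planted peaks; they
# surface in the pipeline as factor-free anchor regions and classify as
# unclassified, exactly as intended decoys.
#
# Planted-truth guarantees: each region's background window is
# rejection-sampled until neither motif has a chance hit at the presence
# threshold, and the cross-motif check after planting uses the unmutated
# consensus site. All clean-checks are therefore independent of the
# mutation rate, and mutation sets are nested across rates (one uniform
# draw per site position, thresholded by the rate), so classification
# accuracy is exactly 100% at rate 0 and non-increasing in the rate.

#' Toy ERE motif count matrix
#'
#' A 13-bp estrogen-response-element-like palindrome (GGTCAnnnTGACC)
#' with sharp counts at the 10 informative positions. Shipped for tests
#' and simulations; real analyses should supply JASPAR matrices.
#' @return a [motif_counts()] object with id `"ERE"`.
#' @export
toy_ere_counts <- function() {
  consensus <- strsplit("GGTCANNNTGACC", "")[[1]]
  m <- sapply(consensus, function(b) {
    if (b == "N") rep(5, 4) else ifelse(DNA_BASES4 == b, 20, 0)
  })
  motif_counts("ERE", m)
}

#' Toy HSE motif count matrix
#'
#' A 15-bp heat-shock-element-like array of inverted nGAAn units
#' (nGAAnnTTCnnGAAn) with sharp counts at the 9 informative positions.
#' @return a [motif_counts()] object with id `"HSE"`.
#' @export
toy_hse_counts <- function() {
  consensus <- strsplit("NGAANNTTCNNGAAN", "")[[1]]
  m <- sapply(consensus, function(b) {
    if (b == "N") rep(5, 4) else ifelse(DNA_BASES4 == b, 20, 0)
  })
  motif_counts("HSE", m)
}

#' Simulation specification
#'
#' The stated world of the generator: region counts per binding mode,
#' geometry of peaks, anchors and loops, motif planting, and the
#' negative-binomial tag model with a treatment enrichment factor.
#' Defaults are chosen once to mirror MACS-like TF ChIP-seq peaks
#' (widths 200-400 bp with summits), kb-scale ChIA-PET anchors with
#' long-range loops, and tag counts with mean 50 and dispersion 5.
#'
#' @param seed master seed; every stream derives from it.
#' @param genome a [genome_spec()]; default 4 synthetic chromosomes of
#'   1.2 Mb.
#' @param n_canonical_er,n_canonical_hsf1 peak-only regions with the
#'   factor's own motif.
#' @param n_cobinding anchored regions with both factors and both motifs.
#' @param n_tether_hsf1_by_er,n_tether_er_by_hsf1 anchored regions with
#'   both factors and only the ERE (resp. only the HSE).
#' @param n_indirect anchored regions with both factors and no motif.
#' @param n_decoy single-factor peaks without their motif (alternating
#'   ER/HSF1); classify as unclassified.
#' @param n_coregulated_pairs pairs of adjacent canonical-ER and
#'   canonical-HSF1 regions sharing one gene, to exercise gene-level
#'   canonical co-regulation.
#' @param peak_width,anchor_width `c(min, max)` bp.
#' @param loop_span `c(min, max)` bp between anchor midpoints; the
#'   minimum must reach beyond the slot zone (validated).
#' @param slot_size exclusive bp per region (default 25000).
#' @param zone_start first slot offset on each chromosome.
#' @param tss_offset `c(min, max)` bp from region center to its gene TSS.
#' @param motif_ere,motif_hse [motif_counts()] matrices to plant and call.
#' @param mutation_rate per-base mutation probability of planted sites.
#' @param background_gc genome GC fraction (default 0.41).
#' @param tag_mean,tag_dispersion negative-binomial mean and size of
#'   control-condition tags.
#' @param enrichment_factor multiplier on the treated mean for
#'   E2-responsive peaks (> 0).
#' @param fraction_responsive fraction of peaks that respond to
#'   treatment.
#' @param libsize nominal library size per condition.
#' @param p_threshold motif presence threshold used for the clean-check
#'   (should match the analysis threshold).
#' @return an object of class `sim_spec` (a validated list).
#' @export
simulation_spec <- function(seed = 1L,
                            genome = genome_spec(paste0("chrS", 1:4),
                                                 rep(1200000, 4)),
                            n_canonical_er = 10L, n_canonical_hsf1 = 10L,
                            n_cobinding = 10L,
                            n_tether_hsf1_by_er = 10L,
                            n_tether_er_by_hsf1 = 10L,
                            n_indirect = 10L, n_decoy = 10L,
                            n_coregulated_pairs = 5L,
                            peak_width = c(200, 400),
                            anchor_width = c(800, 1600),
                            loop_span = c(520000, 620000),
                            slot_size = 25000, zone_start = 10000,
                            tss_offset = c(1000, 10000),
                            motif_ere = toy_ere_counts(),
                            motif_hse = toy_hse_counts(),
                            mutation_rate = 0,
                            background_gc = 0.41,
                            tag_mean = 50, tag_dispersion = 5,
                            enrichment_factor = 4,
                            fraction_responsive = 0.5,
                            libsize = 1e6,
                            p_threshold = 1e-4) {
  counts <- c(n_canonical_er, n_canonical_hsf1, n_cobinding,
              n_tether_hsf1_by_er, n_tether_er_by_hsf1, n_indirect,
              n_decoy, n_coregulated_pairs)
  if (!all(vapply(counts, is_count, logical(1))))
    user_error("all region counts must be non-negative integers")
  if (mutation_rate < 0 || mutation_rate > 1)
    user_error("mutation_rate must be in [0, 1]")
  if (enrichment_factor <= 0) user_error("enrichment_factor must be > 0")
  if (fraction_responsive < 0 || fraction_responsive > 1)
    user_error("fraction_responsive must be in [0, 1]")
  if (tss_offset[2] >= slot_size / 2)
    user_error("tss_offset max must be < slot_size / 2 for unambiguous genes")
  spec <- list(seed = as.integer(seed), genome = genome,
               n_canonical_er = n_canonical_er,
               n_canonical_hsf1 = n_canonical_hsf1,
               n_cobinding = n_cobinding,
               n_tether_hsf1_by_er = n_tether_hsf1_by_er,
               n_tether_er_by_hsf1 = n_tether_er_by_hsf1,
               n_indirect = n_indirect, n_decoy = n_decoy,
               n_coregulated_pairs = n_coregulated_pairs,
               peak_width = peak_width, anchor_width = anchor_width,
               loop_span = loop_span, slot_size = slot_size,
               zone_start = zone_start, tss_offset = tss_offset,
               motif_ere = motif_ere, motif_hse = motif_hse,
               mutation_rate = mutation_rate,
               background_gc = background_gc,
               tag_mean = tag_mean, tag_dispersion = tag_dispersion,
               enrichment_factor = enrichment_factor,
               fraction_responsive = fraction_responsive,
               libsize = libsize, p_threshold = p_threshold)
  class(spec) <- "sim_spec"
  spec
}

# Sample one site sequence from the maximum-likelihood consensus,
# choosing uniformly among tied bases at degenerate positions.
sample_site <- function(count_sets) {
  vapply(count_sets, function(bases)
    if (length(bases) == 1L) bases else bases[sample.int(length(bases), 1L)],
    character(1))
}

runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

#' Generate a full synthetic dataset with ground truth
#'
#' Produces two peak sets (with summits and NB tag counts), anchor pairs
#' forming loops, a genome sequence with planted ERE/HSE sites, a TSS
#' table, per-condition tag counts, and a manifest recording every
#' planted region's mode, gene and motif positions. Fully reproducible
#' from `spec$seed`; placement, sequence and tag randomness flow through
#' named substreams so partial reruns are stable.
#'
#' @param spec a [simulation_spec()].
#' @return an object of class `tether_sim`: list with `spec`, `genome`,
#'   `genome_seq`, `er_peaks`, `hsf1_peaks`, `pairs`, `tss`, `tags`,
#'   `manifest`, `pwms`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  seeds <- derive_seeds(spec$seed, 3L, c("placement", "sequence", "tags"))

  modes_single <- c(rep("canonical_ER", spec$n_canonical_er),
                    rep("canonical_HSF1", spec$n_canonical_hsf1),
                    rep("cobinding", spec$n_cobinding),
                    rep("tethering_HSF1_by_ER", spec$n_tether_hsf1_by_er),
                    rep("tethering_ER_by_HSF1", spec$n_tether_er_by_hsf1),
                    rep("indirect", spec$n_indirect),
                    rep("decoy", spec$n_decoy))
  n_units <- length(modes_single) + 2L * spec$n_coregulated_pairs
  ng <- nrow(spec$genome)
  if (ng == 0L) user_error("genome spec is empty")

  if (n_units == 0L) {
    empty_peaks <- peak_records(character(0), numeric(0), numeric(0))
    return(structure(list(
      spec = spec, genome = spec$genome,
      genome_seq = setNames(character(0), character(0)),
      er_peaks = empty_peaks, hsf1_peaks = empty_peaks,
      pairs = anchor_pairs(character(0), numeric(0), numeric(0),
                           character(0), numeric(0), numeric(0)),
      tss = tss_records(character(0), character(0), character(0), numeric(0)),
      tags = data.frame(name = character(0), factor = character(0),
                        ctrl_tags = integer(0), treat_tags = integer(0),
                        responsive = logical(0)),
      manifest = data.frame(),
      pwms = list(ere = build_pwm(spec$motif_ere),
                  hse = build_pwm(spec$motif_hse))),
      class = "tether_sim"))
  }

  spc <- ceiling(n_units / ng)  # slots per chromosome
  zone_len <- spc * spec$slot_size
  needed <- spec$zone_start + zone_len + spec$loop_span[2] +
    spec$anchor_width[2] + 1000
  if (spec$loop_span[1] < zone_len)
    user_error(sprintf(
      "loop_span min (%d) must be >= slot zone length (%d) so loop partners clear the evidence zone",
      spec$loop_span[1], zone_len))
  if (any(spec$genome$length < needed))
    user_error(sprintf(
      "genome too small for %d regions: chromosomes must be >= %d bp",
      n_units, ceiling(needed)))

  # --- placement stream: slot assignment, geometry, genes, tags skeleton
  pl <- withr::with_seed(seeds[["placement"]], {
    slot_chrom <- rep(seq_len(ng), each = spc)[seq_len(n_units)]
    slot_idx <- (rep(seq_len(spc), times = ng) - 1L)[seq_len(n_units)]
    # co-regulated pairs need two adjacent slots on one chromosome; give
    # them the first pair-aligned slots, shuffle the singles on the rest
    pair_first <- integer(0)
    if (spec$n_coregulated_pairs > 0L) {
      cand <- which(slot_idx %% 2L == 0L &
                      slot_chrom == c(slot_chrom[-1], -1L) &
                      slot_idx + 1L == c(slot_idx[-1], -2L))
      pair_first <- cand[seq_len(spec$n_coregulated_pairs)]
    }
    pair_slots <- c(pair_first, pair_first + 1L)
    single_slots <- setdiff(seq_len(n_units), pair_slots)
    single_order <- sample(single_slots)

    regions <- data.frame(
      mode = character(n_units), chrom_i = slot_chrom, slot = slot_idx,
      coreg = logical(n_units), stringsAsFactors = FALSE)
    regions$mode[single_order] <- modes_single
    if (length(pair_first)) {
      regions$mode[pair_first] <- "canonical_ER"
      regions$mode[pair_first + 1L] <- "canonical_HSF1"
      regions$coreg[pair_slots] <- TRUE
    }
    n_decoy_seen <- 0L
    geom <- vector("list", n_units)
    for (i in seq_len(n_units)) {
      m <- regions$mode[i]
      centre <- spec$zone_start + regions$slot[i] * spec$slot_size +
        spec$slot_size %/% 2
      anchored <- m %in% c("cobinding", "tethering_HSF1_by_ER",
                           "tethering_ER_by_HSF1", "indirect")
      decoy_factor <- NA_character_
      if (m == "decoy") {
        n_decoy_seen <- n_decoy_seen + 1L
        decoy_factor <- if (n_decoy_seen %% 2L == 1L) "ER" else "HSF1"
      }
      has_er <- anchored || m == "canonical_ER" ||
        (m == "decoy" && decoy_factor == "ER")
      has_hs <- anchored || m == "canonical_HSF1" ||
        (m == "decoy" && decoy_factor == "HSF1")
      aw <- if (anchored) runif_int(1, spec$anchor_width[1], spec$anchor_width[2]) else NA
      span <- if (anchored) runif_int(1, spec$loop_span[1], spec$loop_span[2]) else NA
      pet <- if (anchored) runif_int(1, 1, 5) else NA
      mk_peak <- function() {
        pw <- runif_int(1, spec$peak_width[1], spec$peak_width[2])
        jit <- runif_int(1, -(pw %/% 4), pw %/% 4)
        sjit <- runif_int(1, -(pw %/% 8), pw %/% 8)
        c(pw = pw, jit = jit, sjit = sjit)
      }
      erp <- if (has_er) mk_peak() else NULL
      hsp <- if (has_hs) mk_peak() else NULL
      goff <- runif_int(1, spec$tss_offset[1], spec$tss_offset[2]) *
        sample(c(-1L, 1L), 1L)
      gstrand <- sample(c("+", "-"), 1L)
      geom[[i]] <- list(centre = centre, anchored = anchored, aw = aw,
                        span = span, pet = pet, er = erp, hs = hsp,
                        goff = goff, gstrand = gstrand,
                        decoy_factor = decoy_factor)
    }
    list(regions = regions, geom = geom)
  })
  regions <- pl$regions
  geom <- pl$geom
  chroms <- spec$genome$chrom

  # --- assemble intervals, peaks, anchors, genes
  er_rows <- list(); hs_rows <- list(); pair_rows <- list()
  man <- vector("list", n_units)
  gene_rows <- list()
  gene_n <- 0L
  for (i in seq_len(n_units)) {
    g <- geom[[i]]
    ch <- chroms[regions$chrom_i[i]]
    m <- regions$mode[i]
    if (g$anchored) {
      astart <- g$centre - g$aw %/% 2
      aend <- astart + g$aw
      rs <- astart; re <- aend
    }
    place_peak <- function(p) {
      base_mid <- if (g$anchored) floor((rs + re) / 2) else g$centre
      pc <- base_mid + p[["jit"]]
      ps <- pc - p[["pw"]] %/% 2
      summit <- base_mid + p[["sjit"]]
      c(start = ps, end = ps + p[["pw"]], summit = summit - ps)
    }
    if (!g$anchored) {
      # region interval is the (single) peak
      p <- if (!is.null(g$er)) g$er else g$hs
      ps <- g$centre - p[["pw"]] %/% 2
      rs <- ps; re <- ps + p[["pw"]]
    }
    erq <- NULL; hsq <- NULL
    if (!is.null(g$er)) {
      erq <- if (g$anchored) place_peak(g$er)
      else c(start = rs, end = re,
             summit = (re - rs) %/% 2 + g$er[["sjit"]])
      er_rows[[length(er_rows) + 1L]] <-
        data.frame(chrom = ch, start = erq[["start"]], end = erq[["end"]],
                   summit = erq[["summit"]], region = i)
    }
    if (!is.null(g$hs)) {
      hsq <- if (g$anchored) place_peak(g$hs)
      else c(start = rs, end = re,
             summit = (re - rs) %/% 2 + g$hs[["sjit"]])
      hs_rows[[length(hs_rows) + 1L]] <-
        data.frame(chrom = ch, start = hsq[["start"]], end = hsq[["end"]],
                   summit = hsq[["summit"]], region = i)
    }
    if (g$anchored) {
      pstart <- g$centre + g$span - g$aw %/% 2
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(chrom = ch, s1 = rs, e1 = re,
                   s2 = pstart, e2 = pstart + g$aw, pet = g$pet)
    }
    # gene: shared for co-regulated pairs (placed at the slot boundary)
    if (regions$coreg[i]) {
      if (regions$slot[i] %% 2L == 0L) { # first of the pair: create gene
        gene_n <- gene_n + 1L
        gpos <- spec$zone_start + (regions$slot[i] + 1L) * spec$slot_size
        gene_rows[[gene_n]] <- data.frame(
          gene_id = sprintf("G%04d", gene_n), chrom = ch,
          strand = g$gstrand, tss = gpos)
      }
      gid <- sprintf("G%04d", gene_n)
    } else {
      gene_n <- gene_n + 1L
      gid <- sprintf("G%04d", gene_n)
      gene_rows[[gene_n]] <- data.frame(
        gene_id = gid, chrom = ch, strand = g$gstrand,
        tss = g$centre + g$goff)
    }
    man[[i]] <- data.frame(
      sim_id = sprintf("sim_%04d", i), mode = m, chrom = ch,
      start = rs, end = re, anchored = g$anchored, gene_id = gid,
      er_peak = NA_character_, hsf1_peak = NA_character_,
      ere_offset = NA_integer_, ere_strand = NA_character_,
      hse_offset = NA_integer_, hse_strand = NA_character_,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, man)
  # decoys keep mode "unclassified" in the truth table
  manifest$mode[manifest$mode == "decoy"] <- "unclassified"

  er_df <- do.call(rbind, er_rows)
  hs_df <- do.call(rbind, hs_rows)
  er_peaks <- if (is.null(er_df)) peak_records(character(0), numeric(0), numeric(0)) else
    peak_records(er_df$chrom, er_df$start, er_df$end,
                 name = sprintf("er_%04d", seq_len(nrow(er_df))),
                 summit_offset = er_df$summit)
  hsf1_peaks <- if (is.null(hs_df)) peak_records(character(0), numeric(0), numeric(0)) else
    peak_records(hs_df$chrom, hs_df$start, hs_df$end,
                 name = sprintf("hsf1_%04d", seq_len(nrow(hs_df))),
                 summit_offset = hs_df$summit)
  if (!is.null(er_df)) manifest$er_peak[er_df$region] <- er_peaks$name
  if (!is.null(hs_df)) manifest$hsf1_peak[hs_df$region] <- hsf1_peaks$name
  pr <- do.call(rbind, pair_rows)
  pairs <- if (is.null(pr))
    anchor_pairs(character(0), numeric(0), numeric(0),
                 character(0), numeric(0), numeric(0))
  else anchor_pairs(pr$chrom, pr$s1, pr$e1, pr$chrom, pr$s2, pr$e2,
                    pet_count = pr$pet)
  tss <- do.call(rbind, gene_rows)
  tss <- tss_records(tss$gene_id, tss$chrom, tss$strand, tss$tss)

  # --- sequence stream: background genome, clean windows, planted sites
  pwm_ere <- build_pwm(spec$motif_ere)
  pwm_hse <- build_pwm(spec$motif_hse)
  np_ere <- null_pmf(pwm_ere)
  np_hse <- null_pmf(pwm_hse)
  gc <- spec$background_gc
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  genome_seq <- withr::with_seed(seeds[["sequence"]], {
    gs <- setNames(vapply(spec$genome$length, function(L)
      paste(sample(DNA_BASES4, L, replace = TRUE, prob = base_prob),
            collapse = ""), character(1)), chroms)
    clean_window <- function(w) {
      for (try in 1:200) {
        cand <- paste(sample(DNA_BASES4, w, replace = TRUE, prob = base_prob),
                      collapse = "")
        p1 <- scan_sequence(pwm_ere, cand, np_ere)$p_value
        p2 <- scan_sequence(pwm_hse, cand, np_hse)$p_value
        if (!any(c(p1, p2) < spec$p_threshold)) return(cand)
      }
      stop("internal error: could not generate a motif-free window")
    }
    ere_sets <- pwm_consensus(pwm_ere, collapse = FALSE)
    hse_sets <- pwm_consensus(pwm_hse, collapse = FALSE)
    for (i in seq_len(n_units)) {
      m <- manifest$mode[i]
      w <- manifest$end[i] - manifest$start[i]
      want_ere <- m %in% c("canonical_ER", "cobinding", "tethering_HSF1_by_ER")
      want_hse <- m %in% c("canonical_HSF1", "cobinding", "tethering_ER_by_HSF1")
      Le <- pwm_ere$length; Lh <- pwm_hse$length
      for (try in 1:200) {
        win <- clean_window(w)
        # plant consensus sites in the central half of the region; when
        # both motifs are planted the central window is split so the
        # sites cannot overlap
        ere_site <- hse_site <- NULL
        if (want_ere) {
          lo <- ceiling(w / 4)
          hi <- if (want_hse) floor(w / 2) - Le else floor(3 * w / 4) - Le
          off_e <- runif_int(1, lo, hi)
          str_e <- sample(c("+", "-"), 1L)
          site <- paste(sample_site(ere_sets), collapse = "")
          ere_site <- list(off = off_e, strand = str_e, seq = site)
        }
        if (want_hse) {
          lo <- if (want_ere) ceiling(w / 2) else ceiling(w / 4)
          hi <- floor(3 * w / 4) - Lh
          off_h <- runif_int(1, lo, hi)
          str_h <- sample(c("+", "-"), 1L)
          site <- paste(sample_site(hse_sets), collapse = "")
          hse_site <- list(off = off_h, strand = str_h, seq = site)
        }
        # mutation draws are made unconditionally so the RNG stream does
        # not depend on the rate; sets are nested across rates
        mut <- list()
        for (nm in c("ere", "hse")) {
          s <- if (nm == "ere") ere_site else hse_site
          if (is.null(s)) next
          L <- nchar(s$seq)
          u <- stats::runif(L)
          alts <- vapply(strsplit(s$seq, "")[[1]], function(b)
            sample(setdiff(DNA_BASES4, b), 1L), character(1),
            USE.NAMES = FALSE)
          mut[[nm]] <- list(u = u, alts = alts)
        }
        plant <- function(win, s) {
          ins <- if (s$strand == "+") s$seq else revcomp(s$seq)
          substr(win, s$off + 1L, s$off + nchar(ins)) <- ins
          win
        }
        win_cons <- win
        if (want_ere) win_cons <- plant(win_cons, ere_site)
        if (want_hse) win_cons <- plant(win_cons, hse_site)
        # validate the unmutated window: planted motifs must be called
        # present and the other motif absent (rate-independent check)
        ok_e <- motif_present(pwm_ere, win_cons, spec$p_threshold, np_ere)$present
        ok_h <- motif_present(pwm_hse, win_cons, spec$p_threshold, np_hse)$present
        if (ok_e == want_ere && ok_h == want_hse) {
          win_final <- win
          mutate_site <- function(s, mm) {
            b <- strsplit(s$seq, "")[[1]]
            hit <- mm$u < spec$mutation_rate
            b[hit] <- mm$alts[hit]
            s$seq <- paste(b, collapse = "")
            s
          }
          if (want_ere) {
            es <- mutate_site(ere_site, mut$ere)
            win_final <- plant(win_final, es)
            manifest$ere_offset[i] <- ere_site$off
            manifest$ere_strand[i] <- ere_site$strand
          }
          if (want_hse) {
            hs <- mutate_site(hse_site, mut$hse)
            win_final <- plant(win_final, hs)
            manifest$hse_offset[i] <- hse_site$off
            manifest$hse_strand[i] <- hse_site$strand
          }
          ch <- manifest$chrom[i]
          tmp <- gs[[ch]]
          substr(tmp, manifest$start[i] + 1L, manifest$end[i]) <- win_final
          gs[[ch]] <- tmp
          break
        }
        if (try == 200) stop("internal error: could not realize region flags")
      }
    }
    gs
  })

  # --- tag stream: NB counts per peak and condition
  all_names <- c(er_peaks$name, hsf1_peaks$name)
  n_pk <- length(all_names)
  tags <- withr::with_seed(seeds[["tags"]], {
    responsive <- stats::runif(n_pk) < spec$fraction_responsive
    ctrl <- stats::rnbinom(n_pk, mu = spec$tag_mean,
                           size = spec$tag_dispersion)
    mu_tr <- ifelse(responsive, spec$tag_mean * spec$enrichment_factor,
                    spec$tag_mean)
    treat <- stats::rnbinom(n_pk, mu = mu_tr, size = spec$tag_dispersion)
    data.frame(name = all_names,
               factor = rep(c("ER", "HSF1"),
                            c(nrow(er_peaks), nrow(hsf1_peaks))),
               ctrl_tags = ctrl, treat_tags = treat,
               responsive = responsive, stringsAsFactors = FALSE)
  })
  er_peaks$tags <- tags$treat_tags[match(er_peaks$name, tags$name)]
  hsf1_peaks$tags <- tags$treat_tags[match(hsf1_peaks$name, tags$name)]

  structure(list(spec = spec, genome = spec$genome,
                 genome_seq = genome_seq, er_peaks = er_peaks,
                 hsf1_peaks = hsf1_peaks, pairs = pairs, tss = tss,
                 tags = tags, manifest = manifest,
                 pwms = list(ere = pwm_ere, hse = pwm_hse)),
            class = "tether_sim")
}

#' Two independent peak sets for permutation-test calibration
#'
#' Peaks are placed independently and uniformly (chromosomes chosen with
#' probability proportional to length); no relationship is planted, so
#' the overlap permutation test applied to the result should be
#' calibrated.
#'
#' @param n_a,n_b set sizes (defaults 200/200).
#' @param peak_width `c(min, max)` bp.
#' @param genome a [genome_spec()]; default one 2 Mb chromosome.
#' @param seed integer seed.
#' @return list with peak `data.frame`s `a`, `b` and the `genome`.
#' @export
simulate_null_pair <- function(n_a = 200, n_b = 200,
                               peak_width = c(200, 400),
                               genome = genome_spec("chrN1", 2e6),
                               seed = 1) {
  if (nrow(genome) == 0L) user_error("genome spec is empty")
  withr::with_seed(as.integer(seed), {
    draw <- function(n, prefix) {
      ci <- sample.int(nrow(genome), n, replace = TRUE,
                       prob = genome$length)
      w <- runif_int(n, peak_width[1], peak_width[2])
      s <- floor(stats::runif(n) * (genome$length[ci] - w + 1))
      peak_records(genome$chrom[ci], s, s + w,
                   name = sprintf("%s_%04d", prefix, seq_len(n)))
    }
    list(a = draw(n_a, "a"), b = draw(n_b, "b"), genome = genome)
  })
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits `er_peaks.narrowPeak`, `hsf1_peaks.narrowPeak`, `anchors.bedpe`,
#' `genome.fa`, `regions.fa`, `tss.tsv`, `tags.tsv`, `manifest.tsv`,
#' `motifs.jaspar` and `spec.json`. Output is byte-identical across runs
#' with the same spec.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_peaks(sim$er_peaks, fp("er_peaks.narrowPeak"))
  write_peaks(sim$hsf1_peaks, fp("hsf1_peaks.narrowPeak"))
  write_anchor_pairs(sim$pairs, fp("anchors.bedpe"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome_seq),
                              fp("genome.fa"))
  if (nrow(sim$manifest)) {
    rseq <- extract_region_seqs(sim$genome_seq,
                                cbind(region_id = sim$manifest$sim_id,
                                      sim$manifest[, c("chrom", "start", "end")]))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(rseq),
                                fp("regions.fa"))
  }
  write_tss(sim$tss, fp("tss.tsv"))
  utils::write.table(sim$tags, fp("tags.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$manifest, fp("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_jaspar(list(sim$spec$motif_ere, sim$spec$motif_hse),
               fp("motifs.jaspar"))
  cfg <- sim$spec
  cfg$motif_ere <- unname(as.data.frame(cfg$motif_ere$counts))
  cfg$motif_hse <- unname(as.data.frame(cfg$motif_hse$counts))
  jsonlite::write_json(unclass(cfg), fp("spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
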