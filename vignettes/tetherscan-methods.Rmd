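---
title: "Methods: classifying cobinding and tethered transcription-factor binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying cobinding and tethered transcription-factor binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Two transcription factors — here estrogen receptor alpha (ERα) and the
heat-shock factor HSF1 — can co-regulate a gene in qualitatively
different ways. If each occupies a region containing its own sequence
motif, each binds DNA directly (*canonical* binding; a gene with
canonical regions of both factors is *canonically co-regulated*). If
both occupy one region containing both motifs, they *cobind*. If both
occupy one region containing only one motif, the factor lacking its
motif is most plausibly *tethered* to the DNA-bound factor through
protein–protein contact. Both factors with neither motif is recorded as
*indirect* and a single factor without its own motif is left
*unclassified*; neither of these two enters the three headline
categories, but both remain visible in the output for audit.

The package assembles the evidence for this decision from three sources:

1. **ChIP-seq peaks** for each factor (BED/narrowPeak; MACS-style
   summits honored when present).
2. **ChIA-PET anchors**: both intervals of every interaction are pooled
   and merged with `reduce` semantics (overlapping *and* book-ended
   ranges merge), yielding disjoint candidate loop-endpoint regions.
3. **Motif calls** from JASPAR count matrices for the estrogen response
   element (ERE) and heat shock element (HSE).

## Overlap conventions

Peak "position" is the summit when available and the floored midpoint
otherwise; all coordinates are 0-based half-open. Two rules are used,
deliberately kept distinct because they serve different purposes:

* **one-center** (permissive): peaks are *common* if at least one peak's
  center lies within the other. Used for genome-wide common-site counts
  and the overlap permutation test, where sensitivity matters.
* **each-center** (strict): each center must lie within the other
  region. Used to attach peaks to anchors and to pair ERα with HSF1
  peaks during classification, where a false cobinding call is costlier
  than a miss.

The classification methods use the each-center rule throughout. Whether
peak-only (non-anchor) ERα/HSF1 pairing should instead use the
permissive rule is genuinely open; we default to the strict rule for
consistency with the anchor convention and expose
`overlap_rule = "one"` as a switch.

Factors occupying the two *different* anchors of one interaction may
also cooperate through the loop itself. Because it is ambiguous whether
such pairs belong in the tethering category, they are reported as a
separate `loop_pairs` table and never folded into tethering.

## Motif model

A PWM is built from counts `c_ij` as
`log2((c_ij + p * b_j) / (sum_i c_ij + p) / b_j)` — a total pseudocount
`p` (default 1) distributed by the background `b` (MEME's convention),
avoiding infinite scores. The background defaults to uniform 0.25; an
empirical mononucleotide background can be supplied.

Scanning scores every window on both strands in bits; windows containing
`N` are skipped rather than background-scored, which makes presence
calls conservative. Per-window p-values come from the exact null
distribution of the score under i.i.d. background positions, computed by
convolving per-position score distributions on a discrete grid. The
nominal resolution is 0.01 bits; internally the grid step is
`bin_width / (L + 1)` so the rounding error accumulated over `L`
positions stays below one nominal bin — the tests verify agreement with
exhaustive 4^L enumeration at that tolerance.

A motif is *present* when the best window's p-value is below the
threshold. The default threshold is 1e-4 per window, the conventional
MAST hit threshold; the original analysis does not print its cutoff, so
the value is a configuration knob (`p_threshold`) rather than a claim.
Motif calls are made on the full region interval (anchor or peak); the
150-bp summit-centered window convention is reserved for the
central-enrichment statistic, mirroring how motif-discovery QC is
usually separated from classification. With `p_threshold = 1`, presence
degenerates to "any scorable window exists", which the code handles
explicitly since every p-value is ≤ 1.

The central-enrichment statistic is a deliberately simplified stand-in
for CentriMo: given best-hit midpoints in fixed-width regions, it
reports the ratio of the observed central-window fraction to the
expected fraction and a one-sided exact binomial p-value. It answers
"are hits concentrated at region centers?" without CentriMo's
multi-motif machinery.

## Gene aggregation

Each classified region is assigned to the gene minimizing the distance
between the region midpoint and the TSS on the same chromosome.
Distances are signed by gene strand (negative upstream). Exact ties are
broken by lexicographically smaller gene id — an arbitrary but
deterministic rule. The region *midpoint* (not the summit) is used here:
annotation tools conventionally use the peak center, and anchors have no
summit, so one uniform rule is preferable. Gene-level counts then
follow: a gene may carry several modes, and "direct cooperation" is the
union (not the sum) of cobinding and tethering gene sets.

## Peak statistics

Fold enrichment between conditions is computed on tag counts normalized
to counts per million, with a 1-CPM pseudocount guarding empty control
regions — the peak-level analog of coverage-track comparison at
1-million-read scaling. It is an analog, not a re-implementation: no
claim of equivalence with read-level coverage ratios is made.

The overlap permutation test repositions the second peak set uniformly
on its own chromosomes, preserving lengths and summit offsets. This is
simpler than pool-based resampling schemes used by some published tools
(whose parameterization the original analysis does not state) and has a
transparent, well-calibrated null. The add-one estimator
`p = (1 + #{perm ≥ obs}) / (1 + n_perm)` never returns 0 and is mildly
conservative when the overlap distribution is discrete; calibration
tests bound the deviation (over 200 independent null datasets the
fraction of p ≤ 0.05 must fall inside the exact binomial 95% band).

# The synthetic-data generator

The generator's defaults are the package's stated world, fixed once:

| parameter | default | rationale |
|---|---|---|
| genome | 4 chromosomes × 1.2 Mb | smallest size accommodating the slot layout below |
| regions per mode | 10 (plus 5 gene-sharing canonical pairs, 10 decoys) | desk-scale but non-trivial counts per branch |
| peak width | U[200, 400] bp | typical MACS TF peak widths |
| anchor width | U[800, 1600] bp | typical ChIA-PET anchor scale |
| loop span | U[520, 620] kb | lower bound forced by the unambiguity constraint (below); within the 10 kb–1 Mb range of published ERα loops |
| TSS offset | U[1, 10] kb from region center | promoter-proximal to distal-regulatory distances |
| tag model | NB(mean 50, dispersion 5) | overdispersed counts at realistic per-peak depth |
| treatment enrichment | ×4 on 50% of peaks | strong but not saturating induction |
| GC fraction | 0.41 | human genome-wide GC |
| site mutation rate | 0 | exact planted truth by default |

**Unambiguity by construction.** Each region occupies an exclusive
25-kb slot, so no overlap call can cross regions. Loop partner anchors
must land beyond every slot, hence the loop-span lower bound equals the
slot-zone length; partner anchors surface as factor-free regions and
classify as unclassified, serving as built-in negative controls.
Planted genes sit within their region's slot, so nearest-TSS assignment
is unambiguous; gene-sharing canonical pairs place one gene exactly on
the boundary between two adjacent slots.

**Exact planted truth.** Region background windows are rejection-sampled
until neither PWM scores a window below the presence threshold, then
consensus sites (degenerate positions sampled uniformly among tied
bases, strand random) are inserted in the central half — split into
halves when both motifs are planted so sites cannot overlap. The
post-planting validity check runs on the *unmutated* window, so it does
not depend on the mutation rate; mutations are then applied using one
uniform draw per site position thresholded by the rate, with the
alternative base drawn independently of the rate. Consequently mutation
sets are nested across rates: classification accuracy is exactly 100%
at rate 0 and non-increasing as the rate grows, which the tests check
at rates 0–0.3.

**What a green test does and does not establish.** The generator
emulates the statistical structure the analysis assumes — isolated
peaks with summits, disjoint anchors, motif-bearing or motif-free
regions, overdispersed tags — but not real chromatin: no nucleosome
periodicity, mappability artifacts, peak clustering, shared anchors
between loops, copy-number effects or motif self-overlap. A green
planted-truth test establishes that the pipeline's logic is faithful to
its own definitions, not that those definitions recover biological
truth in noisy data.

# Numerical and degenerate-input choices

* Quantiles are linear-interpolation (R type 7) throughout.
* `nearest_tss` returns an `NA` sentinel for regions on chromosomes
  without any TSS; aggregation drops such regions with a warning.
* `central_enrichment` with zero hits returns an `NA` ratio rather than
  erroring.
* Sequences shorter than the motif scan to an empty hit table, not an
  error.
* narrowPeak column 10 values of −1 mean "no summit"; values at or
  above the peak start are treated as absolute 0-based summit
  coordinates and converted to offsets (some MACS dialects emit
  absolute positions). The 0-based reading of the absolute value is a
  choice; both dialects we have seen in the wild are covered by the
  `value ≥ start` detection rule.
* Chromosome names are never normalized; silently mapping "1" to
  "chr1" corrupts overlap analyses, so mismatches simply produce empty
  overlaps (and an explicit error when a region's chromosome is missing
  from the genome FASTA).
* All randomness flows from one seed through named substreams
  (placement, sequence, tags; permutation substreams for the overlap
  test), so identical seeds give byte-identical outputs and partial
  reruns are stable.

# Known limitations

* Gene counts on real cell-line data depend entirely on the peak calls,
  loop calls and motif matrices supplied; this package ships the
  machinery, toy motifs and synthetic fixtures, not any experimental
  dataset.
* The permutation null ignores chromatin accessibility: uniform
  placement overstates the available genome and therefore tends to
  overstate significance on real data; restricting the genome spec to
  accessible regions is the available mitigation.
* MAST-style presence uses the best single window; no E-value
  combination across windows or regions is attempted.
* Tethering is called from co-occupancy plus motif absence; it is a
  hypothesis about mechanism, not proof of protein–protein contact.
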