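# tetherscan

Estrogen receptor alpha (ERα) and HSF1 both bind chromatin in breast
cancer cells, but they cooperate in more than one way: each factor can
bind its own DNA motif (canonical binding), both can occupy one region
that carries both motifs (cobinding), or both can occupy a region that
carries only one motif — the motif-less factor being *tethered* through
protein–protein contact. `tetherscan` is an R package for telling these
modes apart from standard inputs: two transcription-factor ChIP-seq peak
sets, ChIA-PET interaction anchors, a genome FASTA, JASPAR motif
matrices and a gene TSS table.

It is aimed at regulatory genomicists who have peak calls and loop calls
in hand and want a reproducible, tested classification of co-regulated
genes, together with the peak-level statistics that usually accompany
such an analysis.

## What it computes

**Region evidence.** ChIA-PET anchors are merged with GenomicRanges-style
`reduce` semantics. A factor occupies an anchor when the peak center
falls inside the anchor *and* the anchor midpoint falls inside the peak
(the strict "each-center" rule). Peaks unattached to anchors are paired
across factors by the same rule (a permissive "one-center" rule — at
least one center inside the other peak — is available as a switch).

**Motif presence.** ERE and HSE position weight matrices are built from
JASPAR counts with a background-weighted pseudocount; every region
sequence is scanned on both strands with log-odds scores in bits, and
per-window p-values come from the *exact* null score distribution
(convolution over positions, discretized so the total rounding error is
below one 0.01-bit bin). A motif is present when the best window beats a
MAST-style threshold (default p < 1e-4).

**The decision table.** With er/hsf1 occupancy and ere/hse presence in
hand, each region gets exactly one mode:

| er | hsf1 | ere | hse | mode |
|----|------|-----|-----|------|
| +  | +    | +   | +   | cobinding |
| +  | +    | +   | −   | tethering_HSF1_by_ER |
| +  | +    | −   | +   | tethering_ER_by_HSF1 |
| +  | +    | −   | −   | indirect |
| +  | −    | +   | ·   | canonical_ER |
| −  | +    | ·   | +   | canonical_HSF1 |
| otherwise |  |  |  | unclassified |

Regions are assigned to the nearest gene TSS (signed distance, ties by
lexicographic gene id) and summarized at gene level: canonically
co-regulated genes (≥ 1 canonical region of each factor), cobinding
genes, tethering genes, and their union ("direct cooperation").

**Peak statistics.** Tags-per-peak quartiles, treatment-vs-control fold
enrichment on counts normalized to 1 million reads
(`(treat_cpm + c) / (ctrl_cpm + c)`), and a chromosome- and
length-preserving permutation test for peak-set overlap with the add-one
estimator `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`.

**Synthetic data.** `simulate_dataset()` generates a genome, TSS table,
peak sets with summits and negative-binomial tag counts, anchor pairs
and planted ERE/HSE sites with a ground-truth manifest, so the whole
pipeline is verifiable without downloads. Background windows are
rejection-sampled to be motif-free, making planted truth exact.

## Worked example

```r
library(tetherscan)

spec <- simulation_spec(seed = 7)      # 80 planted regions, 4 x 1.2 Mb genome
sim  <- simulate_dataset(spec)
res  <- classify_pipeline(sim$er_peaks, sim$hsf1_peaks, sim$pairs,
                          sim$genome_seq, sim$pwms$ere, sim$pwms$hse,
                          sim$tss)
res$summary$counts
#>          canonical_ER        canonical_HSF1 canonical_coregulated
#>                    15                    15                     5
#>             cobinding             tethering    direct_cooperation
#>                    10                    20                    30
#>              indirect
#>                    10
```

The counts say: 15 genes carry a canonical ERα region and 15 a canonical
HSF1 region, 5 genes carry both (canonical co-regulation); 10 genes have
a cobinding region and 20 a tethering region, and since none coincide
here, 30 genes in total show direct cooperation. This matches the
generator's manifest exactly (the planted world is 10 regions per mode,
with 5 gene-sharing canonical pairs).

```r
summarize_peaks(sim$er_peaks)
#> Peak set: 60 peaks
#>   tags/peak:  min=26 q25=55.75 median=123.5 q75=220.5 max=499 mean=142.467
#>   width bp :  min=200 q25=259.5 median=306.5 q75=356 max=398

fold_enrichment(200, 100, 1e6, 1e6)   # 200 vs 100 tags at equal library size
#> [1] 1.990099

np <- simulate_null_pair(seed = 1)    # two unrelated 200-peak sets
overlap_permutation_test(np$a, np$b, np$genome, n_perm = 99, seed = 2)
#> Peak overlap permutation test
#>   observed: 9 common A-peaks
#>   permutations: 99 (mean 6.28, max 12)
#>   p-value: 0.24
```

Nine of the 200 A-peaks overlap a B-peak by chance; the permutation
null puts that well inside the expected range (p = 0.24), as it should
for independently placed sets.

## Command line

```sh
Rscript inst/scripts/tetherscan.R simulate --seed 7 --out-dir sim/
Rscript inst/scripts/tetherscan.R classify \
    --er sim/er_peaks.narrowPeak --hsf1 sim/hsf1_peaks.narrowPeak \
    --anchors sim/anchors.bedpe --genome-fasta sim/genome.fa \
    --tss sim/tss.tsv --pwm sim/motifs.jaspar --out-dir out/
Rscript inst/scripts/tetherscan.R permtest --a a.narrowPeak --b b.narrowPeak \
    --genome genome.tsv --n-perm 999 --seed 1 --out-dir pt/
```

Each run writes its resolved `config.json` and a checksummed
`run_log.txt` next to the outputs; identical inputs and seeds give
byte-identical output trees. Exit codes: 0 success, 1 user error, 2
internal error.

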