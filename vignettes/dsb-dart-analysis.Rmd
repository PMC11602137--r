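---
title: "Strand-resolved nascent RNA analysis around sequence-specific DSBs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved nascent RNA analysis around sequence-specific DSBs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbdart)
```

## The analysis problem

Cells transcribe short, unstable RNAs at DNA double-strand breaks
(damage-associated RNA transcripts, DARTs). In restriction-enzyme systems
such as AsiSI-ER (DIvA), a defined set of genomic sites is cut on
induction, so nascent transcription can be quantified in a
break-anchored, strand-resolved way: chromatin-associated RNA-seq
(chrRNA-seq) reads are split by transcript strand, converted to
per-nucleotide CPM coverage, and laid out in a sites-by-positions matrix
around each break. Because a DART is only interpretable relative to the
local gene — *sense* transcription runs with the neighbouring gene,
*antisense* against it — each matrix bin is annotated by the orientation
of the gene region it falls in. Break sites are further stratified by
how efficiently they are cut (DSB-capture read counts), which repair
pathway they favour (RAD51 vs XRCC4 occupancy), and how actively the
surrounding region is transcribed. Group differences between conditions
are summarised as windowed log2 fold changes and tested with the
two-sample Wilcoxon (Mann–Whitney) rank-sum test.

`dsbdart` implements this pipeline end to end at desk scale, together
with a synthetic-data generator whose planted ground truth makes every
stage testable without external downloads.

## Coordinates and containers

All coordinates are BED-style 0-based half-open throughout; GTF input is
converted on read. Chromosome names are never normalised — a preflight
check (`check_chrom_names()`) surfaces name-set disagreement instead.
A break-site interval wider than one base (for instance the 8-bp
recognition motif `GCGATCGC`, its own reverse complement) is anchored at
`floor((start + end) / 2)`; the midpoint is the only symmetric choice
when no cut base is specified.

The central container is the `flank_matrix`: sites × bins of mean
per-base CPM over `[anchor − flank, anchor + flank)`, left-to-right in
genomic coordinates (sites are unstranded anchors; orientation enters
later through genes, not through site strand). The reference geometry is
a 2.5 kb flank at 1 bp bins — 5000 columns. Bins hold the *mean*
per-base CPM rather than the sum, so values remain comparable across bin
sizes; at bin size 1 the distinction vanishes.

## From alignments to stranded CPM coverage

`assign_transcript_strand()` maps alignment strand to transcript strand.
The default is the `reverse` (dUTP-type) contract of TruSeq-stranded
libraries: a single-end alignment on `+` encodes a `−` transcript and
vice versa; for paired-end input mate 1 is inverted and mate 2 preserved.
`forward` is the identity. The protocol is a required, logged setting.

`cpm_coverage()` assigns position *p* on strand *s* the value
(number of strand-*s* reads covering *p*) × 10⁶ / library size. Coverage
counts full read spans — no fragment extension and no splice-aware gap
handling in the BED path — which is the simplest contract consistent
with per-nucleotide CPM; spliced reads should be pre-split upstream if
exonic resolution matters. CPM is invariant under duplicating the read
multiset, which the tests exercise directly against a nested-loop pileup
oracle.

## Sense/antisense annotation

For each site, gene regions intersecting the flank window are converted
to bin ranges (`find_gene_flank_overlaps()`; a partially covered bin
counts as covered, a non-question at 1 bp bins). Then, per gene region:
plus-matrix values are sense where the gene is `+` and antisense where
it is `−`, and symmetrically for the minus matrix. Contributions from
multiple gene regions at one site are summed — for antisense and, by the
same procedure, for sense. Bins outside every gene region are zero in
both outputs, and sites with no gene overlap anywhere in the flank are
removed and reported (`excluded_sites`), since their reads cannot be
classified.

Two deliberate choices deserve emphasis:

* **Same-strand gene regions are merged per site before summation.**
  Nested or overlapping same-strand records (isoforms) would otherwise
  double-count the same coverage.
* **A bin inside two genes of opposite strands contributes to both
  matrices** (per-gene annotation, then summation). This breaks the
  simple conservation `sense + antisense = plus + minus`; the
  single-cover conservation property is asserted in tests only where
  every bin overlaps at most one gene.

These rules give clean algebraic invariants — flipping every gene strand
swaps the two matrices exactly; gene input order never matters; adding a
gene never decreases a bin — all verified against a brute-force
site × bin × gene oracle on randomized instances.

## Site stratification

* **Cleavage efficiency**: raw DSB-capture (BLESS-type) read counts in
  `anchor ± 500 bp`, ranked ascending; raw counts, not CPM, because the
  capture assay is quantified by counting reads. Ties break by site id
  (stable). Heatmaps order rows by this ranking.
* **Repair pathway**: `pathway_ratio` = summed RAD51 coverage in
  `± 4 kb` over summed XRCC4 coverage in `± 1 kb`; the top 30 ratios are
  labelled HR-prone and the bottom 30 NHEJ-prone by default. The ratio
  of summed window coverages is this package's fixed interpretation of a
  correlation-ratio classification whose original formula is not
  restated in the source material; it is exposed as such, with windows
  and `k` configurable. A zero denominator sorts as +∞ (strong HR
  evidence, no NHEJ signal).
* **Transcription activity**: per-site total sense CPM across the flank
  in the *undamaged* condition (pre-existing transcription is the
  quantity of interest; post-damage signal would be confounded by the
  DARTs themselves). Terciles by default (`quantile = 1/3`): top third
  high, bottom third low.

## Statistics

**Windowed fold changes.** The box-plot quantity is the per-site sum of
bin values in a signed window relative to the anchor. Width and centre
are explicit parameters (default: 500 bp centred on the break; offsets
of 1, 2, 3 kb give the distance-resolved variant) because the source
descriptions oscillate between "500 bins centred around the DSB" and
"± 500 bp" — the parameterization surfaces the ambiguity rather than
hiding it, and every output records the window used. Fold changes are
`log2((W_cond + c)/(W_ctrl + c))` with pseudocount `c = 0.01` CPM;
sites with zero coverage in both conditions are flagged and excluded
from downstream tests rather than reported as 0.

**Rank-sum test.** `rank_sum_test()` computes the Mann–Whitney U via
midranks. With `n + m ≤ 12` and no ties the p-value is exact by full
enumeration of all label assignments; otherwise a normal approximation
with tie-corrected variance and continuity correction is used, matching
the conventional implementation (and cross-checked against
`stats::wilcox.test` in the tests, which is never the implementation).
The threshold 12 keeps enumeration below `C(12,6) = 924` assignments.
One honest numerical note: at `n = m = 6` the worst-case gap between the
exact and approximated two-sided p-value is 0.0155 (at |U − nm/2| around
1.5 SD); this is a property of the continuity-corrected normal
approximation itself, not of this implementation.

**Replicate PCA.** Samples are observations, per-site coverage in the
5 kb window (`anchor ± 2.5 kb`) the features. Features are centred but
not scaled — coverage features share units (CPM), so variance scaling
would only amplify noise from low-coverage sites. Constant features are
dropped with a warning; component signs are fixed by making the
largest-magnitude loading positive, giving reproducible coordinates.

**qPCR enrichment** uses the standard `2^(−ΔΔCt)` arithmetic.

## The synthetic-data generator

`sim_config()` defines the reference experiment; `generate_annotation()`
lays out the genome and plants per-site truth; `simulate_chrRNA()` emits
one stranded library per condition × replicate; `simulate_track()` emits
DSB-capture and repair-factor tracks. Identical config + seed reproduce
every byte.

The generative model, and why its defaults look the way they do:

* **Genome**: 6 chromosomes × 2 Mb. 1000 regular genes (2–5 kb,
  random strand, non-overlapping) plus 150 highly expressed genes. The
  high-expression class supplies most of the library — as a handful of
  loci do in real chromatin RNA libraries — so that damage-induced reads
  stay a small fraction of the total. This matters quantitatively: CPM
  normalisation divides by library size, so if induced reads were a
  large library fraction, the knockdown condition's global CPM scale
  would shift and bias every fold change; with the defaults the shift is
  about log2(1.02).
* **Transcription**: regular genes emit sense reads at 30 reads/kb per
  library and antisense background at half that rate. The substantial
  antisense rate reflects the unstable antisense and promoter-divergent
  transcription retained in the chromatin fraction, and it is what makes
  the uncut-site antisense fold change a well-defined (finite-count)
  null quantity. A weak unstructured background of 1 read/kb/strand
  covers intergenic space.
* **Sites**: 100 cut and 100 uncut sites, each inside a distinct regular
  gene and at least 500 bp from its ends (so the default ± 250 bp
  analysis window sits fully inside the host gene), plus 3 deliberately
  gene-free sites that exercise the exclusion rule end to end. Cut sites
  carry cleavage efficiencies `e ~ U(0.3, 1)`.
* **Damage induction**: each cut site adds reads on both strands with
  per-position expectation `e · A · exp(−|d| / L)`; `A = 0.5` reads/bp
  at the anchor and `L = 500 bp` concentrate the signal in the ± 500 bp
  analysis window while keeping a visible 2.5 kb tail. Induction is
  symmetric about the anchor and present on both strands (bidirectional
  DARTs); the knockdown condition multiplies the host-gene-strand
  induction by κ_sense = 1.3 and the opposite strand by κ_antisense = 2,
  i.e. the knockdown amplifies antisense transcription preferentially.
  With these rates the expected antisense fold change at cut sites is
  close to log2 κ_antisense (the antisense window is dominated by
  induced signal), while the sense fold change sits below
  log2 κ_sense · (induced fraction) because pre-existing sense
  transcription dilutes it — the same asymmetry argued for the real
  system, where sense RNA is partly pre-synthesised.
* **Counts**: Poisson by default, for analytic tractability of the
  recovery checks; negative binomial (`dispersion = "nb"`) is available
  for overdispersion studies, and `dispersion = "none"` emits rounded
  expectations with evenly spaced reads for noise-free order-recovery
  tests.
* **Replicates**: 3 per condition; fold changes are computed on
  replicate-averaged matrices, which is what stabilises the small-count
  antisense windows at uncut sites.

What the generator does **not** emulate: spliced alignments and CIGAR
structure, mappability and GC biases, fragment-length distributions,
replication timing, resection-dependent asymmetries, or a realistic
isoform-level annotation. Passing tests therefore demonstrate the
correctness of the analysis logic and the recoverability of planted
effects under idealised noise — not robustness to every artefact of real
sequencing data.

## Problem sizes and numerical choices

The test suite validates operations against brute-force oracles on small
random instances (coverage: ≤ 1 kb and ≤ 100 reads; orientation: ≤ 10
sites, ≤ 20 genes, flank ≤ 200 bp, 200 instances) and runs the
reference-scale experiment (203 sites, 6 libraries of ≈ 3.3 M reads)
once for the recovery checks; the whole suite completes in about a
minute on one CPU. Null calibration of the rank-sum test uses 10,000
simulated pairs at n = m = 30. The pipeline writes all numeric tables at
full (17 significant digit) precision so that re-runs are bytewise
comparable; the manifest records an MD5 digest of every output file.

## Known limitations

* The BED read path counts full spans; spliced RNA-seq alignments need
  upstream splitting (the SAM adapter contract counts aligned blocks,
  and BED12 block structure is not interpreted).
* The pathway classifier is a fixed-window coverage-ratio heuristic; it
  does not model peak shape or local background.
* Orientation assignment is gene-level, not isoform-level, and
  intergenic DARTs (no gene in the flank) are excluded rather than
  classified.
* Figures are rendering artifacts; all quantitative claims live in (and
  are tested on) the underlying tables.
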