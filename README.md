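# dsbdart

Strand-resolved analysis of nascent (chromatin-associated) RNA around
sequence-specific DNA double-strand breaks.

## What problem this solves, and for whom

In AsiSI-ER ("DIvA") cells, adding 4-OHT drives a restriction enzyme
into the nucleus where it cuts a defined set of genomic sites
(recognition motif 5'-GCGATCGC-3'). Around these double-strand breaks
(DSBs), cells transcribe short unstable RNAs — damage-associated RNA
transcripts (DARTs) — in both directions. Quantifying them requires a
break-anchored, strand-aware pipeline: whether a read is *sense* or
*antisense* is defined relative to the orientation of the neighbouring
gene, not relative to the genome.

`dsbdart` is for computational biologists analysing stranded
chrRNA-seq (or similar nascent RNA) data around defined break sites. It
provides, as tested R functions:

* transcript-strand assignment for stranded protocols (dUTP-type
  `reverse` default, paired-end aware);
* per-nucleotide CPM coverage, `CPM(p, s) = n_reads(p, s) · 10^6 / N`,
  and DSB-anchored flank matrices (default 2.5 kb flanks, 1 bp bins →
  5000 columns);
* the sense/antisense bin annotation: within each site's flank, bins
  inside a `+` gene take the plus-strand matrix as sense and the
  minus-strand matrix as antisense (and symmetrically for `-` genes);
  per-gene contributions are summed per site, bins outside genes are
  dropped, and sites with no gene in the flank are excluded and
  reported;
* site stratification: cleavage-efficiency ranking by DSB-capture read
  counts in ±500 bp; HR/NHEJ-propensity labels from the ratio
  Σ RAD51(±4 kb) / Σ XRCC4(±1 kb) (top/bottom 30 by default);
  transcription-activity terciles from baseline sense coverage; exact
  motif scanning;
* statistics: metagene profiles, windowed coverage sums, per-site
  `log2((W_cond + c)/(W_ctrl + c))` fold changes, an authored
  Mann–Whitney rank-sum test (exact by enumeration for `n + m ≤ 12`
  tie-free, tie-corrected normal approximation with continuity
  correction otherwise), replicate PCA, and 2^(−ΔΔCt) qPCR enrichment;
* figures: metagene line plots with independent sense/antisense scales,
  heatmaps ordered by ascending cleavage efficiency, per-site fill
  plots, fold-change box plots, PCA scatter;
* a synthetic-data generator (`sim_config()`, `generate_annotation()`,
  `simulate_chrRNA()`, `simulate_track()`) that plants cleavage
  efficiencies, bidirectional exponentially decaying damage induction
  (`e · A · exp(−|d|/L)`), condition multipliers (κ_sense, κ_antisense)
  and pathway labels, and records them in a truth table — so the whole
  pipeline is testable offline.

Genome-scale inputs (real BAM/bigWig against hg19) are deliberately out
of scope at desk scale; the package consumes aligned reads as
BED6/intervals and is validated on synthetic data with planted ground
truth.

## Worked example

A complete synthetic experiment, small enough to run in seconds:

```r
library(dsbdart)

cfg <- sim_config(n_chromosomes = 2, chromosome_length = 3e5,
                  n_genes = 40, n_highexpr_genes = 4, lambda_high = 500,
                  n_cut_sites = 8, n_uncut_sites = 8,
                  n_gene_free_sites = 2, replicates = 2)
res <- run_pipeline(cfg, outdir = "dart_demo", seed = 7)
#> [dsbdart] stage annotation: generating synthetic annotation (seed 7)
#> [dsbdart] stage coverage: 3 condition(s) x 2 replicate(s)
#> [dsbdart] stage orientation: sense/antisense annotation
#> [dsbdart] excluded 2 site(s) with no gene overlap in the flank: site_008, site_018
#> [dsbdart] stage stratification
#> [dsbdart] stage statistics
#> [dsbdart] stage figures

head(res$site_table[, c("site_id", "cleavage_reads", "efficiency_rank",
                        "transcription_class", "cut_status")], 4)
#>    site_id cleavage_reads efficiency_rank transcription_class cut_status
#> 1 site_001              0               1          unlabelled      uncut
#> 2 site_002              0               2                 low      uncut
#> 3 site_003              0               3                high      uncut
#> 4 site_004              0               4                 low      uncut

sapply(res$fc_tables, function(t)
  median(t$log2fc[!t$zero_both & t$cut_status == "cut"]))
#>     sense antisense
#> 0.1034819 0.6494084

res$tests$sense_vs_antisense_cut
#> rank-sum test (two.sided): U = 64 (n = 8, m = 8), p = 0.0009391 [normal-approximation]
```

Reading the output: the two deliberately gene-free sites were excluded
from sense/antisense classification (their reads cannot be oriented);
uncut sites collect zero DSB-capture reads and hold the lowest
efficiency ranks; and knockdown-vs-control fold changes at cut sites are
positive in both orientations but clearly larger antisense — the planted
preferential antisense amplification — with the rank-sum test rejecting
equality of the two fold-change distributions. At this toy scale the
medians are noisy and diluted by background; the reference-scale
configuration (`sim_config()` defaults: 100 cut + 100 uncut sites,
3 replicates) recovers the planted multipliers much more tightly, as the
acceptance script shows. The output tree (`dart_demo/`) contains the
annotation + truth file, sense/antisense matrix TSVs per condition, the
site table, fold-change and test tables, figures, and a `manifest.json`
with an MD5 digest of every file; rerunning with the same config and
seed reproduces the digests exactly.

A thin command-line wrapper for the simulator and pipeline ships at
`inst/scripts/dsbdart.R` (`simulate` and `run` subcommands).

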