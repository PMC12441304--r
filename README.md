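# anchorfuse

Targeted long-read gene fusion detection for kinase-activated leukemia
panels.

## The problem

Ph-like (Philadelphia chromosome–like) B-cell acute lymphoblastic leukemia
is driven by a diverse set of kinase and cytokine-receptor fusions — the
ABL class (*ABL1*, *ABL2*, *CSF1R*, *PDGFRB*) and the JAK/STAT class
(*JAK2*, *EPOR*, *CRLF2*) — each with many possible partner genes and
breakpoints. Timely detection matters because the fusion class determines
targeted therapy, yet conventional workflows (FISH + flow panels, LDA
RT-PCR, short-read RNA-seq) are slow, expensive, or blind to novel
partners, and clinical RNA is often degraded.

*Partial anchored capture* addresses this: hybridization probes capture
only the known panel gene — one side of any potential fusion — and
nanopore long reads carry sequence across the fusion junction, revealing
whichever partner is on the other side. `anchorfuse` implements the
informatics for this assay as an R package:

* **panel model** — merged-exon capture regions from GTF annotation with a
  fast interval→gene index (`read_gene_models()`, `merge_exons()`,
  `target_panel()`, `build_index()`, `query_index()`);
* **read QC** — the standard nanopore read filter (drop reads shorter than
  100 bp or with mean quality below Q7, where mean quality averages *error
  probabilities*: Q = −10·log10(mean 10^(−qᵢ/10))) plus read-set
  statistics (`filter_reads()`, `read_stats()`);
* **fusion caller** — chains primary + supplementary SAM records per read
  with exact query-coordinate reconstruction (hard clips, reverse strand),
  labels segments by maximal exonic overlap, clusters per-read breakpoints
  by single linkage, and applies five switchable false-positive filters:
  panel anchoring, minimum support (default 3 reads), read-through
  rejection (same-strand genes < 100 kb apart), overlapping-gene
  rejection, and minimum flanking-segment length
  (`parse_alignments()`, `assign_genes()`, `call_candidates()`,
  `filter_candidates()`, `fusion_frequency()`, `call_fusions()`);
* **metrics** — capture rate (on-target aligned-base fraction), per-base
  depth and breadth at thresholds, normalized depth at 1000×
  (1000 × gene mean depth / panel mean depth), expression-outlier flags
  (the *CRLF2*-overexpression signature of enhancer fusions with
  uncapturable partners), and enrichment fold versus a non-targeted
  library (fusion-supporting reads per Mb ratio) (`panel_qc()`,
  `enrichment_fold()`);
* **evaluation** — confusion matrices and sensitivity/specificity over
  clinical truth tables, with a packaged 39-sample blind-test cohort
  (`evaluate_cohort()`, `blind_test_cohort()`);
* **simulator** — fully synthetic targeted-capture nanopore experiments:
  random genome + annotation + panel, fusion transcripts, RIN-driven
  fragmentation (per-base cut probability c/RIN²), substitution/indel
  errors with per-read quality draws, and idealized truth alignments, so
  the entire pipeline runs with zero external data (`sim_config()`,
  `simulate_sample()`, `run_pipeline()`).

Fusion frequency is reported as n_support / n_locus, the fraction of reads
overlapping a ±50 bp window around the panel-gene breakpoint that support
the fusion — a qualitative abundance proxy, not a tumour fraction.

## Worked example

A synthetic fusion-positive sample: 2,000 reads, a `BCR::ABL1`-like fusion
expressed at 10% frequency, RIN 7, ~4% sequencing error.

```r
library(anchorfuse)

sim <- simulate_sample(sim_config(seed = 7, n_reads = 2000))
sim$fusions
#>     gene5  gene3 chrom5   bp5 chrom3   bp3 frequency n_junction_reads
#>  1:   BCR   ABL1   chrB 11330   chrA 72149       0.1               18

res <- run_pipeline(sim)   # qc -> align chains -> call -> metrics
res$calls[, .(gene5, gene3, bp5, bp3, n_support, fusion_frequency, status)]
#>     gene5  gene3   bp5   bp3 n_support fusion_frequency status
#>  1:   BCR   ABL1 11330 72149        18        0.0972973   PASS
res$qc
#> panel_qc: capture rate 60.54%, panel mean depth 170.8x, breadth 1x 100.00%, ...
```

All 18 junction-spanning truth reads are recovered as supporting reads;
the called breakpoints equal the simulated junction exactly; the estimated
fusion frequency (9.7%) recovers the configured 10%; the capture rate
(60.5%) recovers the configured on-target fraction of 0.6.

The packaged clinical blind-test cohort reproduces the published
validation metrics:

```r
evaluate_cohort(read_cohort(blind_test_cohort()))
#> group A (n=26): tp=14 fn=1 tn=11 fp=0  sensitivity=93.33%  specificity=100.00%
#> group B (n=9):  tp=5  fn=2 tn=2  fp=0  sensitivity=71.43%  specificity=100.00%
#> excluded from metrics: CBTS-36, CBTS-38, CBTS-37, CBTS-39
```

## Documentation

The methods vignette (`vignettes/anchorfuse-methods.Rmd`) describes the
model, the defaults and their rationale, what the simulator does and does
not emulate, and known limitations. A small CLI (`anchorfuse_cli()`)
exposes the `qc` / `call` / `metrics` / `eval` / `simulate` subcommands.
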