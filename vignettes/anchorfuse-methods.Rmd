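---
title: "Methods: targeted long-read fusion calling in anchorfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted long-read fusion calling in anchorfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorfuse)
```

## The assay and its model

Partial anchored capture sequences targeted cDNA on a nanopore platform.
Hybridization probes tile the merged exon space of a small panel of
fusion-prone kinase and cytokine-receptor genes (default: ABL2, CSF1R,
PDGFRB, JAK2, ABL1, EPOR, CRLF2 — the recurrently rearranged drivers of
Ph-like B-ALL). Because capture needs only *one* side of a junction, and a
long read traverses the junction, the partner gene — known or novel — is
read directly. The informatics problem is therefore:

1. decide which reads are usable (length/quality filter);
2. reconstruct, for each read, the ordered chain of aligned segments that
   a splice-aware aligner reports as one primary plus supplementary
   records;
3. decide which chains are fusion evidence and which are artifacts;
4. quantify capture performance and relative target expression.

### Read QC

A read is kept when its length is at least 100 bp *and* its mean quality
is at least Q7. Mean quality averages error probabilities, not Phred
scores: `Q = -10 log10(mean(10^(-q_i/10)))`, the convention of the
standard nanopore read filters. Thresholds are strict removals ("shorter
than", "lower than"), so a 100 bp read at exactly Q7.00 is kept. Both
thresholds are parameters of `filter_reads()`; `(0, 0)` is the identity.

### Segment chains

`parse_alignments()` drops secondary and unmapped records and rebuilds
query coordinates from the CIGAR *including hard clips*, so a
hard-clipped supplementary record indexes the same read axis as its
primary. For reverse-strand records the stored (reference-forward)
interval is mapped back into the sequenced read's orientation. All
intervals are held 1-based closed in IRanges/GRanges containers — the
standard R/Bioconductor convention — with conversion only at the BED
(0-based half-open) and SAM/GTF (1-based) boundaries.

### From chains to calls

Each segment is labelled with the gene of maximal exonic overlap (aligned
reference bases M/=/X intersected with the gene's merged exon regions),
provided the overlap reaches `min_overlap = 100` bp; ties break by larger
overlap then lexicographic gene id. Every adjacent pair of
distinctly-labelled segments in query order contributes one junction; the
per-read breakpoint on each side is the reference edge of the segment
adjacent to the query-space junction (for a minus-strand segment the
query-adjacent edge is the appropriate reference coordinate, since query
order runs down the reference).

**Pair orientation.** Roughly half of cDNA reads are sequenced antisense.
For such a read both flanking segments align antisense to their genes'
annotated strands, and the query order of the partners is the *reverse*
of transcript order. `call_candidates()` therefore flips the pair (and
breakpoints) when both segments are antisense, so `gene5::gene3` always
reports transcript 5'→3' order; a naive "earlier query interval is the 5'
partner" rule would split every fusion into two half-support candidates
of opposite order. Mixed-sense pairs (inversion-like chimeras) keep query
order; they are rare and typically fail filtering anyway.

Breakpoints of reads supporting the same ordered pair are clustered by
single linkage with gap ≤ `cluster_window = 50` bp, first on the 5' then
on the 3' coordinate; each cluster becomes one candidate whose reported
breakpoints are the cluster medians.

### False-positive filters

The published pipelines in this space describe their filtering only
loosely; `anchorfuse` makes the layer explicit as five ordered,
individually switchable filters (first failure recorded in `status`):

1. **panel_anchor** — one partner must be a panel gene; capture targets
   panel genes, so a junction between two off-panel genes is noise.
2. **min_support** — at least `min_support = 3` supporting reads. The
   default balances the ~10-read support seen in non-targeted long-read
   transcriptomes of strongly positive samples against single-read
   nanopore chimera noise (library chimeras arise in roughly 1 in 10³–10⁴
   reads and are breakpoint-incoherent, so requiring 3 clustered reads
   suppresses them).
3. **read_through** — same chromosome, same annotated strand, gene spans
   separated by < `readthrough_distance = 1e5` bp: the signature of
   transcriptional read-through between neighbouring genes, a canonical
   false-positive class; rejected unless both partners are panel genes.
4. **overlapping_genes** — partners whose merged exon regions intersect
   cannot be distinguished from ambiguous alignment.
5. **segment_length** — a supporting read counts only if both flanking
   segments carry ≥ `min_segment = 100` aligned reference bases; surviving
   support must again reach `min_support` (status
   `FILTERED:segment_length` otherwise). PASS calls report the eligible
   support count.

### Fusion frequency

`fusion_frequency()` reports `n_support / n_locus`, where `n_locus`
counts distinct QC-passed reads overlapping ±50 bp around the
*panel-gene* breakpoint. This denominator is a design choice: clinical
RT-PCR frequencies are known not to agree quantitatively with long-read
estimates (different chemistry, degradation between assays), so the value
is a qualitative abundance proxy and only qualitative agreement should be
asserted.

### Panel metrics

* **capture rate** — fraction of aligned bases (M/=/X) inside the merged
  target regions; capture + off-target = 1 exactly.
* **depth / breadth** — depth counts aligned reference bases of every
  kept record, supplementary included (capture-efficiency semantics);
  deletions and intron `N` gaps contribute nothing. Breadth at *t* is the
  fraction of target bases with depth ≥ *t* and is monotone in *t*.
* **normalized depth at 1000×** — `1000 × gene mean depth / panel mean
  depth` ("average" is the mean over target bases, not the median); a
  gene at the panel average reads exactly 1000.
* **expression outliers** — a gene whose normalized depth exceeds
  `k = 5` times the median of the *other* panel genes is flagged. The
  rule operationalizes the observed signature of enhancer-driven
  rearrangements (e.g. IGH::CRLF2): grossly elevated target expression
  with no callable partner, because the partner contributes no mRNA. The
  paper-scale evidence is only "significantly elevated", so k is a
  configurable invention; 5× is far outside the ~±10% spread seen across
  a well-behaved panel.
* **enrichment fold** — `(n_t/Mb_t) / (n_b/Mb_b)`, fusion-supporting
  reads per megabase of clean bases, targeted versus non-targeted
  library; `NA` when the background yields zero fusion reads. This
  per-megabase read-rate ratio is adopted because it reproduces both
  published example values to two decimals; it is invariant under joint
  rescaling of the two base counts.

### Cohort evaluation

`evaluate_cohort()` scores each sample: TP iff *all* truth fusions are
called (unordered, name-based pair matching — clinical reports do not fix
5'/3' order), FN otherwise for truth-positives; FP/TN for
truth-negatives. Samples whose fusions involve unknown or
immunoglobulin-enhancer partners (group C in the packaged cohort) are
excluded from sensitivity/specificity and reported descriptively, because
an mRNA assay cannot resolve them; partial detections are tallied
separately. Sensitivity = 100·tp/(tp+fn), specificity = 100·tn/(tn+fp),
NA on empty denominators.

## The simulator: a stated world

`simulate_sample()` draws a complete targeted-capture experiment so every
module is testable offline. Its defaults are the conditions the assay is
designed for; they are fixed once, not tuned:

| parameter | default | rationale |
|---|---|---|
| genes | 7 panel + 5 partner | the assay's panel size; a handful of recurrent partners |
| exons/gene, exon length | 3–8, 120–400 bp | typical mRNA exon structure; transcripts ~0.5–3 kb |
| fusion | one inter-chromosomal spec at frequency 0.1 | a typical strongly positive diagnostic sample (~10%) |
| `n_reads` | 2,000 (tests scale up/down) | a low-throughput nanopore run after demultiplexing |
| `rin` | 7 | an intact clinical specimen (commercial facilities require RIN ≥ 7) |
| `cut_coef` | 0.002 | per-base cut probability c/RIN² |
| error rates | 2% sub, 1% ins, 1% del | ~4% total, recent nanopore basecalls |
| mean quality | N(12, 2) truncated to [4, 20] | the typical nanopore per-read Q range |
| `on_target_fraction` | 0.6 | mid-range of published capture rates (~47–70%) |
| `min_fragment` | 200 bp | the assay's library size selection |
| antisense fraction | 0.5 | cDNA reads sequence in both orientations |

Design notes:

* **Two chromosomes, not one.** Panel genes sit on `chrA`, partners on
  `chrB`. On a single small chromosome every simulated fusion would be
  intrachromosomal within 100 kb and be consumed by the read-through
  filter — the filter working exactly as designed. Real fusion partners
  are typically inter-chromosomal, so the default world reflects that;
  read-through material is injected explicitly via `readthrough_specs`
  between neighbouring same-chromosome partner genes. All simulated genes
  are on the plus strand; alignment-strand handling is exercised by the
  antisense read fraction and by hand-built records in the tests.
* **Degradation** is independent per-base cutting at `c/RIN²`; fragments
  under `min_fragment` are lost to size selection. At RIN 7 most
  transcripts stay intact; at RIN 1–2 fragments shrink to the few-hundred
  bp scale. (At RIN 2 the model's mean fragment is ~2 kb before size
  selection — the model is a deliberately simple monotone stand-in for
  degradation chemistry, not a fit.)
* **Errors and qualities.** Error counts are binomial in read length with
  uniform positions (exactly the independent per-base model); each read's
  total error rate follows its drawn mean quality, split in the
  configured sub/ins/del proportions, and its quality string is constant
  at that mean Q, so `mean_read_quality()` recovers the draw exactly and
  the Q7 QC boundary is sharp.
* **Truth alignments are idealized.** The SAM records describe the
  error-free fragment: exon-block `M` runs joined by intron `N` gaps,
  soft-clipped primaries and hard-clipped supplementaries flanking
  junctions, reverse flags for antisense reads. The aligner is assumed to
  recover the true origin; aligner noise (clipped junction bases, split
  mis-assignments, mapping ambiguity) is *not* emulated. A green
  simulation test therefore establishes the correctness of the chaining,
  clustering, filtering and metric arithmetic — not robustness to
  alignment artifacts.
* **Capture** is post-hoc read thinning by `on_target_fraction`, enough
  to exercise capture-rate recovery; probe hybridization physics, GC
  bias and off-target pulldown structure are not modelled.
* Determinism: all randomness flows from `sim_config(seed = )` through
  one RNG stream; identical configs give byte-identical FASTQ/SAM/truth.
  `emit_reads = FALSE` skips the (last-drawn) error stage for caller-only
  studies without changing truth or SAM.

## Numerical and degenerate-input choices

* Empty read sets yield zero statistics with `NA` n50/mean quality;
  zero-length reads are only removable by the length filter.
* `n_locus = 0` makes fusion frequency `NA`; a zero-depth panel makes
  normalized depths `NA` rather than dividing by zero; zero background
  fusion reads make enrichment `NA`; zero aligned bases make capture rate
  `NA`.
* Cluster medians are rounded to integer coordinates; candidate tables
  are sorted (support, gene pair, breakpoints) and reads processed in
  sorted read-id order, so calling is deterministic under record
  permutation.
* Unknown chromosomes in index queries return empty results, not errors;
  malformed GTF/SAM/CIGAR input errors name the offending line where
  possible.
* The merged-exon panel takes "exon regions of all transcripts"
  literally: UTR exons are included, book-ended intervals merge
  (capture regions are contiguous DNA), and gene identity is keyed on
  `gene_id` with `gene_name` collisions allowed.
* A read with more than two gene labels emits one junction per adjacent
  labelled pair; whether a three-segment chimera is one or two events is
  genuinely underdetermined, and per-adjacent-pair emission is the
  conservative, information-preserving choice.

## What the green tests do and do not establish

The acceptance suite verifies: the enrichment-fold and cohort arithmetic
against published values; exact QC boundary behaviour; detection of a 1%
fusion at 50,000 reads in ≥95% of seeded replicates with zero PASS calls
on fusion-free simulations; truth-matched gene pairs and breakpoints over
100 seeded simulations; and binomial-interval recovery of capture rate
and fusion frequency at 10,000 reads. The capture-rate recovery run uses
equal-length transcripts across panel and partner genes so that the
base-weighted capture rate is exactly binomial in the read draw —
otherwise the finite gene set makes transcript-length imbalance a fixed
confounder and the binomial interval is not the correct null.

Not established: performance on real nanopore alignments (aligner
artifacts, basecaller error structure, homopolymers), absolute clinical
sensitivity (the packaged cohort fixes the assay's calls, it does not
re-derive them from reads), resolution of enhancer fusions with
non-templated junction sequence, and quantitative agreement of fusion
frequency with RT-PCR.

## Known limitations

* The false-positive filter set is this package's concrete definition of
  a loosely published layer; real pipelines may differ in detail.
* The degradation and error models are simple independence models; real
  nanopore error is context-dependent.
* Single-transcript genes in the simulator (the panel model itself
  handles multi-transcript GTFs).
* The expression-outlier rule flags relative overexpression only; it
  cannot name the partner.
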