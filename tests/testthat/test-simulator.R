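# simulator: determinism, transcript bookkeeping, degradation, errors,
# truth-alignment round trips

small_cfg <- function(...) {
  sim_config(seed = 99, n_reads = 300,
             fusion_specs = list(fusion_spec("BCR", 2L, "ABL1", 2L, 0.3)),
             ...)
}

test_that("identical config and seed give byte-identical outputs", {
  s1 <- simulate_sample(small_cfg())
  s2 <- simulate_sample(small_cfg())
  expect_identical(s1$sam, s2$sam)
  expect_identical(s1$reads$sequence, s2$reads$sequence)
  expect_identical(s1$reads$quality, s2$reads$quality)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.character(s1$reference$genome),
                   as.character(s2$reference$genome))
  # a different seed changes the world
  s3 <- simulate_sample(sim_config(seed = 100, n_reads = 300))
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("reference honours the configured gene content", {
  ref <- simulate_reference(sim_config(seed = 5))
  expect_setequal(names(ref$genes), c(default_panel_genes(),
                                      c("BCR", "ETV6", "P2RY8", "NUP214", "PAX5")))
  expect_length(ref$panel$genes, 7L)
  # exons_per_gene (1,1) gives one exon feature per gene in the GTF
  cfg1 <- sim_config(seed = 5, exons_per_gene = c(1L, 1L))
  ref1 <- simulate_reference(cfg1)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ref1$genes, path)
  gtf <- readLines(path)
  expect_equal(sum(grepl("\texon\t", gtf)), length(ref1$genes))
  # reference round-trips through the GTF reader
  models <- read_gene_models(path)
  expect_setequal(names(models), names(ref1$genes))
  expect_equal(models$ABL1$exons, ref1$genes$ABL1$exons)
})

test_that("fusion transcripts keep exact length and breakpoint bookkeeping", {
  ref <- simulate_reference(sim_config(seed = 3))
  spec <- fusion_spec("BCR", 2L, "ABL1", 2L, 0.1)
  tx <- make_fusion_transcript(ref, spec)
  g5 <- ref$genes$BCR
  g3 <- ref$genes$ABL1
  w5 <- IRanges::width(g5$exons)[1:2]
  w3 <- IRanges::width(g3$exons)[-1]
  expect_equal(tx$L, sum(w5) + sum(w3))
  expect_equal(nchar(tx$seq), tx$L)
  expect_equal(tx$junction, sum(w5))
  expect_equal(tx$bp5, IRanges::end(g5$exons)[2])
  expect_equal(tx$bp3, IRanges::start(g3$exons)[2])
  # full-gene concatenation when every exon is retained
  full <- make_fusion_transcript(
    ref, fusion_spec("BCR", length(g5$exons), "ABL1", 1L, 0.1))
  expect_equal(full$L, sum(IRanges::width(g5$exons)) +
                 sum(IRanges::width(g3$exons)))
  # sequence equals the spliced exon sequence of the reference
  expect_equal(
    substr(tx$seq, 1, IRanges::width(g5$exons)[1]),
    as.character(Biostrings::subseq(ref$genome[[g5$chrom]],
                                    IRanges::start(g5$exons)[1],
                                    IRanges::end(g5$exons)[1]))
  )
  expect_error(make_fusion_transcript(ref, fusion_spec("BCR", 99L, "ABL1", 2L, 0.1)),
               "exon 99")
})

test_that("degradation follows the RIN model", {
  # rin 10, 500 bp: mean cuts 500 * 0.002 / 100 = 0.01 -> almost always intact
  n_intact <- sum(vapply(1:400, function(i) {
    nrow(degrade(500, rin = 10, min_fragment = 1, seed = i)) == 1L
  }, NA))
  expect_gte(n_intact, 390)
  # monte-carlo ordering: rin 2 fragments are much shorter than rin 8
  frag_len <- function(rin, seeds) {
    unlist(lapply(seeds, function(s) {
      d <- degrade(20000, rin = rin, min_fragment = 1, seed = s)
      d$end - d$start + 1
    }))
  }
  expect_lt(mean(frag_len(2, 1:200)), mean(frag_len(8, 1:200)))
  # fragments shorter than min_fragment are discarded
  expect_equal(nrow(degrade(150, rin = 5, min_fragment = 200)), 0L)
  # sequence input carries the substrings
  d <- degrade(strrep("ACGT", 100), rin = 1, min_fragment = 10, seed = 2)
  expect_true(all(nchar(d$sequence) == d$end - d$start + 1))
})

test_that("add_errors is exact at the limits and recovers its rates", {
  s <- strrep("ACGT", 50)
  none <- add_errors(s, 0, 0, 0)
  expect_equal(none$sequence, s)
  expect_equal(nchar(none$quality), nchar(s))
  # del_rate 1 empties the read
  gone <- add_errors(s, 0, 0, 1)
  expect_equal(gone$sequence, "")
  # substitution recovery: 100,000 bases at 5%, within 3 sigma binomial
  set.seed(31)
  big <- paste(sample(c("A", "C", "G", "T"), 1e5, TRUE), collapse = "")
  out <- add_errors(big, sub_rate = 0.05, ins_rate = 0, del_rate = 0,
                    seed = 77)
  mism <- sum(utf8ToInt(out$sequence) != utf8ToInt(big))
  sigma <- sqrt(1e5 * 0.05 * 0.95)
  expect_lt(abs(mism - 5000), 3 * sigma)
  # quality string encodes the requested mean quality
  q <- add_errors(s, 0.01, 0, 0, mean_quality = 12)
  expect_equal(mean_read_quality(q$quality), 12)
  # deterministic under seed
  a <- add_errors(big, 0.05, 0.02, 0.02, seed = 5)
  b <- add_errors(big, 0.05, 0.02, 0.02, seed = 5)
  expect_identical(a, b)
})

test_that("truth alignments round-trip through parse_alignments", {
  sim <- simulate_sample(small_cfg())
  ch <- parse_alignments(sim$sam)
  seg <- ch$segments
  # conservation: every emitted read appears in SAM, FASTQ and truth
  expect_setequal(unique(seg$read_id), sim$truth$read_id)
  expect_equal(sim$reads$read_id, sim$truth$read_id)
  frag_len <- sim$truth$frag_end - sim$truth$frag_start + 1L
  # per-read query intervals tile [1, fragment length] exactly
  bychain <- split(seg, seg$read_id)
  for (id in names(bychain)) {
    s <- bychain[[id]][order(qstart)]
    want_len <- frag_len[sim$truth$read_id == id]
    expect_equal(s$qstart[1], 1L)
    expect_equal(s$qend[nrow(s)], want_len)
    if (nrow(s) > 1) expect_equal(s$qstart[-1], s$qend[-nrow(s)] + 1L)
    expect_equal(unique(s$read_length), want_len)
  }
  # junction reads have exactly two records flanking the truth breakpoints
  junc <- sim$truth[spans_junction == TRUE]
  expect_gt(nrow(junc), 0)
  fus <- sim$fusions
  for (id in junc$read_id) {
    s <- seg[read_id == id]
    expect_equal(nrow(s), 2L)
    expect_equal(sum(s$is_supplementary), 1L)
    s5 <- s[chrom == fus$chrom5]
    s3 <- s[chrom == fus$chrom3]
    expect_equal(s5$ref_end, fus$bp5)
    expect_equal(s3$ref_start, fus$bp3)
  }
  # non-junction reads are single primary records
  plain <- sim$truth[spans_junction == FALSE]
  expect_true(all(table(seg[read_id %in% plain$read_id, read_id]) == 1))
})

test_that("simulated sample outputs are mutually consistent on disk", {
  sim <- simulate_sample(sim_config(seed = 12, n_reads = 120))
  dir <- withr::local_tempdir()
  write_sim_sample(sim, dir)
  expect_setequal(list.files(dir),
                  c("reference.fa", "annotation.gtf", "panel.bed",
                    "reads.fastq", "alignments.sam", "truth_reads.tsv",
                    "truth_fusions.tsv"))
  back <- read_fastq(file.path(dir, "reads.fastq"))
  expect_equal(back$sequence, sim$reads$sequence)
  ch <- parse_alignments(file.path(dir, "alignments.sam"))
  expect_equal(ch$segments, parse_alignments(sim$sam)$segments)
  genes <- read_gene_models(file.path(dir, "annotation.gtf"))
  expect_setequal(names(genes), names(sim$reference$genes))
})

test_that("fusion frequency zero means no fusion reads and no truth entries", {
  sim <- simulate_sample(sim_config(
    seed = 9, n_reads = 400,
    fusion_specs = list(fusion_spec("BCR", 2L, "ABL1", 2L, 0))))
  expect_equal(sim$fusions$n_junction_reads, 0L)
  expect_false(any(sim$truth$is_fusion))
})

test_that("read-through artifacts produce split chimeric alignments", {
  sim <- simulate_sample(sim_config(
    seed = 14, n_reads = 100, fusion_specs = list(),
    readthrough_specs = list(list(gene5 = "ETV6", gene3 = "P2RY8",
                                  n_reads = 10))))
  art <- sim$truth[is_artifact == TRUE]
  expect_equal(nrow(art), 10L)
  seg <- parse_alignments(sim$sam)$segments
  counts <- table(seg[read_id %in% art$read_id, read_id])
  # junction-spanning artifact fragments align split; truncated ones do not
  jn <- sim$transcripts[["readthrough:ETV6::P2RY8"]]$junction
  spans <- art[frag_start <= jn & frag_end > jn, read_id]
  expect_gt(length(spans), 0L)
  expect_true(all(counts[spans] == 2))
  expect_true(all(counts %in% 1:2))
})
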