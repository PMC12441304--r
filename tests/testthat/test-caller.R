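# fusion caller: gene assignment, candidate calling, filters, frequency

toy_index <- function() build_index(toy_genes())

test_that("assign_genes labels by maximal exonic overlap with a threshold", {
  genes <- list(
    G1 = gene_model("G1", chrom = "c1", exons = IRanges::IRanges(1001, 1150)),
    G2 = gene_model("G2", chrom = "c1", exons = IRanges::IRanges(1151, 1450))
  )
  idx <- build_index(genes)
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:c1\tLN:10000",
           sam_line("r1", 0L, "c1", 1001, "450M"),   # 150 vs 300 bp overlap
           sam_line("r2", 0L, "c1", 1091, "60M"),    # 60 bp < min_overlap
           sam_line("r3", 0L, "c1", 1001, "400M"))   # 150 vs 250 -> G2
  lab <- assign_genes(parse_alignments(sam), idx, min_overlap = 100)
  seg <- lab$segments
  expect_equal(seg[read_id == "r1", gene_id], "G2")
  expect_equal(seg[read_id == "r1", gene_overlap], 300L)
  expect_true(is.na(seg[read_id == "r2", gene_id]))
  expect_equal(seg[read_id == "r3", gene_id], "G2")
})

test_that("spliced segments count only exonic overlap", {
  # 100M2800N100M spans the A gene body; aligned blocks 100+100
  idx <- toy_index()
  sam <- c(sam_header(), sam_line("r", 0L, "chr1", 1, "100M2800N100M"))
  lab <- assign_genes(parse_alignments(sam), idx)
  expect_equal(lab$segments$gene_id, "A")
  expect_equal(lab$segments$gene_overlap, 200L)
})

test_that("fusion junction reads yield an ordered candidate with exact breakpoints", {
  idx <- toy_index()
  sam <- c(sam_header(),
           unlist(lapply(1:5, function(i)
             fusion_read_sam(sprintf("f%d", i), e5 = 1400, b3 = 5001))),
           wt_read_sam("w1", "chr1", 1, 500))
  cand <- call_candidates(assign_genes(parse_alignments(sam), idx))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$gene5, "A")
  expect_equal(cand$gene3, "B")
  expect_equal(cand$bp5, 1400L)
  expect_equal(cand$bp3, 5001L)
  expect_equal(cand$n_support, 5L)
  expect_equal(cand$breakpoint_cluster_span, 0L)
  expect_setequal(cand$supporting_reads[[1]], sprintf("f%d", 1:5))
})

test_that("antisense-sequenced junction reads report the same 5'->3' pair", {
  idx <- toy_index()
  sam <- c(sam_header(),
           fusion_read_sam("fwd", e5 = 1400, b3 = 5001, rev = FALSE),
           fusion_read_sam("rev1", e5 = 1400, b3 = 5001, rev = TRUE),
           fusion_read_sam("rev2", e5 = 1400, b3 = 5001, rev = TRUE))
  cand <- call_candidates(assign_genes(parse_alignments(sam), idx))
  expect_equal(nrow(cand), 1L)   # one candidate, not a swapped duplicate
  expect_equal(cand$gene5, "A")
  expect_equal(cand$gene3, "B")
  expect_equal(cand$bp5, 1400L)
  expect_equal(cand$bp3, 5001L)
  expect_equal(cand$n_support, 3L)
})

test_that("reads within a single gene never form candidates", {
  idx <- toy_index()
  sam <- c(sam_header(),
           wt_read_sam("w1", "chr1", 100, 800),
           sam_line("w2", 0L, "chr1", 100, "200M500N200M"))
  cand <- call_candidates(assign_genes(parse_alignments(sam), idx))
  expect_equal(nrow(cand), 0L)
})

test_that("breakpoint clustering is single-linkage with the given gap", {
  idx <- toy_index()
  bps <- c(1000L, 1010L, 1045L, 1120L)
  sam <- c(sam_header(),
           unlist(lapply(seq_along(bps), function(i)
             fusion_read_sam(sprintf("r%d", i), e5 = bps[i], b3 = 5001))))
  cand <- call_candidates(assign_genes(parse_alignments(sam), idx),
                          cluster_window = 50)
  expect_equal(nrow(cand), 2L)
  expect_setequal(cand$n_support, c(3L, 1L))
  # oracle comparison on the membership structure
  memb <- brute_force_single_linkage(bps, 50)
  expect_equal(sort(table(memb), decreasing = TRUE),
               sort(table(rep(seq_len(nrow(cand)), cand$n_support)),
                    decreasing = TRUE), ignore_attr = TRUE)
  # random oracle rounds
  set.seed(9)
  for (rep in 1:10) {
    x <- sort(sample(1000:3000, 12))
    sam2 <- c(sam_header(),
              unlist(lapply(seq_along(x), function(i)
                fusion_read_sam(sprintf("q%d", i), e5 = x[i], b3 = 5001,
                                la = 400))))
    cand2 <- call_candidates(assign_genes(parse_alignments(sam2), idx),
                             cluster_window = 50)
    memb2 <- brute_force_single_linkage(x, 50)
    expect_equal(nrow(cand2), length(unique(memb2)))
    expect_equal(sort(cand2$n_support),
                 sort(as.integer(table(memb2))), ignore_attr = TRUE)
  }
})

test_that("filters are applied in order with reasons recorded", {
  idx <- toy_index()
  panel <- toy_panel()
  mk_calls <- function(sam, ..., min_overlap = 100) {
    filter_candidates(
      call_candidates(assign_genes(parse_alignments(sam), idx,
                                   min_overlap = min_overlap)),
      idx, panel, ...)
  }
  # PASS: panel gene A to partner B, different chromosomes, 5 reads
  sam_ok <- c(sam_header(), unlist(lapply(1:5, function(i)
    fusion_read_sam(sprintf("f%d", i), 1400, 5001))))
  calls <- mk_calls(sam_ok)
  expect_equal(calls$status, "PASS")
  expect_equal(calls$filters_passed,
               "panel_anchor,min_support,read_through,overlapping_genes,segment_length")

  # panel anchor: B::C junction involves no panel gene
  sam_anchor <- c(sam_header(), unlist(lapply(1:5, function(i)
    fusion_read_sam(sprintf("a%d", i), 5200, 1, la = 200, lb = 200,
                    chromA = "chr2", chromB = "chr3"))))
  expect_equal(mk_calls(sam_anchor)$status, "FILTERED:panel_anchor")

  # min support: 2 reads < 3
  sam_sup <- c(sam_header(), unlist(lapply(1:2, function(i)
    fusion_read_sam(sprintf("s%d", i), 1400, 5001))))
  expect_equal(mk_calls(sam_sup)$status, "FILTERED:min_support")
  expect_equal(mk_calls(sam_sup, min_support = 2)$status, "PASS")

  # read-through: C and D are same-strand chr3 genes ~39 kb apart
  sam_rt <- c(sam_header(), unlist(lapply(1:10, function(i)
    fusion_read_sam(sprintf("t%d", i), 1000, 40001, chromA = "chr3",
                    chromB = "chr3"))))
  rt <- filter_candidates(
    call_candidates(assign_genes(parse_alignments(sam_rt), idx)),
    idx, toy_panel(panel = c("C", "A")))  # one panel anchor, not both
  expect_equal(rt$status, "FILTERED:read_through")
  # both partners on panel: rescued
  rt2 <- filter_candidates(
    call_candidates(assign_genes(parse_alignments(sam_rt), idx)),
    idx, toy_panel(panel = c("C", "D")))
  expect_equal(rt2$status, "PASS")
  # far enough apart the filter does not fire
  rt3 <- filter_candidates(
    call_candidates(assign_genes(parse_alignments(sam_rt), idx)),
    idx, toy_panel(panel = c("C", "A")), readthrough_distance = 30000)
  expect_equal(rt3$status, "PASS")

  # overlapping genes: E and F overlap on chr4 (opposite strands)
  sam_ov <- c(sam_header(), unlist(lapply(1:5, function(i) c(
    sam_line(sprintf("o%d", i), 0L, "chr4", 1, "400M600S"),
    sam_line(sprintf("o%d", i), 2048L, "chr4", 600, "400H600M")))))
  ov <- filter_candidates(
    call_candidates(assign_genes(parse_alignments(sam_ov), idx)),
    idx, toy_panel(panel = c("E", "F")))
  expect_equal(ov$status, "FILTERED:overlapping_genes")

  # segment length: 5' side only 80 aligned bases
  sam_seg <- c(sam_header(), unlist(lapply(1:5, function(i)
    fusion_read_sam(sprintf("g%d", i), 1400, 5001, la = 150, lb = 80))))
  seg <- mk_calls(sam_seg, min_overlap = 50)
  expect_equal(seg$status, "FILTERED:segment_length")

  # filters are individually switchable
  seg2 <- mk_calls(sam_seg, min_overlap = 50,
                   enabled = c("panel_anchor", "min_support"))
  expect_equal(seg2$status, "PASS")
})

test_that("fusion_frequency divides support by breakpoint-window reads", {
  idx <- toy_index()
  panel <- toy_panel()
  sam <- c(sam_header(),
           unlist(lapply(1:10, function(i)
             fusion_read_sam(sprintf("f%02d", i), 1400, 5001))),
           # 90 wild-type reads overlapping the A breakpoint at 1400
           unlist(lapply(1:90, function(i)
             wt_read_sam(sprintf("w%02d", i), "chr1", 1200, 400))),
           # reads far from the breakpoint do not count
           unlist(lapply(1:30, function(i)
             wt_read_sam(sprintf("x%02d", i), "chr1", 2500, 300))))
  chains <- assign_genes(parse_alignments(sam), idx)
  calls <- fusion_frequency(
    filter_candidates(call_candidates(chains), idx, panel), chains, panel)
  expect_equal(calls$status, "PASS")
  expect_equal(calls$fusion_frequency, 10 / 100)
  # all overlapping reads support -> 100%
  sam2 <- c(sam_header(), unlist(lapply(1:4, function(i)
    fusion_read_sam(sprintf("f%d", i), 1400, 5001))))
  ch2 <- assign_genes(parse_alignments(sam2), idx)
  calls2 <- fusion_frequency(
    filter_candidates(call_candidates(ch2), idx, panel), ch2, panel)
  expect_equal(calls2$fusion_frequency, 1)
})

test_that("calling is deterministic and needs supplementary evidence", {
  idx <- toy_index()
  sam <- c(sam_header(),
           fusion_read_sam("b", 1400, 5001),
           fusion_read_sam("a", 1390, 5001),
           fusion_read_sam("c", 1410, 5001))
  ch <- parse_alignments(sam)
  c1 <- call_candidates(assign_genes(ch, idx))
  # shuffled record order gives the identical candidate table
  sam_shuf <- c(sam_header(),
                fusion_read_sam("c", 1410, 5001),
                fusion_read_sam("a", 1390, 5001)[2:1],
                fusion_read_sam("b", 1400, 5001))
  c2 <- call_candidates(assign_genes(parse_alignments(sam_shuf), idx))
  expect_equal(c1$supporting_reads, c2$supporting_reads)
  expect_equal(c1$bp5, c2$bp5)
  # dropping supplementary records leaves no candidates
  no_supp <- sam[!grepl("\t2048\t|\t2064\t", sam)]
  c3 <- call_candidates(assign_genes(parse_alignments(no_supp), idx))
  expect_equal(nrow(c3), 0L)
})

test_that("fusion-call TSV has the documented columns", {
  idx <- toy_index()
  panel <- toy_panel()
  sam <- c(sam_header(), unlist(lapply(1:5, function(i)
    fusion_read_sam(sprintf("f%d", i), 1400, 5001))))
  ch <- assign_genes(parse_alignments(sam), idx)
  calls <- fusion_frequency(
    filter_candidates(call_candidates(ch), idx, panel), ch, panel)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fusion_tsv(calls, path)
  tab <- read.delim(path)
  expect_equal(names(tab),
               c("gene5", "gene3", "chrom5", "bp5", "chrom3", "bp3",
                 "n_support", "fusion_frequency", "status", "filters"))
  expect_equal(tab$fusion_frequency, 100)  # percent
})
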