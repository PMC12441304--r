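# Shared in-code fixtures: toy annotations and hand-built SAM records.

# toy gene set exercising the caller's corner cases:
#   A  panel gene, chr1:+      B  partner, chr2:+
#   C/D adjacent same-strand pair on chr3 (read-through material)
#   E/F overlapping opposite-strand pair on chr4
toy_genes <- function() {
  list(
    A = gene_model("A", chrom = "chr1", strand = "+",
                   exons = IRanges::IRanges(1, 3000)),
    B = gene_model("B", chrom = "chr2", strand = "+",
                   exons = IRanges::IRanges(5001, 8000)),
    C = gene_model("C", chrom = "chr3", strand = "+",
                   exons = IRanges::IRanges(1, 1000)),
    D = gene_model("D", chrom = "chr3", strand = "+",
                   exons = IRanges::IRanges(40001, 41000)),
    E = gene_model("E", chrom = "chr4", strand = "+",
                   exons = IRanges::IRanges(1, 1000)),
    F = gene_model("F", chrom = "chr4", strand = "-",
                   exons = IRanges::IRanges(500, 1500))
  )
}

toy_panel <- function(genes = toy_genes(), panel = "A") {
  target_panel(genes, panel_genes = panel)
}

sam_header <- function(chroms = c(chr1 = 10000, chr2 = 10000,
                                  chr3 = 50000, chr4 = 10000)) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
}

sam_line <- function(qname, flag, rname, pos, cigar, mapq = 60, seq = "*") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
          qname, flag, rname, pos, mapq, cigar, seq)
}

# split-aligned junction read: 5' part of length la ending at ref e5 on
# chromA, 3' part of length lb starting at ref b3 on chromB; rev = TRUE
# emits the same records with the reverse flag (antisense-sequenced read)
fusion_read_sam <- function(id, e5, b3, la = 200, lb = 200, rev = FALSE,
                            chromA = "chr1", chromB = "chr2") {
  fl <- if (rev) 16L else 0L
  c(
    sam_line(id, fl, chromA, e5 - la + 1L, sprintf("%dM%dS", la, lb)),
    sam_line(id, fl + 2048L, chromB, b3, sprintf("%dH%dM", la, lb))
  )
}

# one wild-type read aligned as a single block
wt_read_sam <- function(id, chrom, pos, len, rev = FALSE) {
  sam_line(id, if (rev) 16L else 0L, chrom, pos, sprintf("%dM", len))
}

# a read_set with constant per-read qualities
make_reads <- function(lens, quals, ids = sprintf("q%03d", seq_along(lens))) {
  read_set(
    read_id = ids,
    sequence = vapply(lens, function(L) strrep("A", L), ""),
    quality = mapply(function(L, q) strrep(intToUtf8(q + 33L), L),
                     lens, quals)
  )
}

# brute-force interval->gene overlap scan (oracle for query_index)
brute_force_query <- function(genes, chrom, start, end) {
  res <- lapply(genes, function(g) {
    if (g$chrom != chrom) return(NULL)
    r <- merge_exons(g)
    ov <- sum(pmax(0L, pmin(IRanges::end(r), end) -
                     pmax(IRanges::start(r), start) + 1L))
    if (ov > 0) data.frame(gene_id = g$gene_id, overlap_bp = ov) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(gene_id = character(0),
                                      overlap_bp = integer(0))
  out[order(-out$overlap_bp, out$gene_id), , drop = FALSE]
}

# brute-force 1-D single-linkage clustering (oracle for breakpoint clusters)
brute_force_single_linkage <- function(x, gap) {
  o <- order(x)
  cl <- cumsum(c(1L, diff(x[o]) > gap))
  memb <- integer(length(x))
  memb[o] <- cl
  memb
}

# independent n50: largest length L in the set with sum(len >= L) >= total/2
brute_force_n50 <- function(lens) {
  total <- sum(lens)
  cand <- sort(unique(lens), decreasing = TRUE)
  for (L in cand) if (sum(lens[lens >= L]) >= total / 2) return(L)
  NA_real_
}
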