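#' Parse splice-aware SAM alignments into per-read chains
#'
#' Consumes a SAM stream (header required) and reconstructs, for every read,
#' the ordered chain of aligned segments in *original read* coordinates:
#'
#' * secondary (flag 0x100) and unmapped (flag 0x4) records are dropped;
#'   primary and supplementary (flag 0x800) records are kept and grouped by
#'   read id;
#' * query intervals are rebuilt from the CIGAR including hard clips, so the
#'   coordinates of a hard-clipped supplementary record refer to the same
#'   read axis as its primary;
#' * for reverse-strand records the stored (reference-forward) interval is
#'   mapped back into the sequenced read's orientation.
#'
#' This chaining of split alignments is the raw evidence for fusion
#' junctions in long reads.
#'
#' @param input Path to a SAM file, or a character vector of SAM lines.
#' @return An object of class `read_chains`: list with `segments` (a
#'   `data.table`, one row per kept record, sorted by `read_id` then query
#'   start, with columns `read_id, flag, chrom, ref_start, ref_end, strand,
#'   mapq, cigar, is_supplementary, qstart, qend, aligned_ref_bases,
#'   read_length`) and `header` (the header lines). Query and reference
#'   intervals are 1-based closed.
#' @export
parse_alignments <- function(input) {
  lines <- if (length(input) == 1L && !grepl("[\n\t]", input) && file.exists(input)) {
    readLines(input)
  } else {
    input
  }
  hdr <- grepl("^@", lines)
  if (!any(hdr)) stop("SAM header missing")
  header <- lines[hdr]
  recs <- lines[!hdr & nzchar(lines)]
  empty <- data.table(
    read_id = character(0), flag = integer(0), chrom = character(0),
    ref_start = integer(0), ref_end = integer(0), strand = character(0),
    mapq = integer(0), cigar = character(0), is_supplementary = logical(0),
    qstart = integer(0), qend = integer(0), aligned_ref_bases = integer(0),
    read_length = integer(0)
  )
  if (!length(recs)) {
    return(structure(list(segments = empty, header = header),
                     class = "read_chains"))
  }
  f <- data.table::tstrsplit(recs, "\t", fixed = TRUE, keep = 1:6)
  dt <- data.table(
    read_id = f[[1L]], flag = as.integer(f[[2L]]), chrom = f[[3L]],
    pos = as.integer(f[[4L]]), mapq = as.integer(f[[5L]]), cigar = f[[6L]]
  )
  if (anyNA(dt$flag) || anyNA(dt$pos)) stop("malformed SAM record (FLAG/POS)")
  keep <- bitwAnd(dt$flag, 4L) == 0L & bitwAnd(dt$flag, 256L) == 0L
  dt <- dt[keep]
  if (!nrow(dt)) {
    return(structure(list(segments = empty, header = header),
                     class = "read_chains"))
  }
  ops <- tryCatch(GenomicAlignments::explodeCigarOps(dt$cigar),
                  error = function(e) stop("malformed CIGAR: ", conditionMessage(e)))
  lens <- GenomicAlignments::explodeCigarOpLengths(dt$cigar)
  opt <- GenomicAlignments::cigarOpTable(dt$cigar)
  aligned_q <- opt[, "M"] + opt[, "I"] + opt[, "="] + opt[, "X"]
  ref_w <- opt[, "M"] + opt[, "D"] + opt[, "N"] + opt[, "="] + opt[, "X"]
  arb <- opt[, "M"] + opt[, "="] + opt[, "X"]
  if (any(aligned_q == 0L)) stop("malformed CIGAR: no query-consuming operations")
  total_len <- aligned_q + opt[, "S"] + opt[, "H"]
  lead <- mapply(function(o, l) {
    x <- 0L
    if (length(o) && o[1L] %in% c("H", "S")) {
      x <- l[1L]
      if (o[1L] == "H" && length(o) > 1L && o[2L] == "S") x <- x + l[2L]
    }
    x
  }, ops, lens, USE.NAMES = FALSE)
  qstart_stored <- lead + 1L
  qend_stored <- lead + aligned_q
  rev <- bitwAnd(dt$flag, 16L) != 0L
  qstart <- ifelse(rev, total_len - qend_stored + 1L, qstart_stored)
  qend <- ifelse(rev, total_len - qstart_stored + 1L, qend_stored)
  seg <- data.table(
    read_id = dt$read_id, flag = dt$flag, chrom = dt$chrom,
    ref_start = dt$pos, ref_end = dt$pos + ref_w - 1L,
    strand = ifelse(rev, "-", "+"), mapq = dt$mapq, cigar = dt$cigar,
    is_supplementary = bitwAnd(dt$flag, 2048L) != 0L,
    qstart = as.integer(qstart), qend = as.integer(qend),
    aligned_ref_bases = as.integer(arb), read_length = as.integer(total_len)
  )
  setorder(seg, read_id, qstart, ref_start)
  structure(list(segments = seg, header = header), class = "read_chains")
}

#' @export
print.read_chains <- function(x, ...) {
  cat(sprintf("read_chains: %d segment(s) across %d read(s)\n",
              nrow(x$segments), length(unique(x$segments$read_id))))
  invisible(x)
}

#' Number of reads in a chain set
#' @param chains A `read_chains` object.
#' @return Integer count of distinct reads.
#' @export
n_chains <- function(chains) {
  length(unique(chains$segments$read_id))
}

#' Subset chains to a set of read ids
#'
#' Typically used to restrict alignments to QC-passed reads before fusion
#' calling and coverage metrics.
#'
#' @param chains A `read_chains` object.
#' @param read_ids Character vector of read ids to keep.
#' @return A `read_chains` object.
#' @export
subset_chains <- function(chains, read_ids) {
  structure(list(segments = chains$segments[read_id %in% read_ids],
                 header = chains$header),
            class = "read_chains")
}

# Aligned reference blocks (M/=/X; introns N and deletions D excluded) of
# each segment, as a GRanges with a `seg` index back into `segments`.
.ref_blocks <- function(segments) {
  if (!nrow(segments)) {
    return(GenomicRanges::GRanges(seg = integer(0)))
  }
  irl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    segments$cigar, pos = segments$ref_start, ops = c("M", "=", "X")
  )
  n <- lengths(irl)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(segments$chrom, n),
    ranges = unlist(irl, use.names = FALSE)
  )
  gr$seg <- rep(seq_len(nrow(segments)), n)
  gr
}
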