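#' Assign aligned segments to genes
#'
#' Labels each segment of each read chain with the gene of maximal
#' reference-base overlap between the segment's aligned blocks (M/=/X; intron
#' gaps excluded) and the gene's merged exon regions, provided that overlap
#' reaches `min_overlap` bases; otherwise the segment stays unassigned. Ties
#' are broken by larger overlap, then lexicographic gene id, so labelling is
#' deterministic.
#'
#' @param chains A `read_chains` object from [parse_alignments()].
#' @param index A `gene_index` from [build_index()] (index *all* genes, not
#'   just panel genes: fusion partners are usually off-panel).
#' @param min_overlap Minimum exonic overlap in bp to accept a label
#'   (default 100).
#' @return The `read_chains` object with `gene_id`, `gene_strand` and
#'   `gene_overlap` columns added to `segments`.
#' @export
assign_genes <- function(chains, index, min_overlap = 100) {
  stopifnot(inherits(chains, "read_chains"), inherits(index, "gene_index"))
  seg <- data.table::copy(chains$segments)
  seg[, `:=`(gene_id = NA_character_, gene_strand = NA_character_,
             gene_overlap = 0L)]
  if (nrow(seg)) {
    blocks <- .ref_blocks(seg)
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(blocks, index$regions, ignore.strand = TRUE)
    )
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(blocks)[qh], IRanges::ranges(index$regions)[sh]
      ))
      hits <- data.table(
        seg = blocks$seg[qh],
        gene_id = index$regions$gene_id[sh],
        gene_strand = index$regions$gene_strand[sh],
        w = w
      )
      hits <- hits[, list(w = sum(w)), by = list(seg, gene_id, gene_strand)]
      setorder(hits, seg, -w, gene_id)
      best <- hits[, .SD[1L], by = seg]
      best <- best[w >= min_overlap]
      if (nrow(best)) {
        seg[best$seg, `:=`(gene_id = best$gene_id,
                           gene_strand = best$gene_strand,
                           gene_overlap = as.integer(best$w))]
      }
    }
  }
  structure(list(segments = seg, header = chains$header),
            class = "read_chains")
}

# Junction edge of the query-earlier segment: the reference coordinate
# adjacent to the junction in query space. For a "+" segment that is the
# reference end; for a "-" segment query-forward runs down the reference, so
# it is the reference start. The query-later segment mirrors this.
.edge_left <- function(strand, ref_start, ref_end) {
  ifelse(strand == "+", ref_end, ref_start)
}
.edge_right <- function(strand, ref_start, ref_end) {
  ifelse(strand == "+", ref_start, ref_end)
}

#' Call fusion candidates from gene-labelled read chains
#'
#' Every read whose chain carries two or more distinct gene labels in query
#' order contributes one junction per adjacent labelled pair. Per-read
#' breakpoints are the reference edges of the two segments adjacent to the
#' query-space junction. Reads are oriented to transcript sense before
#' ordering the pair: when both flanking segments align antisense to their
#' genes' annotated strands (the read is the reverse complement of the
#' fusion cDNA) the pair and breakpoints are flipped, so `gene5::gene3`
#' always reports transcript 5'->3' order. Reads supporting the same ordered
#' pair are merged and their breakpoints clustered by single linkage with
#' gap <= `cluster_window` (first on the 5' then on the 3' coordinate); each
#' cluster becomes one candidate.
#'
#' @param chains Gene-labelled `read_chains` from [assign_genes()].
#' @param cluster_window Single-linkage gap in bp (default 50).
#' @return `data.table` of class `fusion_candidates`: one row per candidate
#'   with `gene5, gene3, chrom5, bp5, chrom3, bp3, n_support,
#'   breakpoint_cluster_span, supporting_reads` (list column) and `reads`
#'   (list column of per-read evidence: read id, breakpoints, flanking
#'   segment lengths).
#' @export
call_candidates <- function(chains, cluster_window = 50) {
  stopifnot(inherits(chains, "read_chains"))
  seg <- chains$segments
  if (!"gene_id" %in% names(seg)) stop("chains are not gene-labelled; run assign_genes()")
  lab <- seg[!is.na(gene_id)]
  empty <- data.table(
    gene5 = character(0), gene3 = character(0),
    chrom5 = character(0), bp5 = integer(0),
    chrom3 = character(0), bp3 = integer(0),
    n_support = integer(0), breakpoint_cluster_span = integer(0),
    supporting_reads = list(), reads = list()
  )
  cls <- function(x) {
    data.table::setattr(x, "class", c("fusion_candidates", class(x)))
    data.table::setattr(x, "cluster_window", cluster_window)
    x
  }
  if (nrow(lab) < 2L) return(cls(empty))
  setorder(lab, read_id, qstart, ref_start)
  # adjacent labelled segment pairs within each read, without per-group work
  n <- nrow(lab)
  iL <- seq_len(n - 1L)
  iR <- iL + 1L
  el <- .edge_left(lab$strand, lab$ref_start, lab$ref_end)
  er <- .edge_right(lab$strand, lab$ref_start, lab$ref_end)
  pr <- data.table(
    read_id = lab$read_id[iL],
    gL = lab$gene_id[iL], gR = lab$gene_id[iR],
    sL = lab$strand[iL], sR = lab$strand[iR],
    gsL = lab$gene_strand[iL], gsR = lab$gene_strand[iR],
    cL = lab$chrom[iL], cR = lab$chrom[iR],
    eL = el[iL], eR = er[iR],
    aL = lab$aligned_ref_bases[iL], aR = lab$aligned_ref_bases[iR]
  )
  pr <- pr[lab$read_id[iL] == lab$read_id[iR] & gL != gR]
  if (!nrow(pr)) return(cls(empty))
  anti <- pr$sL != pr$gsL & pr$sR != pr$gsR
  ev <- data.table(
    read_id = pr$read_id,
    gene5 = ifelse(anti, pr$gR, pr$gL),
    gene3 = ifelse(anti, pr$gL, pr$gR),
    chrom5 = ifelse(anti, pr$cR, pr$cL),
    chrom3 = ifelse(anti, pr$cL, pr$cR),
    bp5 = as.integer(ifelse(anti, pr$eR, pr$eL)),
    bp3 = as.integer(ifelse(anti, pr$eL, pr$eR)),
    len5 = as.integer(ifelse(anti, pr$aR, pr$aL)),
    len3 = as.integer(ifelse(anti, pr$aL, pr$aR))
  )
  # one evidence row per (pair, read): a read counts once per ordered pair
  setorder(ev, gene5, gene3, read_id, bp5, bp3)
  ev <- unique(ev, by = c("gene5", "gene3", "read_id"))
  # single-linkage clustering: split sorted breakpoints at gaps > window,
  # on the 5' coordinate first, then on the 3' coordinate within
  ev[, cl5 := {
    o <- order(bp5)
    g <- cumsum(c(1L, diff(bp5[o]) > cluster_window))
    g[order(o)]
  }, by = list(gene5, gene3)]
  ev[, cl3 := {
    o <- order(bp3)
    g <- cumsum(c(1L, diff(bp3[o]) > cluster_window))
    g[order(o)]
  }, by = list(gene5, gene3, cl5)]
  out <- ev[, {
    list(
      chrom5 = chrom5[1L], bp5 = as.integer(round(median(bp5))),
      chrom3 = chrom3[1L], bp3 = as.integer(round(median(bp3))),
      n_support = data.table::uniqueN(read_id),
      breakpoint_cluster_span = max(max(bp5) - min(bp5), max(bp3) - min(bp3)),
      supporting_reads = list(sort(unique(read_id))),
      reads = list(data.table(read_id = read_id, bp5 = bp5, bp3 = bp3,
                              len5 = len5, len3 = len3))
    )
  }, by = list(gene5, gene3, cl5, cl3)]
  out[, c("cl5", "cl3") := NULL]
  setorder(out, -n_support, gene5, gene3, bp5, bp3)
  cls(out[])
}

#' Filter fusion candidates into calls
#'
#' Applies, in order, the false-positive filters of the pipeline; the first
#' failure is recorded in `status` and filters already passed in
#' `filters_passed`:
#'
#' 1. `panel_anchor` - at least one partner must be a panel gene (capture
#'    targets one partner; anything else is alignment noise);
#' 2. `min_support` - at least `min_support` supporting reads;
#' 3. `read_through` - same chromosome, same annotated gene strand and gene
#'    spans separated by less than `readthrough_distance` is the signature
#'    of transcriptional read-through, not rearrangement; rejected unless
#'    both partners are panel genes;
#' 4. `overlapping_genes` - partners whose merged exon regions intersect
#'    cannot be distinguished from ambiguous alignment;
#' 5. `segment_length` - a supporting read only counts if both flanking
#'    segments have at least `min_segment` aligned reference bases; the
#'    surviving support must still reach `min_support`.
#'
#' @param candidates `fusion_candidates` from [call_candidates()].
#' @param index The `gene_index` used for labelling (provides gene spans and
#'   strands).
#' @param panel A `target_panel` (defines panel membership).
#' @param min_support Minimum supporting reads (default 3).
#' @param readthrough_distance Read-through span threshold in bp
#'   (default 1e5).
#' @param min_segment Minimum aligned reference bases per flanking segment
#'   (default 100).
#' @param enabled Character vector of filters to apply; any subset of the
#'   five names above (all by default). Each filter is individually
#'   switchable.
#' @return `data.table` of class `fusion_calls`: candidates plus
#'   `n_support` (eligible reads for PASS calls), `fusion_frequency`
#'   (`NA` until [fusion_frequency()]), `status` (`"PASS"` or
#'   `"FILTERED:<reason>"`) and `filters_passed`.
#' @export
filter_candidates <- function(candidates, index, panel,
                              min_support = 3,
                              readthrough_distance = 1e5,
                              min_segment = 100,
                              enabled = c("panel_anchor", "min_support",
                                          "read_through", "overlapping_genes",
                                          "segment_length")) {
  stopifnot(inherits(candidates, "fusion_candidates"),
            inherits(index, "gene_index"), inherits(panel, "target_panel"))
  pids <- panel_gene_ids(panel)
  gt <- index$genes
  out <- data.table::copy(candidates)
  data.table::setattr(out, "class",
                      setdiff(class(out), "fusion_candidates"))
  n <- nrow(out)
  status <- rep("PASS", n)
  passed <- vector("list", n)
  n_eff <- out$n_support
  gene_regions <- S4Vectors::split(index$regions, index$regions$gene_id)
  for (i in seq_len(n)) {
    g5 <- out$gene5[i]; g3 <- out$gene3[i]
    ok <- character(0)
    fail <- NULL
    r5 <- gt[gene_id == g5]; r3 <- gt[gene_id == g3]
    for (f in c("panel_anchor", "min_support", "read_through",
                "overlapping_genes", "segment_length")) {
      if (!f %in% enabled) next
      bad <- switch(f,
        panel_anchor = !(g5 %in% pids || g3 %in% pids),
        min_support = out$n_support[i] < min_support,
        read_through = {
          both_panel <- g5 %in% pids && g3 %in% pids
          same <- nrow(r5) && nrow(r3) && r5$chrom == r3$chrom &&
            r5$strand == r3$strand
          if (same && !both_panel) {
            gap <- max(0, max(r5$span_start, r3$span_start) -
                         min(r5$span_end, r3$span_end) - 1)
            gap < readthrough_distance
          } else FALSE
        },
        overlapping_genes = {
          if (g5 %in% names(gene_regions) && g3 %in% names(gene_regions)) {
            length(suppressWarnings(GenomicRanges::findOverlaps(
              gene_regions[[g5]], gene_regions[[g3]], ignore.strand = TRUE
            ))) > 0L
          } else FALSE
        },
        segment_length = {
          rd <- out$reads[[i]]
          elig <- rd[len5 >= min_segment & len3 >= min_segment]
          n_eff[i] <- data.table::uniqueN(elig$read_id)
          n_eff[i] < min_support
        }
      )
      if (isTRUE(bad)) { fail <- f; break }
      ok <- c(ok, f)
    }
    status[i] <- if (is.null(fail)) "PASS" else paste0("FILTERED:", fail)
    passed[[i]] <- ok
  }
  out[, n_support := ifelse(status == "PASS", n_eff, n_support)]
  out[, status := status]
  out[, filters_passed := vapply(passed, paste, "", collapse = ",")]
  out[, fusion_frequency := NA_real_]
  data.table::setattr(out, "class", c("fusion_calls", class(out)))
  out[]
}

#' Fusion frequency of a call
#'
#' The fraction of reads at the fusion locus that support the fusion:
#' `n_support / n_locus`, where `n_locus` counts the distinct (QC-passed)
#' reads whose alignment span overlaps a window of `+/- window` bp around
#' the *panel-gene* breakpoint, supporting and non-supporting alike. A
#' qualitative abundance proxy, not a quantitative tumour fraction.
#'
#' @param calls A `fusion_calls` table.
#' @param chains The (QC-passed) `read_chains` the calls were made from.
#' @param panel The `target_panel`.
#' @param window Half-window in bp (default 50).
#' @return The `calls` table with `fusion_frequency` filled in for PASS
#'   calls (fraction in \[0,1\]; `NA` when no read overlaps the locus).
#' @export
fusion_frequency <- function(calls, chains, panel, window = 50) {
  stopifnot(inherits(calls, "fusion_calls"), inherits(chains, "read_chains"))
  pids <- panel_gene_ids(panel)
  seg <- chains$segments
  for (i in seq_len(nrow(calls))) {
    if (calls$status[i] != "PASS") next
    if (calls$gene5[i] %in% pids) {
      bc <- calls$chrom5[i]; bp <- calls$bp5[i]
    } else if (calls$gene3[i] %in% pids) {
      bc <- calls$chrom3[i]; bp <- calls$bp3[i]
    } else {
      next
    }
    n_locus <- data.table::uniqueN(
      seg[chrom == bc & ref_start <= bp + window & ref_end >= bp - window, read_id]
    )
    calls[i, fusion_frequency := if (n_locus > 0L) n_support / n_locus else NA_real_]
  }
  calls[]
}

#' End-to-end fusion calling
#'
#' Convenience wrapper: label chains, call candidates, filter them and
#' compute fusion frequencies.
#'
#' @param chains `read_chains` (restrict to QC-passed reads first, see
#'   [subset_chains()]).
#' @param index `gene_index` over all annotated genes.
#' @param panel `target_panel`.
#' @param min_overlap,cluster_window,min_support,readthrough_distance,min_segment,enabled
#'   Passed to [assign_genes()], [call_candidates()] and
#'   [filter_candidates()].
#' @param frequency_window Passed to [fusion_frequency()].
#' @return A `fusion_calls` table.
#' @export
call_fusions <- function(chains, index, panel,
                         min_overlap = 100, cluster_window = 50,
                         min_support = 3, readthrough_distance = 1e5,
                         min_segment = 100,
                         enabled = c("panel_anchor", "min_support",
                                     "read_through", "overlapping_genes",
                                     "segment_length"),
                         frequency_window = 50) {
  labelled <- assign_genes(chains, index, min_overlap = min_overlap)
  cand <- call_candidates(labelled, cluster_window = cluster_window)
  calls <- filter_candidates(cand, index, panel, min_support = min_support,
                             readthrough_distance = readthrough_distance,
                             min_segment = min_segment, enabled = enabled)
  fusion_frequency(calls, labelled, panel, window = frequency_window)
}

#' Write fusion calls as TSV
#'
#' Columns: `gene5 gene3 chrom5 bp5 chrom3 bp3 n_support fusion_frequency
#' status filters`; breakpoints 1-based; `fusion_frequency` in percent.
#'
#' @param calls A `fusion_calls` table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fusion_tsv <- function(calls, path) {
  dt <- data.table(
    gene5 = calls$gene5, gene3 = calls$gene3,
    chrom5 = calls$chrom5, bp5 = calls$bp5,
    chrom3 = calls$chrom3, bp3 = calls$bp3,
    n_support = calls$n_support,
    fusion_frequency = round(100 * calls$fusion_frequency, 4),
    status = calls$status, filters = calls$filters_passed
  )
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
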