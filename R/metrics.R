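#' Per-base depth over target regions
#'
#' Depth counts aligned reference bases (CIGAR `M`/`=`/`X`) of every kept
#' alignment record, supplementary included (capture-efficiency semantics:
#' each aligned base is evidence of a captured molecule). Deletions and
#' intron gaps (`D`/`N`) do not contribute.
#'
#' @param chains A `read_chains` object (or its `segments` table).
#' @param regions Target regions as a [GenomicRanges::GRanges] (e.g.
#'   `panel$regions`).
#' @return Object of class `depth_profile`: list with `coverage` (an
#'   [IRanges::RleList] keyed by chromosome) and `regions`.
#' @export
depth_profile <- function(chains, regions) {
  seg <- if (inherits(chains, "read_chains")) chains$segments else chains
  blocks <- .ref_blocks(seg)
  cov <- GenomicRanges::coverage(blocks)
  structure(list(coverage = cov, regions = regions), class = "depth_profile")
}

# integer depth vector for one region (zero-filled past coverage end)
.region_depth <- function(profile, chrom, start, end) {
  cov <- profile$coverage
  out <- integer(end - start + 1L)
  if (!chrom %in% names(cov)) return(out)
  r <- cov[[chrom]]
  n <- length(r)
  if (start > n) return(out)
  e <- min(end, n)
  out[seq_len(e - start + 1L)] <- as.integer(S4Vectors::window(r, start, e))
  out
}

#' Per-region depth vectors
#' @param profile A `depth_profile`.
#' @return List of integer vectors, one per target region, in region order.
#' @export
region_depths <- function(profile) {
  r <- profile$regions
  lapply(seq_along(r), function(i) {
    .region_depth(profile, as.character(GenomicRanges::seqnames(r))[i],
                  GenomicRanges::start(r)[i], GenomicRanges::end(r)[i])
  })
}

#' Breadth of coverage at a depth threshold
#'
#' Fraction of target bases with depth at least `threshold`. Monotone
#' non-increasing in the threshold; `threshold = 0` is always 1.
#'
#' @param profile A `depth_profile`.
#' @param threshold Depth threshold (e.g. 1 or 500).
#' @return Fraction in \[0,1\].
#' @export
breadth <- function(profile, threshold) {
  d <- region_depths(profile)
  total <- sum(lengths(d))
  if (total == 0L) stop("empty target regions")
  sum(vapply(d, function(v) sum(v >= threshold), 0L)) / total
}

#' Capture rate
#'
#' Fraction of aligned bases (reference-consuming, CIGAR `M`/`=`/`X`)
#' falling inside the merged target regions. Capture rate plus off-target
#' fraction is exactly 1.
#'
#' @param chains A `read_chains` object.
#' @param panel A `target_panel` (or a GRanges of target regions).
#' @return Fraction in \[0,1\]; `NA` when there are no aligned bases.
#' @export
capture_rate <- function(chains, panel) {
  regions <- if (inherits(panel, "target_panel")) panel$regions else panel
  target <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  blocks <- .ref_blocks(if (inherits(chains, "read_chains")) chains$segments else chains)
  total <- sum(IRanges::width(blocks))
  if (total == 0) return(NA_real_)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(blocks, target, ignore.strand = TRUE)
  )
  on <- if (length(ov)) {
    sum(IRanges::width(IRanges::pintersect(
      IRanges::ranges(blocks)[S4Vectors::queryHits(ov)],
      IRanges::ranges(target)[S4Vectors::subjectHits(ov)]
    )))
  } else 0
  on / total
}

#' Normalized depth at 1000x
#'
#' `1000 * gene_mean_depth / panel_mean_depth`: the gene's average target
#' depth rescaled so a gene at the panel average reads exactly 1000. A
#' relative capture/expression measure comparable across libraries of
#' different yield.
#'
#' @param gene_mean_depth Numeric (vectorised over genes).
#' @param panel_mean_depth Positive scalar.
#' @return Numeric of the same length as `gene_mean_depth`.
#' @export
normalized_depth_1000x <- function(gene_mean_depth, panel_mean_depth) {
  stopifnot(length(panel_mean_depth) == 1L)
  if (!is.finite(panel_mean_depth) || panel_mean_depth <= 0) {
    stop("panel_mean_depth must be > 0")
  }
  1000 * gene_mean_depth / panel_mean_depth
}

#' Expression-outlier flags from normalized depths
#'
#' A panel gene is flagged when its normalized depth exceeds `k` times the
#' median normalized depth of the *other* panel genes. Rationale: a CRLF2-
#' class rearrangement with an uncapturable partner (e.g. an IGH enhancer
#' fusion) produces no chimeric reads but grossly elevated target-gene
#' expression; the flag surfaces such samples for orthogonal testing.
#'
#' @param normalized_depths Named numeric vector (>= 2 genes).
#' @param k Fold threshold (default 5); `Inf` disables flagging.
#' @return Named logical vector.
#' @export
expression_outlier_flags <- function(normalized_depths, k = 5) {
  stopifnot(length(normalized_depths) >= 2L)
  if (!is.finite(k)) {
    return(stats::setNames(rep(FALSE, length(normalized_depths)),
                               names(normalized_depths)))
  }
  flags <- vapply(seq_along(normalized_depths), function(i) {
    normalized_depths[i] > k * median(normalized_depths[-i])
  }, NA)
  stats::setNames(flags, names(normalized_depths))
}

#' Fusion yield of a library
#'
#' @param n_fusion_support_reads Count of fusion-supporting reads.
#' @param qc_mb Clean (QC-passed) bases in megabases.
#' @return Object of class `fusion_yield`.
#' @export
fusion_yield <- function(n_fusion_support_reads, qc_mb) {
  stopifnot(n_fusion_support_reads >= 0, qc_mb >= 0)
  structure(list(n_fusion_support_reads = n_fusion_support_reads,
                 qc_mb = qc_mb), class = "fusion_yield")
}

#' Enrichment fold of a targeted versus a non-targeted library
#'
#' Ratio of fusion-supporting reads per megabase of clean bases:
#' `(targeted$n / targeted$qc_mb) / (background$n / background$qc_mb)`.
#' Invariant under joint rescaling of both `qc_mb`. `NA` when the
#' background library yields zero fusion-supporting reads (the fold is then
#' unbounded).
#'
#' @param targeted,background `fusion_yield` objects.
#' @return Positive numeric fold, or `NA`.
#' @export
enrichment_fold <- function(targeted, background) {
  stopifnot(inherits(targeted, "fusion_yield"),
            inherits(background, "fusion_yield"))
  if (targeted$qc_mb <= 0 || background$qc_mb <= 0) {
    stop("qc_mb must be positive in both libraries")
  }
  if (background$n_fusion_support_reads == 0) return(NA_real_)
  (targeted$n_fusion_support_reads / targeted$qc_mb) /
    (background$n_fusion_support_reads / background$qc_mb)
}

#' Panel QC report
#'
#' Capture rate, per-gene and panel mean target depth, breadth at 1x and at
#' `breadth_threshold`, normalized depth at 1000x and expression-outlier
#' flags, in one pass over the alignments.
#'
#' @param chains A `read_chains` object (QC-passed reads).
#' @param panel A `target_panel`.
#' @param breadth_threshold Depth threshold for the second breadth metric
#'   (default 500).
#' @param outlier_k Fold threshold for [expression_outlier_flags()].
#' @return Object of class `panel_qc`: list with `capture_rate`,
#'   `panel_mean_depth`, `breadth_1x`, `breadth_500x`, and `per_gene`
#'   (`data.table`: `gene_id, target_bases, mean_depth, breadth_1x,
#'   breadth_500x, normalized_depth_1000x, outlier`).
#' @export
panel_qc <- function(chains, panel, breadth_threshold = 500, outlier_k = 5) {
  stopifnot(inherits(panel, "target_panel"))
  prof <- depth_profile(chains, panel$regions)
  d <- region_depths(prof)
  gid <- panel$regions$gene_id
  dt <- data.table(
    gene_id = rep(gid, lengths(d)),
    depth = unlist(d, use.names = FALSE)
  )
  per_gene <- dt[, list(
    target_bases = .N,
    mean_depth = mean(depth),
    breadth_1x = mean(depth >= 1),
    breadth_500x = mean(depth >= breadth_threshold)
  ), by = gene_id]
  panel_mean <- mean(dt$depth)
  per_gene[, normalized_depth_1000x := if (panel_mean > 0)
    normalized_depth_1000x(mean_depth, panel_mean) else NA_real_]
  nd <- stats::setNames(per_gene$normalized_depth_1000x, per_gene$gene_id)
  per_gene[, outlier := if (length(nd) >= 2L && panel_mean > 0)
    as.logical(expression_outlier_flags(nd, k = outlier_k)) else FALSE]
  structure(list(
    capture_rate = capture_rate(chains, panel),
    panel_mean_depth = panel_mean,
    breadth_1x = sum(dt$depth >= 1) / nrow(dt),
    breadth_500x = sum(dt$depth >= breadth_threshold) / nrow(dt),
    breadth_threshold = breadth_threshold,
    per_gene = per_gene[]
  ), class = "panel_qc")
}

#' @export
print.panel_qc <- function(x, ...) {
  cat(sprintf("panel_qc: capture rate %.2f%%, panel mean depth %.1fx, breadth 1x %.2f%%, breadth %dx %.2f%%\n",
              100 * x$capture_rate, x$panel_mean_depth, 100 * x$breadth_1x,
              x$breadth_threshold, 100 * x$breadth_500x))
  print(x$per_gene)
  invisible(x)
}

#' Write a panel QC report as JSON (plus optional per-gene TSV)
#'
#' @param qc A `panel_qc` object.
#' @param path Output JSON path.
#' @param tsv Optional per-gene TSV path.
#' @return Invisibly, `path`.
#' @export
write_panel_qc <- function(qc, path, tsv = NULL) {
  obj <- list(
    capture_rate = qc$capture_rate,
    panel_mean_depth = qc$panel_mean_depth,
    breadth_1x = qc$breadth_1x,
    breadth_500x = qc$breadth_500x,
    breadth_threshold = qc$breadth_threshold,
    per_gene = qc$per_gene
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(tsv)) fwrite(qc$per_gene, tsv, sep = "\t")
  invisible(path)
}
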