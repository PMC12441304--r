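#' @importFrom data.table data.table setorder := setDT rbindlist fwrite fread
#' @importFrom stats median rbinom rnorm runif
#' @importFrom utils head tail
NULL

#' Default target panel gene symbols
#'
#' The seven kinase / cytokine-receptor genes whose rearrangements drive the
#' large majority of Ph-like B-ALL cases: the ABL-class genes (ABL1, ABL2,
#' CSF1R, PDGFRB) and the JAK/STAT-class genes (JAK2, EPOR, CRLF2). Capture
#' anchors one fusion partner; long reads crossing the junction reveal the
#' other.
#'
#' @return Character vector of gene symbols.
#' @export
default_panel_genes <- function() {
  c("ABL2", "CSF1R", "PDGFRB", "JAK2", "ABL1", "EPOR", "CRLF2")
}

#' Construct a gene model
#'
#' A gene model pools the exons of all annotated transcripts of one gene on
#' one chromosome. Exon intervals are 1-based closed ([IRanges::IRanges]);
#' duplicates (identical exons shared between transcripts) are removed.
#'
#' @param gene_id Stable gene identifier (key; collisions in `gene_name` are
#'   allowed).
#' @param gene_name Display symbol; defaults to `gene_id`.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons [IRanges::IRanges] of exon intervals (non-empty).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, gene_name = gene_id, chrom, strand = "+", exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  stopifnot(strand %in% c("+", "-"))
  if (!methods::is(exons, "IRanges")) {
    exons <- IRanges::IRanges(start = exons[, 1L], end = exons[, 2L])
  }
  if (length(exons) == 0L) stop("gene model '", gene_id, "' has no exons")
  exons <- BiocGenerics::sort(BiocGenerics::unique(exons))
  structure(
    list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
         strand = strand, exons = exons),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%d-%d [%s], %d exon(s)\n",
              x$gene_id, x$gene_name, x$chrom,
              min(IRanges::start(x$exons)), max(IRanges::end(x$exons)),
              x$strand, length(x$exons)))
  invisible(x)
}

#' Read gene models from a GTF annotation
#'
#' Parses a GTF stream and returns one [gene_model()] per `gene_id`, pooling
#' the exons of all transcripts (duplicates removed). Genes that carry no
#' `exon` feature are excluded with a warning. Malformed lines (fewer than 9
#' tab-separated fields) raise an error naming the line number.
#'
#' @param path Path to a GTF file (plain or gzip).
#' @return Named list of `gene_model` objects, keyed and ordered by
#'   first-appearance `gene_id`.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body)) {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nf < 9L]
    if (length(bad)) {
      stop(sprintf("malformed GTF line %d in '%s': expected 9 tab-separated fields",
                   bad[1L], path))
    }
  }
  if (!length(body)) return(structure(list(), names = character(0)))
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$gene_id)) stop("GTF has no gene_id attributes: ", path)
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  all_ids <- unique(gr$gene_id)
  ex_ids <- unique(ex$gene_id)
  dropped <- setdiff(all_ids, ex_ids)
  if (length(dropped)) {
    warning("excluding gene(s) with no exon features: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(ex)) return(structure(list(), names = character(0)))
  # preserve first-appearance order
  ids <- ex_ids
  spl <- S4Vectors::split(ex, factor(ex$gene_id, levels = ids))
  models <- lapply(ids, function(id) {
    g <- spl[[id]]
    chroms <- unique(as.character(GenomicRanges::seqnames(g)))
    if (length(chroms) > 1L) {
      stop("gene '", id, "' has exons on multiple chromosomes: ",
           paste(chroms, collapse = ", "))
    }
    nm <- if (!is.null(g$gene_name)) g$gene_name[!is.na(g$gene_name)][1L] else NA
    gene_model(
      gene_id = id,
      gene_name = if (is.na(nm) || is.null(nm)) id else nm,
      chrom = chroms,
      strand = as.character(GenomicRanges::strand(g))[1L],
      exons = IRanges::ranges(g)
    )
  })
  names(models) <- ids
  models
}

#' Merge the exon pool of a gene into disjoint capture regions
#'
#' Returns the minimal set of disjoint, sorted intervals covering exactly the
#' union of exon bases. Book-ended intervals (e.g. 1-based `[100,199]` and
#' `[200,249]`) are merged: capture regions are contiguous DNA.
#'
#' @param x A `gene_model` or an [IRanges::IRanges].
#' @return [IRanges::IRanges] of merged regions.
#' @export
merge_exons <- function(x) {
  ir <- if (inherits(x, "gene_model")) x$exons else x
  IRanges::reduce(BiocGenerics::sort(ir))
}

#' Build a target capture panel from gene models
#'
#' Restricts `genes` to the panel gene set (matched on `gene_name`, falling
#' back to `gene_id`) and merges each panel gene's exons into disjoint target
#' regions, mirroring probe design against the union of all transcript exons.
#'
#' @param genes Named list of `gene_model` objects.
#' @param panel_genes Character vector of panel gene symbols; defaults to
#'   [default_panel_genes()].
#' @return An object of class `target_panel` with elements `genes` (the panel
#'   gene models), `regions` (a [GenomicRanges::GRanges] with `gene_id` and
#'   `gene_name` metadata; disjoint and sorted within each gene) and
#'   `total_target_bases`.
#' @export
target_panel <- function(genes, panel_genes = default_panel_genes()) {
  stopifnot(length(genes) > 0L)
  nm <- vapply(genes, `[[`, "", "gene_name")
  id <- vapply(genes, `[[`, "", "gene_id")
  sel <- nm %in% panel_genes | id %in% panel_genes
  missing <- setdiff(panel_genes, c(nm[sel], id[sel]))
  if (length(missing)) {
    warning("panel gene(s) absent from annotation: ",
            paste(missing, collapse = ", "))
  }
  if (!any(sel)) stop("no panel genes found in annotation")
  pg <- genes[sel]
  regs <- lapply(pg, function(g) {
    r <- merge_exons(g)
    GenomicRanges::GRanges(
      seqnames = g$chrom, ranges = r, strand = g$strand,
      gene_id = g$gene_id, gene_name = g$gene_name
    )
  })
  regions <- suppressWarnings(
    unlist(methods::as(regs, "GRangesList"), use.names = FALSE)
  )
  structure(
    list(genes = pg, regions = regions,
         total_target_bases = sum(IRanges::width(regions))),
    class = "target_panel"
  )
}

#' @export
print.target_panel <- function(x, ...) {
  cat(sprintf("target_panel: %d gene(s), %d region(s), %d target bases\n",
              length(x$genes), length(x$regions), x$total_target_bases))
  invisible(x)
}

panel_gene_ids <- function(panel) {
  vapply(panel$genes, `[[`, "", "gene_id")
}

#' Build a gene interval index
#'
#' Indexes the merged exon regions of every gene for fast interval-to-gene
#' lookup ([query_index()]) and segment gene assignment ([assign_genes()]).
#'
#' @param genes Named list of `gene_model` objects, or a `target_panel` (its
#'   genes are indexed).
#' @return An object of class `gene_index`: list with `regions` (GRanges with
#'   `gene_id`, `gene_name`, `gene_strand`) and `genes` (a `data.table` of
#'   per-gene chromosome, strand and span).
#' @export
build_index <- function(genes) {
  if (inherits(genes, "target_panel")) genes <- genes$genes
  stopifnot(length(genes) > 0L)
  regs <- lapply(genes, function(g) {
    r <- merge_exons(g)
    GenomicRanges::GRanges(
      seqnames = g$chrom, ranges = r, strand = "*",
      gene_id = g$gene_id, gene_name = g$gene_name, gene_strand = g$strand
    )
  })
  regions <- suppressWarnings(
    unlist(methods::as(regs, "GRangesList"), use.names = FALSE)
  )
  gtab <- data.table(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    gene_name = vapply(genes, `[[`, "", "gene_name"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    span_start = vapply(genes, function(g) min(IRanges::start(g$exons)), 0),
    span_end = vapply(genes, function(g) max(IRanges::end(g$exons)), 0)
  )
  structure(list(regions = regions, genes = gtab), class = "gene_index")
}

#' Query a gene index
#'
#' Returns every gene whose merged regions intersect the query interval, with
#' the exact number of overlapped bases. Unknown chromosomes yield an empty
#' result, not an error.
#'
#' @param index A `gene_index` from [build_index()].
#' @param chrom Chromosome name.
#' @param start,end Query interval, 1-based closed.
#' @return `data.table` with columns `gene_id`, `gene_name`, `overlap_bp`,
#'   sorted by decreasing overlap then `gene_id`.
#' @export
query_index <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "gene_index"), end >= start)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(q, index$regions, ignore.strand = TRUE)
  )
  if (!length(ov)) {
    return(data.table(gene_id = character(0), gene_name = character(0),
                      overlap_bp = integer(0)))
  }
  hit <- index$regions[S4Vectors::subjectHits(ov)]
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(hit),
                                          rep(IRanges::ranges(q), length(hit))))
  dt <- data.table(gene_id = hit$gene_id, gene_name = hit$gene_name, overlap_bp = w)
  dt <- dt[, list(overlap_bp = sum(overlap_bp)), by = list(gene_id, gene_name)]
  setorder(dt, -overlap_bp, gene_id)
  dt[]
}

#' Write a target panel as 4-column BED
#'
#' BED coordinates are 0-based half-open; the fourth column is the gene id.
#'
#' @param panel A `target_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel_bed <- function(panel, path) {
  r <- panel$regions
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(r)),
    start = GenomicRanges::start(r) - 1L,
    end = GenomicRanges::end(r),
    name = r$gene_id
  )
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read panel regions from a BED file
#'
#' @param path Path to a BED file (at least 4 columns; 0-based half-open).
#' @return [GenomicRanges::GRanges] with a `gene_id` metadata column.
#' @export
read_panel_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  gr$gene_id <- if (!is.null(gr$name)) gr$name else NA_character_
  gr$name <- NULL
  gr
}
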