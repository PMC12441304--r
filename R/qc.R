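#' Construct a read set
#'
#' A lightweight container for nanopore reads: identifier, nucleotide
#' sequence and a Phred+33 quality string of equal length.
#'
#' @param read_id Character vector of identifiers.
#' @param sequence Character vector of sequences (alphabet `A,C,G,T,N`).
#' @param quality Character vector of Phred+33 quality strings.
#' @return `data.table` of class `read_set` with those three columns.
#' @export
read_set <- function(read_id, sequence, quality) {
  stopifnot(length(read_id) == length(sequence),
            length(sequence) == length(quality))
  if (length(sequence) && any(nchar(sequence) != nchar(quality))) {
    stop("sequence and quality lengths differ")
  }
  dt <- data.table(read_id = as.character(read_id),
                   sequence = as.character(sequence),
                   quality = as.character(quality))
  data.table::setattr(dt, "class", c("read_set", class(dt)))
  dt
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d read(s), %.0f bases\n", nrow(x),
              sum(nchar(x$sequence))))
  if (nrow(x)) NextMethod()
  invisible(x)
}

#' Decode a Phred+33 quality string to integer scores
#' @param qstring A single quality string.
#' @return Integer vector of Phred scores.
#' @export
phred_decode <- function(qstring) {
  if (!nzchar(qstring)) return(integer(0))
  utf8ToInt(qstring) - 33L
}

#' Encode integer Phred scores as a Phred+33 string
#' @param q Integer vector of Phred scores.
#' @return A quality string.
#' @export
phred_encode <- function(q) {
  if (!length(q)) return("")
  intToUtf8(as.integer(q) + 33L)
}

#' Mean read quality on the Phred scale
#'
#' The mean is taken over error probabilities, not Phred scores:
#' `Q = -10 * log10(mean(10^(-q_i/10)))`. This matches the behaviour of the
#' standard nanopore read filters, and is what a "mean quality 7" threshold
#' refers to.
#'
#' @param q Integer/numeric vector of per-base Phred scores, or a single
#'   Phred+33 quality string.
#' @return Mean quality (Phred scale).
#' @export
mean_read_quality <- function(q) {
  if (is.character(q)) {
    stopifnot(length(q) == 1L)
    q <- phred_decode(q)
  }
  if (!length(q)) stop("empty quality vector")
  -10 * log10(mean(10^(-q / 10)))
}

# vectorised mean quality over a read_set (NA for zero-length reads)
.mean_qualities <- function(reads) {
  pow <- 10^(-(0:93) / 10)  # error probability lookup per Phred score
  vapply(reads$quality, function(s) {
    q <- utf8ToInt(s) - 32L  # 1-based into the lookup
    if (!length(q)) return(NA_real_)
    -10 * log10(sum(pow[q]) / length(q))
  }, 0, USE.NAMES = FALSE)
}

#' Filter reads by length and mean quality
#'
#' Removes reads shorter than `min_length` bases or with mean quality (error
#' probability average, see [mean_read_quality()]) below `min_quality`.
#' Thresholds are strict removals: reads exactly at `min_length` or at
#' `min_quality` are kept. With `min_length = 0, min_quality = 0` the filter
#' is the identity.
#'
#' @param reads A `read_set`.
#' @param min_length Minimum read length in bp (default 100).
#' @param min_quality Minimum mean Phred quality (default 7).
#' @return List with `kept` (a `read_set`) and `removed` (a `read_set` with
#'   an additional `reason` column: `"short"` or `"low_quality"`; length is
#'   checked first).
#' @export
filter_reads <- function(reads, min_length = 100, min_quality = 7) {
  stopifnot(inherits(reads, "read_set"))
  if (!nrow(reads)) {
    rem <- reads[0L]
    rem[, reason := character(0)]
    return(list(kept = reads, removed = rem))
  }
  len <- nchar(reads$sequence)
  short <- len < min_length
  mq <- rep(NA_real_, nrow(reads))
  need_q <- !short
  if (min_quality > 0) {
    mq[need_q] <- .mean_qualities(reads[which(need_q)])
  } else {
    mq[need_q] <- Inf
  }
  lowq <- !short & !(is.na(mq) | mq >= min_quality)
  # zero-length reads (empty quality): only removable via min_length
  keep <- !short & !lowq
  removed <- reads[which(!keep)]
  removed[, reason := if (nrow(removed)) ifelse(short[!keep], "short", "low_quality") else character(0)]
  list(kept = reads[which(keep)], removed = removed)
}

#' Summary statistics of a read set
#'
#' `n50` is the largest length L such that reads of length >= L sum to at
#' least half the total bases. `mean_quality` pools error probabilities over
#' all bases (length-weighted).
#'
#' @param reads A `read_set`.
#' @return List with `n_reads`, `total_bases`, `mean_length`, `n50`,
#'   `mean_quality`. An empty set yields zeros with `n50` and `mean_quality`
#'   `NA`.
#' @export
read_stats <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  if (!nrow(reads)) {
    return(list(n_reads = 0L, total_bases = 0, mean_length = 0,
                n50 = NA_real_, mean_quality = NA_real_))
  }
  len <- nchar(reads$sequence)
  total <- sum(len)
  slen <- sort(len, decreasing = TRUE)
  n50 <- slen[which(cumsum(slen) >= total / 2)[1L]]
  mq <- .mean_qualities(reads)
  p <- 10^(-mq / 10)
  ok <- !is.na(p)
  pooled <- if (any(ok)) sum(p[ok] * len[ok]) / sum(len[ok]) else NA_real_
  list(
    n_reads = nrow(reads),
    total_bases = total,
    mean_length = total / nrow(reads),
    n50 = as.numeric(n50),
    mean_quality = if (is.na(pooled)) NA_real_ else -10 * log10(pooled)
  )
}

#' Read a FASTQ file into a read set
#'
#' Four-line FASTQ records, Phred+33 quality encoding (universal for
#' nanopore basecallers); plain or gzip-compressed.
#'
#' @param path Path to a FASTQ(.gz) file.
#' @return A `read_set`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(x))
  read_set(
    read_id = ids,
    sequence = as.character(x, use.names = FALSE),
    quality = as.character(S4Vectors::mcols(x)$qualities, use.names = FALSE)
  )
}

#' Write a read set as FASTQ
#'
#' @param reads A `read_set`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(
    seqs, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
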