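#' Fusion specification for the simulator
#'
#' Describes one expressed fusion transcript: exons 1..`exon5` of `gene5`
#' joined to exons `exon3`..last of `gene3`, expressed at `frequency` (the
#' fraction of breakpoint-covering reads that carry the fusion).
#'
#' @param gene5,gene3 Gene names (5' and 3' partner in transcript order).
#' @param exon5 Last retained exon of the 5' partner (1-based).
#' @param exon3 First retained exon of the 3' partner (1-based).
#' @param frequency Fusion frequency in \[0,1\].
#' @return List of class `fusion_spec`.
#' @export
fusion_spec <- function(gene5, exon5, gene3, exon3, frequency) {
  stopifnot(frequency >= 0, frequency <= 1, exon5 >= 1, exon3 >= 1)
  structure(list(gene5 = gene5, exon5 = as.integer(exon5),
                 gene3 = gene3, exon3 = as.integer(exon3),
                 frequency = frequency), class = "fusion_spec")
}

#' Simulator configuration
#'
#' The stated world of the synthetic experiments: a two-chromosome
#' transcriptome (panel genes on `chrA`, partner genes on `chrB`, all on the
#' plus strand), targeted capture modelled as read thinning by
#' `on_target_fraction`, RIN-driven fragmentation with per-base cut
#' probability `cut_coef / rin^2`, nanopore-like substitution/indel errors
#' and per-read mean qualities drawn from a truncated normal.
#'
#' @param seed Integer RNG seed; a fixed seed makes every output
#'   byte-identical.
#' @param panel_genes Panel gene names (default [default_panel_genes()]).
#' @param partner_genes Off-panel partner gene names.
#' @param exons_per_gene,exon_len,intron_len,intergenic_len Integer ranges
#'   `c(lo, hi)` sampled per gene/exon/intron/gap.
#' @param fusion_specs List of [fusion_spec()] objects. The default is one
#'   inter-chromosomal kinase fusion (`BCR::ABL1`-like) at frequency 0.1,
#'   the order of magnitude of a typical fusion-positive diagnostic sample.
#' @param readthrough_specs List of `list(gene5=, gene3=, n_reads=)` entries
#'   injecting read-through chimeras between two same-chromosome genes
#'   (false-positive material for the caller's filters). Default none.
#' @param n_reads Number of reads to draw.
#' @param rin RNA integrity number in \[1,10\] (default 7, an intact
#'   clinical specimen).
#' @param cut_coef Degradation coefficient `c` in `p = c / rin^2`
#'   (default 0.002).
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities (each in
#'   \[0,0.2\]); defaults 0.02/0.01/0.01, a ~4% total error rate typical of
#'   recent nanopore basecalls. In [simulate_sample()] these set the error
#'   *proportions*; each read's total error rate follows its drawn mean
#'   quality.
#' @param mean_quality,sd_quality,quality_range Per-read mean-Q draw:
#'   normal(`mean_quality`, `sd_quality`) truncated to `quality_range`
#'   (defaults 12, 2, \[4,20\] - the typical nanopore range).
#' @param on_target_fraction Fraction of reads drawn from panel genes
#'   (capture stringency; default 0.6, matching mid-range capture rates of
#'   targeted long-read libraries).
#' @param min_fragment Minimum fragment size in bp retained by library
#'   construction (default 200).
#' @param antisense_fraction Fraction of reads sequenced in reverse
#'   complement (default 0.5; cDNA reads come in both orientations).
#' @param emit_reads Generate the error-bearing FASTQ reads (default
#'   `TRUE`). `FALSE` skips error/quality generation (`reads` is then an
#'   empty `read_set`) for caller-only replicate studies where only the
#'   truth alignments are consumed; truth and SAM are unchanged because the
#'   error draws consume the RNG stream last.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       panel_genes = default_panel_genes(),
                       partner_genes = c("BCR", "ETV6", "P2RY8", "NUP214", "PAX5"),
                       exons_per_gene = c(3L, 8L),
                       exon_len = c(120L, 400L),
                       intron_len = c(200L, 1500L),
                       intergenic_len = c(5000L, 15000L),
                       fusion_specs = list(fusion_spec("BCR", 2L, "ABL1", 2L, 0.1)),
                       readthrough_specs = list(),
                       n_reads = 2000L,
                       rin = 7,
                       cut_coef = 0.002,
                       sub_rate = 0.02, ins_rate = 0.01, del_rate = 0.01,
                       mean_quality = 12, sd_quality = 2,
                       quality_range = c(4, 20),
                       on_target_fraction = 0.6,
                       min_fragment = 200L,
                       antisense_fraction = 0.5,
                       emit_reads = TRUE) {
  stopifnot(rin >= 1, rin <= 10,
            sub_rate >= 0, sub_rate <= 0.2,
            ins_rate >= 0, ins_rate <= 0.2,
            del_rate >= 0, del_rate <= 0.2,
            on_target_fraction >= 0, on_target_fraction <= 1,
            antisense_fraction >= 0, antisense_fraction <= 1,
            n_reads >= 0, min_fragment >= 1)
  for (fs in fusion_specs) stopifnot(inherits(fs, "fusion_spec"))
  cfg <- list(seed = as.integer(seed), panel_genes = panel_genes,
              partner_genes = partner_genes,
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              intergenic_len = as.integer(intergenic_len),
              fusion_specs = fusion_specs,
              readthrough_specs = readthrough_specs,
              n_reads = as.integer(n_reads), rin = rin, cut_coef = cut_coef,
              sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
              mean_quality = mean_quality, sd_quality = sd_quality,
              quality_range = quality_range,
              on_target_fraction = on_target_fraction,
              min_fragment = as.integer(min_fragment),
              antisense_fraction = antisense_fraction,
              emit_reads = emit_reads)
  structure(cfg, class = "sim_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.sample_range <- function(range, n) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

# gene placement on one chromosome; returns list(models, chrom_len)
.place_genes <- function(cfg, names, chrom, strand = "+") {
  cur <- 1L
  models <- vector("list", length(names))
  for (i in seq_along(names)) {
    cur <- cur + .sample_range(cfg$intergenic_len, 1L)
    n_ex <- .sample_range(cfg$exons_per_gene, 1L)
    ex_w <- .sample_range(cfg$exon_len, n_ex)
    in_w <- if (n_ex > 1L) .sample_range(cfg$intron_len, n_ex - 1L) else integer(0)
    starts <- integer(n_ex)
    ends <- integer(n_ex)
    p <- cur
    for (j in seq_len(n_ex)) {
      starts[j] <- p
      ends[j] <- p + ex_w[j] - 1L
      p <- ends[j] + (if (j < n_ex) in_w[j] else 0L) + 1L
    }
    models[[i]] <- gene_model(gene_id = names[i], gene_name = names[i],
                              chrom = chrom, strand = strand,
                              exons = IRanges::IRanges(starts, ends))
    cur <- ends[n_ex]
  }
  list(models = stats::setNames(models, names),
       chrom_len = cur + .sample_range(cfg$intergenic_len, 1L))
}

.sim_reference_impl <- function(cfg) {
  a <- .place_genes(cfg, cfg$panel_genes, "chrA")
  b <- if (length(cfg$partner_genes)) {
    .place_genes(cfg, cfg$partner_genes, "chrB")
  } else NULL
  genes <- c(a$models, if (!is.null(b)) b$models)
  lens <- c(chrA = a$chrom_len, if (!is.null(b)) c(chrB = b$chrom_len))
  genome <- Biostrings::DNAStringSet(vapply(lens, .rand_dna, ""))
  names(genome) <- names(lens)
  panel <- target_panel(genes, panel_genes = cfg$panel_genes)
  structure(list(genome = genome, genes = genes, panel = panel, config = cfg),
            class = "sim_reference")
}

#' Simulate a reference: genome, annotation and capture panel
#'
#' Places the configured genes without overlap (panel genes on `chrA`,
#' partner genes on `chrB`), draws a random genome and derives the
#' merged-exon target panel. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_reference`: list with `genome`
#'   ([Biostrings::DNAStringSet]), `genes` (named list of `gene_model`),
#'   `panel` (`target_panel`) and `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .sim_reference_impl(config))
}

# ---- transcript machinery ---------------------------------------------------

# transcript = contiguous tx coordinate system over genomic exon blocks
# segments: data.table(chrom, start, end, tx_start, tx_end, part)
.tx_from_blocks <- function(tx_id, gene, segs, genome, junction = NA_integer_,
                            gene5 = NA_character_, gene3 = NA_character_,
                            bp5 = NA_integer_, bp3 = NA_integer_,
                            kind = "wt") {
  w <- segs$end - segs$start + 1L
  segs$tx_end <- cumsum(w)
  segs$tx_start <- segs$tx_end - w + 1L
  seqs <- vapply(seq_len(nrow(segs)), function(i) {
    as.character(Biostrings::subseq(genome[[segs$chrom[i]]],
                                    segs$start[i], segs$end[i]))
  }, "")
  list(tx_id = tx_id, gene = gene, segments = segs, L = sum(w),
       seq = paste(seqs, collapse = ""), junction = junction,
       gene5 = gene5, gene3 = gene3, bp5 = bp5, bp3 = bp3, kind = kind)
}

.wt_transcript <- function(ref, gene_name) {
  g <- ref$genes[[gene_name]]
  if (is.null(g)) stop("unknown gene: ", gene_name)
  segs <- data.table(chrom = g$chrom,
                     start = IRanges::start(g$exons),
                     end = IRanges::end(g$exons),
                     part = "5")
  .tx_from_blocks(paste0("wt:", gene_name), gene_name, segs, ref$genome)
}

#' Construct a fusion transcript from a simulated reference
#'
#' Concatenates exons 1..`exon5` of the 5' partner with exons
#' `exon3`..last of the 3' partner and records the genomic junction
#' coordinates: `bp5` is the end of the last retained 5' exon, `bp3` the
#' start of the first retained 3' exon.
#'
#' @param ref A `sim_reference`.
#' @param spec A [fusion_spec()].
#' @return Transcript object (list) with `seq`, `L`, `junction` (transcript
#'   coordinate of the last 5'-partner base), `bp5`, `bp3` and the genomic
#'   `segments` table.
#' @export
make_fusion_transcript <- function(ref, spec) {
  g5 <- ref$genes[[spec$gene5]]
  g3 <- ref$genes[[spec$gene3]]
  if (is.null(g5)) stop("unknown gene: ", spec$gene5)
  if (is.null(g3)) stop("unknown gene: ", spec$gene3)
  if (spec$exon5 > length(g5$exons)) {
    stop("gene ", spec$gene5, " has no exon ", spec$exon5)
  }
  if (spec$exon3 > length(g3$exons)) {
    stop("gene ", spec$gene3, " has no exon ", spec$exon3)
  }
  e5 <- g5$exons[seq_len(spec$exon5)]
  e3 <- g3$exons[spec$exon3:length(g3$exons)]
  segs <- rbind(
    data.table(chrom = g5$chrom, start = IRanges::start(e5),
               end = IRanges::end(e5), part = "5"),
    data.table(chrom = g3$chrom, start = IRanges::start(e3),
               end = IRanges::end(e3), part = "3")
  )
  junction <- sum(IRanges::width(e5))
  .tx_from_blocks(paste0("fusion:", spec$gene5, "::", spec$gene3),
                  spec$gene3, segs, ref$genome, junction = junction,
                  gene5 = spec$gene5, gene3 = spec$gene3,
                  bp5 = max(IRanges::end(e5)), bp3 = min(IRanges::start(e3)),
                  kind = "fusion")
}

.readthrough_transcript <- function(ref, gene5, gene3) {
  g5 <- ref$genes[[gene5]]
  g3 <- ref$genes[[gene3]]
  if (is.null(g5) || is.null(g3)) stop("unknown read-through gene(s)")
  segs <- rbind(
    data.table(chrom = g5$chrom, start = IRanges::start(g5$exons),
               end = IRanges::end(g5$exons), part = "5"),
    data.table(chrom = g3$chrom, start = IRanges::start(g3$exons),
               end = IRanges::end(g3$exons), part = "3")
  )
  junction <- sum(IRanges::width(g5$exons))
  .tx_from_blocks(paste0("readthrough:", gene5, "::", gene3), gene5, segs,
                  ref$genome, junction = junction, gene5 = gene5,
                  gene3 = gene3, bp5 = max(IRanges::end(g5$exons)),
                  bp3 = min(IRanges::start(g3$exons)), kind = "readthrough")
}

# ---- degradation ------------------------------------------------------------

#' Fragment a transcript by RIN-driven random cutting
#'
#' Models chemical degradation as independent per-base cuts with probability
#' `cut_coef / rin^2`: an intact specimen (high RIN) is cut rarely, a
#' degraded one often. Fragments shorter than `min_fragment` are discarded
#' (size selection during library construction).
#'
#' @param x A nucleotide sequence (character scalar) or a transcript length
#'   (single number).
#' @param rin RNA integrity number in \[1,10\].
#' @param min_fragment Minimum retained fragment length (default 200).
#' @param cut_coef Cut coefficient `c` (default 0.002).
#' @param seed Optional seed for a deterministic draw.
#' @return `data.table` with `start`, `end` (1-based, on the transcript) and,
#'   when `x` is a sequence, `sequence`.
#' @export
degrade <- function(x, rin, min_fragment = 200, cut_coef = 0.002, seed = NULL) {
  stopifnot(rin >= 1, rin <= 10)
  is_seq <- is.character(x)
  L <- if (is_seq) nchar(x) else as.integer(x)
  stopifnot(length(L) == 1L, L >= 0)
  run <- function() {
    p <- cut_coef / rin^2
    cuts <- if (L > 1L) {
      k <- rbinom(1L, L - 1L, p)
      if (k > 0L) sort(sample.int(L - 1L, k)) else integer(0)
    } else integer(0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    keep <- (ends - starts + 1L) >= min_fragment
    dt <- data.table(start = starts[keep], end = ends[keep])
    if (is_seq) dt[, sequence := substring(x, start, end)]
    dt[]
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# pick one library fragment per read: k[i] cuts on a transcript of length
# L[i]; a fragment >= min_fragment is chosen uniformly; NA when none passes
.pick_fragments <- function(L, k, min_fragment) {
  n <- length(L)
  fs <- ifelse(k == 0L & L >= min_fragment, 1L, NA_integer_)
  fe <- ifelse(k == 0L & L >= min_fragment, L, NA_integer_)
  for (i in which(k > 0L)) {
    cuts <- sort(sample.int(L[i] - 1L, k[i]))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L[i])
    ok <- which((ends - starts + 1L) >= min_fragment)
    if (!length(ok)) next
    j <- if (length(ok) == 1L) ok else sample(ok, 1L)
    fs[i] <- starts[j]
    fe[i] <- ends[j]
  }
  cbind(fs, fe)
}

# ---- errors -----------------------------------------------------------------

.BASES <- charToRaw("ACGT")

# raw-vector error surgery for one read
.apply_errors_raw <- function(r, sub, ins, del) {
  L <- length(r)
  if (L == 0L) return(r)
  k_sub <- rbinom(1L, L, sub)
  if (k_sub > 0L) {
    pos <- sample.int(L, k_sub)
    old <- match(r[pos], .BASES)
    off <- sample.int(3L, k_sub, replace = TRUE)
    repl <- .BASES[((old - 1L + off) %% 4L) + 1L]
    ok <- !is.na(old)            # leave non-ACGT bases untouched
    r[pos[ok]] <- repl[ok]
  }
  counts <- rep(1L, L)
  k_del <- rbinom(1L, L, del)
  if (k_del > 0L) counts[sample.int(L, k_del)] <- 0L
  k_ins <- rbinom(1L, L, ins)
  ins_pos <- if (k_ins > 0L) sample.int(L, k_ins) else integer(0)
  counts[ins_pos] <- counts[ins_pos] + 1L
  if (k_del == 0L && k_ins == 0L) return(r)
  out <- r[rep.int(seq_len(L), counts)]
  if (length(ins_pos)) {
    slot <- cumsum(counts)[ins_pos]  # inserted base sits last in its slot
    out[slot] <- .BASES[sample.int(4L, length(ins_pos), replace = TRUE)]
  }
  out
}

#' Add nanopore-like sequencing errors to sequences
#'
#' Applies independent per-base substitutions, insertions and deletions at
#' the given rates (exactly: error counts are binomial in the sequence
#' length, positions uniform). Returns a quality string per read, constant
#' at the Phred score consistent with the read's total error rate (or at
#' `mean_quality` when given), so [mean_read_quality()] recovers it.
#'
#' @param sequence Character vector of sequences.
#' @param sub_rate,ins_rate,del_rate Per-base probabilities in \[0,1\],
#'   recycled over reads.
#' @param mean_quality Optional per-read mean Phred quality used for the
#'   quality strings; default derives it from the total error rate.
#' @param seed Optional seed for a deterministic draw.
#' @return List with `sequence` and `quality` character vectors.
#' @export
add_errors <- function(sequence, sub_rate = 0.02, ins_rate = 0.01,
                       del_rate = 0.01, mean_quality = NULL, seed = NULL) {
  n <- length(sequence)
  sub <- rep_len(sub_rate, n)
  ins <- rep_len(ins_rate, n)
  del <- rep_len(del_rate, n)
  stopifnot(all(sub >= 0 & sub <= 1), all(ins >= 0 & ins <= 1),
            all(del >= 0 & del <= 1))
  q <- if (is.null(mean_quality)) {
    tot <- sub + ins + del
    ifelse(tot > 0, pmin(40, round(-10 * log10(pmax(tot, 1e-4)))), 40)
  } else {
    pmax(2, pmin(41, round(rep_len(mean_quality, n))))
  }
  run <- function() {
    out <- character(n)
    qual <- character(n)
    for (i in seq_len(n)) {
      r <- .apply_errors_raw(charToRaw(sequence[i]), sub[i], ins[i], del[i])
      out[i] <- rawToChar(r)
      qual[i] <- strrep(intToUtf8(q[i] + 33L), length(r))
    }
    list(sequence = out, quality = qual)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# ---- truth alignments -------------------------------------------------------

# genomic blocks of tx interval [s, e] restricted to segment rows `rows`
.interval_blocks <- function(segs, s, e) {
  hit <- segs[tx_end >= s & tx_start <= e]
  data.table(
    chrom = hit$chrom,
    start = hit$start + pmax(s, hit$tx_start) - hit$tx_start,
    end = hit$start + pmin(e, hit$tx_end) - hit$tx_start
  )
}

.blocks_cigar <- function(blocks) {
  w <- blocks$end - blocks$start + 1L
  if (nrow(blocks) == 1L) return(paste0(w, "M"))
  gaps <- blocks$start[-1L] - blocks$end[-nrow(blocks)] - 1L
  paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
         w[length(w)], "M")
}

# SAM record templates for a fragment [fs, fe] of transcript tx:
# list of list(chrom, pos, cigar, qs, qe, supp)
.fragment_records <- function(tx, fs, fe) {
  frag_len <- fe - fs + 1L
  junction <- tx$junction
  split_aln <- !is.na(junction) && fs <= junction && fe > junction
  if (!split_aln) {
    bl <- .interval_blocks(tx$segments, fs, fe)
    return(list(list(chrom = bl$chrom[1L], pos = bl$start[1L],
                     cigar = .blocks_cigar(bl), qs = 1L, qe = frag_len,
                     supp = FALSE)))
  }
  la <- junction - fs + 1L
  lb <- frag_len - la
  b5 <- .interval_blocks(tx$segments[part == "5"], fs, junction)
  b3 <- .interval_blocks(tx$segments[part == "3"], junction + 1L, fe)
  list(
    list(chrom = b5$chrom[1L], pos = b5$start[1L],
         cigar = paste0(.blocks_cigar(b5), lb, "S"),
         qs = 1L, qe = la, supp = FALSE),
    list(chrom = b3$chrom[1L], pos = b3$start[1L],
         cigar = paste0(la, "H", .blocks_cigar(b3)),
         qs = la + 1L, qe = frag_len, supp = TRUE)
  )
}

#' Emit truth alignments as SAM
#'
#' Writes the idealized splice-aware alignment of every simulated fragment:
#' a single primary record for non-junction reads; a primary plus a
#' hard-clipped supplementary record flanking the junction for
#' fusion/read-through reads; `N` operations across introns; reads drawn in
#' antisense orientation carry the reverse flag. CIGARs describe the
#' error-free fragment (the aligner is assumed to recover the true origin);
#' the error-bearing sequences live in the FASTQ.
#'
#' @param truth The per-read truth table of a simulation (columns `read_id`,
#'   `tx_id`, `frag_start`, `frag_end`, `orientation`).
#' @param transcripts Named list of transcript objects keyed by `tx_id`.
#' @param reference The `sim_reference`.
#' @return Character vector of SAM lines (header included).
#' @export
emit_truth_alignments <- function(truth, transcripts, reference) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    vapply(names(reference$genome), function(ch) {
      sprintf("@SQ\tSN:%s\tLN:%d", ch, length(reference$genome[[ch]]))
    }, ""),
    "@PG\tID:anchorfuse-sim\tPN:anchorfuse-sim"
  )
  if (!nrow(truth)) return(header)
  tr <- data.table::copy(truth)
  tr[, combo := paste(tx_id, frag_start, frag_end, sep = "|")]
  grp <- tr[, list(idxs = list(.I)), by = combo]
  combos <- unique(tr, by = "combo")
  lines <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    tx <- transcripts[[combos$tx_id[ci]]]
    fs <- combos$frag_start[ci]; fe <- combos$frag_end[ci]
    recs <- .fragment_records(tx, fs, fe)
    rows <- tr[grp$idxs[[ci]]]
    rev <- rows$orientation == "-"
    per_rec <- lapply(recs, function(rc) {
      flag <- (if (rc$supp) 2048L else 0L) + ifelse(rev, 16L, 0L)
      seq <- substr(tx$seq, fs + rc$qs - 1L, fs + rc$qe - 1L)
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
              rows$read_id, flag, rc$chrom, rc$pos, rc$cigar, seq)
    })
    # interleave so each read's records stay adjacent
    lines[[ci]] <- as.vector(t(matrix(unlist(per_rec), nrow = nrow(rows))))
  }
  c(header, unlist(lines))
}

# ---- full sample ------------------------------------------------------------

#' Simulate a full targeted-capture nanopore experiment
#'
#' Draws `n_reads` reads from wild-type and fusion transcripts: each read is
#' assigned to a panel gene with probability `on_target_fraction` (else a
#' partner gene); reads of a gene that anchors a fusion switch to the fusion
#' transcript with that fusion's `frequency`; the transcript is fragmented
#' per RIN, one retained fragment becomes the read; half the reads (by
#' default) are sequenced in reverse complement; sequencing errors and
#' qualities follow the per-read mean-Q draw. Outputs are mutually
#' consistent: every read appears once in the truth table, FASTQ and SAM.
#' Fully deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_sample`: list with `reference`
#'   (`sim_reference`), `transcripts`, `reads` (a `read_set` with errors),
#'   `sam` (character SAM lines, truth alignments), `truth` (per-read
#'   `data.table`: gene, transcript, fragment interval, orientation,
#'   on-target status, fusion/junction flags) and `fusions` (truth fusion
#'   table with genomic breakpoints and realized junction-read counts).
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_sample_impl(config))
}

.simulate_sample_impl <- function(cfg) {
  ref <- .sim_reference_impl(cfg)
  transcripts <- list()
  for (g in names(ref$genes)) transcripts[[paste0("wt:", g)]] <- .wt_transcript(ref, g)
  anchor_of <- character(0)   # gene name -> fusion tx_id
  for (fs in cfg$fusion_specs) {
    tx <- make_fusion_transcript(ref, fs)
    transcripts[[tx$tx_id]] <- tx
    anchor <- if (fs$gene3 %in% cfg$panel_genes) fs$gene3
      else if (fs$gene5 %in% cfg$panel_genes) fs$gene5 else fs$gene3
    anchor_of[anchor] <- tx$tx_id
  }
  for (rt in cfg$readthrough_specs) {
    tx <- .readthrough_transcript(ref, rt$gene5, rt$gene3)
    transcripts[[tx$tx_id]] <- tx
  }
  freq_of <- stats::setNames(
    vapply(cfg$fusion_specs, `[[`, 0, "frequency"),
    vapply(cfg$fusion_specs, function(x) paste0("fusion:", x$gene5, "::", x$gene3), "")
  )

  n <- cfg$n_reads
  p_cut <- cfg$cut_coef / cfg$rin^2
  have_partners <- length(cfg$partner_genes) > 0L
  on <- if (have_partners) runif(n) < cfg$on_target_fraction else rep(TRUE, n)
  gene <- character(n)
  gene[on] <- sample(cfg$panel_genes, sum(on), replace = TRUE)
  if (any(!on)) gene[!on] <- sample(cfg$partner_genes, sum(!on), replace = TRUE)
  tx_id <- paste0("wt:", gene)
  is_anchor <- gene %in% names(anchor_of)
  if (any(is_anchor)) {
    cand <- anchor_of[gene[is_anchor]]
    take <- runif(sum(is_anchor)) < freq_of[cand]
    tx_id[is_anchor][take] <- cand[take]
  }
  is_fusion <- startsWith(tx_id, "fusion:")

  # read-through artifacts are appended beyond n_reads
  rt_tx <- character(0)
  for (rt in cfg$readthrough_specs) {
    id <- paste0("readthrough:", rt$gene5, "::", rt$gene3)
    rt_tx <- c(rt_tx, rep(id, rt$n_reads))
  }
  if (length(rt_tx)) {
    tx_id <- c(tx_id, rt_tx)
    gene <- c(gene, vapply(transcripts[rt_tx], `[[`, "", "gene"))
    on <- c(on, rep(FALSE, length(rt_tx)))
    is_fusion <- c(is_fusion, rep(FALSE, length(rt_tx)))
  }
  ntot <- length(tx_id)

  Lvec <- vapply(transcripts[tx_id], `[[`, 0L, "L")
  kvec <- rbinom(ntot, pmax(Lvec - 1L, 0L), p_cut)
  frag <- .pick_fragments(Lvec, kvec, cfg$min_fragment)
  emitted <- !is.na(frag[, 1L])

  truth <- data.table(
    read_id = sprintf("r%06d", seq_len(ntot)),
    tx_id = tx_id, gene = gene,
    frag_start = frag[, 1L], frag_end = frag[, 2L],
    orientation = ifelse(runif(ntot) < cfg$antisense_fraction, "-", "+"),
    on_target = on,
    is_fusion = is_fusion,
    is_artifact = startsWith(tx_id, "readthrough:")
  )
  junc <- vapply(transcripts[tx_id], `[[`, 0L, "junction")
  truth[, spans_junction := !is.na(junc) & !is.na(frag_start) &
          frag_start <= junc & frag_end > junc & !is_artifact]
  truth <- truth[emitted]

  sam <- emit_truth_alignments(truth, transcripts, ref)

  reads <- if (isTRUE(cfg$emit_reads)) {
    frag_seq <- substring(
      vapply(transcripts[truth$tx_id], `[[`, "", "seq"),
      truth$frag_start, truth$frag_end
    )
    minus <- truth$orientation == "-"
    if (any(minus)) {
      frag_seq[minus] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(frag_seq[minus]))
      )
    }
    qbar <- pmin(cfg$quality_range[2L],
                 pmax(cfg$quality_range[1L],
                      rnorm(nrow(truth), cfg$mean_quality, cfg$sd_quality)))
    base_tot <- cfg$sub_rate + cfg$ins_rate + cfg$del_rate
    scale <- if (base_tot > 0) 10^(-qbar / 10) / base_tot else 0
    err <- add_errors(frag_seq,
                      sub_rate = cfg$sub_rate * scale,
                      ins_rate = cfg$ins_rate * scale,
                      del_rate = cfg$del_rate * scale,
                      mean_quality = qbar)
    read_set(truth$read_id, err$sequence, err$quality)
  } else {
    read_set(character(0), character(0), character(0))
  }

  fus <- rbindlist(lapply(cfg$fusion_specs, function(fs) {
    id <- paste0("fusion:", fs$gene5, "::", fs$gene3)
    tx <- transcripts[[id]]
    data.table(gene5 = fs$gene5, gene3 = fs$gene3,
               chrom5 = ref$genes[[fs$gene5]]$chrom,
               bp5 = tx$bp5,
               chrom3 = ref$genes[[fs$gene3]]$chrom,
               bp3 = tx$bp3,
               frequency = fs$frequency,
               n_junction_reads = truth[tx_id == id & spans_junction, .N])
  }))

  structure(list(reference = ref, transcripts = transcripts, reads = reads,
                 sam = sam, truth = truth, fusions = fus, config = cfg),
            class = "sim_sample")
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf("sim_sample: %d read(s), %d gene(s), %d fusion spec(s), seed %d\n",
              nrow(x$truth), length(x$reference$genes), nrow(x$fusions),
              x$config$seed))
  invisible(x)
}

#' Write a GTF annotation for simulated genes
#'
#' One transcript per gene (`T_<gene_id>`), exon features in genomic order;
#' 1-based closed coordinates per the GTF standard.
#'
#' @param genes Named list of `gene_model` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    span <- c(min(IRanges::start(g$exons)), max(IRanges::end(g$exons)))
    attr_g <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
    attr_t <- sprintf('gene_id "%s"; transcript_id "T_%s"; gene_name "%s";',
                      g$gene_id, g$gene_id, g$gene_name)
    c(
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, span[1L], span[2L], g$strand, attr_g),
      sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, span[1L], span[2L], g$strand, attr_t),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, IRanges::start(g$exons), IRanges::end(g$exons),
              g$strand, attr_t)
    )
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Write all outputs of a simulated sample to a directory
#'
#' Writes `reference.fa`, `annotation.gtf`, `panel.bed`, `reads.fastq`,
#' `alignments.sam`, `truth_reads.tsv` and `truth_fusions.tsv`.
#'
#' @param sim A `sim_sample`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_sim_sample <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$reference$genome,
                              file.path(dir, "reference.fa"))
  write_gtf(sim$reference$genes, file.path(dir, "annotation.gtf"))
  write_panel_bed(sim$reference$panel, file.path(dir, "panel.bed"))
  write_fastq(sim$reads, file.path(dir, "reads.fastq"))
  writeLines(sim$sam, file.path(dir, "alignments.sam"))
  fwrite(sim$truth, file.path(dir, "truth_reads.tsv"), sep = "\t")
  fwrite(sim$fusions, file.path(dir, "truth_fusions.tsv"), sep = "\t")
  invisible(dir)
}
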