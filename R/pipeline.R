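#' Run the full analysis pipeline on a simulated sample
#'
#' QC-filters the reads, restricts the truth alignments to QC-passed reads,
#' calls fusions and computes panel QC — the closed loop
#' simulate -> qc -> call -> metrics with zero external inputs.
#'
#' @param sim A `sim_sample` from [simulate_sample()].
#' @param min_length,min_quality Read QC thresholds (defaults 100 bp / Q7).
#' @param ... Passed to [call_fusions()].
#' @return List with `filter` (QC result), `stats` (kept-read statistics),
#'   `chains` (QC-passed `read_chains`), `calls` (`fusion_calls`) and `qc`
#'   (`panel_qc`).
#' @export
run_pipeline <- function(sim, min_length = 100, min_quality = 7, ...) {
  stopifnot(inherits(sim, "sim_sample"))
  flt <- filter_reads(sim$reads, min_length = min_length,
                      min_quality = min_quality)
  chains <- subset_chains(parse_alignments(sim$sam), flt$kept$read_id)
  index <- build_index(sim$reference$genes)
  calls <- call_fusions(chains, index, sim$reference$panel, ...)
  list(filter = flt, stats = read_stats(flt$kept), chains = chains,
       calls = calls, qc = panel_qc(chains, sim$reference$panel))
}

#' Command-line interface
#'
#' Subcommands: `qc` (read filtering + stats), `call` (fusion calling from
#' SAM), `metrics` (panel QC report), `eval` (cohort evaluation) and
#' `simulate` (write a synthetic sample). Run with no arguments for usage.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Invisibly, `NULL`. Called for its side effects.
#' @export
anchorfuse_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: anchorfuse <command> [options]",
    "commands:",
    "  qc        --min-len N --min-q Q --stats-out F in.fastq out.fastq",
    "  call      --gtf F --panel-genes A,B --min-support N --cluster-window W in.sam out.tsv",
    "  metrics   --gtf F --panel-genes A,B in.sam report.json",
    "  eval      cohort.tsv report.json",
    "  simulate  --seed N --n-reads N --outdir DIR",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(NULL)) }
  cmd <- args[1L]
  rest <- args[-1L]
  opt_list <- switch(cmd,
    qc = list(
      optparse::make_option("--min-len", type = "double", default = 100),
      optparse::make_option("--min-q", type = "double", default = 7),
      optparse::make_option("--stats-out", type = "character", default = NULL)
    ),
    call = list(
      optparse::make_option("--gtf", type = "character"),
      optparse::make_option("--panel-genes", type = "character",
                            default = paste(default_panel_genes(), collapse = ",")),
      optparse::make_option("--min-support", type = "double", default = 3),
      optparse::make_option("--cluster-window", type = "double", default = 50)
    ),
    metrics = list(
      optparse::make_option("--gtf", type = "character"),
      optparse::make_option("--panel-genes", type = "character",
                            default = paste(default_panel_genes(), collapse = ","))
    ),
    eval = list(),
    simulate = list(
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--n-reads", type = "integer", default = 2000L),
      optparse::make_option("--outdir", type = "character", default = "sim")
    ),
    stop(usage)
  )
  p <- optparse::OptionParser(option_list = opt_list)
  pa <- optparse::parse_args(p, args = rest, positional_arguments = TRUE)
  o <- pa$options
  pos <- pa$args
  if (cmd == "qc") {
    reads <- read_fastq(pos[1L])
    flt <- filter_reads(reads, min_length = o$`min-len`, min_quality = o$`min-q`)
    write_fastq(flt$kept, pos[2L])
    if (!is.null(o$`stats-out`)) {
      jsonlite::write_json(read_stats(flt$kept), o$`stats-out`,
                           auto_unbox = TRUE, digits = NA)
    }
    message(sprintf("kept %d / removed %d reads", nrow(flt$kept), nrow(flt$removed)))
  } else if (cmd %in% c("call", "metrics")) {
    genes <- read_gene_models(o$gtf)
    panel <- target_panel(genes, strsplit(o$`panel-genes`, ",")[[1L]])
    chains <- parse_alignments(pos[1L])
    if (cmd == "call") {
      calls <- call_fusions(chains, build_index(genes), panel,
                            min_support = o$`min-support`,
                            cluster_window = o$`cluster-window`)
      write_fusion_tsv(calls, pos[2L])
      message(sprintf("%d PASS call(s)", sum(calls$status == "PASS")))
    } else {
      write_panel_qc(panel_qc(chains, panel), pos[2L])
    }
  } else if (cmd == "eval") {
    ev <- evaluate_cohort(read_cohort(pos[1L]))
    write_eval_json(ev, pos[2L])
    print(ev)
  } else if (cmd == "simulate") {
    sim <- simulate_sample(sim_config(seed = o$seed, n_reads = o$`n-reads`))
    write_sim_sample(sim, o$outdir)
    message("wrote ", o$outdir)
  }
  invisible(NULL)
}
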