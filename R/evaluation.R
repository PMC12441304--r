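#' Parse a fusion-call field
#'
#' Splits a report field like `"P2RY8::CRLF2;MYO18B::ABL1"` into canonical
#' unordered gene pairs (each pair's genes sorted alphabetically). Clinical
#' reports do not fix 5'/3' order consistently, so matching is name-based
#' and unordered. Negative markers (`-`, em-dash, `negative`, empty, `NA`)
#' yield an empty set.
#'
#' @param x Character scalar.
#' @return Character vector of canonical `A::B` pairs (possibly empty).
#' @export
parse_fusions <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  x <- trimws(x)
  if (tolower(x) %in% c("-", "—", "neg", "negative", "none", ".")) {
    return(character(0))
  }
  parts <- trimws(strsplit(x, "[;,]")[[1L]])
  parts <- parts[nzchar(parts)]
  vapply(parts, function(p) {
    g <- trimws(strsplit(p, "::", fixed = TRUE)[[1L]])
    if (length(g) != 2L || !all(nzchar(g))) {
      stop("cannot parse fusion '", p, "'")
    }
    paste(sort(g), collapse = "::")
  }, "", USE.NAMES = FALSE)
}

#' Score one sample against its truth
#'
#' A truth-positive sample is a true positive only if *all* its truth
#' fusions are called (unordered gene-set match); otherwise a false
#' negative. A truth-negative sample with any call is a false positive,
#' else a true negative.
#'
#' @param truth_fusion,called_fusion Report fields (see [parse_fusions()]).
#' @return One of `"TP"`, `"FN"`, `"TN"`, `"FP"`.
#' @export
score_sample <- function(truth_fusion, called_fusion) {
  if (length(truth_fusion) != 1L || length(called_fusion) != 1L) {
    stop("score_sample() scores a single sample")
  }
  tr <- parse_fusions(truth_fusion)
  ca <- parse_fusions(called_fusion)
  if (length(tr) == 0L) {
    if (length(ca) == 0L) "TN" else "FP"
  } else {
    if (all(tr %in% ca)) "TP" else "FN"
  }
}

#' Confusion matrix from outcome labels
#' @param outcomes Character vector of `"TP"/"FN"/"TN"/"FP"` labels.
#' @return List of class `confusion_matrix` with counts `tp, fn, tn, fp`.
#' @export
confusion_matrix <- function(outcomes) {
  stopifnot(all(outcomes %in% c("TP", "FN", "TN", "FP")))
  structure(list(
    tp = sum(outcomes == "TP"), fn = sum(outcomes == "FN"),
    tn = sum(outcomes == "TN"), fp = sum(outcomes == "FP")
  ), class = "confusion_matrix")
}

#' Sensitivity in percent
#' @param cm A `confusion_matrix`.
#' @return `100 * tp / (tp + fn)`; `NA` when there are no positives.
#' @export
sensitivity <- function(cm) {
  if (cm$tp + cm$fn == 0L) return(NA_real_)
  100 * cm$tp / (cm$tp + cm$fn)
}

#' Specificity in percent
#' @param cm A `confusion_matrix`.
#' @return `100 * tn / (tn + fp)`; `NA` when there are no negatives.
#' @export
specificity <- function(cm) {
  if (cm$tn + cm$fp == 0L) return(NA_real_)
  100 * cm$tn / (cm$tn + cm$fp)
}

#' Read a cohort truth/call table
#'
#' Tab-separated with columns `sample_id`, `group`, `truth_fusion`,
#' `called_fusion` and optionally `rin_class`. Multiple fusions in one
#' field are `;`-separated; `-` marks a negative result.
#'
#' @param path TSV path.
#' @return `data.table`.
#' @export
read_cohort <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = "character", na.strings = NULL)
  need <- c("sample_id", "group", "truth_fusion", "called_fusion")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  dt
}

#' Evaluate a clinical cohort
#'
#' Scores each sample ([score_sample()]) and tabulates confusion matrices
#' and sensitivity/specificity per group and overall. Groups listed in
#' `exclude_groups` (by default group C: fusions with unknown or
#' non-codingly rearranged partners, which the assay cannot resolve at the
#' transcript level) are excluded from the metrics and reported
#' descriptively. Samples whose truth holds several fusions count as TP
#' only when every truth fusion is called; partially detected samples are
#' tallied in `partial`.
#'
#' @param records A `data.frame`/`data.table` with columns `sample_id`,
#'   `group`, `truth_fusion`, `called_fusion`.
#' @param by_group Split metrics by `group` (default `TRUE`).
#' @param exclude_groups Groups excluded from metrics (default `"C"`).
#' @return Object of class `cohort_eval`: list with `per_sample`
#'   (`data.table` with an `outcome` column), `groups` (named list of
#'   `list(cm, sensitivity, specificity, n)`), `overall` (same over the
#'   non-excluded groups), `excluded` (descriptive `data.table`) and
#'   `partial` (sample ids with some but not all truth fusions called).
#' @export
evaluate_cohort <- function(records, by_group = TRUE, exclude_groups = "C") {
  dt <- as.data.table(records)
  need <- c("sample_id", "group", "truth_fusion", "called_fusion")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(dt$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(dt$sample_id[duplicated(dt$sample_id)]), collapse = ", "))
  }
  if (!nrow(dt)) {
    return(structure(list(per_sample = dt, groups = list(), overall = NULL,
                          excluded = dt, partial = character(0)),
                     class = "cohort_eval"))
  }
  dt <- data.table::copy(dt)
  dt[, outcome := vapply(seq_len(.N), function(i)
    score_sample(truth_fusion[i], called_fusion[i]), "")]
  dt[, partial := vapply(seq_len(.N), function(i) {
    tr <- parse_fusions(truth_fusion[i]); ca <- parse_fusions(called_fusion[i])
    length(tr) > 1L && any(tr %in% ca) && !all(tr %in% ca)
  }, NA)]
  scored <- dt[!group %in% exclude_groups]
  summarise <- function(x) {
    cm <- confusion_matrix(x$outcome)
    list(cm = cm, sensitivity = sensitivity(cm),
         specificity = specificity(cm), n = nrow(x))
  }
  groups <- if (by_group && nrow(scored)) {
    gs <- sort(unique(scored$group))
    stats::setNames(lapply(gs, function(g) summarise(scored[group == g])), gs)
  } else list()
  structure(list(
    per_sample = dt[],
    groups = groups,
    overall = if (nrow(scored)) summarise(scored) else NULL,
    excluded = dt[group %in% exclude_groups,
                  list(sample_id, group, truth_fusion, called_fusion, outcome)],
    partial = dt[partial == TRUE, sample_id]
  ), class = "cohort_eval")
}

#' @export
print.cohort_eval <- function(x, ...) {
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    cat(sprintf("group %s (n=%d): tp=%d fn=%d tn=%d fp=%d  sensitivity=%.2f%%  specificity=%.2f%%\n",
                g, s$n, s$cm$tp, s$cm$fn, s$cm$tn, s$cm$fp,
                s$sensitivity, s$specificity))
  }
  if (!is.null(x$overall)) {
    s <- x$overall
    cat(sprintf("overall (n=%d): sensitivity=%.2f%%  specificity=%.2f%%\n",
                s$n, s$sensitivity, s$specificity))
  }
  if (nrow(x$excluded)) {
    cat(sprintf("excluded from metrics: %s\n",
                paste(x$excluded$sample_id, collapse = ", ")))
  }
  invisible(x)
}

#' Path to the packaged blind-test cohort fixture
#'
#' A 39-sample clinical blind-test cohort (B-ALL cases and healthy
#' controls) with clinically confirmed truth fusions and the assay's calls:
#' group A (RIN > 3), group B (RIN <= 3), group C (unknown or
#' immunoglobulin-enhancer partners, excluded from metrics).
#'
#' @return Path to the TSV.
#' @export
blind_test_cohort <- function() {
  system.file("extdata", "blind_test_cohort.tsv", package = "anchorfuse",
              mustWork = TRUE)
}

#' Write an evaluation report as JSON
#' @param ev A `cohort_eval`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_eval_json <- function(ev, path) {
  obj <- list(
    groups = lapply(ev$groups, function(s) list(
      n = s$n, tp = s$cm$tp, fn = s$cm$fn, tn = s$cm$tn, fp = s$cm$fp,
      sensitivity = s$sensitivity, specificity = s$specificity
    )),
    overall = if (!is.null(ev$overall)) list(
      n = ev$overall$n, sensitivity = ev$overall$sensitivity,
      specificity = ev$overall$specificity
    ),
    excluded = ev$excluded, partial = ev$partial
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
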