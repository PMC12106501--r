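# Scoring calls against truth labels and cohort-level reporting. Ambiguous
# and no_call samples are excluded from the 2x2 confusion table (they were
# never submitted for confirmation) but always counted separately, so PPV
# and sensitivity are not silently threshold-artifacted.

round_half_up <- function(x, digits = 0L) {
  # base round() is banker's; printed proportions use conventional half-up
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Confusion summary of calls against truth labels
#'
#' @param calls A call `data.frame` (from [call_cohort()] or [read_calls()])
#'   with `sample_id` and `call`.
#' @param truth `data.frame` with `sample_id` and `truth_label`
#'   (`carrier`/`negative`); only labelled samples are scored.
#' @return A `confusion_summary` list: `tp`, `fp`, `tn`, `fn`,
#'   `n_ambiguous_excluded`, `n_no_call_excluded`, `ppv`, `sensitivity`
#'   (both `NA` when their denominator is zero, reported as undefined rather
#'   than 0), and `prevalence_called` (called carriers / labelled samples).
#' @export
confusion <- function(calls, truth) {
  lab <- truth$truth_label
  bad <- !is.na(lab) & !(lab %in% c("carrier", "negative"))
  if (any(bad))
    stop("truth_label must be 'carrier' or 'negative', got '", lab[bad][1], "'")
  truth <- truth[!is.na(truth$truth_label), , drop = FALSE]
  if (nrow(truth) == 0L) stop("no samples with truth labels")
  call <- calls$call[match(truth$sample_id, calls$sample_id)]
  if (anyNA(call))
    stop("truth contains samples absent from the calls: ",
         truth$sample_id[is.na(call)][1])
  is_carrier <- truth$truth_label == "carrier"
  scored <- call %in% c("carrier", "negative")
  tp <- sum(scored & call == "carrier" & is_carrier)
  fp <- sum(scored & call == "carrier" & !is_carrier)
  tn <- sum(scored & call == "negative" & !is_carrier)
  fn <- sum(scored & call == "negative" & is_carrier)
  out <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_ambiguous_excluded = sum(call == "ambiguous"),
    n_no_call_excluded = sum(call == "no_call"),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    prevalence_called = sum(call == "carrier") / nrow(truth)
  )
  class(out) <- "confusion_summary"
  out
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("confusion_summary\n")
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d (ambiguous excluded: %d, no_call: %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_ambiguous_excluded, x$n_no_call_excluded))
  cat("  PPV:        ", if (is.na(x$ppv)) "undefined" else
    sprintf("%.1f%%", 100 * x$ppv), "\n", sep = "")
  cat("  sensitivity:", if (is.na(x$sensitivity)) " undefined" else
    sprintf(" %.1f%%", 100 * x$sensitivity), "\n", sep = "")
  invisible(x)
}

#' Cohort-level run summary
#'
#' Counts per call class, carrier prevalence, a per-array-version breakdown,
#' and — when the manifest carries prior truth labels — the split of called
#' carriers into previously identified vs novel. Percentages are rounded
#' half-up at the printed precision (prevalence to 3 decimals, proportions
#' to whole percent); the raw fractions are always retained alongside.
#'
#' @param calls A call `data.frame`.
#' @param manifest Sample manifest (for array versions and prior labels).
#' @return A `run_summary` list; its `text` element is a human-readable
#'   report block.
#' @export
summarize_run <- function(calls, manifest) {
  manifest <- validate_manifest(manifest)
  n <- nrow(calls)
  counts <- sapply(c("carrier", "negative", "ambiguous", "no_call"),
                   function(k) sum(calls$call == k))
  prevalence_raw <- if (n > 0) counts[["carrier"]] / n else NA_real_
  prevalence_pct <- round_half_up(100 * prevalence_raw, 3L)
  ver <- manifest$array_version[match(calls$sample_id, manifest$sample_id)]
  by_version <- table(ver, factor(calls$call,
                                  c("carrier", "negative", "ambiguous", "no_call")))
  carriers <- calls$sample_id[calls$call == "carrier"]
  prior <- manifest$truth_label[match(carriers, manifest$sample_id)]
  out <- list(
    n_samples = n, counts = counts,
    prevalence_raw = prevalence_raw, prevalence_pct = prevalence_pct,
    by_version = by_version
  )
  lines <- c(
    sprintf("samples analyzed: %d", n),
    sprintf("called carriers: %d (%.3f%%)", counts[["carrier"]], prevalence_pct),
    sprintf("negative: %d, ambiguous: %d, no_call: %d",
            counts[["negative"]], counts[["ambiguous"]], counts[["no_call"]])
  )
  if (counts[["carrier"]] > 0 && any(!is.na(prior))) {
    n_prior <- sum(prior == "carrier", na.rm = TRUE)
    frac_prior <- n_prior / length(carriers)
    out$n_previously_identified <- n_prior
    out$frac_previously_identified <- frac_prior
    out$pct_previously_identified <- round_half_up(100 * frac_prior, 0L)
    out$pct_novel <- round_half_up(100 * (1 - frac_prior), 0L)
    lines <- c(lines, sprintf(
      "previously identified: %d (%.0f%%), novel: %d (%.0f%%)",
      n_prior, out$pct_previously_identified,
      length(carriers) - n_prior, out$pct_novel))
  }
  out$text <- paste(lines, collapse = "\n")
  class(out) <- "run_summary"
  out
}

#' @export
print.run_summary <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Write an evaluation report
#'
#' @param summary A `run_summary` or `confusion_summary`.
#' @param path File path (TSV of the numeric fields plus the text block as
#'   comments for `run_summary`).
#' @export
write_report <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(summary, "run_summary")) {
    writeLines(paste0("# ", strsplit(summary$text, "\n")[[1]]), con)
    writeLines("key\tvalue", con)
    writeLines(sprintf("n_samples\t%d", summary$n_samples), con)
    for (k in names(summary$counts))
      writeLines(sprintf("n_%s\t%d", k, summary$counts[[k]]), con)
    writeLines(sprintf("prevalence_pct\t%.3f", summary$prevalence_pct), con)
    if (!is.null(summary$pct_previously_identified)) {
      writeLines(sprintf("pct_previously_identified\t%.0f",
                         summary$pct_previously_identified), con)
      writeLines(sprintf("pct_novel\t%.0f", summary$pct_novel), con)
    }
  } else if (inherits(summary, "confusion_summary")) {
    writeLines("key\tvalue", con)
    for (k in c("tp", "fp", "tn", "fn", "n_ambiguous_excluded",
                "n_no_call_excluded"))
      writeLines(sprintf("%s\t%d", k, summary[[k]]), con)
    writeLines(sprintf("ppv\t%s", if (is.na(summary$ppv)) "undefined"
                       else sprintf("%.6f", summary$ppv)), con)
    writeLines(sprintf("sensitivity\t%s", if (is.na(summary$sensitivity))
      "undefined" else sprintf("%.6f", summary$sensitivity)), con)
  } else stop("unsupported summary object")
  invisible(path)
}
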