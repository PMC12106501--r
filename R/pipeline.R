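# One-shot pipeline: io -> locus sums -> inverse-normal -> features ->
# calls -> (evaluation when truth labels exist). Every output directory
# carries the config hash so reruns are attributable, and all numeric
# output uses fixed formats so identical inputs give identical bytes.

#' Pipeline configuration
#'
#' @param manifest,intensities,locus_map,regions Input file paths.
#' @param truth Optional truth-label TSV (`sample_id`, `truth_label`).
#' @param out_dir Output directory.
#' @param offset Quantile offset for [inverse_normal_transform()].
#' @param mad_rule Combination rule for [piecewise_mad()].
#' @param diff_max,mad_max Calling thresholds (see [call_thresholds()]).
#' @param suggest_thresholds When `TRUE`, thresholds are derived with
#'   [suggest_thresholds()] from the cohort instead of the fixed values.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest, intensities, locus_map, regions,
                            out_dir, truth = NULL,
                            offset = "hazen", mad_rule = "pooled",
                            diff_max = -2.0, mad_max = 1.5,
                            suggest_thresholds = FALSE) {
  structure(list(manifest = manifest, intensities = intensities,
                 locus_map = locus_map, regions = regions, truth = truth,
                 out_dir = out_dir, offset = offset, mad_rule = mad_rule,
                 diff_max = diff_max, mad_max = mad_max,
                 suggest_thresholds = suggest_thresholds),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file mirroring the fields above.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full screening pipeline
#'
#' Stages run in fixed order; any failure aborts with a stage-tagged error.
#' Outputs written to `config$out_dir`: `locus_sums.tsv`,
#' `locus_normalized.tsv`, `features.tsv`, `calls.tsv`, `report.tsv`,
#' `summary.txt`, and `evaluation.tsv` when truth labels were supplied.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`locus_matrix`, `features`, `calls`, `summary`, and `confusion` when
#'   truth was given).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  hash <- config_hash(config)
  regions <- stage("io", read_regions(config$regions))
  map <- stage("io", read_locus_map(config$locus_map, regions))
  manifest <- stage("io", read_manifest(config$manifest))
  table <- stage("io", read_intensities(config$intensities, manifest, map))
  summed <- stage("sum", sum_to_locus(table, map))
  normalized <- stage("normalize", inverse_normal_transform(summed, config$offset))
  features <- stage("features", compute_features(normalized, map, config$mad_rule))
  thresholds <- stage("call", {
    if (isTRUE(config$suggest_thresholds)) suggest_thresholds(features)
    else call_thresholds(config$diff_max, config$mad_max, "user")
  })
  calls <- stage("call", call_cohort(features, thresholds))
  summary <- stage("evaluate", summarize_run(calls, manifest))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage("write", {
    write_locus_matrix(summed, out("locus_sums.tsv"))
    write_locus_matrix(normalized, out("locus_normalized.tsv"))
    write_features(features, out("features.tsv"))
    write_calls(calls, out("calls.tsv"))
    write_report(summary, out("report.tsv"))
    writeLines(c(paste0("# config_hash: ", hash), summary$text), out("summary.txt"))
  })
  result <- list(locus_matrix = normalized, features = features,
                 calls = calls, summary = summary, thresholds = thresholds,
                 config_hash = hash)
  if (!is.null(config$truth)) {
    truth <- stage("evaluate", read.delim(config$truth, stringsAsFactors = FALSE,
                                          na.strings = c("", "NA")))
    result$confusion <- stage("evaluate", confusion(calls, truth))
    stage("write", write_report(result$confusion, out("evaluation.tsv")))
  }
  message("pipeline complete: ", nrow(calls), " samples, ",
          sum(calls$call == "carrier"), " carrier call(s) [config ", hash, "]")
  invisible(result)
}

#' Screen an in-memory cohort
#'
#' File-free counterpart of [run_pipeline()] for simulated cohorts or
#' already-loaded tables: locus summation, inverse-normal normalization,
#' features, calls, and a confusion summary when truth labels are present.
#'
#' @param cohort A `simulated_cohort`, or a list with `intensities`,
#'   `manifest`, `locus_map` (and optional `truth_label` in the manifest).
#' @param thresholds A `call_thresholds` (default [call_thresholds()]).
#' @param offset,mad_rule Passed through to the respective stages.
#' @return List with `locus_matrix`, `features`, `calls`, and `confusion`
#'   when the manifest has truth labels.
#' @export
screen_cohort <- function(cohort, thresholds = call_thresholds(),
                          offset = "hazen", mad_rule = "pooled") {
  summed <- sum_to_locus(cohort$intensities, cohort$locus_map)
  normalized <- inverse_normal_transform(summed, offset)
  features <- compute_features(normalized, cohort$locus_map, mad_rule)
  calls <- call_cohort(features, thresholds)
  result <- list(locus_matrix = normalized, features = features, calls = calls)
  if (any(!is.na(cohort$manifest$truth_label)))
    result$confusion <- confusion(calls, cohort$manifest)
  result
}
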