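# Threshold-based carrier calling. Explicit thresholds on the two features
# replace visual cluster inspection with a reproducible rule; clustering
# algorithms were deliberately avoided as they are fragile on a class this
# rare (tens of carriers in a cohort of >10^5).

#' Calling thresholds
#'
#' A sample is called `carrier` when its `median_difference` is at or below
#' `diff_max` and its `piecewise_mad` is at or below `mad_max`; samples
#' above `mad_max` are `ambiguous` regardless of the difference (ambiguity
#' takes precedence over carrier, since a high-variance sample cannot be
#' trusted either way); everything else is `negative`. Defaults sit between
#' the theoretical carrier location (a lone carrier among N >= 10^3 samples
#' lands near the inverse-normal tail, about -3.3) and the main cluster
#' (difference near 0, MAD well below 1): `diff_max = -2`, `mad_max = 1.5`.
#'
#' @param diff_max Carrier cut on `median_difference` (must be negative).
#' @param mad_max Ambiguity cut on `piecewise_mad` (must be positive).
#' @param provenance `"default"`, `"user"` or `"suggested"`.
#' @return A `call_thresholds` object.
#' @export
call_thresholds <- function(diff_max = -2.0, mad_max = 1.5,
                            provenance = c("default", "user", "suggested")) {
  provenance <- match.arg(provenance)
  if (!is.finite(diff_max) || diff_max >= 0)
    stop("diff_max must be a finite negative number")
  if (!is.finite(mad_max) || mad_max <= 0)
    stop("mad_max must be a finite positive number")
  structure(list(diff_max = diff_max, mad_max = mad_max,
                 provenance = provenance),
            class = "call_thresholds")
}

#' @export
print.call_thresholds <- function(x, ...) {
  cat(sprintf("call_thresholds (%s): carrier if median_difference <= %g and piecewise_mad <= %g\n",
              x$provenance, x$diff_max, x$mad_max))
  invisible(x)
}

#' Classify samples from their feature pair
#'
#' Vectorized decision rule: `no_call` for missing features, else
#' `ambiguous` if `piecewise_mad > mad_max`, else `carrier` if
#' `median_difference <= diff_max`, else `negative`.
#'
#' @param median_difference,piecewise_mad Numeric vectors (one entry per
#'   sample).
#' @param thresholds A `call_thresholds` object.
#' @return Character vector of calls.
#' @export
classify <- function(median_difference, piecewise_mad, thresholds) {
  stopifnot(inherits(thresholds, "call_thresholds"))
  out <- rep("negative", length(median_difference))
  out[which(median_difference <= thresholds$diff_max)] <- "carrier"
  out[which(piecewise_mad > thresholds$mad_max)] <- "ambiguous"
  out[is.na(median_difference) | is.na(piecewise_mad)] <- "no_call"
  out
}

#' Call an entire cohort
#'
#' @param features Features `data.frame` from [compute_features()].
#' @param thresholds A `call_thresholds` object.
#' @return A `call_set`: the features with a `call` column plus threshold
#'   columns echoed per row; attributes carry the thresholds and summary
#'   counts.
#' @export
call_cohort <- function(features, thresholds = call_thresholds()) {
  calls <- features
  calls$call <- classify(features$median_difference, features$piecewise_mad,
                         thresholds)
  n <- nrow(calls)
  calls$diff_max <- rep(thresholds$diff_max, n)
  calls$mad_max <- rep(thresholds$mad_max, n)
  counts <- c(carrier = sum(calls$call == "carrier"),
              negative = sum(calls$call == "negative"),
              ambiguous = sum(calls$call == "ambiguous"),
              no_call = sum(calls$call == "no_call"))
  attr(calls, "thresholds") <- thresholds
  attr(calls, "counts") <- counts
  attr(calls, "prevalence_called") <- if (n > 0) counts[["carrier"]] / n else NA_real_
  class(calls) <- c("call_set", class(calls))
  calls
}

#' @export
print.call_set <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("call_set:", nrow(x), "samples\n")
  for (k in names(counts)) cat(sprintf("  %-9s %d\n", k, counts[[k]]))
  if (nrow(x) > 0)
    cat(sprintf("  prevalence %.3f%%\n", 100 * attr(x, "prevalence_called")))
  invisible(x)
}

#' Suggest data-driven thresholds for a cohort
#'
#' A reproducible stand-in for visual cluster inspection:
#' `mad_max = Q3 + 3 * IQR` of `piecewise_mad` (a standard far-outlier
#' fence), and `diff_max = min(-2, m - 5 * s)` where `m` and `s` are the
#' median and the normal-consistent MAD (1.4826 scaling) of
#' `median_difference` among samples passing the `mad_max` fence. Suggested
#' thresholds are returned for review, never silently applied.
#'
#' @param features Features `data.frame` with at least 100 non-missing rows.
#' @return A `call_thresholds` with `provenance = "suggested"`.
#' @export
suggest_thresholds <- function(features) {
  ok <- !is.na(features$median_difference) & !is.na(features$piecewise_mad)
  if (sum(ok) < 100L)
    stop("suggest_thresholds needs >= 100 samples with non-missing features")
  pm <- features$piecewise_mad[ok]
  mad_max <- quantile(pm, 0.75, names = FALSE) + 3 * IQR(pm)
  md <- features$median_difference[ok][pm <= mad_max]
  spread <- mad(md)  # 1.4826 * median absolute deviation
  if (spread == 0 || mad_max <= 0)
    stop("degenerate cohort: features have zero spread, cannot suggest thresholds")
  diff_max <- min(-2.0, median(md) - 5 * spread)
  call_thresholds(diff_max, mad_max, provenance = "suggested")
}

#' Write / read a calls table
#'
#' @param calls A `call_set`.
#' @param path File path.
#' @export
write_calls <- function(calls, path) {
  out <- as.data.frame(calls)[, c("sample_id", "call", "median_difference",
                                  "piecewise_mad", "diff_max", "mad_max")]
  out$median_difference <- sprintf("%.6f", out$median_difference)
  out$piecewise_mad <- sprintf("%.6f", out$piecewise_mad)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "nan"))
  for (col in c("median_difference", "piecewise_mad", "diff_max", "mad_max"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
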