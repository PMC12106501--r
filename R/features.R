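# The two per-sample features driving carrier detection: the difference
# between the median normalized intensity of the deletion region and of the
# pooled flanking regions, and a piecewise median absolute deviation that
# measures within-sample scatter around each region's own median. A
# heterozygous carrier sits far left on the difference axis with low MAD;
# noisy, unclassifiable samples sit high on the MAD axis.

med_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  median(x)
}

#' Deletion-minus-flank median difference
#'
#' Median of the deletion-region normalized values minus the median of all
#' flanking values (left and right flanks pooled). Even-length medians are
#' the mean of the two central values. In standard-normal units.
#'
#' @param deletion_values,flank_values Numeric vectors of a single sample's
#'   normalized locus values; `NA` entries are ignored.
#' @return Scalar difference, or `NA` if either region has no non-missing
#'   values.
#' @export
median_difference <- function(deletion_values, flank_values) {
  med_or_na(deletion_values) - med_or_na(flank_values)
}

#' Piecewise median absolute deviation
#'
#' Robust within-sample scatter computed region-wise: absolute deviations of
#' each locus value from its own region's median (deletion; flanks pooled),
#' then combined. The default `"pooled"` rule takes the median of all
#' deviations from both regions together, yielding one number that is zero
#' for an ideal carrier (each region internally constant) — unlike a plain
#' MAD over all loci, which a clean heterozygous deletion would inflate.
#' No normal-consistency constant (1.4826) is applied; the features feed a
#' threshold rule, so the constant would just be absorbed into thresholds.
#'
#' @inheritParams median_difference
#' @param rule How to combine the two regions' deviations: `"pooled"`
#'   (median of pooled deviations, default), `"max"` (larger of the two
#'   region MADs), or `"weighted"` (locus-count-weighted mean of the two
#'   region MADs).
#' @return Non-negative scalar, or `NA` if either region is empty.
#' @export
piecewise_mad <- function(deletion_values, flank_values,
                          rule = c("pooled", "max", "weighted")) {
  rule <- match.arg(rule)
  d <- deletion_values[!is.na(deletion_values)]
  f <- flank_values[!is.na(flank_values)]
  if (!length(d) || !length(f)) return(NA_real_)
  dev_d <- abs(d - median(d))
  dev_f <- abs(f - median(f))
  switch(rule,
         pooled = median(c(dev_d, dev_f)),
         max = max(median(dev_d), median(dev_f)),
         weighted = (length(d) * median(dev_d) + length(f) * median(dev_f)) /
           (length(d) + length(f)))
}

#' Compute per-sample features from a normalized locus matrix
#'
#' @param lm A `locus_matrix` with `stage = "normalized"` (raw sums are
#'   rejected: features are only comparable on the normalized scale).
#' @param map The `locus_map` defining region membership.
#' @param mad_rule Combination rule passed to [piecewise_mad()].
#' @return `data.frame` with one row per sample: `sample_id`,
#'   `median_difference`, `piecewise_mad`, `n_deletion_loci_used`,
#'   `n_flank_loci_used`, `flagged` (`TRUE` when either region had no usable
#'   loci and the features are `NA`). Samples are never dropped.
#' @export
compute_features <- function(lm, map, mad_rule = c("pooled", "max", "weighted")) {
  mad_rule <- match.arg(mad_rule)
  stopifnot(inherits(lm, "locus_matrix"), inherits(map, "locus_map"))
  if (lm$stage != "normalized")
    stop("compute_features requires a normalized locus_matrix (got stage=",
         lm$stage, ")")
  v <- lm$values
  del_ids <- map$loci$locus_id[map$loci$region == "deletion"]
  fl_ids <- map$loci$locus_id[map$loci$region != "deletion"]
  del <- v[, intersect(colnames(v), del_ids), drop = FALSE]
  fl <- v[, intersect(colnames(v), fl_ids), drop = FALSE]
  med_d <- apply(del, 1L, med_or_na)
  med_f <- apply(fl, 1L, med_or_na)
  dev_d <- abs(del - med_d)  # recycles med_d down columns
  dev_f <- abs(fl - med_f)
  pm <- vapply(seq_len(nrow(v)), function(i) {
    if (is.na(med_d[i]) || is.na(med_f[i])) return(NA_real_)
    dd <- dev_d[i, ]; ff <- dev_f[i, ]
    dd <- dd[!is.na(dd)]; ff <- ff[!is.na(ff)]
    switch(mad_rule,
           pooled = median(c(dd, ff)),
           max = max(median(dd), median(ff)),
           weighted = (length(dd) * median(dd) + length(ff) * median(ff)) /
             (length(dd) + length(ff)))
  }, numeric(1))
  out <- data.frame(
    sample_id = rownames(v),
    median_difference = med_d - med_f,
    n_deletion_loci_used = as.integer(rowSums(!is.na(del))),
    n_flank_loci_used = as.integer(rowSums(!is.na(fl))),
    stringsAsFactors = FALSE
  )
  out$piecewise_mad <- pm
  out$flagged <- is.na(out$median_difference) | is.na(out$piecewise_mad)
  rownames(out) <- NULL
  out[, c("sample_id", "median_difference", "piecewise_mad",
          "n_deletion_loci_used", "n_flank_loci_used", "flagged")]
}

#' Write / read the features table
#'
#' TSV surface for downstream calling and for a cluster-plot of the two
#' features (the scatter that makes carriers visually separable).
#'
#' @param features Features `data.frame` from [compute_features()].
#' @param path File path.
#' @export
write_features <- function(features, path) {
  out <- features
  out$median_difference <- sprintf("%.6f", out$median_difference)
  out$piecewise_mad <- sprintf("%.6f", out$piecewise_mad)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "nan"))
  df$median_difference <- as.numeric(df$median_difference)
  df$piecewise_mad <- as.numeric(df$piecewise_mad)
  df
}

#' Cluster plot of the two detection features
#'
#' Convenience scatter of `median_difference` (x) against `piecewise_mad`
#' (y), optionally colouring calls; carriers form a low-MAD outlier cluster
#' left of the main cloud.
#'
#' @param features Features `data.frame`.
#' @param calls Optional call `data.frame` (from [call_cohort()]) used to
#'   colour points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_features <- function(features, calls = NULL, ...) {
  col <- "grey40"
  if (!is.null(calls)) {
    cls <- calls$call[match(features$sample_id, calls$sample_id)]
    col <- c(carrier = "red", negative = "grey40", ambiguous = "orange",
             no_call = "blue")[cls]
  }
  graphics::plot(features$median_difference, features$piecewise_mad,
                 col = col, pch = 16, cex = 0.5,
                 xlab = "median difference (deletion - flank)",
                 ylab = "piecewise MAD", ...)
  invisible(NULL)
}
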