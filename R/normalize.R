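# Locus-level summation and per-locus inverse-normal quantile normalization.
# The summed A+B intensity of all probe sets at a locus represents the total
# chromosomal signal there; rank-to-normal-quantile mapping across samples
# puts every locus on a common standard-normal scale, which is what makes a
# heterozygous deletion visible as a tail outlier.

#' Construct a samples-by-loci matrix container
#'
#' @param values Numeric matrix, rows = samples, columns = loci (position
#'   order); `NA` marks missing entries.
#' @param stage `"summed"` (raw locus totals) or `"normalized"`.
#' @param offset Quantile offset used for normalization (`NA` when summed).
#' @return `locus_matrix` object.
#' @export
locus_matrix <- function(values, stage = c("summed", "normalized"), offset = NA_character_) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(list(values = values, stage = stage, offset = offset),
            class = "locus_matrix")
}

#' @export
print.locus_matrix <- function(x, ...) {
  cat("locus_matrix [", x$stage, "]: ", nrow(x$values), " samples x ",
      ncol(x$values), " loci, ", sum(is.na(x$values)), " missing\n", sep = "")
  invisible(x)
}

#' Sum allele intensities to locus totals
#'
#' For every sample and locus, sums the intensities of both alleles of all
#' of that locus's probe sets that the sample has records for. A sample with
#' no records at a locus (e.g. the locus's probe sets are private to the
#' other array version) gets a missing value, which propagates through
#' normalization rather than being imputed.
#'
#' @param table Validated intensity table (long format).
#' @param map A `locus_map`.
#' @return A `locus_matrix` with `stage = "summed"`; rows are sorted sample
#'   ids, columns are loci in genomic position order.
#' @export
sum_to_locus <- function(table, map) {
  stopifnot(inherits(map, "locus_map"))
  pt <- probe_table(map)
  if (any(!nzchar(pt$array_versions)))
    stop("locus map contains probe sets carried by no array version")
  dt <- data.table::data.table(
    sample_id = table$sample_id,
    locus_id = pt$locus_id[match(table$probe_set_id, pt$probe_set_id)],
    intensity = table$intensity
  )
  if (anyNA(dt$locus_id))
    stop("intensity table contains probe sets absent from the locus map; ",
         "validate with read_intensities()/validate_intensities() first")
  sums <- dt[, list(value = sum(intensity)), by = c("sample_id", "locus_id")]
  samples <- sort(unique(table$sample_id))
  loci <- map$loci$locus_id
  m <- matrix(NA_real_, length(samples), length(loci),
              dimnames = list(samples, loci))
  m[cbind(match(sums$sample_id, samples), match(sums$locus_id, loci))] <- sums$value
  locus_matrix(m, "summed")
}

#' Inverse-normal (rank-based quantile) transform per locus
#'
#' Each locus is normalized independently across samples: the N non-missing
#' values are ranked ascending (ties receive average ranks) and mapped to
#' standard-normal quantiles `qnorm(p(r, N))`. The default offset is Hazen,
#' `p = (r - 0.5) / N`, which is symmetric and keeps extreme ranks finite;
#' Blom `(r - 3/8)/(N + 1/4)` and van der Waerden `r/(N + 1)` are available.
#' Missing values stay missing and do not count towards N. Loci with fewer
#' than two non-missing values cannot be ranked meaningfully and are set
#' all-missing with a warning.
#'
#' @param lm A `locus_matrix` with `stage = "summed"`.
#' @param offset Rank-to-probability offset scheme.
#' @return A `locus_matrix` with `stage = "normalized"`.
#' @export
inverse_normal_transform <- function(lm, offset = c("hazen", "blom", "vanderwaerden")) {
  offset <- match.arg(offset)
  stopifnot(inherits(lm, "locus_matrix"))
  if (lm$stage != "summed")
    stop("inverse_normal_transform expects a summed locus_matrix")
  v <- lm$values
  if (any(is.infinite(v)) || any(is.nan(v)))
    stop("non-finite locus sums; validate inputs upstream")
  out <- matrix(apply(v, 2L, normal_scores, offset = offset),
                nrow = nrow(v), ncol = ncol(v), dimnames = dimnames(v))
  too_few <- colSums(!is.na(v)) < 2L
  if (any(too_few))
    warning("locus with < 2 non-missing values set to all-missing: ",
            paste(colnames(v)[too_few], collapse = ", "))
  locus_matrix(out, "normalized", offset)
}

# rank -> normal quantile for one locus (column); NA-preserving
normal_scores <- function(x, offset) {
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  if (n < 2L) return(out)
  r <- rank(x[ok], ties.method = "average")
  p <- switch(offset,
              hazen = (r - 0.5) / n,
              blom = (r - 3 / 8) / (n + 0.25),
              vanderwaerden = r / (n + 1))
  out[ok] <- qnorm(p)
  out
}

#' Export / import a locus matrix as TSV
#'
#' First column `sample_id`, remaining columns the locus ids in position
#' order; missing encoded as `NA`. A leading comment line records the stage
#' and offset so a round trip preserves them.
#'
#' @param lm A `locus_matrix`.
#' @param path File path.
#' @export
write_locus_matrix <- function(lm, path) {
  stopifnot(inherits(lm, "locus_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# locus_matrix stage=%s offset=%s", lm$stage, lm$offset), con)
  writeLines(paste(c("sample_id", colnames(lm$values)), collapse = "\t"), con)
  body <- apply(format(lm$values, digits = 15, trim = TRUE, scientific = FALSE),
                1L, paste, collapse = "\t")
  writeLines(paste(rownames(lm$values), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_locus_matrix
#' @export
read_locus_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- sub(".*stage=(\\S+).*", "\\1", first)
  offset <- sub(".*offset=(\\S+).*", "\\1", first)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample_id
  locus_matrix(m, stage, if (identical(offset, "NA")) NA_character_ else offset)
}
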