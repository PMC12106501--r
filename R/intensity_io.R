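# I/O for the long-format intensity table and sample manifest. These files
# stand in for the per-probe-set allele intensities extracted upstream from
# raw array data; the package never touches CEL files.

#' Read / write a sample manifest
#'
#' TSV with header `sample_id`, `array_version`, `truth_label`; `truth_label`
#' is optional per row (empty allowed) and restricted to
#' `carrier` / `negative` when present.
#'
#' @param path File path.
#' @return `data.frame` with those three columns (`truth_label` is `NA`
#'   where empty).
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  need <- c("sample_id", "array_version")
  if (!all(need %in% names(df)))
    stop("manifest '", path, "' must have columns sample_id, array_version")
  if (!"truth_label" %in% names(df)) df$truth_label <- NA_character_
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest Manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  out <- manifest[, c("sample_id", "array_version", "truth_label")]
  out$truth_label[is.na(out$truth_label)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @export
validate_manifest <- function(manifest) {
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in manifest: ",
         manifest$sample_id[duplicated(manifest$sample_id)][1])
  lab <- manifest$truth_label
  bad <- !is.na(lab) & !(lab %in% c("carrier", "negative"))
  if (any(bad))
    stop("truth_label must be 'carrier' or 'negative', got '", lab[bad][1], "'")
  manifest$sample_id <- as.character(manifest$sample_id)
  manifest$array_version <- as.character(manifest$array_version)
  manifest
}

#' Read a long-format intensity table
#'
#' One record per (sample, probe set, allele) with a non-negative intensity
#' in arbitrary fluorescence units. Records for probe sets absent from the
#' locus map are dropped with a message; records for probe sets not carried
#' by the sample's array version are an error (they cannot exist on the
#' physical chip). Parse errors report the offending 1-based data line.
#'
#' @param path File path of a TSV with header
#'   `sample_id`, `probe_set_id`, `allele`, `intensity`.
#' @param manifest Validated manifest covering every sample in the file.
#' @param map A `locus_map`.
#' @return Validated intensity `data.frame`.
#' @export
read_intensities <- function(path, manifest, map) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "probe_set_id", "allele", "intensity")
  if (!all(need %in% names(df)))
    stop("intensity table '", path, "' must have columns ",
         paste(need, collapse = ", "))
  validate_intensities(df, manifest, map)
}

#' @rdname read_intensities
#' @param table Intensity `data.frame`.
#' @export
write_intensities <- function(table, path) {
  write.table(table[, c("sample_id", "probe_set_id", "allele", "intensity")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_intensities
#' @export
validate_intensities <- function(table, manifest, map) {
  manifest <- validate_manifest(manifest)
  bad <- which(!is.finite(table$intensity) | table$intensity < 0)
  if (length(bad))
    stop("non-finite or negative intensity at data line ", bad[1],
         " (sample ", table$sample_id[bad[1]], ")")
  bad <- which(!table$allele %in% c("A", "B"))
  if (length(bad))
    stop("allele must be 'A' or 'B' at data line ", bad[1])
  unknown <- which(!table$sample_id %in% manifest$sample_id)
  if (length(unknown))
    stop("unknown sample '", table$sample_id[unknown[1]],
         "' at data line ", unknown[1])
  pt <- probe_table(map)
  inmap <- table$probe_set_id %in% pt$probe_set_id
  if (any(!inmap)) {
    message("dropping ", sum(!inmap),
            " record(s) for probe sets absent from the locus map")
    table <- table[inmap, , drop = FALSE]
  }
  dup <- which(duplicated(table[, c("sample_id", "probe_set_id", "allele")]))
  if (length(dup))
    stop("duplicate (sample, probe set, allele) record at data line ", dup[1],
         " (", table$sample_id[dup[1]], ", ", table$probe_set_id[dup[1]], ")")
  # array-version membership: a sample can only have records for probe sets
  # physically present on its chip version
  ver <- manifest$array_version[match(table$sample_id, manifest$sample_id)]
  av <- strsplit(pt$array_versions, ";", fixed = TRUE)
  valid_pairs <- paste(rep(pt$probe_set_id, lengths(av)),
                       unlist(av, use.names = FALSE))
  ok <- paste(table$probe_set_id, ver) %in% valid_pairs
  if (any(!ok)) {
    i <- which(!ok)[1]
    stop("record at data line ", i, ": probe set ", table$probe_set_id[i],
         " is not on array version ", ver[i], " of sample ", table$sample_id[i])
  }
  rownames(table) <- NULL
  table
}

#' Per-sample completeness of the intensity table
#'
#' For each manifest sample, the fraction of expected (probe set, allele)
#' records actually present, where the expectation is 2 alleles for every
#' in-map probe set carried by the sample's array version. Useful for
#' surfacing partially failed samples before normalization.
#'
#' @param table Validated intensity table.
#' @param map A `locus_map`.
#' @param manifest Validated manifest.
#' @param threshold Samples with completeness below this are flagged
#'   (default 0.95).
#' @return `data.frame` with `sample_id`, `n_expected`, `n_present`,
#'   `completeness`, `flagged`.
#' @export
completeness_report <- function(table, map, manifest, threshold = 0.95) {
  manifest <- validate_manifest(manifest)
  versions <- unique(manifest$array_version)
  n_ps <- vapply(versions, function(v) length(probe_sets_for_version(map, v)),
                 integer(1))
  expected <- 2L * n_ps[match(manifest$array_version, versions)]
  present <- table(factor(table$sample_id, levels = manifest$sample_id))
  out <- data.frame(
    sample_id = manifest$sample_id,
    n_expected = as.integer(expected),
    n_present = as.integer(present),
    stringsAsFactors = FALSE
  )
  out$completeness <- ifelse(out$n_expected > 0, out$n_present / out$n_expected, 0)
  out$flagged <- out$completeness < threshold
  out
}
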