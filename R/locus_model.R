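#' @import data.table
#' @importFrom stats median qnorm quantile rbeta rbinom rnorm runif setNames IQR mad
#' @importFrom utils read.delim write.table
NULL

REGION_LABELS <- c("deletion", "flank_left", "flank_right")

#' Default target and flanking regions
#'
#' The default target is the 3,538 bp in-frame deletion removing exon 16 of
#' *MLH1* (GRCh38 3:37044575-37048112), a Finnish founder Lynch-syndrome
#' variant. Flanking regions extend symmetrically on both sides and serve as
#' the within-sample copy-number baseline. All coordinates are 1-based
#' inclusive, so a region's length is `end - start + 1`.
#'
#' @param flank_span Width in bp of each flanking region (default 5000).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`
#'   (one row per region, labels `deletion`, `flank_left`, `flank_right`).
#' @export
default_regions <- function(flank_span = 5000L) {
  del_start <- 37044575L
  del_end <- 37048112L
  regions <- data.frame(
    chrom = "3",
    start = c(del_start, del_start - as.integer(flank_span), del_end + 1L),
    end = c(del_end, del_start - 1L, del_end + as.integer(flank_span)),
    label = REGION_LABELS,
    stringsAsFactors = FALSE
  )
  validate_regions(regions)
}

#' Validate a region table
#'
#' Checks the three-region contract: labels are exactly `deletion`,
#' `flank_left`, `flank_right`; `start <= end`; regions do not overlap.
#' Flanks may abut the deletion but not intrude into it.
#'
#' @param regions A region `data.frame` (see [default_regions()]).
#' @return The validated `data.frame`, invisibly the same object.
#' @export
validate_regions <- function(regions) {
  need <- c("chrom", "start", "end", "label")
  if (!is.data.frame(regions) || !all(need %in% names(regions)))
    stop("regions must be a data.frame with columns ", paste(need, collapse = ", "))
  if (!setequal(regions$label, REGION_LABELS) || nrow(regions) != 3L)
    stop("regions must contain exactly one row per label: ",
         paste(REGION_LABELS, collapse = ", "))
  if (any(regions$start > regions$end))
    stop("region start must be <= end (1-based inclusive coordinates)")
  # pairwise overlap check within each chromosome
  for (i in 1:2) for (j in (i + 1):3) {
    a <- regions[i, ]; b <- regions[j, ]
    if (a$chrom == b$chrom && a$start <= b$end && b$start <= a$end)
      stop("regions '", a$label, "' and '", b$label, "' overlap")
  }
  rownames(regions) <- NULL
  regions
}

#' Region length in base pairs
#'
#' Coordinates are 1-based inclusive, so length is `end - start + 1`; the
#' printed deletion coordinates 3:37044575-37048112 give 3538 bp.
#'
#' @param regions Region `data.frame` (one or more rows) or a list/row with
#'   `start` and `end`.
#' @return Integer vector of lengths, one per row.
#' @export
region_length <- function(regions) {
  as.integer(regions$end) - as.integer(regions$start) + 1L
}

#' Assign a genomic position to a region
#'
#' Membership is inclusive on both boundaries. Positions outside all three
#' regions (or on another chromosome) return `"outside"`.
#'
#' @param pos Integer vector of 1-based positions.
#' @param regions Validated region `data.frame`.
#' @param chrom Chromosome of `pos` (scalar or vector); defaults to the
#'   deletion region's chromosome.
#' @return Character vector: `deletion`, `flank_left`, `flank_right` or
#'   `outside`.
#' @export
assign_region <- function(pos, regions, chrom = NULL) {
  regions <- validate_regions(regions)
  if (any(pos < 1L)) stop("positions must be >= 1")
  if (is.null(chrom)) chrom <- regions$chrom[regions$label == "deletion"]
  chrom <- rep_len(as.character(chrom), length(pos))
  out <- rep("outside", length(pos))
  for (i in seq_len(nrow(regions))) {
    hit <- chrom == regions$chrom[i] &
      pos >= regions$start[i] & pos <= regions$end[i]
    out[hit] <- regions$label[i]
  }
  out
}

#' Construct a locus map
#'
#' A locus map ties probe sets to loci and loci to regions. Each locus is a
#' unique genomic position interrogated by one or more probe sets; each
#' probe set carries the set of array versions that include it. Loci are
#' sorted by (chrom, pos) with ties broken on `locus_id`; identical
#' positions are disallowed (probe sets at one position must share a locus).
#'
#' @param regions Validated region `data.frame`.
#' @param loci A `data.frame` with columns `locus_id`, `chrom`, `pos`,
#'   `region`, and list-columns `probe_set_ids` (character vectors) and
#'   `array_versions` (character vectors parallel to `probe_set_ids`, each
#'   entry the versions carrying that probe set joined by `";"`).
#' @return An object of class `locus_map`: a list with elements `regions`
#'   and `loci`.
#' @export
locus_map <- function(regions, loci) {
  regions <- validate_regions(regions)
  need <- c("locus_id", "chrom", "pos", "region", "probe_set_ids", "array_versions")
  if (!all(need %in% names(loci)))
    stop("loci must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(loci$locus_id))
    stop("duplicate locus_id: ",
         paste(unique(loci$locus_id[duplicated(loci$locus_id)]), collapse = ", "))
  if (anyDuplicated(loci[, c("chrom", "pos")]))
    stop("loci at identical positions are disallowed; merge their probe sets")
  assigned <- assign_region(loci$pos, regions, loci$chrom)
  bad <- which(assigned != loci$region)
  if (length(bad))
    stop("locus ", loci$locus_id[bad[1]], " labelled '", loci$region[bad[1]],
         "' but position ", loci$pos[bad[1]], " lies in '", assigned[bad[1]], "'")
  nps <- vapply(loci$probe_set_ids, length, integer(1))
  if (any(nps == 0L)) stop("every locus needs at least one probe set")
  nav <- vapply(loci$array_versions, length, integer(1))
  if (any(nav != nps))
    stop("array_versions must be parallel to probe_set_ids for every locus")
  ps <- unlist(loci$probe_set_ids, use.names = FALSE)
  if (anyDuplicated(ps))
    stop("probe set assigned to more than one locus: ",
         paste(unique(ps[duplicated(ps)]), collapse = ", "))
  ord <- order(loci$chrom, loci$pos, loci$locus_id)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(regions = regions, loci = loci), class = "locus_map")
}

#' @export
print.locus_map <- function(x, ...) {
  tab <- table(x$loci$region)
  cat("locus_map:", nrow(x$loci), "loci,",
      length(unlist(x$loci$probe_set_ids)), "probe sets\n")
  cat("  deletion region:", x$regions$chrom[x$regions$label == "deletion"], ":",
      x$regions$start[x$regions$label == "deletion"], "-",
      x$regions$end[x$regions$label == "deletion"],
      sprintf("(%d bp)\n", region_length(x$regions[x$regions$label == "deletion", ])))
  for (r in REGION_LABELS)
    cat(sprintf("  %-11s %d loci\n", r, if (r %in% names(tab)) tab[[r]] else 0L))
  invisible(x)
}

#' Flatten a locus map to a per-probe-set table
#'
#' @param map A `locus_map`.
#' @return `data.frame` with one row per probe set: `probe_set_id`,
#'   `locus_id`, `region`, `pos`, `array_versions` (";"-joined string).
#' @export
probe_table <- function(map) {
  stopifnot(inherits(map, "locus_map"))
  n <- vapply(map$loci$probe_set_ids, length, integer(1))
  data.frame(
    probe_set_id = unlist(map$loci$probe_set_ids, use.names = FALSE),
    locus_id = rep(map$loci$locus_id, n),
    region = rep(map$loci$region, n),
    pos = rep(map$loci$pos, n),
    array_versions = unlist(map$loci$array_versions, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Probe sets present on one array version
#'
#' @param map A `locus_map`.
#' @param version Array version string (e.g. `"v1"`).
#' @return Character vector of probe set ids carried by that version.
#' @export
probe_sets_for_version <- function(map, version) {
  pt <- probe_table(map)
  carried <- vapply(strsplit(pt$array_versions, ";", fixed = TRUE),
                    function(v) version %in% v, logical(1))
  pt$probe_set_id[carried]
}

#' Build the default locus-map template
#'
#' Mirrors the array content of the target assay: `n_deletion_loci` loci
#' inside the deletion interrogated by `n_probe_sets_deletion` probe sets
#' (the surplus probe sets double up on the first loci), and `n_flank_per_side`
#' evenly spaced loci per flank, each with one probe set shared across both
#' array versions. Flank probe sets are always shared (only probe sets present
#' on both arrays are usable as a common baseline); a configurable minority of
#' deletion probe sets can be version-specific.
#'
#' @param regions Region table; default [default_regions()].
#' @param n_deletion_loci Loci inside the deletion (default 18).
#' @param n_probe_sets_deletion Total deletion probe sets (default 21,
#'   must be `>= n_deletion_loci`).
#' @param n_flank_per_side Flanking loci per side (default 25, i.e. 50 total).
#' @param array_versions Character vector of version names.
#' @param n_deletion_version_specific How many deletion probe sets are
#'   private to a single version (alternating across versions; default 2).
#' @return A `locus_map`.
#' @export
default_locus_map <- function(regions = default_regions(),
                              n_deletion_loci = 18L,
                              n_probe_sets_deletion = 21L,
                              n_flank_per_side = 25L,
                              array_versions = c("v1", "v2"),
                              n_deletion_version_specific = 2L) {
  regions <- validate_regions(regions)
  if (n_probe_sets_deletion < n_deletion_loci)
    stop("n_probe_sets_deletion must be >= n_deletion_loci")
  if (n_deletion_version_specific > n_probe_sets_deletion)
    stop("n_deletion_version_specific must be <= n_probe_sets_deletion")
  del <- regions[regions$label == "deletion", ]
  fl <- regions[regions$label == "flank_left", ]
  fr <- regions[regions$label == "flank_right", ]
  spread <- function(a, b, n) as.integer(round(seq(a, b, length.out = n + 2L)))[2:(n + 1L)]
  pos_del <- spread(del$start, del$end, n_deletion_loci)
  pos_fl <- spread(fl$start, fl$end, n_flank_per_side)
  pos_fr <- spread(fr$start, fr$end, n_flank_per_side)
  all_versions <- paste(array_versions, collapse = ";")

  # deletion loci: surplus probe sets double up on the earliest loci;
  # the first n_deletion_version_specific probe sets cycle through single
  # versions, the rest are shared.
  extra <- n_probe_sets_deletion - n_deletion_loci
  ps_per_locus <- rep(1L, n_deletion_loci)
  if (extra > 0L) ps_per_locus[seq_len(extra)] <- ps_per_locus[seq_len(extra)] + 1L
  ps_counter <- 0L
  del_ps <- vector("list", n_deletion_loci)
  del_av <- vector("list", n_deletion_loci)
  spec_left <- n_deletion_version_specific
  for (i in seq_len(n_deletion_loci)) {
    ids <- sprintf("PSD%04d", ps_counter + seq_len(ps_per_locus[i]))
    ps_counter <- ps_counter + ps_per_locus[i]
    av <- rep(all_versions, length(ids))
    for (j in seq_along(ids)) {
      if (spec_left > 0L) {
        av[j] <- array_versions[(n_deletion_version_specific - spec_left) %%
                                  length(array_versions) + 1L]
        spec_left <- spec_left - 1L
      }
    }
    del_ps[[i]] <- ids
    del_av[[i]] <- av
  }

  loci <- data.frame(
    locus_id = c(sprintf("del_%02d", seq_len(n_deletion_loci)),
                 sprintf("fl_%02d", seq_len(n_flank_per_side)),
                 sprintf("fr_%02d", seq_len(n_flank_per_side))),
    chrom = del$chrom,
    pos = c(pos_del, pos_fl, pos_fr),
    region = c(rep("deletion", n_deletion_loci),
               rep("flank_left", n_flank_per_side),
               rep("flank_right", n_flank_per_side)),
    stringsAsFactors = FALSE
  )
  loci$probe_set_ids <- c(del_ps,
                          as.list(sprintf("PSL%04d", seq_len(n_flank_per_side))),
                          as.list(sprintf("PSR%04d", seq_len(n_flank_per_side))))
  loci$array_versions <- c(del_av, rep(list(all_versions), 2L * n_flank_per_side))
  locus_map(regions, loci)
}

#' Write / read the region table
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `label`. Unlike BED
#' proper, coordinates are 1-based inclusive; this dialect is stated in a
#' leading comment line.
#'
#' @param regions Region `data.frame`.
#' @param path File path.
#' @export
write_regions <- function(regions, path) {
  regions <- validate_regions(regions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive (length = end - start + 1)", con)
  writeLines(paste(c("chrom", "start", "end", "label"), collapse = "\t"), con)
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start,
                     regions$end, regions$label), con)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  validate_regions(df)
}

#' Write / read a locus map
#'
#' TSV with header `chrom`, `pos`, `locus_id`, `region`, `probe_set_ids`
#' (comma-joined) and `array_versions` (comma-joined, parallel to
#' `probe_set_ids`; versions within one entry joined by `";"`). Loci are
#' sorted by position on read; invariant violations raise errors that name
#' the offending line.
#'
#' @param map A `locus_map`.
#' @param path File path.
#' @export
write_locus_map <- function(map, path) {
  stopifnot(inherits(map, "locus_map"))
  lc <- map$loci
  df <- data.frame(
    chrom = lc$chrom, pos = lc$pos, locus_id = lc$locus_id, region = lc$region,
    probe_set_ids = vapply(lc$probe_set_ids, paste, "", collapse = ","),
    array_versions = vapply(lc$array_versions, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locus_map
#' @param regions Region table the map belongs to (read separately, see
#'   [read_regions()]).
#' @export
read_locus_map <- function(path, regions) {
  df <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE,
               colClasses = c(chrom = "character")),
    error = function(e) stop("cannot parse locus map '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("locus map '", path, "' is empty")
  need <- c("chrom", "pos", "locus_id", "region", "probe_set_ids", "array_versions")
  if (!all(need %in% names(df)))
    stop("locus map '", path, "' must have columns ", paste(need, collapse = ", "))
  dup <- which(duplicated(df$locus_id))
  if (length(dup))
    stop("duplicate locus_id '", df$locus_id[dup[1]], "' at line ", dup[1] + 1L)
  assigned <- assign_region(df$pos, regions, df$chrom)
  bad <- which(assigned == "outside")
  if (length(bad))
    stop("locus '", df$locus_id[bad[1]], "' at line ", bad[1] + 1L,
         " lies outside all regions")
  mis <- which(assigned != df$region)
  if (length(mis))
    stop("locus '", df$locus_id[mis[1]], "' at line ", mis[1] + 1L,
         " labelled '", df$region[mis[1]], "' but lies in '", assigned[mis[1]], "'")
  df$probe_set_ids <- strsplit(df$probe_set_ids, ",", fixed = TRUE)
  df$array_versions <- strsplit(df$array_versions, ",", fixed = TRUE)
  locus_map(regions, df[, need])
}
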