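# Small in-code fixtures shared across test files.

# A 3-locus map (1 deletion locus with 2 probe sets, 1 locus per flank)
tiny_map <- function() {
  regions <- data.frame(
    chrom = "3",
    start = c(37044575L, 37039575L, 37048113L),
    end = c(37048112L, 37044574L, 37053112L),
    label = c("deletion", "flank_left", "flank_right"),
    stringsAsFactors = FALSE)
  loci <- data.frame(
    locus_id = c("d1", "l1", "r1"),
    chrom = "3",
    pos = c(37045000L, 37040000L, 37050000L),
    region = c("deletion", "flank_left", "flank_right"),
    stringsAsFactors = FALSE)
  loci$probe_set_ids <- list(c("PA", "PB"), "PL", "PR")
  loci$array_versions <- list(c("v1;v2", "v2"), "v1;v2", "v1;v2")
  locus_map(regions, loci)
}

tiny_manifest <- function(n = 2L, versions = c("v1", "v2")) {
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             array_version = rep_len(versions, n),
             truth_label = NA_character_,
             stringsAsFactors = FALSE)
}

# long intensity table from a named list: sample -> probe set -> c(A, B)
build_intensities <- function(spec) {
  rows <- list()
  for (s in names(spec)) for (p in names(spec[[s]])) {
    v <- spec[[s]][[p]]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s, probe_set_id = p, allele = c("A", "B"),
      intensity = v, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# a random valid locus map, for round-trip property tests
random_locus_map <- function(seed) {
  set.seed(seed)
  n_del <- sample(2:6, 1)
  n_fl <- sample(2:5, 1)
  default_locus_map(n_deletion_loci = n_del,
                    n_probe_sets_deletion = n_del + sample(0:3, 1),
                    n_flank_per_side = n_fl,
                    n_deletion_version_specific = sample(0:2, 1))
}

# column-wise ranks of a matrix, NA-preserving
rank_matrix <- function(m) {
  apply(m, 2L, function(x) rank(x, na.last = "keep", ties.method = "average"))
}

# independent brute-force inverse-normal oracle: average ranks computed by
# pairwise counting (no call to rank()), Hazen offset
oracle_int <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  xs <- x[ok]
  r <- vapply(xs, function(xi) sum(xs < xi) + (sum(xs == xi) + 1) / 2, numeric(1))
  out[ok] <- qnorm((r - 0.5) / n)
  out
}
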