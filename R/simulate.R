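# Synthetic-cohort generator. Emulates the statistical structure the
# detection method relies on: two array versions with overlapping probe-set
# content, multiplicative lognormal intensity noise, heterozygous carriers
# with halved total signal across all deletion-region probe sets, and a
# minority class of high-variance "noisy" samples. Everything downstream of
# probe-intensity extraction is exercised end to end on these cohorts.

#' Simulation configuration
#'
#' Defaults encode the conditions of the target assay: 18 deletion
#' loci interrogated by 21 probe sets, 25 flanking loci per side (50 total),
#' 28% of samples on array v1, carrier prevalence 0.024%, and a signal
#' ratio of 0.5 for heterozygous carriers (one of two copies lost). Noise
#' defaults reflect intensities that have already passed vendor-side
#' summarization and normalization, so between-sample scale differences are
#' small while probe-level scatter dominates: `sample_scale_sd = 0.03`,
#' `probe_noise_sd = 0.12` (both on the log scale). Noisy samples get
#' `noisy_extra_sd = 0.05` added to their per-record noise sd — roughly a
#' doubling of record-noise variance, emulating degraded but still
#' hybridized arrays; see the methods vignette for why a much larger
#' elevation would contradict the cluster geometry the real assay shows.
#'
#' @param n_samples Cohort size.
#' @param carrier_fraction Per-sample probability of being a heterozygous
#'   carrier (default 0.00024).
#' @param n_carriers Optional exact carrier count; when given it overrides
#'   the binomial draw implied by `carrier_fraction` (useful for planting a
#'   fixed number of carriers in evaluation runs).
#' @param noisy_fraction Probability (among non-carriers) of the
#'   high-variance class (default 0.01).
#' @param n_deletion_loci,n_probe_sets_deletion,n_flank_per_side Locus-map
#'   template parameters (defaults 18 / 21 / 25).
#' @param n_deletion_version_specific Deletion probe sets private to one
#'   array version (default 2).
#' @param baseline_mean Typical per-probe-set total intensity in
#'   fluorescence units (default 2000).
#' @param probe_baseline_sd Log-scale scatter of per-probe-set brightness
#'   around `baseline_mean` (default 0.4; probes differ several-fold in
#'   brightness on real arrays).
#' @param sample_scale_sd Log-scale per-sample multiplicative scatter.
#' @param probe_noise_sd Log-scale per-record noise sd.
#' @param deletion_signal_ratio Expected carrier/non-carrier total-signal
#'   ratio at deletion loci (default 0.5 = heterozygous).
#' @param noisy_extra_sd Additional per-record noise sd for noisy samples.
#' @param v1_fraction Fraction of samples on array version v1 (default 0.28).
#' @param rng_seed Integer seed; the whole cohort is a deterministic
#'   function of the config including this seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 10000L,
                              carrier_fraction = 0.00024,
                              n_carriers = NULL,
                              noisy_fraction = 0.01,
                              n_deletion_loci = 18L,
                              n_probe_sets_deletion = 21L,
                              n_flank_per_side = 25L,
                              n_deletion_version_specific = 2L,
                              baseline_mean = 2000,
                              probe_baseline_sd = 0.4,
                              sample_scale_sd = 0.03,
                              probe_noise_sd = 0.12,
                              deletion_signal_ratio = 0.5,
                              noisy_extra_sd = 0.05,
                              v1_fraction = 0.28,
                              rng_seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              carrier_fraction = carrier_fraction,
              n_carriers = if (is.null(n_carriers)) NULL else as.integer(n_carriers),
              noisy_fraction = noisy_fraction,
              n_deletion_loci = as.integer(n_deletion_loci),
              n_probe_sets_deletion = as.integer(n_probe_sets_deletion),
              n_flank_per_side = as.integer(n_flank_per_side),
              n_deletion_version_specific = as.integer(n_deletion_version_specific),
              baseline_mean = baseline_mean,
              probe_baseline_sd = probe_baseline_sd,
              sample_scale_sd = sample_scale_sd,
              probe_noise_sd = probe_noise_sd,
              deletion_signal_ratio = deletion_signal_ratio,
              noisy_extra_sd = noisy_extra_sd,
              v1_fraction = v1_fraction,
              rng_seed = as.integer(rng_seed))
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 1L) stop("n_samples must be positive")
    if (carrier_fraction < 0 || carrier_fraction > 1)
      stop("carrier_fraction must be in [0, 1]")
    if (noisy_fraction < 0 || noisy_fraction > 1)
      stop("noisy_fraction must be in [0, 1]")
    if (carrier_fraction + noisy_fraction > 1)
      stop("carrier_fraction + noisy_fraction must be <= 1")
    if (!is.null(n_carriers) && (n_carriers < 0 || n_carriers > n_samples))
      stop("n_carriers must be between 0 and n_samples")
    if (n_probe_sets_deletion < n_deletion_loci)
      stop("n_probe_sets_deletion must be >= n_deletion_loci")
    if (baseline_mean <= 0) stop("baseline_mean must be positive")
    if (sample_scale_sd < 0 || probe_noise_sd < 0 || noisy_extra_sd < 0 ||
        probe_baseline_sd < 0)
      stop("noise sds must be non-negative")
    if (deletion_signal_ratio <= 0 || deletion_signal_ratio > 1)
      stop("deletion_signal_ratio must be in (0, 1]")
    if (v1_fraction < 0 || v1_fraction > 1)
      stop("v1_fraction must be in [0, 1]")
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate a synthetic cohort
#'
#' Per-record model: `intensity = baseline(probe set) * sample_scale *
#' copy_factor * allele_split * exp(noise)`, where `copy_factor` is
#' `deletion_signal_ratio` for carrier samples at deletion-region probe sets
#' and 1 otherwise; `sample_scale` is lognormal with sd `sample_scale_sd`;
#' the probe-set total is split between the A and B alleles by a Beta(2, 2)
#' draw (only the A+B sum matters downstream, the split keeps the I/O
#' schema honest); and `noise` is normal with sd `probe_noise_sd`
#' (+ `noisy_extra_sd` for noisy samples). A single RNG stream seeded from
#' `rng_seed` makes the cohort byte-reproducible; the caller's RNG state is
#' left untouched.
#'
#' @param config A `simulation_config`.
#' @return A `simulated_cohort` list: `manifest` (with `truth_label` and a
#'   `noisy` flag), `intensities` (long table), `locus_map`, `config`.
#' @export
simulate_cohort <- function(config) {
  config <- validate_simulation_config(config)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$rng_seed)

  map <- default_locus_map(
    n_deletion_loci = config$n_deletion_loci,
    n_probe_sets_deletion = config$n_probe_sets_deletion,
    n_flank_per_side = config$n_flank_per_side,
    n_deletion_version_specific = config$n_deletion_version_specific)
  pt <- probe_table(map)
  baselines <- setNames(
    config$baseline_mean * exp(rnorm(nrow(pt), 0, config$probe_baseline_sd)),
    pt$probe_set_id)

  n <- config$n_samples
  sample_id <- sprintf("S%06d", seq_len(n))
  version <- ifelse(runif(n) < config$v1_fraction, "v1", "v2")
  if (is.null(config$n_carriers)) {
    carrier <- runif(n) < config$carrier_fraction
  } else {
    carrier <- rep(FALSE, n)
    carrier[sample.int(n, config$n_carriers)] <- TRUE
  }
  noisy <- !carrier & runif(n) < config$noisy_fraction
  scale <- exp(rnorm(n, 0, config$sample_scale_sd))

  manifest <- data.frame(
    sample_id = sample_id, array_version = version,
    truth_label = ifelse(carrier, "carrier", "negative"),
    noisy = noisy, stringsAsFactors = FALSE)

  ps_by_version <- lapply(c(v1 = "v1", v2 = "v2"),
                          function(v) probe_sets_for_version(map, v))
  nps <- vapply(ps_by_version, length, integer(1))[ifelse(version == "v1", 1L, 2L)]
  # one block of records per sample, probe sets of its version, alleles A+B
  samp_idx <- rep.int(seq_len(n), nps)
  ps <- unlist(ps_by_version[ifelse(version == "v1", 1L, 2L)], use.names = FALSE)
  region <- pt$region[match(ps, pt$probe_set_id)]
  copy <- ifelse(carrier[samp_idx] & region == "deletion",
                 config$deletion_signal_ratio, 1)
  total <- baselines[match(ps, pt$probe_set_id)] * scale[samp_idx] * copy
  sd_rec <- config$probe_noise_sd + ifelse(noisy[samp_idx], config$noisy_extra_sd, 0)
  split_a <- rbeta(length(ps), 2, 2)
  nrec <- length(ps)
  base_a <- total * split_a
  # B is the exact complement so that A + B == total bit-for-bit when the
  # record noise is zero (keeps noiseless samples exactly tied in ranks)
  base_b <- total - base_a
  int_a <- base_a * exp(rnorm(nrec, 0, sd_rec))
  int_b <- base_b * exp(rnorm(nrec, 0, sd_rec))

  intensities <- data.frame(
    sample_id = rep(sample_id[samp_idx], 2L),
    probe_set_id = rep(ps, 2L),
    allele = rep(c("A", "B"), each = nrec),
    intensity = c(int_a, int_b),
    stringsAsFactors = FALSE)
  ord <- order(intensities$sample_id, intensities$probe_set_id, intensities$allele)
  intensities <- intensities[ord, , drop = FALSE]
  rownames(intensities) <- NULL

  structure(list(manifest = manifest, intensities = intensities,
                 locus_map = map, config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort:", nrow(x$manifest), "samples,",
      nrow(x$intensities), "intensity records\n")
  cat("  carriers:", sum(x$manifest$truth_label == "carrier"),
      " noisy:", sum(x$manifest$noisy), "\n")
  invisible(x)
}

#' Analytic feature location of an ideal noiseless carrier
#'
#' With all noise sds at zero, every non-carrier ties at each locus and the
#' `k` carriers tie below them at deletion loci. Under average ranks and the
#' Hazen offset, each carrier's normalized deletion value is exactly
#' `qnorm(((k + 1)/2 - 0.5) / N)` while flank values (all N tied) map to 0,
#' so the expected `median_difference` equals that quantile and the expected
#' `piecewise_mad` is 0. With `deletion_signal_ratio = 1` (or `k = N`) all
#' samples tie everywhere and the difference collapses to 0: rank-based
#' normalization is blind to shifts shared by every sample.
#'
#' @param config A `simulation_config`.
#' @param n_carriers Number of carriers `k` (default `config$n_carriers`,
#'   else the expected count `n_samples * carrier_fraction` rounded).
#' @return List with `median_difference` and `piecewise_mad`.
#' @export
expected_feature_location <- function(config, n_carriers = NULL) {
  config <- validate_simulation_config(config)
  k <- if (!is.null(n_carriers)) as.integer(n_carriers)
       else if (!is.null(config$n_carriers)) config$n_carriers
       else as.integer(round(config$n_samples * config$carrier_fraction))
  n <- config$n_samples
  if (k <= 0L) stop("expected_feature_location is undefined for zero carriers")
  if (k > n) stop("n_carriers cannot exceed n_samples")
  md <- if (config$deletion_signal_ratio == 1) 0 else qnorm(((k + 1) / 2 - 0.5) / n)
  list(median_difference = md, piecewise_mad = 0)
}

#' Write a simulated cohort to a directory
#'
#' Writes `manifest.tsv`, `intensities.tsv`, `locus_map.tsv`, `regions.tsv`
#' and `truth.tsv` (sample_id, truth_label, noisy), plus `config.yaml`
#' echoing the generating configuration.
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  write_intensities(cohort$intensities, file.path(dir, "intensities.tsv"))
  write_locus_map(cohort$locus_map, file.path(dir, "locus_map.tsv"))
  write_regions(cohort$locus_map$regions, file.path(dir, "regions.tsv"))
  truth <- cohort$manifest[, c("sample_id", "truth_label", "noisy")]
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- cohort$config
  cfg$n_carriers <- if (is.null(cfg$n_carriers)) "" else cfg$n_carriers
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a simulation config from YAML
#'
#' Flat key: value file mirroring [simulation_config()] arguments; unknown
#' keys are an error.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown simulation config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$n_carriers) && identical(raw$n_carriers, "")) raw$n_carriers <- NULL
  do.call(simulation_config, raw)
}
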