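test_that("config validation rejects infeasible settings", {
  expect_error(simulation_config(n_samples = 0), "positive")
  expect_error(simulation_config(carrier_fraction = 1.5), "carrier_fraction")
  expect_error(simulation_config(carrier_fraction = 0.6, noisy_fraction = 0.6),
               "<= 1")
  expect_error(simulation_config(deletion_signal_ratio = 0), "signal_ratio")
  expect_error(simulation_config(n_carriers = 11, n_samples = 10),
               "between 0 and n_samples")
})

test_that("simulation is deterministic and leaves the caller RNG alone", {
  cfg <- simulation_config(n_samples = 200L, rng_seed = 5L)
  set.seed(99)
  before <- .Random.seed
  a <- simulate_cohort(cfg)
  expect_identical(.Random.seed, before)
  b <- simulate_cohort(cfg)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$manifest, b$manifest)
  # and a different seed gives different data
  c <- simulate_cohort(simulation_config(n_samples = 200L, rng_seed = 6L))
  expect_false(identical(a$intensities$intensity, c$intensities$intensity))
})

test_that("carrier planting follows the config", {
  cfg0 <- simulation_config(n_samples = 300L, carrier_fraction = 0,
                            rng_seed = 1L)
  expect_identical(sum(simulate_cohort(cfg0)$manifest$truth_label == "carrier"), 0L)
  cfg8 <- simulation_config(n_samples = 300L, n_carriers = 8L, rng_seed = 1L)
  expect_identical(sum(simulate_cohort(cfg8)$manifest$truth_label == "carrier"), 8L)
})

test_that("carrier counts follow the binomial law across seeds", {
  # mean carrier count over 200 seeds of Binomial(10000, 2.4e-4) cohorts
  # within 3 standard errors of n*p = 2.4 (tiny locus map to keep it fast)
  counts <- vapply(1:200, function(s) {
    cfg <- simulation_config(n_samples = 10000L, rng_seed = s,
                             n_deletion_loci = 2L, n_probe_sets_deletion = 2L,
                             n_flank_per_side = 2L,
                             n_deletion_version_specific = 0L)
    sum(simulate_cohort(cfg)$manifest$truth_label == "carrier")
  }, numeric(1))
  p <- 0.00024; n <- 10000
  se <- sqrt(n * p * (1 - p) / 200)
  expect_lt(abs(mean(counts) - n * p), 3 * se)
  expect_gt(stats::var(counts), 0)  # a realized draw, not a constant
})

test_that("simulated intensities follow the multiplicative model", {
  # noiseless: carrier total at deletion loci = ratio x non-carrier total
  # all probe sets shared so carrier/non-carrier values are comparable
  # without mixing array-version probe content
  cfg <- simulation_config(n_samples = 20L, n_carriers = 4L,
                           sample_scale_sd = 0, probe_noise_sd = 0,
                           noisy_fraction = 0,
                           n_deletion_version_specific = 0L, rng_seed = 3L)
  co <- simulate_cohort(cfg)
  lm <- sum_to_locus(co$intensities, co$locus_map)
  del <- co$locus_map$loci$locus_id[co$locus_map$loci$region == "deletion"]
  carr <- co$manifest$truth_label == "carrier"
  for (l in del) {
    v <- lm$values[, l]
    ok <- !is.na(v)
    expect_equal(mean(v[carr & ok]) / mean(v[!carr & ok]), 0.5,
                 tolerance = 1e-12)
  }
  # with small noise the ratio converges in the mean
  cfg2 <- simulation_config(n_samples = 400L, n_carriers = 100L,
                            sample_scale_sd = 0, probe_noise_sd = 0.01,
                            noisy_fraction = 0, rng_seed = 3L)
  co2 <- simulate_cohort(cfg2)
  lm2 <- sum_to_locus(co2$intensities, co2$locus_map)
  carr2 <- co2$manifest$truth_label == "carrier"
  r <- mean(lm2$values[carr2, del[3]]) / mean(lm2$values[!carr2, del[3]])
  expect_equal(r, 0.5, tolerance = 0.01)
})

test_that("array-version split and probe content match the config", {
  cfg <- simulation_config(n_samples = 5000L, rng_seed = 9L)
  co <- simulate_cohort(cfg)
  v1 <- mean(co$manifest$array_version == "v1")
  expect_lt(abs(v1 - 0.28), 3 * sqrt(0.28 * 0.72 / 5000))
  # samples only carry probe sets of their own version
  pt <- probe_table(co$locus_map)
  expect_silent(validate_intensities(co$intensities, co$manifest,
                                     co$locus_map))
  # v1-only and v2-only deletion probe sets exist by default
  expect_identical(sum(!grepl(";", pt$array_versions)), 2L)
})

test_that("analytic feature location matches the noiseless pipeline", {
  cfg <- simulation_config(n_samples = 1000L, n_carriers = 1L,
                           sample_scale_sd = 0, probe_noise_sd = 0,
                           noisy_fraction = 0, rng_seed = 10L)
  pred <- expected_feature_location(cfg)
  expect_equal(pred$median_difference, qnorm(0.5 / 1000), tolerance = 1e-12)
  expect_identical(pred$piecewise_mad, 0)
  co <- simulate_cohort(cfg)
  res <- screen_cohort(co)
  carr <- which(co$manifest$truth_label == "carrier")
  expect_equal(res$features$median_difference[carr], pred$median_difference,
               tolerance = 1e-6)
  expect_equal(res$features$piecewise_mad[carr], 0, tolerance = 1e-6)
  # degenerate limits
  expect_error(expected_feature_location(
    simulation_config(carrier_fraction = 0)), "zero carriers")
  expect_identical(expected_feature_location(
    simulation_config(deletion_signal_ratio = 1, n_carriers = 5L)
  )$median_difference, 0)
  expect_identical(expected_feature_location(
    simulation_config(n_samples = 100L, n_carriers = 100L)
  )$median_difference, 0)
})

test_that("scaling one sample's intensities preserves others via ranks", {
  cfg <- simulation_config(n_samples = 50L, n_carriers = 2L, rng_seed = 12L)
  co <- simulate_cohort(cfg)
  base <- screen_cohort(co)$locus_matrix$values
  # a small rank-preserving rescaling of one mid-cluster sample changes
  # nothing anywhere (rank-based normalization sees only the ordering)
  co2 <- co
  target <- co$manifest$sample_id[10]
  idx <- co2$intensities$sample_id == target
  co2$intensities$intensity[idx] <- co2$intensities$intensity[idx] * 1.0001
  after <- screen_cohort(co2)$locus_matrix$values
  expect_identical(rank_matrix(base), rank_matrix(after))
  # a large rescaling may move that sample's ranks but other samples'
  # values only change through rank shifts, never through scale
  co3 <- co
  co3$intensities$intensity[idx] <- co3$intensities$intensity[idx] * 5
  after3 <- screen_cohort(co3)$locus_matrix$values
  others <- setdiff(rownames(base), target)
  for (j in colnames(base)) {
    a <- base[others, j]; b <- after3[others, j]
    ok <- !is.na(a) & !is.na(b)
    expect_identical(order(a[ok]), order(b[ok]))
  }
})

test_that("a cohort where every sample is a carrier yields no carrier calls", {
  cfg <- simulation_config(n_samples = 1000L, n_carriers = 1000L,
                           rng_seed = 14L)
  co <- simulate_cohort(cfg)
  res <- screen_cohort(co)
  expect_identical(sum(res$calls$call == "carrier"), 0L)
  # population-wide shifts are invisible to rank normalization
  expect_lt(max(abs(res$features$median_difference)), 2)
})

test_that("cohorts and simulation configs round-trip to disk", {
  cfg <- simulation_config(n_samples = 30L, n_carriers = 2L, rng_seed = 8L)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("manifest.tsv", "intensities.tsv", "locus_map.tsv",
           "regions.tsv", "truth.tsv", "config.yaml")))))
  cfg2 <- read_simulation_config(file.path(dir, "config.yaml"))
  expect_equal(unclass(cfg2), unclass(cfg))
  regions <- read_regions(file.path(dir, "regions.tsv"))
  map <- read_locus_map(file.path(dir, "locus_map.tsv"), regions)
  mani <- read_manifest(file.path(dir, "manifest.tsv"))
  tab <- read_intensities(file.path(dir, "intensities.tsv"), mani, map)
  lm1 <- sum_to_locus(co$intensities, co$locus_map)
  lm2 <- sum_to_locus(tab, map)
  expect_equal(lm2$values, lm1$values, tolerance = 1e-9)
})
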