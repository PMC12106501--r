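test_that("sum_to_locus adds both alleles of all probe sets at a locus", {
  map <- tiny_map()
  tab <- build_intensities(list(
    S01 = list(PA = c(1, 2), PB = c(3, 4), PL = c(0, 0), PR = c(1, 1))))
  lm <- sum_to_locus(tab, map)
  expect_identical(lm$stage, "summed")
  expect_identical(lm$values["S01", "d1"], 10)
  expect_identical(lm$values["S01", "l1"], 0)
})

test_that("version membership: absent probe sets are not missing data", {
  map <- tiny_map()  # locus d1 = shared PA + v2-only PB
  # v1 sample with only the shared probe set: sum over what exists
  tab <- build_intensities(list(S01 = list(PA = c(2, 3), PL = c(1, 1),
                                           PR = c(1, 1))))
  lm <- sum_to_locus(tab, map)
  expect_identical(lm$values["S01", "d1"], 5)
  # but a sample with no records at a locus is missing there
  tab2 <- build_intensities(list(S01 = list(PL = c(1, 1))))
  lm2 <- sum_to_locus(tab2, map)
  expect_true(is.na(lm2$values["S01", "d1"]))
})

test_that("inverse-normal transform matches hand-computed quantiles", {
  m <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("S", 1:4), "d1"))
  ninv <- inverse_normal_transform(locus_matrix(m, "summed"))
  expect_identical(ninv$stage, "normalized")
  expect_equal(as.numeric(ninv$values),
               qnorm(c(0.125, 0.375, 0.625, 0.875)), tolerance = 1e-12)
  # ties share average ranks -> equal outputs; N=2 tie maps to 0
  m2 <- matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "d1"))
  expect_identical(as.numeric(inverse_normal_transform(locus_matrix(m2, "summed"))$values),
                   c(0, 0))
  # the sample holding the middle value of an odd tie-free locus maps to 0
  m3 <- matrix(c(10, 30, 20), 3, 1, dimnames = list(c("a", "b", "c"), "d1"))
  expect_identical(inverse_normal_transform(locus_matrix(m3, "summed"))$values["c", 1], 0)
})

test_that("transform equals brute-force rank enumeration for N <= 8 with ties", {
  set.seed(11)
  for (n in 2:8) {
    for (rep in 1:20) {
      x <- sample(round(rnorm(n), 1), n, replace = TRUE)  # forces ties often
      m <- matrix(x, n, 1, dimnames = list(paste0("S", 1:n), "L"))
      got <- inverse_normal_transform(locus_matrix(m, "summed"))$values[, 1]
      expect_equal(unname(got), oracle_int(x), tolerance = 1e-12)
    }
  }
})

test_that("normalization is rank-preserving and monotone-invariant", {
  set.seed(7)
  x <- rlnorm(40, 7, 0.3)
  m <- matrix(x, 40, 1, dimnames = list(sprintf("S%02d", 1:40), "L"))
  base <- inverse_normal_transform(locus_matrix(m, "summed"))$values[, 1]
  expect_identical(order(base), order(x))
  for (f in list(function(v) v * 3 + 10, function(v) v^2, log, sqrt,
                 function(v) exp(v / max(v)))) {
    m2 <- m; m2[, 1] <- f(x)
    got <- inverse_normal_transform(locus_matrix(m2, "summed"))$values[, 1]
    expect_equal(got, base, tolerance = 1e-12)
  }
})

test_that("normalized scores are symmetric with mean 0 and variance -> 1", {
  set.seed(3)
  n <- 10000
  m <- matrix(rlnorm(n, 7, 0.2), n, 1, dimnames = list(sprintf("S%05d", 1:n), "L"))
  z <- inverse_normal_transform(locus_matrix(m, "summed"))$values[, 1]
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(var(z), 1, tolerance = 0.01)
  expect_equal(sort(unname(z)), sort(unname(-z)), tolerance = 1e-10)  # antisymmetric ranks
})

test_that("missing values are excluded from ranks and preserved", {
  m <- matrix(c(3, NA, 1, 2), 4, 1, dimnames = list(paste0("S", 1:4), "L"))
  z <- inverse_normal_transform(locus_matrix(m, "summed"))$values[, 1]
  expect_true(is.na(z[2]))
  expect_equal(unname(z[c(3, 4, 1)]),
               qnorm((1:3 - 0.5) / 3), tolerance = 1e-12)
  # a locus with < 2 usable values becomes all-missing with a warning
  m2 <- cbind(m, L2 = c(NA, NA, NA, 5))
  expect_warning(z2 <- inverse_normal_transform(locus_matrix(m2, "summed")),
                 "< 2 non-missing")
  expect_true(all(is.na(z2$values[, "L2"])))
})

test_that("alternative quantile offsets are available", {
  m <- matrix(1:5, 5, 1, dimnames = list(paste0("S", 1:5), "L"))
  blom <- inverse_normal_transform(locus_matrix(m, "summed"), "blom")$values[, 1]
  vdw <- inverse_normal_transform(locus_matrix(m, "summed"), "vanderwaerden")$values[, 1]
  expect_equal(unname(blom), qnorm((1:5 - 3 / 8) / 5.25), tolerance = 1e-12)
  expect_equal(unname(vdw), qnorm((1:5) / 6), tolerance = 1e-12)
})

test_that("locus matrices round-trip through TSV", {
  set.seed(5)
  m <- matrix(rlnorm(12, 7, 0.5), 4, 3,
              dimnames = list(paste0("S", 1:4), c("l1", "d1", "r1")))
  m[2, 3] <- NA
  lm <- inverse_normal_transform(locus_matrix(m, "summed"))
  dir <- withr::local_tempdir()
  write_locus_matrix(lm, file.path(dir, "lm.tsv"))
  lm2 <- read_locus_matrix(file.path(dir, "lm.tsv"))
  expect_identical(lm2$stage, "normalized")
  expect_identical(lm2$offset, "hazen")
  expect_equal(lm2$values, lm$values, tolerance = 1e-12)
})
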