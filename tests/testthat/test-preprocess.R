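test_that("sliding-block segmentation matches brute-force enumeration", {
  expect_length(segment_blocks(numeric(150000), 500), 66)
  expect_length(segment_blocks(numeric(16384), 500), 1)
  expect_length(segment_blocks(numeric(20000), 500), 2)
  expect_error(segment_blocks(numeric(16383), 500), "shorter")

  b <- segment_blocks(seq_len(20000), 500)
  expect_identical(vapply(b, `[[`, numeric(1), "start_sample"), c(0, 2048))
  expect_identical(b[[2]]$raw, seq_len(20000)[2049:(2048 + 16384)])

  withr::with_seed(99, {
    for (i in 1:200) {
      L <- sample(10:5000, 1)
      S <- sample(1:L, 1)
      n <- L + sample(0:20000, 1)
      expect_identical(
        length(segment_blocks(numeric(n), 1, block_s = L, stride_s = S)),
        as.integer(count_blocks_brute(n, L, S)))
    }
  })
})

test_that("standardization uses the population convention and is idempotent", {
  z <- standardize_block(c(1, 2, 3))
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-10)

  expect_error(standardize_block(rep(5, 100)), "zero variance")

  expect_equal(standardize_block(c(31000, 33000, 33000, 35000)),
               c(-sqrt(2), 0, 0, sqrt(2)), tolerance = 1e-12)

  withr::with_seed(4, {
    for (i in 1:20) {
      x <- rnorm(512, 32800, 100)
      z1 <- standardize_block(x)
      expect_lt(max(abs(standardize_block(z1) - z1)), 1e-10)
    }
  })
})

test_that("raw-amplitude gate excludes exactly the above-threshold blocks", {
  d <- reject_noisy_raw(c(rep(32800, 100), 35000))
  expect_false(d$included)
  expect_identical(d$statistic, 35000)
  expect_true(reject_noisy_raw(c(rep(32800, 100), 33999))$included)

  # excluded fraction grows with the artifact rate
  frac_excluded <- function(rate) {
    p <- synth_params(duration_s = 300, artifact_rate_per_min = rate)
    co <- generate_cohort(1, 1, p, seed = 31)
    sp <- cohort_spectra(co, "BCG2")
    mean(!sp$meta$included)
  }
  f0 <- frac_excluded(0)
  f2 <- frac_excluded(2)
  f8 <- frac_excluded(8)
  expect_identical(f0, 0)
  expect_gt(f2, 0)
  expect_gt(f8, f2)
})

test_that("standardized gate and its calibration round-trip exactly", {
  expect_true(reject_noisy_standardized(rnorm(100), Inf)$included)
  expect_false(reject_noisy_standardized(rep(1, 100), 10)$included)

  # Gaussian blocks essentially never exceed a standardized max of 6
  withr::with_seed(8, {
    stats6 <- replicate(200, max(standardize_block(rnorm(16384))))
    expect_lt(mean(stats6 > 6), 0.01)
  })

  expect_error(calibrate_standardized_threshold(numeric(0), 0.1), "blocks")
  expect_error(calibrate_standardized_threshold(1:5, 1), "fraction")

  s10 <- c(1.1, 2.3, 3.1, 0.4, 5.5, 4.2, 2.9, 3.8, 1.7, 0.9)
  expect_identical(calibrate_standardized_threshold(s10, 0), max(s10))
  th <- calibrate_standardized_threshold(s10, 0.3)
  expect_identical(sum(s10 > th), 3L)

  # round-trip across random statistics (with ties) and fractions
  withr::with_seed(12, {
    for (i in 1:50) {
      s <- round(runif(sample(5:60, 1), 0, 6), sample(1:3, 1))
      f <- runif(1, 0, 0.95)
      th <- calibrate_standardized_threshold(s, f)
      expect_lte(sum(s > th), floor(f * length(s)))  # ties exclude fewer
      if (!anyDuplicated(s))
        expect_identical(sum(s > th), as.integer(floor(f * length(s))))
    }
  })
})

test_that("windowed power spectrum has the canonical shape and peak", {
  x <- numeric(16384)
  sp <- power_spectrum(x, 500)
  expect_length(sp$freq, 8193)
  expect_identical(range(sp$freq), c(0, 250))
  expect_true(all(sp$power == 0))

  expect_error(power_spectrum(numeric(101), 500), "even")

  # unit sine at exactly bin k = 33 (1.0070801 Hz): global power maximum
  k <- 33L
  f_k <- k * 500 / 16384
  tone <- sin(2 * pi * f_k * (0:16383) / 500)
  spt <- power_spectrum(tone, 500)
  expect_identical(which.max(spt$power) - 1L, k)
})

test_that("binning conserves cropped power across the whole settings grid", {
  withr::with_seed(77, {
    spec <- list(freq = (0:8192) * 500 / 16384,
                 power = rexp(8193))
  })
  expect_error(
    crop_and_bin(list(freq = c(100, 200), power = c(1, 1)),
                 spectrum_setting(0.1, 10, 3)), "survive")

  s1 <- spectrum_setting(0, 10, 1)
  in_band <- spec$freq >= 0 & spec$freq <= 10
  expect_equal(crop_and_bin(spec, s1), sum(spec$power[in_band]))

  expect_length(crop_and_bin(spec, spectrum_setting(0, 10, 30)), 30)

  for (lc in c(0, 0.5, 0.7, 1.0, 1.2))
    for (hc in c(10, 20, 40, 250))
      for (nb in c(3, 5, 10, 30, 40, 50, 100, 150)) {
        st <- spectrum_setting(lc, hc, nb)
        v <- crop_and_bin(spec, st)
        expect_length(v, nb)
        expect_true(all(v >= 0))
        keep <- spec$freq >= lc & spec$freq <= hc
        expect_equal(sum(v), sum(spec$power[keep]),
                     tolerance = 1e-9)
      }
})

test_that("cohort spectra table keeps identity, inclusion, and alignment", {
  p <- tiny_params(artifact_rate_per_min = 1)
  co <- generate_cohort(2, 2, p, seed = 18)
  sp <- cohort_spectra(co, c("BCG1", "BCG2"))
  expect_identical(nrow(sp$meta), 4L * 2L * 9L)
  expect_gt(sum(sp$meta$included), 0)
  expect_true(all(sp$meta$included == (sp$meta$raw_max <= 34000)))
  inc <- sp$meta[sp$meta$included, ]
  expect_identical(sort(unique(inc$spec_row)), seq_len(nrow(sp$power)))
  ft <- bin_features(sp, spectrum_setting(0, 10, 30))
  expect_identical(nrow(ft$x), nrow(inc))
  expect_identical(ncol(ft$x), 30L)
})
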