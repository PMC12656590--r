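# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# Short-recording simulator parameters for cheap unit tests:
# 65.536 s -> 9 blocks per channel at 500 Hz.
tiny_params <- function(...) synth_params(duration_s = 65.536, ...)

# Brute-force oracle for sliding-window block counts.
count_blocks_brute <- function(n, L, S) {
  count <- 0L
  start <- 0L
  while (start + L <= n) {
    count <- count + 1L
    start <- start + S
  }
  count
}

# ADA-focused tuning grid: the chest-sensor winning neighbourhood.
ada_grid <- function() list(
  classifier_config("ADA", spectrum_setting(0, 10, 30),
                    max_depth = 7, learning_rate = 0.9),
  classifier_config("ADA", spectrum_setting(0, 10, 30),
                    max_depth = 1, learning_rate = 0.8),
  classifier_config("ADA", spectrum_setting(1, 10, 50),
                    max_depth = 7, learning_rate = 0.9),
  classifier_config("ADA", spectrum_setting(1.2, 20, 10),
                    max_depth = 2, learning_rate = 1.0)
)

# Full study-scale pipeline run (67 train / 17 test participants, 300 s,
# AdaBoost tuning) shared by the learning and fusion suites.
default_ada_run <- function() cache_fixture("ada_run", function() {
  run_pipeline(default_config(seed = 101L), grid = ada_grid())
})

# A small two-class set of clean standardized BCG2 blocks with known heart
# rates, for spectral-separation checks.
harmonic_blocks <- function(n_per_class = 24) {
  cache_fixture("harmonic_blocks", function() {
    p <- synth_params(duration_s = 65.536, artifact_rate_per_min = 0)
    per_rec <- 9
    n_rec <- ceiling(n_per_class / per_rec)
    build <- function(label, seed0) {
      out <- list()
      for (i in seq_len(n_rec)) {
        hr <- 55 + 7 * i
        beats <- generate_rr_series(label, p$duration_s, p, seed = seed0 + i,
                                    mean_hr_bpm = hr)
        x <- synthesize_channel(beats, "BCG2", p, seed = seed0 + 100 + i)
        for (b in segment_blocks(x, p$fs)) {
          out[[length(out) + 1]] <- list(
            spec = power_spectrum(standardize_block(b$raw), p$fs),
            hr_hz = hr / 60)
        }
      }
      out[seq_len(n_per_class)]
    }
    list(non_af = build("NON_AF", 300), af = build("AF", 600))
  })
}

# Total power within +/- half_bw Hz of the first three heart-rate harmonics.
harmonic_band_power <- function(spec, hr_hz, half_bw = 0.15) {
  tot <- 0
  for (h in 1:3) {
    keep <- spec$freq >= h * hr_hz - half_bw & spec$freq <= h * hr_hz + half_bw
    tot <- tot + sum(spec$power[keep])
  }
  tot
}

# Separable toy feature set: one informative dimension plus noise.
toy_features <- function(n_per_class = 40, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(cbind(rnorm(n_per_class, 3), rnorm(n_per_class)),
               cbind(rnorm(n_per_class, -3), rnorm(n_per_class)))
    colnames(x) <- c("feature_0", "feature_1")
    list(x = x, y = rep(c("AF", "NON_AF"), each = n_per_class))
  })
}
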