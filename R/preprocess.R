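#' Segment a channel into sliding analysis blocks
#'
#' Splits a raw channel into fixed-length windows of `block_s` seconds
#' advanced every `stride_s` seconds. With the defaults at 500 Hz the window
#' is 16,384 samples (a power of two, hence the 32.768 s length) and the
#' stride 2,048 samples, so a 300 s recording yields 66 blocks. A trailing
#' partial window is dropped.
#'
#' @param signal Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param block_s Window length in seconds.
#' @param stride_s Hop between window starts in seconds.
#'
#' @return List of blocks, each a list with `start_sample` (0-based) and
#'   `raw` (the window samples).
#' @export
segment_blocks <- function(signal, fs, block_s = 32.768, stride_s = 4.096) {
  L <- round(block_s * fs)
  S <- round(stride_s * fs)
  n <- length(signal)
  if (n < L) stop_param("signal shorter than one block (", n, " < ", L, ")")
  n_blocks <- floor((n - L) / S) + 1
  lapply(seq_len(n_blocks) - 1, function(b) {
    start <- b * S
    list(start_sample = start, raw = signal[(start + 1):(start + L)])
  })
}

# Closed-form block count; oracle-checked against enumeration in the tests.
n_blocks_expected <- function(n, L = 16384L, S = 2048L) {
  if (n < L) 0L else as.integer(floor((n - L) / S) + 1)
}

#' Standardize one block
#'
#' Subtracts the block mean and divides by the block standard deviation. The
#' population convention (divisor N) is used so the transform is an exact,
#' reproducible contract; at N = 16,384 the difference from the sample SD is
#' negligible but a fixed convention is needed for bit-reproducibility.
#'
#' @param x Numeric sample vector (one block).
#' @return Standardized vector with mean 0 and population SD 1.
#' @export
standardize_block <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop_param("degenerate block: zero variance")
  (x - m) / s
}

noise_decision <- function(included, rule, statistic, threshold) {
  list(included = included, rule = rule,
       statistic = statistic, threshold = threshold)
}

#' Raw-amplitude motion-artifact gate
#'
#' Body motion drives the raw BCG amplitude above 34,000 counts; a block is
#' excluded when its per-block maximum raw amplitude exceeds the threshold.
#'
#' @param raw Numeric raw sample vector of one block.
#' @param threshold Raw-amplitude threshold in counts.
#' @return A noise decision list: `included`, `rule`, `statistic`,
#'   `threshold`, with `included == (max(raw) <= threshold)`.
#' @export
reject_noisy_raw <- function(raw, threshold = 34000) {
  stat <- max(raw)
  noise_decision(stat <= threshold, "RAW_THRESHOLD", stat, threshold)
}

#' Standardized-amplitude noise gate
#'
#' Alternative gate on the per-block maximum of the standardized samples;
#' mirrors the raw rule on the dimensionless scale. A block that cannot be
#' standardized (zero variance) is excluded.
#'
#' @param raw Numeric raw sample vector of one block.
#' @param threshold Dimensionless threshold on the standardized maximum.
#' @return A noise decision list as in [reject_noisy_raw()].
#' @export
reject_noisy_standardized <- function(raw, threshold) {
  std <- tryCatch(standardize_block(raw), error = function(e) NULL)
  if (is.null(std))
    return(noise_decision(FALSE, "STD_THRESHOLD", NA_real_, threshold))
  stat <- max(std)
  noise_decision(stat <= threshold, "STD_THRESHOLD", stat, threshold)
}

#' Calibrate the standardized threshold to a target exclusion fraction
#'
#' Finds the standardized-amplitude threshold whose exclusion count matches a
#' raw-amplitude gate, so the two rules can be compared at equal data loss:
#' the returned threshold excludes exactly `floor(fraction * n)` blocks (ties
#' broken toward excluding fewer).
#'
#' @param statistics Numeric vector of per-block maximum standardized
#'   amplitudes (the [reject_noisy_standardized()] statistic).
#' @param target_excluded_fraction Proportion of blocks to exclude, in
#'   `[0, 1)`.
#' @return The calibrated threshold.
#' @export
calibrate_standardized_threshold <- function(statistics,
                                             target_excluded_fraction) {
  if (!length(statistics)) stop_param("no blocks to calibrate on")
  if (target_excluded_fraction < 0 || target_excluded_fraction >= 1)
    stop_param("target fraction must be in [0, 1)")
  n <- length(statistics)
  m <- floor(target_excluded_fraction * n)
  s <- sort(statistics, decreasing = TRUE)
  if (m == 0) s[1] else s[m + 1]
}

#' One-sided power spectrum of a standardized block
#'
#' Applies a Hanning window pointwise and takes `|FFT|^2 / N` at the
#' non-negative frequencies `k * fs / N`, `k = 0..N/2`. For the canonical
#' 16,384-sample block at 500 Hz this yields 8,193 points spanning 0-250 Hz.
#' No window-gain compensation is applied: the classifiers only ever see
#' consistently scaled features.
#'
#' @param x Standardized block samples (full block length, even N).
#' @param fs Sampling rate in Hz.
#' @return List with `freq` (Hz) and `power` vectors of length `N/2 + 1`.
#' @export
power_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 2 || n %% 2 != 0) stop_param("block length must be even and >= 2")
  w <- signal::hanning(n)
  X <- stats::fft(x * w)
  k <- 0:(n / 2)
  list(freq = k * fs / n, power = Mod(X[k + 1])^2 / n)
}

#' Validate a spectral featurization setting
#'
#' @param lowcut_hz,highcut_hz Frequency crop bounds in Hz (`lowcut <
#'   highcut`).
#' @param nbins Number of equal-width frequency bins.
#' @return List of class `spectrum_setting`.
#' @export
spectrum_setting <- function(lowcut_hz, highcut_hz, nbins) {
  if (lowcut_hz >= highcut_hz) stop_param("lowcut must be below highcut")
  if (nbins < 1) stop_param("nbins must be >= 1")
  structure(list(lowcut_hz = lowcut_hz, highcut_hz = highcut_hz,
                 nbins = as.integer(nbins)),
            class = "spectrum_setting")
}

#' Crop a spectrum and aggregate it into equal-width frequency bins
#'
#' Retains spectral points with `lowcut <= f <= highcut` (both ends closed;
#' `lowcut = 0` keeps the DC point), partitions `[lowcut, highcut]` into
#' `nbins` equal-width contiguous intervals (the last closed on the right),
#' and sums the power in each. Summation conserves total cropped power, which
#' keeps the `nbins = 1` case interpretable as band power.
#'
#' @param spectrum List with `freq` and `power` as from [power_spectrum()].
#' @param setting A [spectrum_setting()].
#' @return Numeric feature vector of length `nbins` (empty bins are 0).
#' @export
crop_and_bin <- function(spectrum, setting) {
  keep <- spectrum$freq >= setting$lowcut_hz &
    spectrum$freq <= setting$highcut_hz
  if (!any(keep)) stop_param("no spectral points survive cropping")
  f <- spectrum$freq[keep]
  p <- spectrum$power[keep]
  width <- (setting$highcut_hz - setting$lowcut_hz) / setting$nbins
  bin <- pmin(setting$nbins,
              floor((f - setting$lowcut_hz) / width) + 1)
  out <- numeric(setting$nbins)
  agg <- tapply(p, bin, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Build the per-block spectral table of a cohort
#'
#' Runs the full preprocessing chain for each requested sensor channel of
#' each recording: sliding-block segmentation, the noise gate on the raw
#' samples, standardization, and the Hanning-FFT power spectrum (stored up to
#' `max_freq` to bound memory). Excluded blocks keep their metadata row but
#' no spectrum. The result feeds [bin_features()] with any featurization
#' setting without re-running the FFT.
#'
#' @param cohort List of recordings from [generate_cohort()] or
#'   [read_recording()].
#' @param placements Character vector of channels to process.
#' @param threshold Raw-amplitude noise threshold in counts.
#' @param max_freq Highest frequency (Hz) retained in the stored spectra.
#'
#' @return List with `meta` (data.frame: participant_id, placement,
#'   start_sample, label, raw_max, std_max, included), `power` (matrix, one
#'   row per included block, aligned with `meta$spec_row`), and `freq`.
#' @export
cohort_spectra <- function(cohort, placements = "BCG2", threshold = 34000,
                           max_freq = 40) {
  meta_rows <- list()
  spectra <- list()
  freq <- NULL
  for (rec in cohort) {
    for (pl in placements) {
      blocks <- segment_blocks(rec$channels[[pl]], rec$fs)
      if (is.null(freq)) {
        L <- length(blocks[[1]]$raw)
        f_all <- (0:(L / 2)) * rec$fs / L
        freq <- f_all[f_all <= max_freq]
      }
      for (b in blocks) {
        dec <- reject_noisy_raw(b$raw, threshold)
        std_max <- NA_real_
        spec_row <- NA_integer_
        if (dec$included) {
          std <- tryCatch(standardize_block(b$raw), error = function(e) NULL)
          if (is.null(std)) {
            dec$included <- FALSE
          } else {
            std_max <- max(std)
            sp <- power_spectrum(std, rec$fs)
            spectra[[length(spectra) + 1]] <- sp$power[sp$freq <= max_freq]
            spec_row <- length(spectra)
          }
        }
        meta_rows[[length(meta_rows) + 1]] <- data.frame(
          participant_id = rec$participant_id, placement = pl,
          start_sample = b$start_sample, label = rec$label,
          raw_max = dec$statistic, std_max = std_max,
          included = dec$included, spec_row = spec_row,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  list(meta = meta,
       power = if (length(spectra)) do.call(rbind, spectra) else
         matrix(numeric(0), 0, length(freq)),
       freq = freq)
}

#' Featurize included blocks under one setting
#'
#' @param spectra A [cohort_spectra()] object.
#' @param setting A [spectrum_setting()]; its `highcut_hz` must not exceed
#'   the `max_freq` the spectra were stored with.
#' @return List with `meta` (included rows only) and `x` (feature matrix,
#'   `nbins` columns).
#' @export
bin_features <- function(spectra, setting) {
  if (setting$highcut_hz > max(spectra$freq) + 1e-9)
    stop_param("setting highcut exceeds stored spectrum range")
  inc <- spectra$meta[spectra$meta$included, , drop = FALSE]
  if (nrow(inc) == 0) {
    x <- matrix(numeric(0), 0, setting$nbins)
  } else {
    x <- t(apply(spectra$power[inc$spec_row, , drop = FALSE], 1, function(p)
      crop_and_bin(list(freq = spectra$freq, power = p), setting)))
    if (setting$nbins == 1) x <- matrix(as.numeric(x), ncol = 1)
  }
  colnames(x) <- paste0("feature_", seq_len(ncol(x)) - 1)
  list(meta = inc, x = x)
}
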