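#' Sensor placements of the multi-site BCG array
#'
#' Four piezoelectric sheet sensors are laid across the bed at fixed distances
#' from the base of the head: BCG1 at 0 cm (head), BCG2 at 25 cm (chest /
#' heart level), BCG3 at 45 cm (lumbar), BCG4 at 65 cm (sacral).
#'
#' @return Named integer vector mapping placement id to offset in cm.
#' @export
sensor_placements <- function() {
  c(BCG1 = 0L, BCG2 = 25L, BCG3 = 45L, BCG4 = 65L)
}

#' Parameters of the synthetic BCG cohort generator
#'
#' Bundles every tunable of the simulator with defaults chosen to emulate the
#' signal structure of supine bed-sensor BCG: a near-periodic train of
#' heartbeat-induced damped oscillations (producing a harmonic comb at
#' multiples of the heart rate below ~10 Hz in sinus rhythm), a slow
#' respiratory oscillation, a large DC offset from the 16-bit unsigned ADC,
#' white sensor noise, and sporadic high-amplitude motion-artifact bursts.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param mean_hr_bpm Cohort mean heart rate (beats/min); per-participant rates
#'   are jittered around label-specific means by [generate_cohort()].
#' @param rr_cv_sinus Coefficient of variation of RR intervals in sinus rhythm.
#' @param rr_cv_af Coefficient of variation of RR intervals in atrial
#'   fibrillation; must exceed `rr_cv_sinus`.
#' @param kernel_freq_hz Carrier frequency of the damped-oscillation heartbeat
#'   kernel (Hz).
#' @param kernel_decay_s Exponential decay time constant of the kernel (s).
#' @param resp_freq_hz Respiratory oscillation frequency (Hz).
#' @param dc_offset ADC baseline in counts.
#' @param cardiac_gain Named numeric, counts of cardiac amplitude per
#'   placement; largest under the chest (BCG2).
#' @param resp_gain Named numeric, counts of respiratory amplitude per
#'   placement; relatively largest at the lumbar/sacral sensors.
#' @param noise_sd White-noise standard deviation in counts.
#' @param artifact_rate_per_min Expected motion-artifact bursts per minute.
#' @param artifact_amplitude Peak artifact excursion above baseline in counts;
#'   `dc_offset + artifact_amplitude` must exceed 34,000 so every burst trips
#'   the raw-amplitude noise gate.
#' @param hr_jitter_bpm Between-participant heart-rate standard deviation.
#'
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(duration_s = 300,
                         fs = 500,
                         mean_hr_bpm = 65,
                         rr_cv_sinus = 0.03,
                         rr_cv_af = 0.24,
                         kernel_freq_hz = 5,
                         kernel_decay_s = 0.15,
                         resp_freq_hz = 0.25,
                         dc_offset = 32800,
                         cardiac_gain = c(BCG1 = 400, BCG2 = 800,
                                          BCG3 = 250, BCG4 = 150),
                         resp_gain = c(BCG1 = 60, BCG2 = 80,
                                       BCG3 = 150, BCG4 = 150),
                         noise_sd = 20,
                         artifact_rate_per_min = 0.5,
                         artifact_amplitude = 6000,
                         hr_jitter_bpm = 8) {
  if (fs <= 0) stop_param("fs must be positive")
  if (duration_s <= 0) stop_param("duration_s must be positive")
  if (mean_hr_bpm <= 0) stop_param("mean_hr_bpm must be positive")
  if (any(cardiac_gain < 0) || any(resp_gain < 0))
    stop_param("gains must be non-negative")
  if (rr_cv_af <= rr_cv_sinus)
    stop_param("rr_cv_af must exceed rr_cv_sinus")
  if (kernel_decay_s <= 0) stop_param("kernel_decay_s must be positive")
  if (artifact_rate_per_min < 0) stop_param("artifact rate must be >= 0")
  structure(list(
    duration_s = duration_s, fs = fs, mean_hr_bpm = mean_hr_bpm,
    rr_cv_sinus = rr_cv_sinus, rr_cv_af = rr_cv_af,
    kernel_freq_hz = kernel_freq_hz, kernel_decay_s = kernel_decay_s,
    resp_freq_hz = resp_freq_hz, dc_offset = dc_offset,
    cardiac_gain = cardiac_gain, resp_gain = resp_gain,
    noise_sd = noise_sd, artifact_rate_per_min = artifact_rate_per_min,
    artifact_amplitude = artifact_amplitude, hr_jitter_bpm = hr_jitter_bpm
  ), class = "synth_params")
}

#' Generate a beat-time series for one participant
#'
#' Sinus rhythm draws successive RR intervals from a normal distribution with
#' mean `60/mean_hr_bpm` and coefficient of variation `rr_cv_sinus`, truncated
#' below at 0.2 s. Atrial fibrillation draws independent log-normal RR
#' intervals with the same mean and coefficient of variation `rr_cv_af`; the
#' much larger beat-to-beat variability destroys the harmonic comb in the
#' block spectrum, which is the feature the classifier exploits.
#'
#' @param label `"AF"` or `"NON_AF"`.
#' @param duration_s Length of the series in seconds.
#' @param params A [synth_params()] object.
#' @param seed Integer seed; identical seeds give identical beat times.
#' @param mean_hr_bpm Optional heart-rate override (beats/min), used for
#'   per-participant jitter.
#'
#' @return Strictly increasing numeric vector of beat times in
#'   `[0, duration_s)`.
#' @export
generate_rr_series <- function(label, duration_s, params = synth_params(),
                               seed = 1L, mean_hr_bpm = NULL) {
  label <- match.arg(label, c("AF", "NON_AF"))
  if (duration_s < 0) stop_param("duration_s must be >= 0")
  hr <- mean_hr_bpm %||% params$mean_hr_bpm
  if (hr <= 0) stop_param("heart rate must be positive")
  if (duration_s == 0) return(numeric(0))

  mu <- 60 / hr
  n_draw <- ceiling(duration_s / mu * 1.5) + 20
  with_seed(seed, {
    beats <- numeric(0)
    t_last <- 0
    repeat {
      rr <- if (label == "NON_AF") {
        # truncated normal via inverse CDF, lower bound 0.2 s
        sd <- params$rr_cv_sinus * mu
        p0 <- stats::pnorm(0.2, mu, sd)
        u <- stats::runif(n_draw, p0, 1)
        stats::qnorm(u, mu, sd)
      } else {
        # log-normal parameterized by mean mu and CV rr_cv_af
        s2 <- log(1 + params$rr_cv_af^2)
        stats::rlnorm(n_draw, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
      }
      new <- t_last + cumsum(rr)
      beats <- c(beats, new)
      t_last <- beats[length(beats)]
      if (t_last >= duration_s) break
    }
    beats[beats < duration_s]
  })
}

# Zero-DC damped-oscillation heartbeat kernel sampled at fs.
bcg_kernel <- function(params) {
  tk <- seq(0, 5 * params$kernel_decay_s, by = 1 / params$fs)
  k <- exp(-tk / params$kernel_decay_s) *
    sin(2 * pi * params$kernel_freq_hz * tk)
  k - mean(k)
}

#' Synthesize one sensor channel from a beat-time series
#'
#' The channel model is `dc_offset + g_c * (impulse train at beat times
#' convolved with a damped-sinusoid kernel) + g_r * sin(2*pi*f_resp*t + phase)
#' + white noise`, rounded and clipped to the 16-bit range `[0, 65535]`.
#' Gains `g_c`, `g_r` depend on placement: the chest-level sensor (BCG2)
#' carries the strongest cardiac content, the lumbar/sacral sensors (BCG3/4)
#' relatively more respiration.
#'
#' @param beat_times Numeric vector of beat times (s) within the recording.
#' @param placement One of `"BCG1".."BCG4"`.
#' @param params A [synth_params()] object.
#' @param seed Integer seed for the noise and respiratory phase.
#'
#' @return Numeric vector of `round(duration_s * fs)` samples in
#'   `[0, 65535]`.
#' @export
synthesize_channel <- function(beat_times, placement, params = synth_params(),
                               seed = 1L) {
  placement <- match.arg(placement, names(sensor_placements()))
  if (params$kernel_decay_s <= 0) stop_param("kernel_decay_s must be positive")
  n <- round(params$duration_s * params$fs)
  if (length(beat_times) &&
      (min(beat_times) < 0 || max(beat_times) >= params$duration_s))
    stop_param("beat_times must lie in [0, duration_s)")

  impulses <- numeric(n)
  if (length(beat_times)) {
    idx <- pmin(n, floor(beat_times * params$fs) + 1)
    impulses[idx] <- impulses[idx] + 1
  }
  k <- bcg_kernel(params)
  # causal convolution: kernel onset at each beat sample
  cardiac <- stats::convolve(impulses, rev(k), type = "open")[seq_len(n)]

  tt <- (seq_len(n) - 1) / params$fs
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    resp <- sin(2 * pi * params$resp_freq_hz * tt + phase)
    x <- params$dc_offset +
      params$cardiac_gain[[placement]] * cardiac +
      params$resp_gain[[placement]] * resp +
      stats::rnorm(n, 0, params$noise_sd)
    pmin(65535, pmax(0, round(x)))
  })
}

#' Inject motion-artifact bursts into a channel
#'
#' Superimposes Poisson-distributed body-motion transients: event count is
#' Poisson with mean `artifact_rate_per_min * duration/60`, each event a
#' half-sine bump of random duration 0.5-2 s and peak excursion
#' `artifact_amplitude` counts above the running signal, so every burst's raw
#' amplitude exceeds the 34,000-count motion threshold by construction.
#'
#' @param signal Numeric sample vector (counts).
#' @param params A [synth_params()] object.
#' @param seed Integer seed.
#'
#' @return Signal with bursts added, clipped to `[0, 65535]`; non-burst
#'   samples unchanged.
#' @export
inject_motion_artifacts <- function(signal, params = synth_params(),
                                    seed = 1L) {
  if (params$artifact_rate_per_min < 0) stop_param("artifact rate must be >= 0")
  if (params$artifact_amplitude + params$dc_offset <= 34000)
    stop_param("artifact_amplitude + dc_offset must exceed 34,000")
  n <- length(signal)
  duration_min <- n / params$fs / 60
  with_seed(seed, {
    n_ev <- stats::rpois(1, params$artifact_rate_per_min * duration_min)
    if (n_ev == 0) return(signal)
    out <- signal
    starts <- stats::runif(n_ev, 0, n / params$fs)
    lens <- stats::runif(n_ev, 0.5, 2)
    for (i in seq_len(n_ev)) {
      i0 <- floor(starts[i] * params$fs) + 1
      i1 <- min(n, i0 + round(lens[i] * params$fs) - 1)
      idx <- i0:i1
      bump <- sin(pi * seq(0, 1, length.out = length(idx)))
      out[idx] <- out[idx] + params$artifact_amplitude * bump
    }
    pmin(65535, pmax(0, round(out)))
  })
}

#' Generate a labelled synthetic multi-sensor cohort
#'
#' Produces `n_af + n_non_af` recordings, each with the four simultaneous
#' sensor channels, a participant-level rhythm label, and a per-participant
#' heart rate jittered around label-specific means (70 bpm for AF, 64 bpm for
#' sinus, the clinical anchor for this population) truncated to 40-120 bpm.
#' All randomness flows from `seed`; per-participant and per-channel
#' sub-streams are derived deterministically, so identical calls are
#' bit-identical.
#'
#' @param n_af Number of AF participants.
#' @param n_non_af Number of non-AF participants.
#' @param params A [synth_params()] object.
#' @param seed Integer master seed.
#' @param id_prefix Prefix for participant ids.
#'
#' @return List of recordings; each is a list with `participant_id`, `label`,
#'   `fs`, `hr_bpm`, and `channels` (named list BCG1..BCG4 of sample vectors).
#' @export
generate_cohort <- function(n_af, n_non_af, params = synth_params(),
                            seed = 1L, id_prefix = "P") {
  if (n_af < 0 || n_non_af < 0) stop_param("cohort sizes must be >= 0")
  labels <- c(rep("AF", n_af), rep("NON_AF", n_non_af))
  n <- length(labels)
  if (n == 0) return(list())
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    hr_mean <- if (lab == "AF") 70 else 64
    hr <- with_seed(derive_seed(seed, i, 0), {
      h <- stats::rnorm(1, hr_mean, params$hr_jitter_bpm)
      min(120, max(40, h))
    })
    beats <- generate_rr_series(lab, params$duration_s, params,
                                seed = derive_seed(seed, i, 1),
                                mean_hr_bpm = hr)
    channels <- lapply(seq_along(sensor_placements()), function(j) {
      pl <- names(sensor_placements())[j]
      x <- synthesize_channel(beats, pl, params,
                              seed = derive_seed(seed, i, 10 + j))
      if (params$artifact_rate_per_min > 0)
        x <- inject_motion_artifacts(x, params,
                                     seed = derive_seed(seed, i, 20 + j))
      x
    })
    names(channels) <- names(sensor_placements())
    recs[[i]] <- list(
      participant_id = sprintf("%s%03d", id_prefix, i),
      label = lab, fs = params$fs, hr_bpm = hr, channels = channels
    )
  }
  recs
}
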