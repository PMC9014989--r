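# Forward synthesis of fNIRS hemoglobin series with known ground-truth
# activation amplitudes, plus an additive structured-noise model.

#' Noise-free activation series with known per-channel amplitudes
#'
#' `dHbO(ch) = beta_true(ch) * r(t)` where `r` is the peak-normalized
#' boxcar-by-HRF task regressor; `dHbR = -hbr_ratio * dHbO` (typical
#' anticorrelated deoxy response).
#'
#' @param beta_true per-channel HbO amplitudes (uM).
#' @param onsets_s,durations_s task block onsets and durations (s).
#' @param duration_s total run length (s).
#' @param fs sampling rate (Hz).
#' @param hrf_params optional HRF parameter overrides (see [canonical_hrf()]).
#' @param hbr_ratio magnitude of the HbR/HbO amplitude ratio.
#' @param condition optional label.
#' @return a [hemoglobin_series()] with attribute `beta_true`.
#' @export
synthesize_activation <- function(beta_true, onsets_s = 60, durations_s = 180,
                                  duration_s = 300, fs = 2,
                                  hrf_params = list(), hbr_ratio = 1 / 3,
                                  condition = NULL) {
  if (fs <= 0) stop("fs must be > 0")
  if (any(durations_s < 0)) stop("negative event duration")
  if (any(onsets_s < 0) || any(onsets_s > duration_s))
    stop("onsets must lie within the run")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  reg <- hrf_regressor(onsets_s, durations_s, fs, n, hrf_params)
  hbo <- outer(beta_true, as.numeric(reg))
  out <- hemoglobin_series(t, hbo, -hbr_ratio * hbo, fs, condition = condition)
  attr(out, "beta_true") <- beta_true
  attr(out, "regressor") <- as.numeric(reg)
  out
}

#' Structured fNIRS noise model
#'
#' @param drift_slope linear drift, uM/s.
#' @param mayer_amp_um Mayer-wave sinusoid amplitude (uM) at `mayer_freq_hz`.
#' @param mayer_freq_hz Mayer-wave frequency (default 0.1 Hz).
#' @param cardiac_amp_um cardiac sinusoid amplitude (uM).
#' @param cardiac_freq_hz cardiac frequency; at a 2-Hz sampling rate anything
#'   above 1 Hz aliases — the generator uses the aliased frequency explicitly.
#' @param white_sd_um white noise SD (uM).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(drift_slope = 0.003,
                        mayer_amp_um = 0.05, mayer_freq_hz = 0.1,
                        cardiac_amp_um = 0.1, cardiac_freq_hz = 1.1,
                        white_sd_um = 0.1) {
  if (any(c(mayer_amp_um, cardiac_amp_um, white_sd_um) < 0))
    stop("noise amplitudes must be >= 0")
  structure(list(drift_slope = drift_slope, mayer_amp_um = mayer_amp_um,
                 mayer_freq_hz = mayer_freq_hz,
                 cardiac_amp_um = cardiac_amp_um,
                 cardiac_freq_hz = cardiac_freq_hz,
                 white_sd_um = white_sd_um),
            class = "noise_model")
}

# frequency actually present in samples at rate fs (folding about Nyquist)
alias_frequency <- function(f, fs) {
  f_mod <- f %% fs
  min(f_mod, fs - f_mod)
}

#' Add structured noise to a hemoglobin series
#'
#' Adds, per channel with independent seeded streams: a linear drift, a
#' Mayer-wave sinusoid, a cardiac sinusoid (at its aliased frequency for the
#' series' sampling rate), and white noise. Sinusoid phases are drawn
#' uniformly per channel. HbR receives the same structured noise scaled by
#' `hbr_scale`.
#'
#' @param hemo a [hemoglobin_series()].
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param hbr_scale noise scale applied to the HbR channels.
#' @return a [hemoglobin_series()] with noise added.
#' @export
add_noise <- function(hemo, noise, seed = 1L, hbr_scale = 1 / 3) {
  stopifnot(inherits(hemo, "hemoglobin_series"), inherits(noise, "noise_model"))
  t <- hemo$t_s
  f_card <- alias_frequency(noise$cardiac_freq_hz, hemo$fs)
  hbo <- hemo$delta_hbo; hbr <- hemo$delta_hbr
  for (ch in seq_len(nrow(hbo))) {
    eta <- with_stream(seed, sprintf("fnirs-noise/ch%02d", ch), {
      ph <- stats::runif(2, 0, 2 * pi)
      noise$drift_slope * t +
        noise$mayer_amp_um * sin(2 * pi * noise$mayer_freq_hz * t + ph[1]) +
        noise$cardiac_amp_um * sin(2 * pi * f_card * t + ph[2]) +
        stats::rnorm(length(t), 0, noise$white_sd_um)
    })
    hbo[ch, ] <- hbo[ch, ] + eta
    hbr[ch, ] <- hbr[ch, ] + hbr_scale * eta
  }
  out <- hemoglobin_series(t, hbo, hbr, hemo$fs, condition = hemo$condition)
  attr(out, "beta_true") <- attr(hemo, "beta_true")
  out
}
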