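# Load-dependent RR-interval (tachogram) synthesis: a sinusoids-plus-noise
# model whose mean heart rate rises with load and whose LF (~0.10 Hz) and HF
# (~0.25 Hz) components give the spectral HRV features known ground truth.

#' Autonomic parameters of the RR generator
#'
#' @param mean_rr_ms baseline mean RR interval at zero load (ms).
#' @param lf_amp_ms,lf_freq_hz amplitude (ms) and frequency of the
#'   low-frequency (Mayer-wave, sympathetic-associated) modulation;
#'   the frequency must lie in the LF band 0.04-0.15 Hz.
#' @param hf_amp_ms,hf_freq_hz amplitude and frequency of the high-frequency
#'   (respiratory, parasympathetic-associated) modulation; frequency in
#'   (0.15, 0.40] Hz.
#' @param white_sd_ms SD of white beat-to-beat noise (ms).
#' @param load_hr_slope increase in mean heart rate per load step (bpm).
#' @return object of class `autonomic_params`.
#' @export
autonomic_params <- function(mean_rr_ms = 893,
                             lf_amp_ms = 25, lf_freq_hz = 0.10,
                             hf_amp_ms = 25, hf_freq_hz = 0.25,
                             white_sd_ms = 25,
                             load_hr_slope = 1.2) {
  if (mean_rr_ms <= 0) stop("mean_rr_ms must be > 0 (configuration error)")
  if (lf_amp_ms < 0 || hf_amp_ms < 0 || white_sd_ms < 0)
    stop("amplitudes must be >= 0 (configuration error)")
  if (lf_freq_hz < 0.04 || lf_freq_hz > 0.15)
    stop("lf_freq_hz must lie in [0.04, 0.15] (configuration error)")
  if (hf_freq_hz <= 0.15 || hf_freq_hz > 0.40)
    stop("hf_freq_hz must lie in (0.15, 0.40] (configuration error)")
  structure(list(mean_rr_ms = mean_rr_ms, lf_amp_ms = lf_amp_ms,
                 lf_freq_hz = lf_freq_hz, hf_amp_ms = hf_amp_ms,
                 hf_freq_hz = hf_freq_hz, white_sd_ms = white_sd_ms,
                 load_hr_slope = load_hr_slope),
            class = "autonomic_params")
}

#' Synthesize a load-dependent RR-interval series
#'
#' Beat k at cumulative time t_k gets
#' `RR = mean_rr(load) + lf_amp sin(2 pi f_lf t_k) + hf_amp sin(2 pi f_hf t_k
#' + phi) + eps`, with `mean_rr(load) = 60000 / (60000 / mean_rr_ms +
#' load_step * load_hr_slope)` (i.e. heart rate rises linearly with load) and
#' `phi` a seeded random phase. Beats are generated until the cumulative time
#' reaches `duration_s`.
#'
#' @param params an [autonomic_params()].
#' @param load_step integer 0 (low), 1 (medium), 2 (high).
#' @param duration_s run length (s).
#' @param seed integer seed.
#' @param condition optional condition label carried in the result.
#' @return object of class `rr_series` with `rr_ms`, cumulative `t_ms` and the
#'   condition label.
#' @export
synthesize_rr <- function(params, load_step, duration_s = 180, seed = 1L,
                          condition = NULL) {
  stopifnot(inherits(params, "autonomic_params"))
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (!load_step %in% 0:2) stop("load_step must be 0, 1 or 2")
  mean_rr <- 60000 / (60000 / params$mean_rr_ms +
                        load_step * params$load_hr_slope)
  with_stream(seed, "rr", {
    phi <- stats::runif(1, 0, 2 * pi)
    # generous beat budget, then truncate at duration
    n_max <- ceiling(duration_s * 1000 / max(mean_rr - 6 * params$white_sd_ms -
                                               params$lf_amp_ms -
                                               params$hf_amp_ms, 200)) + 16L
    rr <- numeric(0); t <- numeric(0)
    cum <- 0
    eps <- stats::rnorm(n_max, 0, params$white_sd_ms)
    k <- 0L
    while (cum < duration_s * 1000) {
      k <- k + 1L
      if (k > length(eps)) eps <- c(eps, stats::rnorm(n_max, 0, params$white_sd_ms))
      t_s <- cum / 1000
      val <- mean_rr +
        params$lf_amp_ms * sin(2 * pi * params$lf_freq_hz * t_s) +
        params$hf_amp_ms * sin(2 * pi * params$hf_freq_hz * t_s + phi) +
        eps[k]
      val <- max(val, 250)  # physiological floor keeps intervals positive
      cum <- cum + val
      rr <- c(rr, val); t <- c(t, cum)
    }
    rr_series(rr, condition = condition)
  })
}

#' Construct an RR series from intervals
#' @param rr_ms positive RR intervals in ms.
#' @param condition optional label.
#' @return object of class `rr_series`.
#' @export
rr_series <- function(rr_ms, condition = NULL) {
  if (any(rr_ms <= 0)) stop("all RR intervals must be > 0")
  structure(list(rr_ms = as.numeric(rr_ms), t_ms = cumsum(as.numeric(rr_ms)),
                 condition = condition), class = "rr_series")
}
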