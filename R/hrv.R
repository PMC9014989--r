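# Heart-rate-variability features from RR-interval series: artifact cleaning,
# time-domain features (mean HR, SDNN, RMSSD) and frequency-domain band powers
# (LF 0.04-0.15 Hz, HF 0.15-0.40 Hz) from a Lomb-Scargle periodogram of the
# unevenly sampled tachogram.

#' Replace artifactual RR intervals
#'
#' An interval differing from the previously accepted interval by more than
#' `max_rel_jump` (relative) is replaced by the mean of its neighbors
#' (linear interpolation); beat times are rebuilt from the cleaned intervals.
#' More than 20% flagged beats is treated as unusable data.
#'
#' @param rr an [rr_series()].
#' @param max_rel_jump maximum tolerated relative jump (default 0.2).
#' @return cleaned [rr_series()] with attribute `n_replaced`.
#' @export
clean_rr <- function(rr, max_rel_jump = 0.2) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr_ms
  if (!length(x)) stop("empty RR series")
  n <- length(x)
  flagged <- logical(n)
  # the reference beat is the last interval that passed the filter itself;
  # comparing against interpolated replacements would let a sustained
  # artifact re-baseline the filter within two beats
  prev <- x[1]
  for (i in 2:max(n, 2)) {
    if (i > n) break
    if (abs(x[i] - prev) / prev > max_rel_jump) {
      flagged[i] <- TRUE
      nxt <- if (i < n) x[i + 1] else prev
      x[i] <- (prev + nxt) / 2
    } else {
      prev <- x[i]
    }
  }
  # quality gate: a run dominated by artifacts is unusable; a lone artifact
  # in a short series is not (the fraction rule alone would reject any
  # single jump in a <5-beat series)
  if (sum(flagged) / n > 0.2 && sum(flagged) >= 3)
    stop("data-quality error: ", sum(flagged), "/", n, " beats flagged")
  out <- rr_series(x, condition = rr$condition)
  attr(out, "n_replaced") <- sum(flagged)
  out
}

#' Time-domain HRV features
#'
#' `mean HR = 60000 / mean(RR)`; SDNN is the sample standard deviation
#' (n - 1 denominator) of the intervals; RMSSD the root mean square of
#' successive differences.
#'
#' @param rr an [rr_series()] with at least 3 intervals.
#' @return list with `mean_hr_bpm`, `sdnn_ms`, `rmssd_ms`.
#' @export
hrv_time_domain <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr_ms
  if (length(x) < 3) stop("insufficient data: need >= 3 intervals")
  list(mean_hr_bpm = 60000 / mean(x),
       sdnn_ms = stats::sd(x),
       rmssd_ms = sqrt(mean(diff(x)^2)))
}

#' Lomb-Scargle power spectral density of an uneven time series
#'
#' Classical Lomb-Scargle periodogram with the per-frequency time offset tau,
#' scaled to a one-sided PSD such that the integral over (0, f_Nyquist]
#' equals the sample variance (`f_Nyquist = 1 / (2 mean(dt))`). A sinusoid of
#' amplitude A therefore integrates to a band power of ~A^2/2.
#'
#' @param t sample times (s).
#' @param y sample values (here RR intervals, ms).
#' @param freq frequencies (Hz) at which to evaluate.
#' @return data.frame with `freq` and `psd` (units of y^2 per Hz).
#' @export
lomb_psd <- function(t, y, freq) {
  stopifnot(length(t) == length(y))
  y <- y - mean(y)
  f_nyq <- 1 / (2 * mean(diff(t)))
  w <- 2 * pi * freq
  p <- vapply(w, function(wi) {
    s2 <- sum(sin(2 * wi * t)); c2 <- sum(cos(2 * wi * t))
    tau <- atan2(s2, c2) / (2 * wi)
    arg <- wi * (t - tau)
    ct <- cos(arg); st <- sin(arg)
    yc <- sum(y * ct); ys <- sum(y * st)
    0.5 * (yc^2 / sum(ct^2) + ys^2 / sum(st^2))
  }, numeric(1))
  # E[p] = variance per frequency under white noise; dividing by the mean-rate
  # Nyquist frequency calibrates the flat spectrum so the PSD integrates to
  # the variance, and a sinusoid of amplitude A to ~A^2/2
  data.frame(freq = freq, psd = p / f_nyq)
}

#' Frequency-domain HRV features
#'
#' Lomb-Scargle PSD of the tachogram (beat times vs. RR intervals, no
#' resampling) integrated by the trapezoidal rule over half-open bands
#' `[lo, hi)`.
#'
#' @param rr an [rr_series()] of at least 60 s duration.
#' @param lf_band,hf_band band edges in Hz.
#' @param oversample frequency grid oversampling factor.
#' @return list with `lf_power`, `hf_power` (ms^2) and `lf_hf_ratio`
#'   (`NA` when HF power is zero).
#' @export
hrv_frequency_domain <- function(rr, lf_band = c(0.04, 0.15),
                                 hf_band = c(0.15, 0.40), oversample = 4) {
  stopifnot(inherits(rr, "rr_series"))
  t <- rr$t_ms / 1000
  dur <- t[length(t)] - t[1]
  if (dur < 60) stop("insufficient data: series duration ", round(dur, 1),
                     " s < 60 s")
  df <- 1 / (dur * oversample)
  fmax <- max(hf_band[2], lf_band[2])
  freq <- seq(df, fmax, by = df)
  psd <- lomb_psd(t, rr$rr_ms, freq)
  band_power <- function(band) {
    # half-open [lo, hi): drop grid points at or beyond hi
    sel <- psd$freq >= band[1] & psd$freq < band[2]
    if (sum(sel) < 2) return(0)
    f <- psd$freq[sel]; p <- psd$psd[sel]
    sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  }
  lf <- band_power(lf_band)
  hf <- band_power(hf_band)
  list(lf_power = lf, hf_power = hf,
       lf_hf_ratio = if (hf > 0) lf / hf else NA_real_)
}

#' All HRV features of one run
#'
#' Convenience wrapper: [clean_rr()] then time- and frequency-domain features.
#'
#' @param rr an [rr_series()].
#' @param clean apply artifact cleaning first.
#' @return one-row data.frame: mean HR, SDNN, RMSSD, LF, HF, LF/HF.
#' @export
hrv_features <- function(rr, clean = TRUE) {
  if (clean) rr <- clean_rr(rr)
  td <- hrv_time_domain(rr)
  fd <- hrv_frequency_domain(rr)
  data.frame(mean_hr_bpm = td$mean_hr_bpm, sdnn_ms = td$sdnn_ms,
             rmssd_ms = td$rmssd_ms, lf_power = fd$lf_power,
             hf_power = fd$hf_power, lf_hf_ratio = fd$lf_hf_ratio)
}
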