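# Canonical double-gamma hemodynamic response function, used both as the
# regressor kernel of the GLM design and as its precoloring low-pass filter.

#' Canonical double-gamma HRF
#'
#' `h(t) = g(t; peak, 1) - g(t; undershoot, 1) / ratio` with unit-rate gamma
#' densities: response peaking near `peak` seconds with an undershoot near
#' `undershoot` seconds at amplitude `1/ratio` of the peak lobe.
#'
#' @param t time points (s).
#' @param peak_s time-to-peak parameter (gamma shape) of the positive lobe.
#' @param undershoot_s shape of the undershoot lobe.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param normalize `"peak"` scales so max = 1, `"area"` so the (discrete)
#'   integral is 1, `"none"` leaves the raw difference of densities.
#' @return numeric vector of HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak_s = 6, undershoot_s = 16, ratio = 6,
                          normalize = c("peak", "area", "none")) {
  normalize <- match.arg(normalize)
  h <- stats::dgamma(t, shape = peak_s, rate = 1) -
    stats::dgamma(t, shape = undershoot_s, rate = 1) / ratio
  h[t < 0] <- 0
  switch(normalize,
         peak = h / max(h),
         area = {
           dt <- if (length(t) > 1) t[2] - t[1] else 1
           h / (sum(h) * dt)
         },
         none = h)
}

# HRF sampled on the acquisition grid; kernel_s caps the support (the
# double-gamma is numerically zero past ~32 s)
.hrf_kernel <- function(fs, kernel_s = 32, ...) {
  canonical_hrf(seq(0, kernel_s, by = 1 / fs), ...)
}

# causal discrete convolution of x with kernel k, truncated to length(x)
.conv_causal <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(k) - 1)),
                         rev(k), type = "open")
  out[seq_len(n)]
}

#' Task regressor: boxcar convolved with the canonical HRF
#'
#' Builds the boxcar from event onsets/durations on the sampling grid,
#' convolves with the double-gamma HRF and peak-normalizes the result (the
#' maximum of the regressor is 1; for a long block the plateau settles just
#' below the transient peak).
#'
#' @param onsets_s,durations_s event onsets and durations (s), equal length.
#' @param fs sampling rate (Hz).
#' @param n_samples length of the output grid.
#' @param hrf_params optional list overriding `peak_s`, `undershoot_s`,
#'   `ratio` of [canonical_hrf()].
#' @return numeric regressor of length `n_samples`; all-zero (attribute
#'   `empty = TRUE`) if the event list has zero total duration.
#' @export
hrf_regressor <- function(onsets_s, durations_s, fs, n_samples,
                          hrf_params = list()) {
  stopifnot(length(onsets_s) == length(durations_s))
  if (any(durations_s < 0)) stop("negative event duration")
  t <- (seq_len(n_samples) - 1L) / fs
  box <- numeric(n_samples)
  for (i in seq_along(onsets_s)) {
    if (onsets_s[i] > t[n_samples]) stop("event onset beyond run end")
    box[t >= onsets_s[i] & t < onsets_s[i] + durations_s[i]] <- 1
  }
  if (!any(box > 0)) {
    return(structure(box, empty = TRUE))
  }
  k <- do.call(.hrf_kernel, c(list(fs = fs, normalize = "none"), hrf_params))
  reg <- .conv_causal(box, k)
  structure(reg / max(reg), empty = FALSE)
}
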