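# Orthogonal discrete wavelet transform (periodized) with the sym8
# least-asymmetric Daubechies filters, and universal-threshold soft wavelet
# denoising. No DWT package ships with this environment, so the pyramid
# algorithm is implemented directly; tests verify orthonormality of the
# filter, perfect reconstruction, and the eight vanishing moments.

# sym8 decomposition lowpass filter (least-asymmetric Daubechies, 8 vanishing
# moments), derived by spectral factorization of the Daubechies half-band
# polynomial; sums to sqrt(2), unit energy.
SYM8_DEC_LO <- c(
  -0.0033824159510050032, -0.0005421323318000246,
   0.0316950878115259540,  0.0076074873249766823,
  -0.1432942383512725800, -0.0612733590678111450,
   0.4813596512590533900,  0.7771857516996276700,
   0.3644418948361796100, -0.0519458381078818370,
  -0.0272190299171039260,  0.0491371796737302070,
   0.0038087520138945278, -0.0149522583370621730,
  -0.0003029205147241394,  0.0018899503327676841
)

.qmf_high <- function(lo) {
  L <- length(lo)
  (-1)^(seq_len(L) - 1) * rev(lo)
}

# one analysis step, periodic boundary: x (even length) -> list(a, d)
.dwt_step <- function(x, lo, hi) {
  n <- length(x)
  L <- length(lo)
  half <- n / 2
  a <- numeric(half); d <- numeric(half)
  idx0 <- (seq_len(half) - 1L) * 2L  # 0-based start
  for (m in seq_len(L)) {
    xi <- x[((idx0 + m - 1L) %% n) + 1L]
    a <- a + lo[m] * xi
    d <- d + hi[m] * xi
  }
  list(a = a, d = d)
}

# one synthesis step (transpose of the analysis operator); for fixed filter
# tap m the target positions are distinct, so vectorized accumulation is exact
.idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2L * half
  L <- length(lo)
  x <- numeric(n)
  idx0 <- (seq_len(half) - 1L) * 2L
  for (m in seq_len(L)) {
    pos <- ((idx0 + m - 1L) %% n) + 1L
    x[pos] <- x[pos] + lo[m] * a + hi[m] * d
  }
  x
}

# periodized multi-level DWT; length(x) must be divisible by 2^level
dwt_periodic <- function(x, level, lo = SYM8_DEC_LO) {
  n <- length(x)
  if (level < 1) stop("level must be >= 1")
  if (n %% 2^level != 0) stop("length must be divisible by 2^level")
  if (n / 2^level < 1) stop("series too short for this level")
  hi <- .qmf_high(lo)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- .dwt_step(a, lo, hi)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, level = level)
}

idwt_periodic <- function(w, lo = SYM8_DEC_LO) {
  hi <- .qmf_high(lo)
  a <- w$approx
  for (j in rev(seq_len(w$level))) {
    a <- .idwt_step(a, w$details[[j]], lo, hi)
  }
  a
}

.soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

# denoise one numeric vector (arbitrary length; symmetric padding to a
# power-of-two grid, truncated after reconstruction)
.wavelet_denoise_vec <- function(x, level, lo) {
  n <- length(x)
  n_pad <- 2^ceiling(log2(n))
  if (n_pad < 2^level) n_pad <- 2^level
  pad <- n_pad - n
  xp <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
  w <- dwt_periodic(xp, level, lo)
  finest <- w$details[[1]]
  sigma <- stats::mad(finest, center = 0)
  thr <- sigma * sqrt(2 * log(length(xp)))
  w$details <- lapply(w$details, .soft_threshold, thr = thr)
  y <- idwt_periodic(w, lo)
  y[seq_len(n)]
}

#' Soft-threshold wavelet denoising of a hemoglobin series
#'
#' Per channel: periodized sym8 DWT to `level`, soft thresholding of all
#' detail coefficients with the universal threshold `sigma_hat *
#' sqrt(2 log n)` (`sigma_hat` = MAD of the finest-scale details), and
#' reconstruction. Output length equals input length (series of non-dyadic
#' length are reflection-padded internally).
#'
#' @param hemo a [hemoglobin_series()].
#' @param level decomposition depth; default `floor(log2(n)) - 4`.
#' @param wavelet only `"sym8"` is shipped.
#' @return a denoised [hemoglobin_series()].
#' @export
wavelet_denoise <- function(hemo, level = NULL, wavelet = "sym8") {
  stopifnot(inherits(hemo, "hemoglobin_series"))
  lo <- switch(wavelet, sym8 = SYM8_DEC_LO,
               stop("unknown wavelet: ", wavelet))
  n <- ncol(hemo$delta_hbo)
  if (n < length(lo)) stop("series shorter than the wavelet filter support")
  if (is.null(level)) level <- max(1L, floor(log2(n)) - 4L)
  if (n < 2^level) stop("series length ", n, " < 2^level")
  hbo <- t(apply(hemo$delta_hbo, 1, .wavelet_denoise_vec, level = level, lo = lo))
  hbr <- t(apply(hemo$delta_hbr, 1, .wavelet_denoise_vec, level = level, lo = lo))
  out <- hemoglobin_series(hemo$t_s, hbo, hbr, hemo$fs,
                           condition = hemo$condition)
  attr(out, "beta_true") <- attr(hemo, "beta_true")
  out
}
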