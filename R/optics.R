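# Optics configuration and the modified Beer-Lambert law (MBLL), forward and
# inverse. Concentrations are in micromolar; the source-detector distance and
# differential pathlength factor are folded into the 2x2 system so GLM betas
# come out in uM.

#' Default hemoglobin extinction coefficients
#'
#' Reads the tabulated molar extinction coefficients shipped with the package
#' (Gratzer/Prahl compilation as used by common fNIRS toolboxes), in
#' cm^-1/(mol/L), for the requested wavelengths.
#'
#' @param wavelengths_nm wavelengths to look up.
#' @return matrix with rows = wavelengths, columns `hbo`, `hbr`.
#' @export
default_extinction_coeffs <- function(wavelengths_nm = c(760, 850)) {
  path <- system.file("extdata", "extinction_coefficients.csv",
                      package = "flightload")
  tab <- utils::read.csv(path)
  idx <- match(wavelengths_nm, tab$wavelength_nm)
  if (anyNA(idx))
    stop("no extinction entry for wavelength(s): ",
         paste(wavelengths_nm[is.na(idx)], collapse = ", "))
  m <- as.matrix(tab[idx, c("hbo_cm_per_mol_l", "hbr_cm_per_mol_l")])
  dimnames(m) <- list(wavelengths_nm, c("hbo", "hbr"))
  m
}

#' Optical configuration of the fNIRS recording
#'
#' @param wavelengths_nm the two laser/LED wavelengths.
#' @param source_detector_distance_cm optode separation.
#' @param dpf differential pathlength factor, one per wavelength (recycled).
#' @param extinction_coeffs 2x2 matrix (wavelength x chromophore), in
#'   cm^-1/(mol/L); default from [default_extinction_coeffs()].
#' @param sampling_hz acquisition rate.
#' @param n_channels number of measurement channels.
#' @return object of class `optics_config`; the effective uM-scale MBLL
#'   matrix and its condition number are precomputed.
#' @export
optics_config <- function(wavelengths_nm = c(760, 850),
                          source_detector_distance_cm = 3.5,
                          dpf = c(6.0, 6.0),
                          extinction_coeffs = NULL,
                          sampling_hz = 2,
                          n_channels = 8L) {
  if (length(wavelengths_nm) != 2L) stop("exactly two wavelengths required")
  if (source_detector_distance_cm <= 0) stop("distance must be > 0")
  if (sampling_hz <= 0) stop("sampling_hz must be > 0")
  dpf <- rep_len(dpf, 2L)
  if (is.null(extinction_coeffs))
    extinction_coeffs <- default_extinction_coeffs(wavelengths_nm)
  E <- as.matrix(extinction_coeffs)
  stopifnot(all(dim(E) == c(2L, 2L)))
  # uM-scale system: dOD(lambda) = A %*% c(dHbO, dHbR) with concentrations uM
  A <- (E * 1e-6) * (source_detector_distance_cm * dpf)
  kappa <- kappa(A, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e12)
    stop("singular extinction matrix for wavelength pair ",
         paste(wavelengths_nm, collapse = "/"))
  structure(list(wavelengths_nm = wavelengths_nm,
                 source_detector_distance_cm = source_detector_distance_cm,
                 dpf = dpf, extinction_coeffs = E, mbll_matrix = A,
                 condition_number = kappa, sampling_hz = sampling_hz,
                 n_channels = as.integer(n_channels)),
            class = "optics_config")
}

#' Hemoglobin concentration-change series
#'
#' @param t_s sample times (s), uniform grid.
#' @param delta_hbo,delta_hbr channels x samples matrices, uM.
#' @param fs sampling rate (Hz).
#' @param condition optional label.
#' @return object of class `hemoglobin_series`.
#' @export
hemoglobin_series <- function(t_s, delta_hbo, delta_hbr, fs, condition = NULL) {
  delta_hbo <- rbind(delta_hbo); delta_hbr <- rbind(delta_hbr)
  stopifnot(ncol(delta_hbo) == length(t_s),
            all(dim(delta_hbo) == dim(delta_hbr)))
  if (!all(is.finite(delta_hbo)) || !all(is.finite(delta_hbr)))
    stop("non-finite hemoglobin values")
  structure(list(t_s = t_s, delta_hbo = delta_hbo, delta_hbr = delta_hbr,
                 fs = fs, condition = condition),
            class = "hemoglobin_series")
}

#' Forward modified Beer-Lambert law
#'
#' Maps concentration changes to optical-density changes:
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF`.
#'
#' @param hemo a [hemoglobin_series()].
#' @param optics an [optics_config()].
#' @return object of class `od_series` with `delta_od`, a 3-d array
#'   channels x wavelengths x samples.
#' @export
mbll_forward <- function(hemo, optics) {
  stopifnot(inherits(hemo, "hemoglobin_series"), inherits(optics, "optics_config"))
  A <- optics$mbll_matrix
  nch <- nrow(hemo$delta_hbo); ns <- ncol(hemo$delta_hbo)
  od <- array(NA_real_, dim = c(nch, 2L, ns),
              dimnames = list(NULL, optics$wavelengths_nm, NULL))
  for (ch in seq_len(nch)) {
    od[ch, , ] <- A %*% rbind(hemo$delta_hbo[ch, ], hemo$delta_hbr[ch, ])
  }
  structure(list(t_s = hemo$t_s, delta_od = od, fs = hemo$fs,
                 wavelengths_nm = optics$wavelengths_nm,
                 condition = hemo$condition),
            class = "od_series")
}

#' Invert the modified Beer-Lambert law
#'
#' Solves the per-sample 2x2 system for `dHbO`/`dHbR` in uM. Errors if the
#' MBLL matrix is ill-conditioned (condition number > 1e6).
#'
#' @param od an `od_series` as produced by [mbll_forward()] or read from disk.
#' @param optics an [optics_config()] whose wavelengths match the data.
#' @return a [hemoglobin_series()].
#' @export
mbll_invert <- function(od, optics) {
  stopifnot(inherits(od, "od_series"), inherits(optics, "optics_config"))
  if (!isTRUE(all.equal(as.numeric(od$wavelengths_nm),
                        as.numeric(optics$wavelengths_nm))))
    stop("data wavelengths (", paste(od$wavelengths_nm, collapse = "/"),
         ") do not match optics (",
         paste(optics$wavelengths_nm, collapse = "/"), ")")
  if (optics$condition_number > 1e6)
    stop("ill-conditioned extinction matrix for wavelength pair ",
         paste(optics$wavelengths_nm, collapse = "/"),
         " (condition number ", format(optics$condition_number), ")")
  Ainv <- solve(optics$mbll_matrix)
  nch <- dim(od$delta_od)[1]; ns <- dim(od$delta_od)[3]
  hbo <- matrix(NA_real_, nch, ns); hbr <- matrix(NA_real_, nch, ns)
  for (ch in seq_len(nch)) {
    conc <- Ainv %*% od$delta_od[ch, , ]
    hbo[ch, ] <- conc[1, ]; hbr[ch, ] <- conc[2, ]
  }
  hemoglobin_series(od$t_s, hbo, hbr, od$fs, condition = od$condition)
}
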