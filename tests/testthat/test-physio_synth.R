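# Physiological synthesis: RR tachograms, forward fNIRS activation, noise,
# and the forward/inverse Beer-Lambert pair.

test_that("noiseless degenerate RR series is constant", {
  ap <- autonomic_params(mean_rr_ms = 800, lf_amp_ms = 0, hf_amp_ms = 0,
                         white_sd_ms = 0)
  rr <- synthesize_rr(ap, 0, duration_s = 60, seed = 1)
  expect_true(all(rr$rr_ms == 800))
  expect_equal(rr$t_ms, cumsum(rr$rr_ms))
})

test_that("load raises mean heart rate as configured", {
  # base mean HR 66 bpm, slope 2 bpm/step, load 2 -> realized ~70 bpm
  ap <- autonomic_params(mean_rr_ms = 60000 / 66, load_hr_slope = 2,
                         white_sd_ms = 10)
  hr <- vapply(1:10, function(s)
    60000 / mean(synthesize_rr(ap, 2, seed = s)$rr_ms), numeric(1))
  expect_true(all(abs(hr - 70) < 1))
  # law-of-large-numbers check at zero load
  hr0 <- vapply(1:10, function(s)
    60000 / mean(synthesize_rr(ap, 0, seed = 100 + s)$rr_ms), numeric(1))
  expect_lt(abs(mean(hr0) - 66), 0.5)
})

test_that("RR generator is a pure function of (params, seed)", {
  ap <- autonomic_params()
  r1 <- synthesize_rr(ap, 1, seed = 7)
  r2 <- synthesize_rr(ap, 1, seed = 7)
  expect_identical(r1$rr_ms, r2$rr_ms)
  r3 <- synthesize_rr(ap, 1, seed = 8)
  expect_false(identical(r1$rr_ms, r3$rr_ms))
})

test_that("autonomic parameter invariants are enforced", {
  expect_error(autonomic_params(mean_rr_ms = -5), "mean_rr_ms")
  expect_error(autonomic_params(lf_freq_hz = 0.2), "lf_freq_hz")
  expect_error(autonomic_params(hf_freq_hz = 0.1), "hf_freq_hz")
  expect_error(autonomic_params(white_sd_ms = -1), "amplitudes")
})

test_that("activation synthesis is linear in the true amplitudes", {
  z <- synthesize_activation(rep(0, 8))
  expect_true(all(z$delta_hbo == 0) && all(z$delta_hbr == 0))
  a1 <- synthesize_activation(c(0.5, 1, 0.2, 0, 0.7, 0.3, 0.9, 0.1))
  a2 <- synthesize_activation(2 * c(0.5, 1, 0.2, 0, 0.7, 0.3, 0.9, 0.1))
  expect_equal(a2$delta_hbo, 2 * a1$delta_hbo, tolerance = 1e-12)
  # HbR is the configured negative fraction of HbO
  expect_equal(a1$delta_hbr, -a1$delta_hbo / 3, tolerance = 1e-12)
})

test_that("single long boxcar regressor peaks at 1 with a near-1 plateau", {
  hemo <- synthesize_activation(1, onsets_s = 0, durations_s = 180,
                                duration_s = 180, fs = 2)
  reg <- attr(hemo, "regressor")
  expect_length(reg, 360)
  expect_equal(max(reg), 1)
  # after the HRF settles the response is flat near its peak value
  plateau <- reg[seq(120, 340)]
  expect_lt(max(abs(plateau - mean(plateau))), 0.01)
  expect_gt(mean(plateau), 0.85)
})

test_that("additive noise behaves as specified", {
  hemo <- synthesize_activation(rep(0, 8), duration_s = 180, fs = 2)
  nil <- noise_model(drift_slope = 0, mayer_amp_um = 0, cardiac_amp_um = 0,
                     white_sd_um = 0)
  expect_equal(add_noise(hemo, nil, seed = 1)$delta_hbo, hemo$delta_hbo)
  # white-only noise: realized SD within 20% of sigma (Monte Carlo over
  # channels x seeds; 360 samples each)
  wn <- noise_model(drift_slope = 0, mayer_amp_um = 0, cardiac_amp_um = 0,
                    white_sd_um = 0.2)
  sds <- unlist(lapply(1:5, function(s) {
    apply(add_noise(hemo, wn, seed = s)$delta_hbo, 1, stats::sd)
  }))
  expect_true(all(abs(sds - 0.2) / 0.2 < 0.2))
  nm <- noise_model()
  expect_identical(add_noise(hemo, nm, seed = 4)$delta_hbo,
                   add_noise(hemo, nm, seed = 4)$delta_hbo)
  expect_error(noise_model(white_sd_um = -1), "amplitudes")
})

test_that("cardiac frequency aliases onto the sampled band", {
  expect_equal(alias_frequency(1.1, 2), 0.9)
  expect_equal(alias_frequency(0.3, 2), 0.3)
  expect_equal(alias_frequency(2.0, 2), 0)
})

test_that("forward and inverse MBLL are exact inverses", {
  optics <- optics_config()
  set.seed(42)
  for (rep in 1:5) {
    h <- hemoglobin_series((0:49) / 2, matrix(rnorm(400), 8),
                           matrix(rnorm(400), 8), fs = 2)
    od <- mbll_forward(h, optics)
    back <- mbll_invert(od, optics)
    expect_lt(max(abs(back$delta_hbo - h$delta_hbo)), 1e-10)
    expect_lt(max(abs(back$delta_hbr - h$delta_hbr)), 1e-10)
  }
  # zero in, zero out
  z <- hemoglobin_series((0:9) / 2, matrix(0, 8, 10), matrix(0, 8, 10), fs = 2)
  expect_true(all(mbll_forward(z, optics)$delta_od == 0))
  # pathlength linearity: doubling d doubles OD
  optics2 <- optics_config(source_detector_distance_cm = 7.0)
  h1 <- hemoglobin_series((0:9) / 2, matrix(1, 1, 10), matrix(0.5, 1, 10), fs = 2)
  expect_equal(mbll_forward(h1, optics2)$delta_od,
               2 * mbll_forward(h1, optics_config())$delta_od,
               tolerance = 1e-12)
})

test_that("wavelength permutation with matching config is representation-invariant", {
  optics <- optics_config()
  optics_flip <- optics_config(wavelengths_nm = c(850, 760),
                               extinction_coeffs =
                                 default_extinction_coeffs(c(850, 760)))
  set.seed(7)
  h <- hemoglobin_series((0:19) / 2, matrix(rnorm(40), 2),
                         matrix(rnorm(40), 2), fs = 2)
  od <- mbll_forward(h, optics)
  od_flip <- od
  od_flip$delta_od <- od$delta_od[, 2:1, , drop = FALSE]
  od_flip$wavelengths_nm <- c(850, 760)
  b1 <- mbll_invert(od, optics)
  b2 <- mbll_invert(od_flip, optics_flip)
  expect_equal(b1$delta_hbo, b2$delta_hbo, tolerance = 1e-12)
  # mismatched wavelengths error names the pair
  expect_error(mbll_invert(od_flip, optics), "760")
})

test_that("degenerate optics are rejected", {
  E_sing <- matrix(c(1, 1, 2, 2), 2, 2)
  expect_error(optics_config(extinction_coeffs = E_sing))
  expect_error(optics_config(source_detector_distance_cm = 0), "distance")
})
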