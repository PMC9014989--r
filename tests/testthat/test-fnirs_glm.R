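# fNIRS analysis chain: wavelet denoising, design construction, precolored
# GLM estimation, and the full MBLL -> denoise -> GLM recovery.

test_that("sym8 filter bank is orthonormal with eight vanishing moments", {
  lo <- flightload:::SYM8_DEC_LO
  expect_equal(sum(lo), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(lo^2), 1, tolerance = 1e-12)
  for (k in 1:7) {
    expect_lt(abs(sum(lo[1:(16 - 2 * k)] * lo[(2 * k + 1):16])), 1e-12)
  }
  hi <- flightload:::.qmf_high(lo)
  for (m in 0:7) {
    expect_lt(abs(sum(hi * (0:15)^m)), 1e-6)
  }
})

test_that("periodized DWT reconstructs perfectly", {
  set.seed(3)
  for (n in c(64, 256, 1024)) {
    x <- stats::rnorm(n)
    w <- flightload:::dwt_periodic(x, 4)
    expect_lt(max(abs(flightload:::idwt_periodic(w) - x)), 1e-12)
  }
  expect_error(flightload:::dwt_periodic(rnorm(100), 3), "divisible")
})

test_that("wavelet denoising passes smooth signals and shrinks noise", {
  t <- (0:599) / 2
  mk <- function(m) hemoglobin_series(t, rbind(m), rbind(-m / 3), fs = 2)
  # zero in, zero out
  z <- wavelet_denoise(mk(rep(0, 600)))
  expect_true(all(z$delta_hbo == 0))
  # noiseless smooth ramp survives within 1% RMS
  ramp <- seq(0, 1, length.out = 600)
  dn <- wavelet_denoise(mk(ramp))
  expect_lt(sqrt(mean((dn$delta_hbo[1, ] - ramp)^2)) / sqrt(mean(ramp^2)),
            0.01)
  # HRF-shaped signal at SNR 1: denoising reduces RMSE vs truth (50 seeds)
  sig <- attr(synthesize_activation(1, duration_s = 300, fs = 2),
              "regressor")
  sd_n <- stats::sd(sig)
  rmse <- vapply(1:50, function(s) {
    set.seed(s)
    noisy <- sig + stats::rnorm(600, 0, sd_n)
    dn <- wavelet_denoise(hemoglobin_series(t, rbind(noisy),
                                            rbind(-noisy / 3), fs = 2))
    c(before = sqrt(mean((noisy - sig)^2)),
      after = sqrt(mean((dn$delta_hbo[1, ] - sig)^2)))
  }, numeric(2))
  expect_lt(mean(rmse["after", ]), mean(rmse["before", ]))
  expect_gte(mean(rmse["after", ] < rmse["before", ]), 0.9)
  expect_error(wavelet_denoise(mk(rep(0, 600)), level = 12), "2\\^level")
})

test_that("design matrix has the documented structure", {
  des <- build_design(0, 180, fs = 2, n_samples = 360, drift_order = 1)
  expect_equal(colnames(des$X), c("task", "constant", "drift1"))
  expect_equal(max(des$X[, "task"]), 1)
  expect_equal(which.max(des$X[, "task"] > 0.5) > 1, TRUE)
  # zero-duration event list: nuisance-only design, flagged
  des0 <- build_design(10, 0, fs = 2, n_samples = 360)
  expect_true(des0$empty_task)
  expect_false("task" %in% colnames(des0$X))
  expect_error(fit_glm(synthesize_activation(rep(0, 2), duration_s = 180,
                                             fs = 2),
                       des0), "degenerate")
  expect_error(build_design(0, 180, fs = 2, n_samples = 3), "exceed")
})

test_that("noiseless GLM returns the exact coefficient", {
  des <- build_design(60, 180, fs = 2, n_samples = 600)
  hemo <- synthesize_activation(rep(2, 8))
  shift <- hemo
  shift$delta_hbo <- shift$delta_hbo + 1.0   # constant offset absorbed
  for (pc in c(TRUE, FALSE)) {
    fit <- fit_glm(shift, des, precolor = pc)
    expect_equal(unname(fit$beta), rep(2, 8), tolerance = 1e-8)
    expect_equal(fit$mean_beta, 2, tolerance = 1e-8)
  }
})

test_that("GLM is unbiased on pure white noise", {
  des <- build_design(60, 180, fs = 2, n_samples = 600)
  ctx <- prepare_precolor(des)
  t <- (0:599) / 2
  betas <- vapply(1:200, function(s) {
    set.seed(s)
    y <- stats::rnorm(600, 0, 0.1)
    fit <- fit_glm(hemoglobin_series(t, rbind(y), rbind(y), fs = 2),
                   des, context = ctx)
    fit$beta[1]
  }, numeric(1))
  mc_se <- stats::sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas)), 2 * mc_se + 1e-6)
})

test_that("mean activation read-out increases with true amplitude", {
  des <- build_design(60, 180, fs = 2, n_samples = 600)
  ctx <- prepare_precolor(des)
  nm <- noise_model()
  reads <- vapply(c(0, 0.2, 0.5, 1.0), function(bt) {
    mean(vapply(1:10, function(s) {
      noisy <- add_noise(synthesize_activation(rep(bt, 8)), nm, seed = s)
      fit_glm(noisy, des, context = ctx)$mean_beta
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(reads) > 0))
})

test_that("high-load activation exceeds low-load in seed-paired runs", {
  # truth separation of 0.5 uM (>= 2x the noise-limited SE): the high-load
  # fit must win in at least 95% of seed-paired comparisons
  des <- build_design(60, 180, fs = 2, n_samples = 600)
  ctx <- prepare_precolor(des)
  nm <- noise_model()
  wins <- vapply(1:40, function(s) {
    lo <- fit_glm(add_noise(synthesize_activation(rep(0.1, 8)), nm,
                            seed = s), des, context = ctx)$mean_beta
    hi <- fit_glm(add_noise(synthesize_activation(rep(0.6, 8)), nm,
                            seed = 10000 + s), des, context = ctx)$mean_beta
    hi > lo
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("full chain on noise-free forward data recovers amplitudes to <1%", {
  optics <- optics_config()
  beta_true <- c(0.2, 0.4, 0.6, 0.8, 1.0, 0.3, 0.5, 0.7)
  hemo <- synthesize_activation(beta_true)
  od <- mbll_forward(hemo, optics)
  hb <- wavelet_denoise(mbll_invert(od, optics))
  des <- build_design(60, 180, fs = 2, n_samples = 600)
  fit <- fit_glm(hb, des)
  expect_true(all(abs(fit$beta - beta_true) / beta_true < 0.01))
})

test_that("non-finite data are reported per channel", {
  des <- build_design(60, 180, fs = 2, n_samples = 600)
  hemo <- synthesize_activation(rep(1, 3))
  hemo$delta_hbo[2, 5] <- NA
  expect_error(fit_glm(hemo, des), "channel\\(s\\): 2")
})
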