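# Orchestration and interchange formats: determinism, counterbalancing,
# stream isolation, file round trips, and the report bundle.

test_that("behavior log and RR CSV round-trip through disk", {
  tc <- task_config("high", rng_seed = 21)
  log <- simulate_session(tc, operator_profile())
  tmp <- tempfile(fileext = ".jsonl")
  write_behavior_log(log, tmp)
  lines <- readLines(tmp)
  hdr <- jsonlite::fromJSON(lines[1])
  expect_equal(hdr$condition, "high")
  expect_equal(hdr$seed, 21)
  streams <- vapply(lines[-1], function(l) jsonlite::fromJSON(l)$stream, "")
  expect_true(all(streams %in% c("alarm", "meter", "emergency", "numeral")))
  expect_equal(sum(streams == "emergency"), nrow(log$emergency_events))
  tracking_csv <- sub("\\.jsonl$", "_tracking.csv", tmp)
  tr <- utils::read.csv(tracking_csv)
  expect_equal(tr$distance_mm, log$tracking_samples$distance_mm)

  rr <- synthesize_rr(autonomic_params(), 1, seed = 4)
  tmp2 <- tempfile(fileext = ".csv")
  write_rr_csv(rr, tmp2)
  rr2 <- read_rr_csv(tmp2)
  expect_equal(rr2$rr_ms, rr$rr_ms)
  expect_equal(rr2$t_ms, rr$t_ms)
})

test_that("fNIRS CSV container round-trips data and metadata", {
  optics <- optics_config()
  set.seed(2)
  hemo <- hemoglobin_series((0:99) / 2, matrix(stats::rnorm(800), 8),
                            matrix(stats::rnorm(800), 8), fs = 2,
                            condition = "medium")
  tmp <- tempfile(fileext = ".csv")
  write_fnirs_csv(hemo, tmp, optics)
  back <- read_fnirs_csv(tmp)
  expect_lt(max(abs(back$delta_hbo - hemo$delta_hbo)), 1e-12)
  expect_lt(max(abs(back$delta_hbr - hemo$delta_hbr)), 1e-12)
  expect_identical(back$condition, "medium")
  meta <- attr(back, "optics_meta")
  expect_equal(meta$wavelengths_nm, optics$wavelengths_nm)
  expect_equal(meta$dpf, optics$dpf)

  od <- mbll_forward(hemo, optics)
  tmp_od <- tempfile(fileext = ".csv")
  write_fnirs_csv(od, tmp_od, optics)
  od2 <- read_fnirs_csv(tmp_od)
  expect_lt(max(abs(od2$delta_od - od$delta_od)), 1e-12)

  # missing wavelength metadata is a parse error naming the field
  sidecar <- paste0(tmp, ".json")
  meta_raw <- jsonlite::fromJSON(readLines(sidecar))
  meta_raw$wavelengths_nm <- NULL
  writeLines(jsonlite::toJSON(meta_raw, auto_unbox = TRUE), sidecar)
  expect_error(read_fnirs_csv(tmp), "wavelengths_nm")
})

test_that("CSV container and in-memory series analyze identically", {
  optics <- optics_config()
  hemo <- add_noise(synthesize_activation(rep(0.5, 8)), noise_model(),
                    seed = 31)
  des <- build_design(60, 180, fs = 2, n_samples = 600)
  direct <- fit_glm(wavelet_denoise(hemo), des)
  tmp <- tempfile(fileext = ".csv")
  write_fnirs_csv(hemo, tmp, optics)
  via_disk <- fit_glm(wavelet_denoise(read_fnirs_csv(tmp)), des)
  expect_equal(via_disk$beta, direct$beta, tolerance = 1e-10)
})

test_that("counterbalancing assigns each condition to each position evenly", {
  for (n in c(9, 26)) {
    orders <- counterbalance_orders(n)
    for (pos in 1:3) {
      counts <- table(orders[, pos])
      expect_true(all(abs(counts - n / 3) <= 1))
    }
    # every subject sees all three conditions exactly once
    expect_true(all(apply(orders, 1, function(r)
      setequal(r, c("low", "medium", "high")))))
  }
})

test_that("a study is reproducible from its root seed", {
  cfg <- fast_study_config(seed = 17)
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_identical(r1$measures, r2$measures)
  expect_identical(r1$anova, r2$anova)
  expect_identical(r1$correlations, r2$correlations)
})

test_that("stages draw from isolated seed streams", {
  # perturbing only the fNIRS noise stream must leave behavior, TLX and
  # cardiac outputs bit-identical while changing the activation estimates
  r1 <- run_study(fast_study_config(seed = 23))
  r2 <- run_study(fast_study_config(seed = 23, fnirs_noise_salt = "x"))
  expect_identical(r1$performance, r2$performance)
  expect_identical(r1$tlx, r2$tlx)
  expect_identical(r1$hrv, r2$hrv)
  expect_false(identical(r1$fnirs$mean_beta, r2$fnirs$mean_beta))
  expect_identical(r1$fnirs$mean_beta_true, r2$fnirs$mean_beta_true)
})

test_that("the report bundle is complete, mirrors 'none' cells, and is deterministic", {
  res <- run_study(fast_study_config(seed = 29))
  dir1 <- tempfile(); dir2 <- tempfile()
  make_report(res, dir1)
  make_report(res, dir2)
  an <- utils::read.csv(file.path(dir1, "anova.csv"))
  expect_setequal(an$measure, flightload:::STUDY_MEASURES)
  expect_equal(nrow(an), length(flightload:::STUDY_MEASURES))
  perf <- utils::read.csv(file.path(dir1, "performance_by_condition.csv"))
  low_meter <- perf$low[perf$feature == "meter_rt_s"]
  expect_true(is.na(low_meter) || low_meter == "")
  expect_false(perf$medium[perf$feature == "meter_rt_s"] == "")
  expect_true(is.na(perf$medium[perf$feature == "emergency_rt_s"]) ||
                perf$medium[perf$feature == "emergency_rt_s"] == "")
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("study stages fail with stage-tagged errors", {
  cfg <- fast_study_config(seed = 1)
  cfg$task$tick_hz <- 0
  expect_error(run_study(cfg), "stage 'behavior'")
  cfg2 <- fast_study_config(seed = 1)
  cfg2$optics$wavelengths_nm <- 760
  expect_error(run_study(cfg2), "stage 'fnirs'")
})

test_that("child seeds are stable, bounded, and stream-separated", {
  s1 <- child_seed(1, "a")
  expect_identical(s1, child_seed(1, "a"))
  expect_true(s1 >= 1 && s1 < 2^31 - 1)
  expect_false(child_seed(1, "a") == child_seed(1, "b"))
  expect_false(child_seed(1, "a") == child_seed(2, "a"))
})
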