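# Task engine: resource allocation, session simulation, performance scoring.

test_that("resource allocation fills greedily by priority", {
  prof <- operator_profile(capacity = 1.0,
                           priority_order = c("tracking", "meter",
                                              "emergency", "residual"))
  # single consumer takes all it asks for
  expect_equal(allocate_resources(prof, "tracking", c(tracking = 1.0)),
               c(tracking = 1.0))
  # greedy fill: tracking 0.6 granted, meter gets the 0.4 remainder,
  # residual nothing
  sh <- allocate_resources(prof, c("tracking", "meter", "residual"),
                           c(tracking = 0.6, meter = 0.6, residual = 0.3))
  expect_equal(sh, c(tracking = 0.6, meter = 0.4, residual = 0.0))
  # empty pool
  prof0 <- operator_profile(capacity = 0)
  sh0 <- allocate_resources(prof0, c("tracking", "residual"),
                            c(tracking = 0.5, residual = 0.5))
  expect_true(all(sh0 == 0))
  # unknown task id is a configuration error
  expect_error(allocate_resources(prof, c("tracking", "warp"),
                                  c(warp = 1)), "unknown task")
  # primaries with pending demands are served fully before residual gets any
  sh2 <- allocate_resources(prof, c("tracking", "meter", "residual"),
                            c(tracking = 0.3, meter = 0.3, residual = 0.9))
  expect_equal(unname(sh2[c("tracking", "meter")]), c(0.3, 0.3))
  expect_equal(unname(sh2[["residual"]]), 0.4)
})

test_that("condition determines the active subtask set", {
  expect_setequal(active_tasks("low"), c("tracking", "residual"))
  expect_setequal(active_tasks("medium"), c("tracking", "residual", "meter"))
  expect_setequal(active_tasks("high"),
                  c("tracking", "residual", "meter", "emergency"))
  log <- simulate_session(task_config("low", rng_seed = 11),
                          operator_profile())
  expect_identical(nrow(log$meter_events), 0L)
  expect_identical(nrow(log$emergency_events), 0L)
})

test_that("simulation is deterministic in the seed and invariants hold", {
  tc <- task_config("high", rng_seed = 99)
  op <- operator_profile()
  l1 <- simulate_session(tc, op)
  l2 <- simulate_session(tc, op)
  expect_identical(l1, l2)
  # all event times within the run, distances nonnegative
  expect_true(all(l1$tracking_samples$time_s >= 0 &
                    l1$tracking_samples$time_s <= tc$duration_s))
  expect_true(all(l1$tracking_samples$distance_mm >= 0))
  ee <- l1$emergency_events
  expect_true(all(ee$removal_s - ee$onset_s <= tc$emergency_window_s + 1e-9))
  ans <- !is.na(ee$response_s)
  expect_true(all(ee$response_s[ans] >= ee$onset_s[ans]))
  expect_true(all(ee$response_s[ans] - ee$onset_s[ans] <=
                    tc$emergency_window_s + 1e-9))
  # inter-onset gap at least the configured gap
  if (nrow(ee) > 1)
    expect_true(all(diff(ee$onset_s) >= tc$emergency_gap_s - 1e-9))
  # answered meter events respond after their warning onset
  me <- l1$meter_events
  mans <- !is.na(me$response_s)
  expect_true(all(me$response_s[mans] >= me$warning_onset_s[mans]))
})

test_that("noiseless tracking from the fixed point stays at zero", {
  tc <- task_config("low", rng_seed = 3)
  op <- operator_profile(tracking_noise_sd = 0)
  log <- simulate_session(tc, op)
  expect_true(all(log$tracking_samples$distance_mm == 0))
  expect_equal(score_performance(log, tc)$n_alarms, 0)
})

test_that("scoring matches hand-computed values on constructed logs", {
  # constant 10 mm never crosses the 30-mm threshold
  tr <- data.frame(time_s = seq(0, 179.95, by = 0.05), distance_mm = 10)
  log <- manual_log("low", tr)
  tc <- task_config("low")
  p <- score_performance(log, tc)
  expect_equal(p$avg_distance_mm, 10)
  expect_equal(p$n_alarms, 0)
  expect_true(is.na(p$meter_rt_s) && is.na(p$emergency_rt_s))

  # one contiguous 5-s excursion at 35 mm -> exactly 1 onset at 1-Hz checks
  tr2 <- tr
  tr2$distance_mm[tr2$time_s >= 50 & tr2$time_s < 55] <- 35
  tc_onset <- task_config("low", alarm_mode = "onset")
  expect_equal(score_performance(manual_log("low", tr2), tc_onset)$n_alarms, 1)
  # per-check mode counts each of the 5 checks inside the excursion
  expect_equal(score_performance(manual_log("low", tr2), tc)$n_alarms, 5)

  # meter metrics: 4 warnings, 3 answered correctly at +2, +3, +4 s
  me <- data.frame(warning_onset_s = c(10, 40, 70, 100),
                   response_s = c(12, 43, 74, NA),
                   correct = c(TRUE, TRUE, TRUE, FALSE),
                   end_s = c(12, 43, 74, 103), meter = 1:4)
  pm <- score_performance(manual_log("medium", tr, meter_events = me),
                          task_config("medium"))
  expect_equal(pm$meter_rt_s, 3.0)
  expect_equal(pm$meter_accuracy_pct, 75.0)

  # empty tracking is an undefined-metric error
  expect_error(score_performance(
    manual_log("low", data.frame(time_s = numeric(0),
                                 distance_mm = numeric(0))), tc),
    "empty tracking")
})

test_that("performance 'none' pattern matches the condition", {
  op <- operator_profile()
  for (cond in c("low", "medium", "high")) {
    tc <- task_config(cond, rng_seed = 5)
    p <- score_performance(simulate_session(tc, op), tc)
    expect_identical(is.na(p$meter_rt_s), cond == "low")
    expect_identical(is.na(p$meter_accuracy_pct), cond == "low")
    expect_identical(is.na(p$emergency_rt_s), cond != "high")
    expect_identical(is.na(p$emergency_accuracy_pct), cond != "high")
  }
})

test_that("mean performance degrades monotonically with load", {
  # statistical property over seeded replicates: distance and alarms
  # nondecreasing, numeral responses nonincreasing from low to high
  op <- operator_profile()
  n_rep <- 60
  means <- sapply(c("low", "medium", "high"), function(cond) {
    out <- vapply(seq_len(n_rep), function(i) {
      tc <- task_config(cond, rng_seed = 1000 + i)
      p <- score_performance(simulate_session(tc, op), tc)
      c(p$avg_distance_mm, p$n_alarms, p$n_numeral_responses)
    }, numeric(3))
    rowMeans(out)
  })
  expect_true(means[1, "low"] < means[1, "medium"])
  expect_true(means[1, "medium"] < means[1, "high"])
  expect_true(means[2, "low"] < means[2, "medium"])
  expect_true(means[2, "medium"] < means[2, "high"])
  expect_true(means[3, "low"] > means[3, "medium"])
  expect_true(means[3, "medium"] > means[3, "high"])
})

test_that("alarm count rises with tracking noise", {
  op_lo <- operator_profile(tracking_noise_sd = 14)
  op_hi <- operator_profile(tracking_noise_sd = 24)
  alarms <- function(op) mean(vapply(1:60, function(i) {
    tc <- task_config("low", rng_seed = 2000 + i)
    score_performance(simulate_session(tc, op), tc)$n_alarms
  }, numeric(1)))
  expect_lt(alarms(op_lo), alarms(op_hi))
})

test_that("configuration errors are caught", {
  expect_error(task_config("low", tick_hz = 0), "tick_hz")
  expect_error(task_config("low", meter_speeds = c(9, 9, 15, 18)), "distinct")
  expect_error(operator_profile(capacity = -1), "capacity")
  expect_error(operator_profile(
    priority_order = c("residual", "meter", "emergency", "tracking")),
    "ranked last")
})
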