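# Discrete-time simulator of the four-subtask flight multitasking paradigm:
# compensatory tracking, meter monitoring, emergency (red-dot counting), and a
# residual-capacity numeral task, driven by a limited-capacity operator model.

TASKS <- c("tracking", "meter", "emergency", "residual")

#' Task configuration for one multitasking run
#'
#' The three load conditions differ only in which subtasks are active:
#' low = tracking + residual capacity, medium adds the four meters,
#' high adds the emergency (red-dot) task.
#'
#' @param condition `"low"`, `"medium"` or `"high"`.
#' @param duration_s run length in seconds.
#' @param tick_hz simulation step rate for the tracking process.
#' @param alarm_threshold_mm tracking distance above which an alarm is scored.
#' @param alarm_check_hz rate of the alarm check grid.
#' @param alarm_mode `"per_check"` (default) counts every check above
#'   threshold; `"onset"` counts upward threshold crossings on the check grid.
#'   The default is per-check: an onset count saturates near 90 per 180 s and
#'   is non-monotone in tracking noise once the error level and its
#'   autocorrelation move together, whereas the per-check count is monotone
#'   and matches the magnitude of published alarm counts.
#' @param dot_count_range integer range (inclusive) for the number of red dots.
#' @param emergency_window_s seconds after which unanswered dots disappear.
#' @param emergency_gap_s gap between dot removal and the next onset.
#' @param first_emergency_s onset time of the first emergency.
#' @param meter_count number of dashboards.
#' @param meter_speeds pointer speeds, degrees/s, one per meter, distinct.
#' @param warning_arc_deg angular extent of each red warning area.
#' @param warning_arc_start_deg angle at which each warning area begins.
#' @param rng_seed integer root seed for the run.
#' @return object of class `task_config`.
#' @export
task_config <- function(condition = c("low", "medium", "high"),
                        duration_s = 180,
                        tick_hz = 20,
                        alarm_threshold_mm = 30,
                        alarm_check_hz = 1,
                        alarm_mode = c("per_check", "onset"),
                        dot_count_range = c(10L, 20L),
                        emergency_window_s = 30,
                        emergency_gap_s = 30,
                        first_emergency_s = 10,
                        meter_count = 4L,
                        meter_speeds = c(9, 12, 15, 18),
                        warning_arc_deg = 30,
                        warning_arc_start_deg = c(120, 150, 180, 210),
                        rng_seed = 1L) {
  condition <- match.arg(condition)
  alarm_mode <- match.arg(alarm_mode)
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (tick_hz <= 0) stop("tick_hz must be > 0 (configuration error)")
  if (length(dot_count_range) != 2L || dot_count_range[1] > dot_count_range[2])
    stop("dot_count_range must be an increasing integer pair")
  if (length(meter_speeds) != meter_count || any(meter_speeds <= 0) ||
      anyDuplicated(meter_speeds))
    stop("meter_speeds must be ", meter_count, " distinct positive values")
  if (length(warning_arc_start_deg) != meter_count)
    stop("need one warning_arc_start_deg per meter")
  structure(list(
    condition = condition, duration_s = duration_s, tick_hz = tick_hz,
    alarm_threshold_mm = alarm_threshold_mm, alarm_check_hz = alarm_check_hz,
    alarm_mode = alarm_mode, dot_count_range = as.integer(dot_count_range),
    emergency_window_s = emergency_window_s, emergency_gap_s = emergency_gap_s,
    first_emergency_s = first_emergency_s, meter_count = as.integer(meter_count),
    meter_speeds = meter_speeds, warning_arc_deg = warning_arc_deg,
    warning_arc_start_deg = warning_arc_start_deg,
    rng_seed = as.integer(rng_seed)
  ), class = "task_config")
}

#' Subtasks active under a condition
#' @param condition load condition label.
#' @return character vector of active task names.
#' @export
active_tasks <- function(condition) {
  switch(condition,
    low = c("tracking", "residual"),
    medium = c("tracking", "residual", "meter"),
    high = c("tracking", "residual", "meter", "emergency"),
    stop("unknown condition: ", condition)
  )
}

#' Limited-capacity synthetic operator
#'
#' The operator embodies single-pool resource competition: each subtask
#' requests a share of a fixed capacity, primary tasks are served strictly
#' before the residual-capacity task, and tracking quality degrades in
#' proportion to the share it actually receives. Event-driven subtasks
#' (meters, emergencies) request a small idle share for scanning and a large
#' share while a warning or dot group is pending.
#'
#' @param capacity total resource pool (dimensionless, >= 0).
#' @param priority_order service order over subtasks; the residual-capacity
#'   task must come last.
#' @param tracking_noise_sd diffusion of the tracking error, mm per sqrt(s).
#' @param tracking_gain error-correction rate (1/s) per unit allocated share.
#' @param meter_latency_s,emergency_latency_s,numeral_latency_s mean response
#'   latencies (the numeral latency is the mean at full residual share).
#' @param latency_shift_s named shifts of the response-latency distributions.
#' @param accuracy_probs named per-subtask probability of a correct response.
#' @param demands named requested shares; `meter` and `emergency` carry
#'   `idle`/`pending` pairs, `tracking` and `residual` a single value.
#' @return object of class `operator_profile`.
#' @export
operator_profile <- function(capacity = 1.0,
                             priority_order = c("meter", "emergency",
                                                "tracking", "residual"),
                             tracking_noise_sd = 19,
                             tracking_gain = 0.45,
                             meter_latency_s = 1.2,
                             emergency_latency_s = 18,
                             numeral_latency_s = 0.75,
                             latency_shift_s = c(meter = 0.4, emergency = 4),
                             accuracy_probs = c(meter = 0.9, emergency = 0.9,
                                                numeral = 0.95),
                             demands = list(tracking = 0.55, residual = 0.45,
                                            meter = c(idle = 0.05, pending = 0.8),
                                            emergency = c(idle = 0.05, pending = 0.6))) {
  if (capacity < 0) stop("capacity must be >= 0")
  if (!setequal(priority_order, TASKS)) stop("priority_order must rank all subtasks")
  if (utils::tail(priority_order, 1) != "residual")
    stop("residual-capacity task must be ranked last")
  lat <- c(meter_latency_s, emergency_latency_s, numeral_latency_s)
  if (any(lat <= 0)) stop("latencies must be > 0")
  if (any(accuracy_probs < 0 | accuracy_probs > 1))
    stop("accuracy_probs must lie in [0, 1]")
  structure(list(
    capacity = capacity, priority_order = priority_order,
    tracking_noise_sd = tracking_noise_sd, tracking_gain = tracking_gain,
    meter_latency_s = meter_latency_s, emergency_latency_s = emergency_latency_s,
    numeral_latency_s = numeral_latency_s, latency_shift_s = latency_shift_s,
    accuracy_probs = accuracy_probs, demands = demands
  ), class = "operator_profile")
}

#' Greedy priority allocation of operator resources
#'
#' Fills requested shares in priority order until capacity is exhausted.
#' Primary tasks with pending demands therefore receive their full request
#' before the residual-capacity task receives anything; a lower-priority task
#' may be part-served with whatever remains.
#'
#' @param profile an [operator_profile()].
#' @param active character vector of active task names.
#' @param demands named numeric vector of requested shares for (a subset of)
#'   the active tasks.
#' @return named numeric vector of granted shares for `active` tasks.
#' @export
allocate_resources <- function(profile, active, demands) {
  if (length(active) == 0L) stop("active task set must be non-empty")
  bad <- setdiff(union(active, names(demands)), TASKS)
  if (length(bad)) stop("unknown task identifier: ", paste(bad, collapse = ", "))
  if (length(setdiff(names(demands), active)))
    stop("shares requested for inactive task")
  shares <- stats::setNames(numeric(length(active)), active)
  remaining <- profile$capacity
  for (task in intersect(profile$priority_order, active)) {
    req <- if (task %in% names(demands)) demands[[task]] else 0
    grant <- min(req, remaining)
    shares[[task]] <- grant
    remaining <- remaining - grant
  }
  shares
}

# requested share of an event-driven task given pending state
.demand_of <- function(profile, task, pending) {
  d <- profile$demands[[task]]
  if (length(d) == 1L) return(unname(d))
  unname(if (pending) d[["pending"]] else d[["idle"]])
}

# shifted-exponential response latency, NA if beyond the truncation window
.draw_latency <- function(n, shift, mean_extra, window) {
  lat <- shift + stats::rexp(n, rate = 1 / mean_extra)
  lat[lat > window] <- NA_real_
  lat
}

# Simulate one meter's warning/response renewal cycle over the run.
.simulate_meter <- function(config, profile, speed, arc_start) {
  window <- config$warning_arc_deg / speed
  rise <- arc_start / speed
  t <- 0
  onset <- resp <- numeric(0); corr <- logical(0)
  repeat {
    w_on <- t + rise
    if (w_on >= config$duration_s) break
    lat <- .draw_latency(1, profile$latency_shift_s[["meter"]],
                         profile$meter_latency_s -
                           profile$latency_shift_s[["meter"]], window)
    ok <- if (is.na(lat)) FALSE else stats::runif(1) < profile$accuracy_probs[["meter"]]
    fall <- if (ok) w_on + lat else w_on + window
    onset <- c(onset, w_on)
    resp <- c(resp, if (is.na(lat)) NA_real_ else min(w_on + lat, config$duration_s))
    corr <- c(corr, ok)
    t <- fall
  }
  data.frame(warning_onset_s = onset, response_s = resp, correct = corr,
             end_s = pmin(ifelse(corr, resp, onset + window), config$duration_s))
}

.simulate_meters <- function(config, profile) {
  out <- lapply(seq_len(config$meter_count), function(i) {
    df <- .simulate_meter(config, profile, config$meter_speeds[i],
                          config$warning_arc_start_deg[i])
    if (nrow(df)) df$meter <- i else df$meter <- integer(0)
    df
  })
  df <- do.call(rbind, out)
  df[order(df$warning_onset_s), , drop = FALSE]
}

.simulate_emergencies <- function(config, profile) {
  t <- config$first_emergency_s
  onset <- resp <- numeric(0); corr <- logical(0); dots <- integer(0)
  removal <- numeric(0)
  while (t < config$duration_s) {
    lat <- .draw_latency(1, profile$latency_shift_s[["emergency"]],
                         profile$emergency_latency_s -
                           profile$latency_shift_s[["emergency"]],
                         config$emergency_window_s)
    ok <- if (is.na(lat)) FALSE else
      stats::runif(1) < profile$accuracy_probs[["emergency"]]
    rem <- if (ok) t + lat else t + config$emergency_window_s
    onset <- c(onset, t)
    dots <- c(dots, sample(seq(config$dot_count_range[1],
                               config$dot_count_range[2]), 1))
    resp <- c(resp, if (is.na(lat)) NA_real_ else t + lat)
    corr <- c(corr, ok)
    removal <- c(removal, min(rem, config$duration_s))
    t <- rem + config$emergency_gap_s
  }
  drop <- !is.na(resp) & resp > config$duration_s
  resp[drop] <- NA_real_; corr[drop] <- FALSE
  data.frame(onset_s = onset, dot_count = dots, response_s = resp,
             correct = corr, removal_s = removal)
}

# Piecewise-constant share timeline for tracking and residual, derived from
# the pending intervals of the event-driven primaries.
.share_timeline <- function(config, profile, meter_events, emergency_events) {
  act <- active_tasks(config$condition)
  cuts <- c(0, config$duration_s)
  m_int <- e_int <- NULL
  if ("meter" %in% act && nrow(meter_events)) {
    m_int <- cbind(meter_events$warning_onset_s,
                   pmin(meter_events$end_s, config$duration_s))
    cuts <- c(cuts, m_int)
  }
  if ("emergency" %in% act && nrow(emergency_events)) {
    e_int <- cbind(emergency_events$onset_s,
                   pmin(emergency_events$removal_s, config$duration_s))
    cuts <- c(cuts, e_int)
  }
  cuts <- sort(unique(pmin(pmax(cuts, 0), config$duration_s)))
  t0 <- cuts[-length(cuts)]; t1 <- cuts[-1]
  keep <- t1 > t0
  t0 <- t0[keep]; t1 <- t1[keep]
  mid <- (t0 + t1) / 2
  in_any <- function(ints, x) {
    if (is.null(ints) || !nrow(ints)) return(rep(FALSE, length(x)))
    vapply(x, function(v) any(ints[, 1] <= v & v < ints[, 2]), logical(1))
  }
  m_pend <- in_any(m_int, mid)
  e_pend <- in_any(e_int, mid)
  tr <- res <- numeric(length(mid))
  for (i in seq_along(mid)) {
    demands <- c(tracking = profile$demands$tracking,
                 residual = profile$demands$residual)
    if ("meter" %in% act)
      demands["meter"] <- .demand_of(profile, "meter", m_pend[i])
    if ("emergency" %in% act)
      demands["emergency"] <- .demand_of(profile, "emergency", e_pend[i])
    sh <- allocate_resources(profile, act, demands[act])
    tr[i] <- sh[["tracking"]]; res[i] <- sh[["residual"]]
  }
  data.frame(t0 = t0, t1 = t1, tracking = tr, residual = res)
}

# Ornstein-Uhlenbeck tracking error with piecewise-constant reversion rate,
# Euler-Maruyama at tick_hz; the per-segment recursion runs through
# stats::filter (C loop) for speed.
.simulate_tracking <- function(config, profile, timeline) {
  dt <- 1 / config$tick_hz
  n <- round(config$duration_s * config$tick_hz)
  t <- (seq_len(n) - 1L) * dt
  theta <- profile$tracking_gain *
    timeline$tracking[findInterval(t, timeline$t0)]
  a <- pmax(1 - theta * dt, 0)
  innov <- profile$tracking_noise_sd * sqrt(dt) * stats::rnorm(n)
  e <- numeric(n)
  # segment boundaries where the AR coefficient changes
  seg_start <- c(1L, which(diff(a) != 0) + 1L)
  seg_end <- c(seg_start[-1L] - 1L, n)
  prev <- 0
  for (s in seq_along(seg_start)) {
    idx <- seg_start[s]:seg_end[s]
    x <- stats::filter(innov[idx] + c(a[idx[1]] * prev, numeric(length(idx) - 1L)),
                       a[idx[1]], method = "recursive")
    # filter() computes x_k = a x_{k-1} + u_k with x_0 = 0; seeding the first
    # innovation with a*prev chains segments exactly
    e[idx] <- as.numeric(x)
    prev <- e[idx[length(idx)]]
  }
  data.frame(time_s = t, distance_mm = abs(e))
}

# Residual-capacity numeral stream: service rate = residual share /
# numeral_latency; event completion via unit-exponential hazard accumulation
# over the piecewise-constant share timeline.
.simulate_numerals <- function(config, profile, timeline) {
  rate <- timeline$residual / profile$numeral_latency_s
  seg_len <- timeline$t1 - timeline$t0
  shown <- resp <- numeric(0); corr <- logical(0)
  t_now <- 0
  shown_now <- 0
  seg <- 1L
  H_target <- stats::rexp(1)
  acc <- 0
  while (seg <= nrow(timeline)) {
    seg_end <- timeline$t1[seg]
    r <- rate[seg]
    avail <- (seg_end - t_now) * r
    if (acc + avail >= H_target && r > 0) {
      t_resp <- t_now + (H_target - acc) / r
      ok <- stats::runif(1) < profile$accuracy_probs[["numeral"]]
      shown <- c(shown, shown_now); resp <- c(resp, t_resp); corr <- c(corr, ok)
      if (ok) shown_now <- t_resp  # next numeral appears immediately
      t_now <- t_resp
      acc <- 0
      H_target <- stats::rexp(1)
    } else {
      acc <- acc + avail
      t_now <- seg_end
      seg <- seg + 1L
    }
  }
  data.frame(shown_s = shown, response_s = resp, correct = corr)
}

.alarm_times <- function(samples, config) {
  check_t <- seq(0, config$duration_s - 1e-9, by = 1 / config$alarm_check_hz)
  idx <- findInterval(check_t + 1e-9, samples$time_s)
  idx[idx < 1] <- 1L
  d <- samples$distance_mm[idx]
  above <- d > config$alarm_threshold_mm
  if (config$alarm_mode == "per_check") return(check_t[above])
  onset <- above & !c(FALSE, above[-length(above)])
  check_t[onset]
}

#' Simulate one multitasking session
#'
#' Runs the event-driven subtasks (meters, emergencies), derives the
#' piecewise-constant resource shares granted to tracking and the residual
#' task, then integrates the tracking error (mean-reverting toward zero at
#' rate `tracking_gain * share`, diffusion `tracking_noise_sd`) and the
#' numeral response stream. Identical `(config, profile)` including the seed
#' reproduce the identical log.
#'
#' @param config a [task_config()].
#' @param profile an [operator_profile()].
#' @return object of class `behavior_log`: tracking samples, alarm times and
#'   the per-subtask event tables (empty for subtasks the condition excludes).
#' @export
simulate_session <- function(config, profile) {
  stopifnot(inherits(config, "task_config"), inherits(profile, "operator_profile"))
  act <- active_tasks(config$condition)
  empty_meters <- data.frame(warning_onset_s = numeric(0), response_s = numeric(0),
                             correct = logical(0), end_s = numeric(0),
                             meter = integer(0))
  empty_emerg <- data.frame(onset_s = numeric(0), dot_count = integer(0),
                            response_s = numeric(0), correct = logical(0),
                            removal_s = numeric(0))
  meter_events <- if ("meter" %in% act)
    with_stream(config$rng_seed, "task/meter", .simulate_meters(config, profile))
  else empty_meters
  emergency_events <- if ("emergency" %in% act)
    with_stream(config$rng_seed, "task/emergency",
                .simulate_emergencies(config, profile))
  else empty_emerg
  timeline <- .share_timeline(config, profile, meter_events, emergency_events)
  tracking <- with_stream(config$rng_seed, "task/tracking",
                          .simulate_tracking(config, profile, timeline))
  numerals <- with_stream(config$rng_seed, "task/numeral",
                          .simulate_numerals(config, profile, timeline))
  structure(list(
    condition = config$condition,
    tracking_samples = tracking,
    alarm_events = .alarm_times(tracking, config),
    meter_events = meter_events,
    emergency_events = emergency_events,
    numeral_events = numerals,
    share_timeline = timeline,
    seed = config$rng_seed
  ), class = "behavior_log")
}

#' Score behavioral performance of one session
#'
#' Computes the run-level performance metrics: mean tracking distance, alarm
#' count (checks at `alarm_check_hz`; an alarm is an upward crossing of the
#' threshold in `"onset"` mode, or any above-threshold check in `"per_check"`
#' mode), number of correct numeral responses, and mean response time /
#' percent-correct for the meter and emergency subtasks. Metrics of subtasks
#' the condition excludes are `NA` ("none").
#'
#' @param log a [simulate_session()] result.
#' @param config the matching [task_config()].
#' @return object of class `performance_summary`.
#' @export
score_performance <- function(log, config) {
  stopifnot(inherits(log, "behavior_log"))
  if (!nrow(log$tracking_samples))
    stop("undefined metric: empty tracking_samples")
  act <- active_tasks(log$condition)
  alarms <- .alarm_times(log$tracking_samples, config)
  me <- log$meter_events; ee <- log$emergency_events
  meter_rt <- meter_acc <- emerg_rt <- emerg_acc <- NA_real_
  if ("meter" %in% act && nrow(me)) {
    ans <- !is.na(me$response_s)
    meter_rt <- if (any(ans)) mean(me$response_s[ans] - me$warning_onset_s[ans])
                else NA_real_
    meter_acc <- 100 * sum(me$correct) / nrow(me)
  }
  if ("emergency" %in% act && nrow(ee)) {
    ans <- !is.na(ee$response_s)
    emerg_rt <- if (any(ans)) mean(ee$response_s[ans] - ee$onset_s[ans])
                else NA_real_
    emerg_acc <- 100 * sum(ee$correct) / nrow(ee)
  }
  structure(list(
    condition = log$condition,
    avg_distance_mm = mean(log$tracking_samples$distance_mm),
    n_alarms = length(alarms),
    n_numeral_responses = sum(log$numeral_events$correct),
    meter_rt_s = meter_rt, meter_accuracy_pct = meter_acc,
    emergency_rt_s = emerg_rt, emergency_accuracy_pct = emerg_acc
  ), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Performance (%s load):\n", x$condition))
  cat(sprintf("  avg distance     %6.2f mm\n", x$avg_distance_mm))
  cat(sprintf("  alarms           %6d\n", x$n_alarms))
  cat(sprintf("  numeral responses%6d\n", x$n_numeral_responses))
  fmt <- function(v, unit) if (is.na(v)) "  none" else sprintf("%6.2f %s", v, unit)
  cat("  meter RT        ", fmt(x$meter_rt_s, "s"), "\n")
  cat("  meter accuracy  ", fmt(x$meter_accuracy_pct, "%"), "\n")
  cat("  emergency RT    ", fmt(x$emergency_rt_s, "s"), "\n")
  cat("  emergency acc.  ", fmt(x$emergency_accuracy_pct, "%"), "\n")
  invisible(x)
}
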