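# shared fixture builders (everything is generated in code; no data files)

# behavior log built by hand for scoring tests
manual_log <- function(condition, tracking, meter_events = NULL,
                       emergency_events = NULL, numeral_events = NULL,
                       alarm_events = numeric(0)) {
  structure(list(
    condition = condition,
    tracking_samples = tracking,
    alarm_events = alarm_events,
    meter_events = meter_events %||% data.frame(
      warning_onset_s = numeric(0), response_s = numeric(0),
      correct = logical(0), end_s = numeric(0), meter = integer(0)),
    emergency_events = emergency_events %||% data.frame(
      onset_s = numeric(0), dot_count = integer(0), response_s = numeric(0),
      correct = logical(0), removal_s = numeric(0)),
    numeral_events = numeral_events %||% data.frame(
      shown_s = numeric(0), response_s = numeric(0), correct = logical(0)),
    seed = 0L
  ), class = "behavior_log")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# RR series following a pure sinusoidal tachogram (deterministic)
sinusoid_rr <- function(freq_hz, amp_ms = 20, base_ms = 800,
                        duration_s = 180) {
  t <- 0; rr <- numeric(0)
  while (t < duration_s * 1000) {
    v <- base_ms + amp_ms * sin(2 * pi * freq_hz * t / 1000)
    rr <- c(rr, v)
    t <- t + v
  }
  rr_series(rr)
}

# strict-ranking pairwise choices: dimension earlier in `ranking` beats later
ranked_choices <- function(ranking = tlx_dimensions()) {
  pairs <- tlx_pairs()
  pairs$winner <- vapply(seq_len(nrow(pairs)), function(j) {
    if (match(pairs$a[j], ranking) < match(pairs$b[j], ranking))
      pairs$a[j] else pairs$b[j]
  }, character(1))
  pairs
}

# random valid pairwise choice set
random_choices <- function() {
  pairs <- tlx_pairs()
  pick <- stats::runif(nrow(pairs)) < 0.5
  pairs$winner <- ifelse(pick, pairs$a, pairs$b)
  pairs
}

# small repeated-measures table from a matrix (rows = subjects)
rm_table <- function(m, conditions = paste0("c", seq_len(ncol(m)))) {
  data.frame(subject = rep(sprintf("s%02d", seq_len(nrow(m))), ncol(m)),
             condition = rep(conditions, each = nrow(m)),
             value = as.vector(m))
}

# independent RM-ANOVA oracle: additive two-way fit via lm()
rm_anova_oracle <- function(table) {
  fit <- stats::lm(value ~ factor(subject) + factor(condition), data = table)
  an <- stats::anova(fit)
  f <- an["factor(condition)", "F value"]
  p <- an["factor(condition)", "Pr(>F)"]
  list(F = f, p = p)
}

fast_study_config <- function(seed = 1L, n_subjects = 8L, ...) {
  study_config(seed = seed, n_subjects = n_subjects, ...)
}
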