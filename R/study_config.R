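# Study-level configuration: the stated world of the synthetic experiment.
# Defaults mirror the protocol (26 subjects, three 180-s counterbalanced
# runs with 1-min rests) and couple load to physiology with fixed slopes.

#' Configuration of a full synthetic study
#'
#' @param n_subjects number of within-subject participants.
#' @param conditions the load conditions, in increasing-load order.
#' @param run_duration_s task duration per run.
#' @param rest_s rest before/after each task block (brackets the fNIRS run).
#' @param seed root seed; every stage stream derives from it.
#' @param task base [task_config()] arguments (condition and seed are filled
#'   per run).
#' @param operator base [operator_profile()] arguments.
#' @param operator_sd between-subject SDs: `tracking_noise_sd` (mm/sqrt(s)).
#' @param autonomic base [autonomic_params()] arguments.
#' @param hr_between_sd_bpm between-subject SD of baseline heart rate.
#' @param hr_run_jitter_bpm within-subject per-run heart-rate jitter.
#' @param tlx list with per-dimension `base` and load `slope` vectors (0-100
#'   scale), between-subject intercept SD `subject_sd` and rating noise SD
#'   `noise_sd`; mental and temporal demand carry the largest slopes.
#' @param beta list: `base` (uM at low load), `slope` (uM per load step),
#'   `subject_sd`, `channel_sd`, `run_sd`.
#' @param noise [noise_model()] arguments for the fNIRS noise.
#' @param optics [optics_config()] arguments.
#' @param glm list: `drift_order`, `precolor`.
#' @param fnirs_noise_salt string mixed into the fNIRS noise seed stream
#'   only; changing it must leave every other stage bit-identical (stream
#'   isolation).
#' @return object of class `study_config`.
#' @export
study_config <- function(n_subjects = 26L,
                         conditions = c("low", "medium", "high"),
                         run_duration_s = 180,
                         rest_s = 60,
                         seed = 1L,
                         task = list(),
                         operator = list(),
                         operator_sd = list(tracking_noise_sd = 2),
                         autonomic = list(),
                         hr_between_sd_bpm = 9,
                         hr_run_jitter_bpm = 0.8,
                         tlx = list(
                           base = c(md = 35, pd = 20, td = 30,
                                    op = 40, ef = 45, fr = 25),
                           slope = c(md = 12, pd = 2, td = 14,
                                     op = 5, ef = 4, fr = 3),
                           subject_sd = 8, noise_sd = 6),
                         beta = list(base = 0.1, slope = 0.25,
                                     subject_sd = 0.1, channel_sd = 0.05,
                                     run_sd = 0.03),
                         noise = list(),
                         optics = list(),
                         glm = list(drift_order = 1L, precolor = TRUE),
                         fnirs_noise_salt = "") {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  stopifnot(all(conditions %in% c("low", "medium", "high")))
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 run_duration_s = run_duration_s, rest_s = rest_s,
                 seed = as.integer(seed), task = task, operator = operator,
                 operator_sd = operator_sd, autonomic = autonomic,
                 hr_between_sd_bpm = hr_between_sd_bpm,
                 hr_run_jitter_bpm = hr_run_jitter_bpm,
                 tlx = tlx, beta = beta, noise = noise, optics = optics,
                 glm = glm, fnirs_noise_salt = fnirs_noise_salt),
            class = "study_config")
}

#' Zero out every load effect (type-I calibration world)
#'
#' Returns a copy of the config in which no measure depends on condition:
#' task demands and dynamics identical across conditions is not possible
#' (conditions differ by construction), so the null world instead makes all
#' conditions low-load replicas with zero physiological and subjective
#' slopes.
#'
#' @param config a [study_config()].
#' @return modified config with attribute `null_world = TRUE`.
#' @export
null_effects <- function(config) {
  config$tlx$slope[] <- 0
  config$beta$slope <- 0
  config$autonomic$load_hr_slope <- 0
  config$force_condition <- "low"
  attr(config, "null_world") <- TRUE
  config
}

#' Counterbalanced condition orders (Latin-square rotation)
#'
#' Subject s receives rotation `s mod 3` of (low, medium, high), so each
#' condition occupies each ordinal position `n/3 +- 1` times.
#'
#' @param n_subjects number of subjects.
#' @param conditions condition labels.
#' @return matrix `n_subjects x k` of condition labels in presentation order.
#' @export
counterbalance_orders <- function(n_subjects, conditions = c("low", "medium", "high")) {
  k <- length(conditions)
  t(vapply(seq_len(n_subjects), function(s) {
    rot <- (s - 1L) %% k
    conditions[((seq_len(k) - 1L + rot) %% k) + 1L]
  }, character(k)))
}
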