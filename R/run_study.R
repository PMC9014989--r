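# End-to-end synthetic study: subject parameter draws, per-run simulation and
# synthesis, per-run analysis, and the study-level statistics. Every stage
# draws from its own seed stream derived from the root seed, so perturbing
# one stage leaves all others bit-identical.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw per-subject parameters for a study
#'
#' Subject-level heterogeneity: operator tracking noise, baseline heart rate,
#' NASA-TLX intercepts and dimension saliences, fNIRS activation baselines,
#' and the counterbalanced condition order.
#'
#' @param config a [study_config()].
#' @return data.frame of per-subject parameters (one row per subject) with
#'   the order matrix in attribute `orders`.
#' @export
draw_subjects <- function(config) {
  n <- config$n_subjects
  base_auto <- do.call(autonomic_params, config$autonomic)
  base_op <- do.call(operator_profile, config$operator)
  subj <- with_stream(config$seed, "study/subjects", {
    data.frame(
      subject = sprintf("s%02d", seq_len(n)),
      tracking_noise_sd = pmax(
        stats::rnorm(n, base_op$tracking_noise_sd,
                     config$operator_sd$tracking_noise_sd %||% 0), 1),
      base_hr_bpm = pmax(stats::rnorm(n, 60000 / base_auto$mean_rr_ms,
                                      config$hr_between_sd_bpm), 40),
      tlx_intercept = stats::rnorm(n, 0, config$tlx$subject_sd),
      beta_base = stats::rnorm(n, config$beta$base, config$beta$subject_sd)
    )
  })
  attr(subj, "orders") <- counterbalance_orders(n, config$conditions)
  subj
}

.load_step <- function(condition) {
  c(low = 0L, medium = 1L, high = 2L)[[condition]]
}

# --- stage: behavior ---------------------------------------------------------

#' Simulate the behavioral runs of a study
#' @param config a [study_config()].
#' @param subjects a [draw_subjects()] table.
#' @return data.frame of performance summaries, one row per subject x
#'   condition; behavior logs attached as attribute `logs` (a named list).
#' @export
study_behavior <- function(config, subjects) {
  rows <- list(); logs <- list()
  for (i in seq_len(nrow(subjects))) {
    for (cond in config$conditions) {
      sim_cond <- config$force_condition %||% cond
      tc_args <- config$task
      tc_args$condition <- sim_cond
      tc_args$duration_s <- config$run_duration_s
      tc_args$rng_seed <- child_seed(config$seed,
                                     sprintf("behavior/%s/%s",
                                             subjects$subject[i], cond))
      tc <- do.call(task_config, tc_args)
      op_args <- config$operator
      op_args$tracking_noise_sd <- subjects$tracking_noise_sd[i]
      op <- do.call(operator_profile, op_args)
      log <- simulate_session(tc, op)
      perf <- score_performance(log, tc)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects$subject[i], condition = cond,
        avg_distance_mm = perf$avg_distance_mm, n_alarms = perf$n_alarms,
        n_numeral_responses = perf$n_numeral_responses,
        meter_rt_s = perf$meter_rt_s,
        meter_accuracy_pct = perf$meter_accuracy_pct,
        emergency_rt_s = perf$emergency_rt_s,
        emergency_accuracy_pct = perf$emergency_accuracy_pct)
      logs[[paste(subjects$subject[i], cond, sep = "/")]] <- log
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "logs") <- logs
  out
}

# --- stage: NASA-TLX ---------------------------------------------------------

#' Synthesize and score NASA-TLX responses
#'
#' Per-dimension latent workload is an affine function of load step with a
#' subject random intercept and rating noise; pairwise-comparison winners
#' follow each subject's dimension saliences (latent importance plus Gumbel
#' noise, i.e. Bradley-Terry-style choices). Scores are weighted as in
#' [weighted_score()].
#'
#' @param config a [study_config()].
#' @param subjects a [draw_subjects()] table.
#' @return data.frame: subject, condition, six ratings, overall score;
#'   per-subject weights attached as attribute `weights`.
#' @export
study_tlx <- function(config, subjects) {
  dims <- tlx_dimensions()
  base <- config$tlx$base[dims]; slope <- config$tlx$slope[dims]
  rows <- list(); wts <- list()
  pairs <- tlx_pairs()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject[i]
    # one pairwise-comparison set per subject
    choices <- with_stream(config$seed, sprintf("tlx-pairs/%s", sid), {
      salience <- base + slope * 1 + stats::rnorm(length(dims), 0, 5)
      names(salience) <- dims
      winner <- vapply(seq_len(nrow(pairs)), function(j) {
        a <- pairs$a[j]; b <- pairs$b[j]
        ua <- salience[[a]] - log(-log(stats::runif(1)))
        ub <- salience[[b]] - log(-log(stats::runif(1)))
        if (ua >= ub) a else b
      }, character(1))
      cbind(pairs, winner = winner)
    })
    w <- compute_weights(choices)
    wts[[sid]] <- w
    for (cond in config$conditions) {
      step <- .load_step(cond)
      rating <- with_stream(config$seed, sprintf("tlx/%s/%s", sid, cond), {
        r <- base + slope * step + subjects$tlx_intercept[i] +
          stats::rnorm(length(dims), 0, config$tlx$noise_sd)
        pmin(pmax(r, 0), 100)
      })
      names(rating) <- dims
      sc <- weighted_score(rating, w)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, condition = cond, t(rating),
        tlx_total = sc$overall_exact)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "weights") <- wts
  out
}

# --- stage: physiology -------------------------------------------------------

#' Synthesize and analyze cardiac data for a study
#' @param config a [study_config()].
#' @param subjects a [draw_subjects()] table.
#' @return data.frame of HRV features per subject x condition; the RR series
#'   attached as attribute `rr` (named list).
#' @export
study_cardiac <- function(config, subjects) {
  rows <- list(); series <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject[i]
    for (cond in config$conditions) {
      step <- .load_step(cond)
      jitter <- with_stream(config$seed, sprintf("hr-jitter/%s/%s", sid, cond),
                            stats::rnorm(1, 0, config$hr_run_jitter_bpm))
      auto_args <- config$autonomic
      auto_args$mean_rr_ms <- 60000 / (subjects$base_hr_bpm[i] + jitter)
      ap <- do.call(autonomic_params, auto_args)
      rr <- synthesize_rr(ap, step, duration_s = config$run_duration_s,
                          seed = child_seed(config$seed,
                                            sprintf("rr/%s/%s", sid, cond)),
                          condition = cond)
      feats <- hrv_features(rr)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject = sid, condition = cond), feats)
      series[[paste(sid, cond, sep = "/")]] <- rr
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rr") <- series
  out
}

#' Synthesize and analyze fNIRS data for a study
#'
#' For every run: ground-truth per-channel activation (subject baseline +
#' load slope + channel scatter), forward HRF synthesis over a
#' rest-task-rest window, structured noise, forward MBLL to optical density,
#' then the analysis chain (MBLL inversion, wavelet denoising, precolored
#' GLM). The design and its precoloring context are computed once and shared.
#'
#' @param config a [study_config()].
#' @param subjects a [draw_subjects()] table.
#' @return data.frame per subject x condition with `mean_beta` and the mean
#'   true amplitude `mean_beta_true`; per-run activation results attached as
#'   attribute `fits`.
#' @export
study_fnirs <- function(config, subjects) {
  optics <- do.call(optics_config, config$optics)
  nm <- do.call(noise_model, config$noise)
  fs <- optics$sampling_hz
  run_s <- config$run_duration_s + 2 * config$rest_s
  n <- round(run_s * fs)
  design <- build_design(onsets_s = config$rest_s,
                         durations_s = config$run_duration_s,
                         fs = fs, n_samples = n,
                         drift_order = config$glm$drift_order %||% 1L)
  ctx <- if (isTRUE(config$glm$precolor %||% TRUE)) prepare_precolor(design)
         else NULL
  rows <- list(); fits <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject[i]
    for (cond in config$conditions) {
      step <- .load_step(cond)
      beta_true <- with_stream(config$seed,
                               sprintf("beta-true/%s/%s", sid, cond), {
        subjects$beta_base[i] + config$beta$slope * step +
          stats::rnorm(1, 0, config$beta$run_sd) +
          stats::rnorm(optics$n_channels, 0, config$beta$channel_sd)
      })
      hemo <- synthesize_activation(beta_true, onsets_s = config$rest_s,
                                    durations_s = config$run_duration_s,
                                    duration_s = run_s, fs = fs,
                                    condition = cond)
      noisy <- add_noise(hemo, nm,
                         seed = child_seed(config$seed,
                                           sprintf("fnirs-noise%s/%s/%s",
                                                   config$fnirs_noise_salt %||% "",
                                                   sid, cond)))
      od <- mbll_forward(noisy, optics)
      hb <- mbll_invert(od, optics)
      hb <- wavelet_denoise(hb)
      fit <- fit_glm(hb, design, precolor = isTRUE(config$glm$precolor %||% TRUE),
                     context = ctx)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, condition = cond, mean_beta = fit$mean_beta,
        mean_beta_true = mean(beta_true))
      fits[[paste(sid, cond, sep = "/")]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "design") <- design
  out
}

# --- stage: statistics -------------------------------------------------------

STUDY_MEASURES <- c("tlx_total", "avg_distance_mm", "n_alarms",
                    "n_numeral_responses", "mean_hr_bpm", "sdnn_ms",
                    "rmssd_ms", "lf_hf_ratio", "mean_beta")

MEASURE_FAMILY <- c(tlx_total = "subjective", avg_distance_mm = "performance",
                    n_alarms = "performance", n_numeral_responses = "performance",
                    mean_hr_bpm = "ecg", sdnn_ms = "ecg", rmssd_ms = "ecg",
                    lf_hf_ratio = "ecg", mean_beta = "fnirs")

#' Study-level statistics over the assembled measures
#'
#' One-way repeated-measures ANOVA and Bonferroni post-hocs per measure, and
#' within-condition Pearson correlations for every measure pair crossing
#' family boundaries (pairs internal to the ECG family or to the performance
#' family are excluded).
#'
#' @param measures wide data.frame: subject, condition, one column per
#'   measure in `STUDY_MEASURES`.
#' @param alpha significance level.
#' @return list with `anova`, `pairwise`, `correlations` data.frames.
#' @export
study_statistics <- function(measures, alpha = 0.05) {
  anova_rows <- list(); pw_rows <- list()
  for (m in STUDY_MEASURES) {
    tab <- data.frame(subject = measures$subject,
                      condition = measures$condition,
                      value = measures[[m]])
    a <- rm_anova_oneway(tab)
    anova_rows[[m]] <- data.frame(measure = m, F = a$F, df_num = a$df_num,
                                  df_den = a$df_den, p = a$p)
    pw <- bonferroni_pairwise(tab, alpha = alpha)
    pw_rows[[m]] <- cbind(measure = m, pw$pairs,
                          threshold = pw$threshold,
                          threshold_display = pw$threshold_display)
  }
  corr_rows <- list()
  pairs <- utils::combn(STUDY_MEASURES, 2)
  for (cond in unique(measures$condition)) {
    sub <- measures[measures$condition == cond, ]
    sub <- sub[order(sub$subject), ]
    for (j in seq_len(ncol(pairs))) {
      m1 <- pairs[1, j]; m2 <- pairs[2, j]
      fam <- MEASURE_FAMILY[c(m1, m2)]
      if (fam[1] == fam[2] && fam[1] %in% c("ecg", "performance")) next
      x <- sub[[m1]]; y <- sub[[m2]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- pearson_corr(x[ok], y[ok])
      corr_rows[[length(corr_rows) + 1L]] <- data.frame(
        condition = cond, measure1 = m1, measure2 = m2,
        r = ct$r, n = ct$n, p = ct$p)
    }
  }
  list(anova = do.call(rbind, c(anova_rows, make.row.names = FALSE)),
       pairwise = do.call(rbind, c(pw_rows, make.row.names = FALSE)),
       correlations = do.call(rbind, corr_rows))
}

#' Run a full synthetic study
#'
#' Simulates behavior, NASA-TLX, cardiac and fNIRS data for every subject and
#' condition, analyzes each modality, assembles the subject-by-condition
#' measures table, and computes the ANOVA/post-hoc/correlation family. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [study_config()].
#' @param keep_raw keep per-run logs, RR series and GLM fits as attributes
#'   (memory-heavy for many subjects).
#' @return object of class `study_results`: `subjects`, `measures` (wide),
#'   `tlx`, `performance`, `hrv`, `fnirs`, `anova`, `pairwise`,
#'   `correlations`, `config`.
#' @export
run_study <- function(config = study_config(), keep_raw = FALSE) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  subjects <- stage("subjects", draw_subjects(config))
  perf <- stage("behavior", study_behavior(config, subjects))
  tlx <- stage("tlx", study_tlx(config, subjects))
  hrv <- stage("cardiac", study_cardiac(config, subjects))
  fnirs <- stage("fnirs", study_fnirs(config, subjects))
  key <- function(df) paste(df$subject, df$condition)
  measures <- data.frame(subject = perf$subject, condition = perf$condition,
                         tlx_total = tlx$tlx_total[match(key(perf), key(tlx))],
                         avg_distance_mm = perf$avg_distance_mm,
                         n_alarms = perf$n_alarms,
                         n_numeral_responses = perf$n_numeral_responses,
                         mean_hr_bpm = hrv$mean_hr_bpm[match(key(perf), key(hrv))],
                         sdnn_ms = hrv$sdnn_ms[match(key(perf), key(hrv))],
                         rmssd_ms = hrv$rmssd_ms[match(key(perf), key(hrv))],
                         lf_hf_ratio = hrv$lf_hf_ratio[match(key(perf), key(hrv))],
                         mean_beta = fnirs$mean_beta[match(key(perf), key(fnirs))])
  stats_out <- stage("statistics", study_statistics(measures))
  out <- list(subjects = subjects, measures = measures, tlx = tlx,
              performance = perf, hrv = hrv,
              fnirs = fnirs[, c("subject", "condition", "mean_beta",
                                "mean_beta_true")],
              anova = stats_out$anova, pairwise = stats_out$pairwise,
              correlations = stats_out$correlations, config = config)
  if (keep_raw) {
    out$raw <- list(logs = attr(perf, "logs"), rr = attr(hrv, "rr"),
                    fits = attr(fnirs, "fits"))
  }
  structure(out, class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("Synthetic workload study: %d subjects x %d conditions (seed %d)\n",
              x$config$n_subjects, length(x$config$conditions), x$config$seed))
  agg <- stats::aggregate(cbind(tlx_total, avg_distance_mm, n_numeral_responses,
                                mean_hr_bpm, mean_beta) ~ condition,
                          data = x$measures, FUN = mean)
  agg <- agg[match(x$config$conditions, agg$condition), ]
  print(agg, row.names = FALSE, digits = 4)
  cat("\nRepeated-measures ANOVA:\n")
  print(transform(x$anova, F = round(F, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}
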