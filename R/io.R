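# Plain-text interchange formats: behavior logs as JSON Lines + tracking CSV,
# RR series as two-column CSV, fNIRS series as wide CSV with a JSON optics
# sidecar. All numeric round trips are exact to double precision (%.17g).

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

.write_table_exact <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) .fmt_num(col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
}

#' Write a behavior log as JSON Lines plus a tracking CSV
#'
#' Events go to `<path>` one JSON object per line (`{"stream": ..., "t": ...,
#' ...}`, with a header line carrying condition and seed); the dense tracking
#' samples go to `<path_tracking>` as CSV `time_s,distance_mm`.
#'
#' @param log a [simulate_session()] result.
#' @param path JSONL destination.
#' @param path_tracking CSV destination; default replaces the extension.
#' @return invisibly, the two paths.
#' @export
write_behavior_log <- function(log, path,
                               path_tracking = sub("\\.jsonl?$", "", path)) {
  stopifnot(inherits(log, "behavior_log"))
  if (path_tracking == path) path_tracking <- paste0(path, ".tracking")
  path_tracking <- paste0(path_tracking, "_tracking.csv")
  lines <- c(jsonlite::toJSON(list(stream = "header", condition = log$condition,
                                   seed = log$seed), auto_unbox = TRUE))
  add <- function(stream, df, tcol) {
    if (!nrow(df)) return(invisible())
    for (i in seq_len(nrow(df))) {
      rec <- c(list(stream = stream, t = df[[tcol]][i]),
               as.list(df[i, setdiff(names(df), tcol), drop = FALSE]))
      lines <<- c(lines, jsonlite::toJSON(rec, auto_unbox = TRUE,
                                          digits = NA, na = "null"))
    }
  }
  add("alarm", data.frame(t_s = log$alarm_events), "t_s")
  add("meter", log$meter_events, "warning_onset_s")
  add("emergency", log$emergency_events, "onset_s")
  add("numeral", log$numeral_events, "shown_s")
  writeLines(lines, path)
  .write_table_exact(log$tracking_samples, path_tracking)
  invisible(c(path, path_tracking))
}

#' Write / read an RR series as CSV
#'
#' Two columns: `beat_time_ms` (cumulative) and `rr_ms`.
#'
#' @param rr an [rr_series()].
#' @param path file path.
#' @return `write_rr_csv`: the path, invisibly. `read_rr_csv`: an
#'   [rr_series()].
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  .write_table_exact(data.frame(beat_time_ms = rr$t_ms, rr_ms = rr$rr_ms),
                     path)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("beat_time_ms", "rr_ms") %in% names(df)))
    stop("malformed RR CSV: need beat_time_ms, rr_ms")
  rr_series(df$rr_ms)
}

#' Write / read fNIRS series as wide CSV with a JSON optics sidecar
#'
#' Hemoglobin series are written as `t_s, ch<k>_hbo, ch<k>_hbr`; optical
#' density series as `t_s, ch<k>_od<wavelength>`. The sidecar
#' (`<path>.json`) carries the series type, sampling rate, wavelengths and
#' optics metadata; the round trip reproduces samples to double precision
#' and metadata exactly.
#'
#' @param x a [hemoglobin_series()] or `od_series`.
#' @param path CSV destination; sidecar written to `paste0(path, ".json")`.
#' @param optics an [optics_config()] for the sidecar.
#' @return `write_fnirs_csv`: the path, invisibly; `read_fnirs_csv`: the
#'   series with the optics metadata in attribute `optics_meta`.
#' @export
write_fnirs_csv <- function(x, path, optics) {
  stopifnot(inherits(optics, "optics_config"))
  if (inherits(x, "hemoglobin_series")) {
    nch <- nrow(x$delta_hbo)
    df <- data.frame(t_s = x$t_s)
    for (ch in seq_len(nch)) {
      df[[sprintf("ch%d_hbo", ch)]] <- x$delta_hbo[ch, ]
      df[[sprintf("ch%d_hbr", ch)]] <- x$delta_hbr[ch, ]
    }
    type <- "hemoglobin"
  } else if (inherits(x, "od_series")) {
    nch <- dim(x$delta_od)[1]
    df <- data.frame(t_s = x$t_s)
    for (ch in seq_len(nch)) {
      for (wi in 1:2) {
        df[[sprintf("ch%d_od%g", ch, x$wavelengths_nm[wi])]] <-
          x$delta_od[ch, wi, ]
      }
    }
    type <- "od"
  } else stop("x must be a hemoglobin_series or od_series")
  .write_table_exact(df, path)
  meta <- list(type = type, fs = x$fs, n_channels = nch,
               condition = x$condition,
               wavelengths_nm = optics$wavelengths_nm,
               source_detector_distance_cm = optics$source_detector_distance_cm,
               dpf = optics$dpf,
               extinction_coeffs = unname(apply(optics$extinction_coeffs, 1,
                                                as.list, simplify = FALSE)))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_fnirs_csv
#' @export
read_fnirs_csv <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("parse error: missing sidecar ", sidecar)
  meta <- jsonlite::fromJSON(readLines(sidecar), simplifyVector = TRUE)
  for (field in c("type", "fs", "n_channels", "wavelengths_nm")) {
    if (is.null(meta[[field]]))
      stop("parse error: sidecar missing field '", field, "'")
  }
  df <- utils::read.csv(path)
  nch <- meta$n_channels
  cond <- if (is.null(meta$condition)) NULL else meta$condition
  if (meta$type == "hemoglobin") {
    hbo <- t(as.matrix(df[sprintf("ch%d_hbo", seq_len(nch))]))
    hbr <- t(as.matrix(df[sprintf("ch%d_hbr", seq_len(nch))]))
    out <- hemoglobin_series(df$t_s, hbo, hbr, meta$fs, condition = cond)
  } else if (meta$type == "od") {
    ns <- nrow(df)
    od <- array(NA_real_, c(nch, 2L, ns),
                dimnames = list(NULL, meta$wavelengths_nm, NULL))
    for (ch in seq_len(nch)) {
      for (wi in 1:2) {
        col <- sprintf("ch%d_od%g", ch, meta$wavelengths_nm[wi])
        if (!col %in% names(df)) stop("parse error: missing column ", col)
        od[ch, wi, ] <- df[[col]]
      }
    }
    out <- structure(list(t_s = df$t_s, delta_od = od, fs = meta$fs,
                          wavelengths_nm = meta$wavelengths_nm,
                          condition = cond),
                     class = "od_series")
  } else stop("parse error: unknown series type '", meta$type, "'")
  attr(out, "optics_meta") <- meta
  out
}

#' Write the study report bundle
#'
#' Tidy CSVs mirroring the study's result tables: per-condition behavioral
#' performance (mean +- SD, with empty cells where a subtask is inactive),
#' per-condition heart measures, the measures table, ANOVA, post-hoc and
#' correlation tables; optionally bar/scatter figures (requires ggplot2).
#'
#' @param results a [run_study()] result.
#' @param dir output directory (created if needed).
#' @param figures also write figures as PDFs.
#' @return invisibly, the paths written.
#' @export
make_report <- function(results, dir, figures = FALSE) {
  stopifnot(inherits(results, "study_results"))
  if (anyNA(results$measures[STUDY_MEASURES]))
    stop("incomplete results: missing cells in measures table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  msd <- function(x) if (all(is.na(x))) NA_character_ else
    sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))
  perf_feats <- c("avg_distance_mm", "n_alarms", "n_numeral_responses",
                  "meter_rt_s", "meter_accuracy_pct", "emergency_rt_s",
                  "emergency_accuracy_pct")
  perf_tab <- data.frame(feature = perf_feats)
  for (cond in results$config$conditions) {
    sub <- results$performance[results$performance$condition == cond, ]
    perf_tab[[cond]] <- vapply(perf_feats, function(f) msd(sub[[f]]),
                               character(1))
  }
  put(perf_tab, "performance_by_condition.csv")
  heart_feats <- c("mean_hr_bpm", "sdnn_ms", "rmssd_ms", "lf_hf_ratio")
  heart_tab <- data.frame(feature = heart_feats)
  for (cond in results$config$conditions) {
    sub <- results$hrv[results$hrv$condition == cond, ]
    heart_tab[[cond]] <- vapply(heart_feats, function(f) msd(sub[[f]]),
                                character(1))
  }
  put(heart_tab, "heart_by_condition.csv")
  put(results$measures, "measures.csv")
  put(results$anova, "anova.csv")
  put(results$pairwise, "pairwise.csv")
  put(results$correlations, "correlations.csv")
  if (figures && requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- ggplot2::ggplot(results$measures,
                          ggplot2::aes(x = factor(condition,
                                                  results$config$conditions),
                                       y = tlx_total)) +
      ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70") +
      ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                            width = 0.2) +
      ggplot2::labs(x = "task load", y = "NASA-TLX weighted score")
    p <- file.path(dir, "tlx_by_condition.pdf")
    ggplot2::ggsave(p, gg, width = 4, height = 3)
    paths <- c(paths, p)
    gg2 <- ggplot2::ggplot(results$measures,
                           ggplot2::aes(x = factor(condition,
                                                   results$config$conditions),
                                        y = mean_beta)) +
      ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70") +
      ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                            width = 0.2) +
      ggplot2::labs(x = "task load", y = "mean HbO beta (uM)")
    p2 <- file.path(dir, "beta_by_condition.pdf")
    ggplot2::ggsave(p2, gg2, width = 4, height = 3)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
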