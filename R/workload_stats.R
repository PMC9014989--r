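# Inferential layer: one-way repeated-measures ANOVA (subject as blocking
# factor), Bonferroni-corrected paired post-hocs, and Pearson correlations.

.check_rm_table <- function(table) {
  req <- c("subject", "condition", "value")
  if (!all(req %in% names(table)))
    stop("table needs columns subject, condition, value")
  tab <- table(table$subject, table$condition)
  if (any(tab != 1L)) {
    bad <- rownames(tab)[apply(tab != 1L, 1, any)]
    stop("incomplete repeated-measures table; offending subject(s): ",
         paste(bad, collapse = ", "))
  }
  k <- length(unique(table$condition))
  n <- length(unique(table$subject))
  if (k < 2) stop("need at least 2 conditions")
  if (n < 3) stop("need at least 3 subjects")
  list(k = k, n = n)
}

#' One-way repeated-measures ANOVA
#'
#' Two-way additive decomposition with subject as blocking factor:
#' `F = MS_condition / MS_error` where the error term is the
#' condition-by-subject interaction, on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom. No sphericity adjustment is applied.
#'
#' @param table long data.frame with columns `subject`, `condition`, `value`,
#'   one row per cell (complete design).
#' @return object of class `anova_result` with `F`, `df_num`, `df_den`, `p`
#'   and the sums of squares.
#' @export
rm_anova_oneway <- function(table) {
  dims <- .check_rm_table(table)
  k <- dims$k; n <- dims$n
  grand <- mean(table$value)
  cond_means <- tapply(table$value, table$condition, mean)
  subj_means <- tapply(table$value, table$subject, mean)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((table$value - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_num <- k - 1L
  df_den <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df_num
  ms_err <- ss_err / df_den
  if (ms_err <= .Machine$double.eps * max(ss_tot, 1)) {
    warning("zero error variance; F and p reported at their boundary")
    if (ms_cond <= .Machine$double.eps * max(ss_tot, 1)) {
      F_stat <- 0; p <- 1
    } else {
      F_stat <- Inf; p <- 0
    }
  } else {
    F_stat <- ms_cond / ms_err
    p <- stats::pf(F_stat, df_num, df_den, lower.tail = FALSE)
  }
  structure(list(F = F_stat, df_num = df_num, df_den = df_den, p = p,
                 ss_condition = ss_cond, ss_subject = ss_subj,
                 ss_error = ss_err, ss_total = ss_tot, n = n, k = k),
            class = "anova_result")
}

#' Bonferroni-corrected pairwise post-hoc tests
#'
#' Paired t tests on subject-wise differences for every condition pair;
#' a pair is significant when its raw p-value falls below `alpha / m` with
#' `m = k (k - 1) / 2`. The displayed threshold truncates to 3 decimals
#' (0.05 / 3 -> .016) while the stored value is exact.
#'
#' @param table as in [rm_anova_oneway()].
#' @param alpha familywise significance level.
#' @return object of class `pairwise_result`: data.frame of pairs plus the
#'   exact and displayed thresholds.
#' @export
bonferroni_pairwise <- function(table, alpha = 0.05) {
  dims <- .check_rm_table(table)
  conds <- unique(as.character(table$condition))
  m <- dims$k * (dims$k - 1L) / 2L
  threshold <- alpha / m
  threshold_display <- floor(threshold * 1000) / 1000
  wide <- split(table, table$condition)
  pairs <- utils::combn(conds, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    c1 <- pairs[1, j]; c2 <- pairs[2, j]
    x1 <- wide[[c1]][order(wide[[c1]]$subject), "value"]
    x2 <- wide[[c2]][order(wide[[c2]]$subject), "value"]
    d <- x1 - x2
    if (stats::sd(d) == 0) {
      warning("exact tie for pair ", c1, "-", c2, "; p = 1")
      t_stat <- 0; p <- 1
    } else {
      tt <- stats::t.test(d)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(cond1 = c1, cond2 = c2, mean_diff = mean(d), t = t_stat,
               p_raw = p, significant = p < threshold)
  })
  structure(list(pairs = do.call(rbind, rows), m = m, alpha = alpha,
                 threshold = threshold,
                 threshold_display = threshold_display),
            class = "pairwise_result")
}

#' Pearson correlation with two-sided p-value
#'
#' `r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`;
#' p from `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 df (boundary |r| = 1
#' reported as p = 0).
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return object of class `correlation_result` with `r`, `n`, `p`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
  }
  structure(list(r = r, n = n, p = p), class = "correlation_result")
}
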