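# Evaluation harness: leave-one-participant-out cross-validation,
# intensity-stratified RMSE, sedentary-classification metrics, one-way
# repeated-measures ANOVA with Bonferroni-corrected paired t post-hocs
# and Cohen's d, and Bland-Altman agreement analysis.

#' Root mean square error
#' @param pred,truth Equal-length numeric vectors (non-empty).
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L)
    wm_contract_error("pred and truth must be non-empty and equal length")
  sqrt(mean((pred - truth)^2))
}

pool_intensity <- function(intensity) {
  ifelse(intensity %in% c("moderate", "vigorous"), "moderate_vigorous",
         intensity)
}

#' RMSE stratified by activity intensity
#'
#' Moderate and vigorous windows are pooled into one stratum. An empty
#' stratum is reported as `NA` (absent), never as zero. The overall RMSE
#' satisfies the decomposition
#' `overall^2 = sum(n_s * rmse_s^2) / sum(n_s)` over occupied strata.
#'
#' @param df Data frame with columns `met_pred`, `met_true` and
#'   `intensity_class` (e.g. rows bound from [lopo_evaluate()] folds).
#' @return Named numeric vector `sedentary, light, moderate_vigorous,
#'   overall`.
#' @export
rmse_by_class <- function(df) {
  strata <- c("sedentary", "light", "moderate_vigorous")
  cls <- pool_intensity(df$intensity_class)
  out <- vapply(strata, function(s) {
    i <- which(cls == s)
    if (!length(i)) return(NA_real_)
    rmse(df$met_pred[i], df$met_true[i])
  }, numeric(1))
  c(out, overall = rmse(df$met_pred, df$met_true))
}

#' Precision, recall and F1 of the sedentary gate
#'
#' Sedentary is the positive class. With zero predicted positives the
#' precision is undefined and reported as `NaN` with a warning.
#'
#' @param pred Logical (or 0/1) predicted sedentary flags.
#' @param truth Logical true sedentary flags; both classes must occur.
#' @return Named numeric vector `precision, recall, f1`.
#' @export
classification_metrics <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(unique(truth)) < 2L)
    wm_contract_error("both classes must be present in truth")
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (tp + fp == 0L) {
    warning("no predicted positives; precision undefined", call. = FALSE)
    precision <- NaN
  } else precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (is.nan(precision) || precision + recall == 0) NaN else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Leave-one-participant-out cross-validation of the two-stage model
#'
#' One fold per participant: the model (including feature selection) is
#' refitted without that participant's windows or demographics, then
#' predicts the held-out windows. The fold partition is asserted on every
#' run: the held-out participant never appears in its training set, and
#' the union of test windows over folds is exactly the full window set.
#'
#' @param windows A labelled [window_set()] spanning >= 2 participants.
#' @param demographics A [demographics()] table.
#' @param ... Passed to [wristmet()] (e.g. `select`, `seed`,
#'   `stage1_params`).
#' @return A list of class `lopo_result`; each fold holds `held_out` and
#'   a per-window data frame with `met_true`, `met_pred`,
#'   `intensity_class`, `stage1_pred` and `sedentary_true`. Use
#'   [lopo_windows()] to bind all folds.
#' @export
lopo_evaluate <- function(windows, demographics, ...) {
  meta <- as.data.frame(windows)
  pids <- unique(meta$participant_id)
  if (length(pids) < 2L)
    wm_contract_error("LOPO-CV needs at least 2 participants")
  folds <- lapply(pids, function(pid) {
    test_i <- which(meta$participant_id == pid)
    train_i <- which(meta$participant_id != pid)
    stopifnot(length(intersect(test_i, train_i)) == 0L)
    tr <- windows; tr$windows <- windows$windows[train_i]
    te <- windows; te$windows <- windows$windows[test_i]
    stopifnot(!pid %in% vapply(tr$windows, `[[`, "", "participant_id"))
    fit <- wristmet(tr, demographics[demographics$participant_id != pid, ,
                                     drop = FALSE], ...)
    pr <- predict(fit, te, demographics, type = "frame")
    list(held_out = pid,
         windows = data.frame(
           participant_id = meta$participant_id[test_i],
           start = meta$start[test_i],
           met_true = meta$met_true[test_i],
           met_pred = pr$met,
           intensity_class = meta$intensity_class[test_i],
           stage1_pred = pr$stage1_label == "sedentary",
           sedentary_true = meta$intensity_class[test_i] == "sedentary"))
  })
  n_test <- sum(vapply(folds, function(f) nrow(f$windows), integer(1)))
  stopifnot(n_test == length(windows$windows))
  structure(folds, class = "lopo_result")
}

#' Bind the held-out windows of all LOPO folds
#' @param folds A `lopo_result` from [lopo_evaluate()].
#' @return One data frame with every window exactly once.
#' @export
lopo_windows <- function(folds) {
  do.call(rbind, lapply(folds, `[[`, "windows"))
}

#' @export
print.lopo_result <- function(x, ...) {
  df <- lopo_windows(x)
  cat(sprintf("<lopo_result> %d fold(s), %d held-out window(s)\n",
              length(x), nrow(df)))
  cat(sprintf("  overall RMSE: %.3f MET\n", rmse(df$met_pred, df$met_true)))
  invisible(x)
}

#' One-way repeated-measures ANOVA over algorithms
#'
#' Rows are participants (the repeated measure), columns are algorithms
#' (the within-subject factor); cells hold each algorithm's per-
#' participant RMSE. Fitted with [stats::aov()] using a participant error
#' stratum; with k algorithms and n participants the degrees of freedom
#' are (k - 1, (k - 1)(n - 1)). No sphericity correction is applied.
#' When the matrix has no within-cell variance at all (e.g. identical
#' columns) the F statistic is degenerate and reported as `NaN` with
#' p = 1.
#'
#' @param rmse_matrix Complete numeric matrix, participants x algorithms,
#'   with >= 2 algorithm columns and >= 3 participant rows.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(rmse_matrix) {
  x <- as.matrix(rmse_matrix)
  if (any(!is.finite(x))) wm_contract_error("rmse_matrix has missing cells")
  n <- nrow(x); k <- ncol(x)
  if (k < 2L || n < 3L)
    wm_contract_error("need >= 2 algorithms and >= 3 participants")
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  grand <- mean(x)
  ss_a <- n * sum((colMeans(x) - grand)^2)
  ss_s <- k * sum((rowMeans(x) - grand)^2)
  ss_e <- sum((x - grand)^2) - ss_a - ss_s
  if (ss_e <= .Machine$double.eps * sum(x^2)) {
    return(list(F = NaN, df1 = df1, df2 = df2, p = 1))
  }
  long <- data.frame(value = as.vector(x),
                     participant = factor(rep(seq_len(n), times = k)),
                     algorithm = factor(rep(colnames(x) %||%
                                              seq_len(k), each = n)))
  fit <- aov(value ~ algorithm + Error(participant), data = long)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  list(F = tab["algorithm", "F value"], df1 = df1, df2 = df2,
       p = tab["algorithm", "Pr(>F)"])
}

#' Bonferroni-corrected paired t-tests with Cohen's d
#'
#' Every pair of algorithm columns is compared with a paired t-test; raw
#' p-values are multiplied by the number of comparisons and capped at 1.
#' Cohen's d uses the paired-design denominator, `mean(diff) / sd(diff)`
#' with `diff = column a - column b`, so with the proposed method as
#' column `a` a negative d means the proposed method has the lower RMSE.
#' Zero-variance non-zero differences give d = +/-Inf with a warning;
#' identical columns give d = 0 and adjusted p = 1.
#'
#' @param rmse_matrix As in [rm_anova()].
#' @return Data frame with one row per pair: `method_a, method_b,
#'   mean_diff, t, df, p, p_adj, d`.
#' @export
posthoc_paired_t <- function(rmse_matrix) {
  x <- as.matrix(rmse_matrix)
  if (any(!is.finite(x))) wm_contract_error("rmse_matrix has missing cells")
  k <- ncol(x)
  if (k < 2L) wm_contract_error("need >= 2 algorithms")
  nm <- colnames(x) %||% paste0("algo", seq_len(k))
  pairs <- combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    d_ab <- x[, a] - x[, b]
    if (sd(d_ab) <= .Machine$double.eps^0.75 * (abs(mean(d_ab)) + 1)) {
      if (all(d_ab == 0)) {
        tt <- list(statistic = 0, parameter = nrow(x) - 1L, p.value = 1)
        dval <- 0
      } else {
        warning("zero-variance differences; Cohen's d is infinite",
                call. = FALSE)
        tt <- list(statistic = sign(mean(d_ab)) * Inf,
                   parameter = nrow(x) - 1L, p.value = 0)
        dval <- sign(mean(d_ab)) * Inf
      }
    } else {
      tt <- t.test(x[, a], x[, b], paired = TRUE)
      dval <- mean(d_ab) / sd(d_ab)
    }
    data.frame(method_a = nm[a], method_b = nm[b], mean_diff = mean(d_ab),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_adj = min(1, tt$p.value * m), d = dval)
  })
  do.call(rbind, rows)
}

#' Bland-Altman agreement analysis of two MET series
#'
#' Differences `a - b` are summarised by their mean and standard
#' deviation (n - 1); the limits of agreement are the mean +/- 1.96 SD.
#' Each aligned window is flagged `over` when its difference exceeds the
#' upper limit (method a overestimates relative to b), `under` below the
#' lower limit, and `within` otherwise. With `a` the method under test
#' and `b` the reference, the fraction within is the headline agreement
#' rate.
#'
#' @param a,b Aligned equal-length numeric MET series, n >= 3.
#' @return Object of class `agreement_report`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, per-window `flag`, `fraction_within`, and the
#'   plot data (`mean`, `diff` per window).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) wm_contract_error("series must be equal length")
  if (length(a) < 3L) wm_contract_error("need at least 3 paired values")
  d <- a - b
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  loa_low <- mean_diff - 1.96 * sd_diff
  loa_high <- mean_diff + 1.96 * sd_diff
  flag <- rep("within", length(d))
  flag[d > loa_high] <- "over"
  flag[d < loa_low] <- "under"
  structure(list(mean_diff = mean_diff, sd_diff = sd_diff,
                 loa_low = loa_low, loa_high = loa_high,
                 flag = flag, fraction_within = mean(flag == "within"),
                 data = data.frame(mean = (a + b) / 2, diff = d)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Bland-Altman agreement\n")
  cat(sprintf("  mean difference: %.4f (SD %.4f)\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  limits of agreement: [%.4f, %.4f]\n", x$loa_low, x$loa_high))
  cat(sprintf("  %.2f%% of %d window(s) within limits (%d over, %d under)\n",
              100 * x$fraction_within, length(x$flag),
              sum(x$flag == "over"), sum(x$flag == "under")))
  invisible(x)
}

#' @export
plot.agreement_report <- function(x, ...) {
  plot(x$data$mean, x$data$diff, xlab = "mean of methods (MET)",
       ylab = "difference (MET)",
       col = c(within = "grey30", over = "firebrick",
               under = "steelblue")[x$flag], pch = 20, ...)
  graphics::abline(h = c(x$loa_low, x$mean_diff, x$loa_high),
                   lty = c(2, 1, 2))
  invisible(x)
}

#' Multi-window evaluation report
#'
#' Runs the full pipeline (windowing, labelling, LOPO-CV) at each window
#' size and tabulates intensity-stratified RMSE for all sizes plus
#' sedentary-classification metrics for the subset of sizes used by
#' related count-based methods.
#'
#' @param sessions List of sessions (see [generate_session()] or
#'   [windows_from_session()] for the expected shape).
#' @param demographics A [demographics()] table.
#' @param window_sizes RMSE table rows; default the nine standard sizes
#'   5--90 s.
#' @param class_windows Classification table rows; default
#'   `c(10, 12.8, 15, 30, 60)`.
#' @param trim_s,overlap Windowing parameters (defaults 120 s, 0.5).
#' @param select Run wrapper feature selection inside each fold? Default
#'   `FALSE` for tractable multi-window sweeps; single-window analyses
#'   use `TRUE`.
#' @param ... Passed to [lopo_evaluate()].
#' @return List of class `wm_report` with data frames `rmse_table`
#'   (window x sedentary/light/moderate_vigorous/overall) and
#'   `classification_table` (window x precision/recall/f1).
#' @export
evaluation_report <- function(sessions, demographics,
                              window_sizes = c(5, 10, 12.8, 15, 30, 40, 50,
                                               60, 90),
                              class_windows = c(10, 12.8, 15, 30, 60),
                              trim_s = 120, overlap = 0.5, select = FALSE,
                              ...) {
  rmse_rows <- list()
  cls_rows <- list()
  for (wsz in window_sizes) {
    ws <- windows_from_sessions(sessions, wsz, overlap = overlap,
                                trim_s = trim_s)
    folds <- lopo_evaluate(ws, demographics, select = select, ...)
    df <- lopo_windows(folds)
    rmse_rows[[length(rmse_rows) + 1L]] <-
      data.frame(window = wsz, t(rmse_by_class(df)))
    if (wsz %in% class_windows) {
      cm <- classification_metrics(df$stage1_pred, df$sedentary_true)
      cls_rows[[length(cls_rows) + 1L]] <- data.frame(window = wsz, t(cm))
    }
  }
  structure(list(rmse_table = do.call(rbind, rmse_rows),
                 classification_table = do.call(rbind, cls_rows)),
            class = "wm_report")
}

#' @export
print.wm_report <- function(x, ...) {
  cat("MET estimation RMSE by window size and intensity stratum:\n")
  print(x$rmse_table, row.names = FALSE, digits = 3)
  cat("\nSedentary-classification metrics by window size:\n")
  print(x$classification_table, row.names = FALSE, digits = 3)
  invisible(x)
}
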