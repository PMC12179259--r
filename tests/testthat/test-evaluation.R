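test_that("RMSE matches hand arithmetic and strata decompose exactly", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(2, 3, 4), c(1, 2, 3)), 1)
  expect_equal(rmse(c(1, 3), c(1, 1)), sqrt(2))
  expect_error(rmse(1:3, 1:2), class = "wm_contract_error")

  set.seed(40)
  df <- data.frame(
    met_pred = runif(200, 1, 8), met_true = runif(200, 1, 8),
    intensity_class = sample(c("sedentary", "light", "moderate", "vigorous"),
                             200, replace = TRUE))
  by_cls <- rmse_by_class(df)
  cls <- ifelse(df$intensity_class %in% c("moderate", "vigorous"),
                "moderate_vigorous", df$intensity_class)
  n_s <- table(cls)[names(by_cls)[1:3]]
  expect_equal(unname(by_cls[["overall"]]^2),
               unname(sum(n_s * by_cls[1:3]^2) / sum(n_s)))

  # an empty stratum is absent (NA), not zero
  df2 <- df[df$intensity_class != "sedentary", ]
  expect_true(is.na(rmse_by_class(df2)[["sedentary"]]))
})

test_that("classification metrics follow confusion-matrix arithmetic", {
  expect_equal(unname(classification_metrics(c(T, T, F, F), c(T, T, F, F))),
               c(1, 1, 1))

  # TP=2, FP=1, FN=2
  pred <- c(T, T, T, F, F, F, F)
  truth <- c(T, T, F, T, T, F, F)
  m <- classification_metrics(pred, truth)
  expect_equal(unname(m), c(2 / 3, 1 / 2, 4 / 7))

  expect_warning(m0 <- classification_metrics(rep(FALSE, 4), c(T, T, F, F)),
                 "precision undefined")
  expect_equal(m0[["recall"]], 0)
  expect_true(is.nan(m0[["precision"]]))
  expect_error(classification_metrics(c(T, F), c(T, T)),
               class = "wm_contract_error")
})

test_that("repeated-measures ANOVA matches the closed-form sums of squares", {
  # independent oracle: textbook one-way RM-ANOVA sums of squares
  rm_anova_oracle <- function(x) {
    n <- nrow(x); k <- ncol(x); grand <- mean(x)
    ss_a <- n * sum((colMeans(x) - grand)^2)
    ss_s <- k * sum((rowMeans(x) - grand)^2)
    ss_e <- sum((x - grand)^2) - ss_a - ss_s
    f <- (ss_a / (k - 1)) / (ss_e / ((k - 1) * (n - 1)))
    list(F = f, p = pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
  }

  set.seed(41)
  x <- matrix(runif(12, 0.2, 0.6), nrow = 4, ncol = 3,
              dimnames = list(NULL, c("proposed", "m1", "m2")))
  got <- rm_anova(x)
  ora <- rm_anova_oracle(x)
  expect_equal(got$F, ora$F, tolerance = 1e-6)
  expect_equal(got$p, ora$p, tolerance = 1e-6)
  expect_equal(c(got$df1, got$df2), c(2, 6))

  # df formula at k = 3 algorithms, n = 26 participants
  x26 <- matrix(rnorm(78, 0.3, 0.05), nrow = 26, ncol = 3)
  expect_equal(c(rm_anova(x26)$df1, rm_anova(x26)$df2), c(2, 50))

  # identical columns: no effect, degenerate F, non-significant path
  same <- matrix(rep(runif(5, 0.2, 0.5), 2), ncol = 2)
  res <- rm_anova(same)
  expect_true(is.nan(res$F) || res$F == 0)
  expect_gte(res$p, 0.05)

  expect_error(rm_anova(matrix(c(1, NA, 2, 3, 4, 5), ncol = 2)),
               class = "wm_contract_error")
})

test_that("Bonferroni paired t-tests match t.test and the d sign convention", {
  set.seed(42)
  proposed <- runif(10, 0.25, 0.35)
  # a comparator uniformly 0.1 worse with sd(diff) = 0.05 gives d = -2
  diffs <- rnorm(10, 0, 1)
  diffs <- (diffs - mean(diffs)) / sd(diffs) * 0.05  # exact mean 0, sd 0.05
  comparator <- proposed + 0.1 + diffs
  x <- cbind(proposed = proposed, comparator = comparator)

  res <- posthoc_paired_t(x)
  expect_equal(res$d, -2, tolerance = 1e-10)
  expect_equal(res$mean_diff, -0.1, tolerance = 1e-10)

  # p agrees with stats::t.test and adjustment never exceeds 1
  tt <- t.test(x[, 1], x[, 2], paired = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  x3 <- cbind(x, other = runif(10, 0.5, 0.9))
  res3 <- posthoc_paired_t(x3)
  expect_equal(nrow(res3), 3L)
  expect_true(all(res3$p_adj <= 1))
  expect_equal(res3$p_adj, pmin(1, res3$p * 3))

  # identical columns: d = 0, adjusted p = 1
  same <- cbind(a = proposed, b = proposed)
  rs <- posthoc_paired_t(same)
  expect_equal(rs$d, 0)
  expect_equal(rs$p_adj, 1)

  # constant non-zero differences: infinite-d sentinel with warning
  expect_warning(ri <- posthoc_paired_t(cbind(a = proposed,
                                              b = proposed + 0.2)),
                 "infinite")
  expect_equal(ri$d, -Inf)
})

test_that("Bland-Altman limits, flags and self-comparison behave as defined", {
  # identical series: limits collapse at 0 and nothing is flagged
  x <- runif(50, 1, 5)
  rep0 <- bland_altman(x, x)
  expect_equal(rep0$mean_diff, 0)
  expect_equal(c(rep0$loa_low, rep0$loa_high), c(0, 0))
  expect_true(all(rep0$flag == "within"))
  expect_equal(rep0$fraction_within, 1)

  # a single large outlier is flagged with the correct sign
  a <- rep(2, 30) + rnorm(30, 0, 0.01)
  b <- a; a[7] <- a[7] + 1
  expect_equal(bland_altman(a, b)$flag[7], "over")
  a2 <- b; a2[9] <- a2[9] - 1
  expect_equal(bland_altman(a2, b)$flag[9], "under")

  expect_error(bland_altman(1:2, 1:2), class = "wm_contract_error")

  # limits are mean +/- 1.96 * sd of the differences
  set.seed(43)
  a <- rnorm(500, 3, 1); b <- rnorm(500, 3, 1)
  r <- bland_altman(a, b)
  d <- a - b
  expect_equal(r$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(r$loa_high, mean(d) + 1.96 * sd(d))
})

test_that("LOPO folds partition windows with no participant leakage", {
  coh <- wm_cohort4()
  ws <- wm_windows4()
  folds <- lopo_evaluate(ws, coh$demographics, select = FALSE, seed = 3L)
  expect_length(folds, 4L)

  df <- lopo_windows(folds)
  expect_equal(nrow(df), length(ws$windows))
  for (f in folds) {
    expect_true(all(f$windows$participant_id == f$held_out))
  }
  # every window appears exactly once
  key <- paste(df$participant_id, df$start)
  meta <- as.data.frame(ws)
  expect_setequal(key, paste(meta$participant_id, meta$start))
  expect_equal(anyDuplicated(key), 0L)

  one <- ws
  one$windows <- ws$windows[as.data.frame(ws)$participant_id == "P001"]
  expect_error(lopo_evaluate(one, coh$demographics),
               class = "wm_contract_error")
})
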