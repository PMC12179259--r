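# The two-stage MET estimator. Stage 1 is a gradient-boosted decision
# tree (XGBoost) binary classifier over the 42 descriptive statistics
# that gates each window as sedentary or non-sedentary. Sedentary windows
# are assigned 1.0 MET (resting rate). Stage 2 is a random-forest
# regressor over intensity + demographic features, fitted on the truly
# non-sedentary training windows only, whose predictions are floored at
# 1.0 MET. Windows the gate misclassifies as non-sedentary still receive
# near-resting estimates because their intensity features are low.

default_stage1_params <- function() {
  list(objective = "binary:logistic", max_depth = 4, eta = 0.3,
       nrounds = 50, nthread = 1)
}

default_stage2_params <- function() {
  list(num.trees = 300, num.threads = 1)
}

#' Fit the two-stage MET estimation model
#'
#' @param windows A labelled [window_set()] (training windows, typically
#'   from several participants) carrying `intensity_class` and `met_true`.
#' @param demographics A [demographics()] table covering every participant.
#' @param sedentary Logical vector, `TRUE` for sedentary windows; defaults
#'   to `intensity_class == "sedentary"`.
#' @param met Ground-truth MET per window; defaults to `met_true`.
#' @param select Run wrapper (greedy forward) feature selection for the
#'   regressor? Default `TRUE`.
#' @param selection_tol Stop selection when the best addition improves
#'   cross-validated RMSE by less than this (default 1e-3 MET).
#' @param seed Integer seed; two fits with the same seed and data give
#'   identical predictions.
#' @param stage1_params XGBoost parameter overrides (`max_depth`, `eta`,
#'   `nrounds`, ...).
#' @param stage2_params Random-forest parameter overrides (`num.trees`, ...).
#' @param sedentary_met MET assigned to sedentary-gated windows (1.0).
#' @param met_floor Lower bound applied to regression output (1.0).
#' @param rmssd_scaling Passed to [rmssd()].
#' @return An object of class `wristmet` with `print`, `summary`,
#'   `predict`, `fitted` and `residuals` methods.
#' @export
wristmet <- function(windows, demographics, sedentary = NULL, met = NULL,
                     select = TRUE, selection_tol = 1e-3, seed = 1L,
                     stage1_params = list(), stage2_params = list(),
                     sedentary_met = 1.0, met_floor = 1.0,
                     rmssd_scaling = "pairs") {
  meta <- as.data.frame(windows)
  if (is.null(sedentary)) sedentary <- meta$intensity_class == "sedentary"
  if (is.null(met)) met <- meta$met_true
  n <- length(windows$windows)
  if (n == 0L) wm_contract_error("no training windows")
  if (length(sedentary) != n || length(met) != n)
    wm_contract_error("sedentary and met must have one entry per window")
  if (length(unique(sedentary)) < 2L)
    wm_contract_error("training set contains a single class")

  p1 <- utils::modifyList(default_stage1_params(), stage1_params)
  p2 <- utils::modifyList(default_stage2_params(), stage2_params)

  x_cls <- as.matrix(feature_matrix(windows, branch = "classifier"))
  nrounds <- p1$nrounds
  p1$nrounds <- NULL
  p1$seed <- seed
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x_cls, label = as.numeric(sedentary))
  stage1 <- xgboost::xgb.train(params = p1, data = dtrain, nrounds = nrounds,
                               verbose = 0)

  x_reg <- feature_matrix(windows, demographics, branch = "regressor",
                          rmssd_scaling = rmssd_scaling)
  reg_rows <- which(!sedentary)
  x_fit <- x_reg[reg_rows, , drop = FALSE]
  y_fit <- met[reg_rows]
  selected <- names(x_reg)
  if (isTRUE(select)) {
    selected <- select_features(x_fit, y_fit,
                                groups = meta$participant_id[reg_rows],
                                tol = selection_tol, seed = seed)
  }
  stage2 <- ranger::ranger(x = x_fit[selected], y = y_fit,
                           num.trees = p2$num.trees, seed = seed,
                           num.threads = p2$num.threads)

  model <- structure(
    list(stage1 = stage1, stage2 = stage2, selected_features = selected,
         classifier_features = colnames(x_cls),
         regressor_features = names(x_reg),
         window_s = windows$window_s, sampling_rate = windows$sampling_rate,
         sedentary_met = sedentary_met, met_floor = met_floor, seed = seed,
         stage1_params = c(p1, nrounds = nrounds), stage2_params = p2,
         rmssd_scaling = rmssd_scaling,
         n_train = n, n_participants = length(unique(meta$participant_id))),
    class = "wristmet")
  model$training <- list(met_true = met, sedentary = sedentary,
                         fitted = predict(model, windows, demographics))
  model
}

#' Greedy forward wrapper feature selection for the MET regressor
#'
#' Starting from the single best feature, repeatedly adds the candidate
#' that most reduces participant-grouped cross-validated RMSE of a
#' random-forest regressor, stopping when the best addition improves RMSE
#' by less than `tol` (so `tol = Inf` returns just the best single
#' feature). Deterministic under a fixed seed.
#'
#' @param x Data frame of candidate features (>= 2 columns).
#' @param y Ground-truth MET per row.
#' @param groups Grouping vector (participant ids) for the CV folds;
#'   `NULL` for plain row folds.
#' @param tol Minimum RMSE improvement to keep adding (default 1e-3).
#' @param seed Integer seed.
#' @param nfolds Number of CV folds (default 3).
#' @param num_trees Forest size used during the search (default 100).
#' @return Character vector of selected feature names (a subset of
#'   `names(x)`).
#' @export
select_features <- function(x, y, groups = NULL, tol = 1e-3, seed = 1L,
                            nfolds = 3L, num_trees = 100L) {
  if (ncol(x) < 2L) return(names(x))
  n <- nrow(x)
  if (is.null(groups)) {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(nfolds), n))
  } else {
    ug <- sort(unique(as.character(groups)))
    k <- min(nfolds, length(ug))
    gf <- stats::setNames(rep_len(seq_len(k), length(ug)), ug)
    fold <- gf[as.character(groups)]
  }
  if (length(unique(fold)) < 2L) {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(min(nfolds, n)), n))
  }

  cv_rmse <- function(feats) {
    resid <- numeric(0)
    for (f in sort(unique(fold))) {
      tr <- fold != f
      fit <- ranger::ranger(x = x[tr, feats, drop = FALSE], y = y[tr],
                            num.trees = num_trees, seed = seed,
                            num.threads = 1)
      pred <- predict(fit, data = x[!tr, feats, drop = FALSE])$predictions
      resid <- c(resid, pred - y[!tr])
    }
    sqrt(mean(resid^2))
  }

  remaining <- names(x)
  chosen <- character(0)
  best_rmse <- Inf
  repeat {
    scores <- vapply(remaining, function(f) cv_rmse(c(chosen, f)), numeric(1))
    cand <- remaining[which.min(scores)]
    improvement <- best_rmse - min(scores)
    if (length(chosen) > 0L && !(improvement >= tol)) break
    chosen <- c(chosen, cand)
    remaining <- setdiff(remaining, cand)
    best_rmse <- min(scores)
    if (!length(remaining)) break
  }
  chosen
}

#' Predict METs for new windows
#'
#' Each window is first gated by the sedentary classifier; sedentary
#' windows receive `sedentary_met` (1.0), non-sedentary windows receive
#' the random-forest estimate floored at `met_floor` (1.0). All returned
#' values are therefore >= 1.0.
#'
#' @param object A fitted [wristmet()] model.
#' @param windows A [window_set()] with the model's window length.
#' @param demographics A [demographics()] table covering every participant.
#' @param type `"met"` for the numeric MET vector (default) or `"frame"`
#'   for a data frame with the stage-1 label, the raw regression output
#'   and the final MET.
#' @param ... Unused.
#' @return Numeric vector or data frame, one entry per window.
#' @export
predict.wristmet <- function(object, windows, demographics = NULL,
                             type = c("met", "frame"), ...) {
  type <- match.arg(type)
  if (is.null(object$stage1) || is.null(object$stage2))
    wm_contract_error("model is not fitted")
  n <- length(windows$windows)
  if (n == 0L) {
    out <- numeric(0)
    if (type == "met") return(out)
    return(data.frame(stage1_label = character(0), met_raw = numeric(0),
                      met = numeric(0)))
  }
  if (!isTRUE(all.equal(windows$window_s, object$window_s)))
    warning(sprintf("window length %gs differs from the model's %gs",
                    windows$window_s, object$window_s), call. = FALSE)
  x_cls <- as.matrix(feature_matrix(windows, branch = "classifier"))
  prob_sed <- predict(object$stage1, xgboost::xgb.DMatrix(x_cls))
  sed <- prob_sed > 0.5

  met <- rep(object$sedentary_met, n)
  met_raw <- rep(NA_real_, n)
  if (any(!sed)) {
    if (is.null(demographics))
      wm_contract_error("demographics are required to predict non-sedentary windows")
    sub <- windows
    sub$windows <- windows$windows[!sed]
    x_reg <- feature_matrix(sub, demographics, branch = "regressor",
                            rmssd_scaling = object$rmssd_scaling)
    raw <- predict(object$stage2,
                   data = x_reg[object$selected_features])$predictions
    met_raw[!sed] <- raw
    met[!sed] <- pmax(raw, object$met_floor)
  }
  if (type == "met") return(met)
  data.frame(stage1_label = ifelse(sed, "sedentary", "non-sedentary"),
             met_raw = met_raw, met = met)
}

#' @export
print.wristmet <- function(x, ...) {
  cat("Two-stage wrist-IMU MET estimator\n")
  cat(sprintf("  window: %gs at %g Hz; trained on %d windows from %d participant(s)\n",
              x$window_s, x$sampling_rate, x$n_train, x$n_participants))
  cat(sprintf("  stage 1: XGBoost sedentary gate (%d features, %d rounds)\n",
              length(x$classifier_features), x$stage1_params$nrounds))
  cat(sprintf("  stage 2: random forest (%d trees) on %d selected feature(s): %s\n",
              x$stage2_params$num.trees, length(x$selected_features),
              paste(x$selected_features, collapse = ", ")))
  cat(sprintf("  sedentary MET %.1f, floor %.1f, seed %d\n",
              x$sedentary_met, x$met_floor, x$seed))
  invisible(x)
}

#' @export
summary.wristmet <- function(object, ...) {
  tr <- object$training
  res <- tr$met_true - tr$fitted
  out <- list(model = object,
              train_rmse = sqrt(mean(res^2)),
              train_sedentary_frac = mean(tr$sedentary),
              selected_features = object$selected_features)
  class(out) <- "summary.wristmet"
  out
}

#' @export
print.summary.wristmet <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training RMSE (resubstitution): %.3f MET over %d windows (%.0f%% sedentary)\n",
              x$train_rmse, length(x$model$training$met_true),
              100 * x$train_sedentary_frac))
  invisible(x)
}

#' @export
fitted.wristmet <- function(object, ...) object$training$fitted

#' @export
residuals.wristmet <- function(object, ...) {
  object$training$met_true - object$training$fitted
}

#' Save a fitted model to a single archive file
#'
#' The archive holds both learners (the XGBoost booster in its portable
#' raw form), the selected-feature list, the configuration and a format
#' version field.
#'
#' @param object A fitted [wristmet()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_wristmet <- function(object, path) {
  obj <- unclass(object)
  obj$stage1 <- xgboost::xgb.save.raw(object$stage1)
  saveRDS(list(format_version = 1L, model = obj), path)
  invisible(path)
}

#' Load a model archive written by [save_wristmet()]
#' @param path Archive file path.
#' @return A fitted `wristmet` model.
#' @export
load_wristmet <- function(path) {
  arch <- readRDS(path)
  if (!identical(arch$format_version, 1L))
    wm_data_error("unsupported model archive version")
  obj <- arch$model
  obj$stage1 <- xgboost::xgb.load.raw(obj$stage1)
  structure(obj, class = "wristmet")
}
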