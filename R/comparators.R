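# Published closed-form MET equations used as benchmarks. Coefficients
# are not hard-coded: they ship in an editable, citation-annotated CSV
# (inst/extdata/comparator_coefficients.csv) so users can swap in the
# exact variant (e.g. wrist vs hip, adult vs youth calibration) their
# study requires. Trained-model baselines (random-forest/HMM or CRF
# pipelines) are not re-implemented; their per-window MET outputs can be
# supplied as an external predictions CSV and fed to [bland_altman()].

#' Euclidean norm minus one (ENMO) of an accelerometer window
#'
#' `mean over samples of max(0, sqrt(ax^2 + ay^2 + az^2) - 1) * 1000`,
#' in milli-g. A stationary gravity-aligned window (norm 1 g) scores 0;
#' sub-gravity norms are truncated at zero before averaging. Input must
#' be in g.
#'
#' @param w A window or numeric matrix with columns `ax, ay, az` (g).
#' @return ENMO in mg.
#' @export
enmo <- function(w) {
  m <- if (is.matrix(w)) w else w$samples
  norm <- sqrt(rowSums(m[, WM_ACCEL, drop = FALSE]^2))
  mean(pmax(0, norm - 1)) * 1000
}

#' Bundled comparator equation specifications
#'
#' Reads the coefficient file: one row per equation with `name`,
#' `input_kind` (`raw_accel_enmo` in mg or `counts_per_min`), `form`
#' (`linear`: `MET = a + b * x`; `linear_vo2`:
#' `MET = (a + b * x) / 3.5` with the linear part in ml O2/kg/min;
#' `power_vo2`: `MET = (a * x^b) / 3.5`), coefficients `a, b`, and the
#' literature `citation`.
#'
#' @param path Coefficient CSV; defaults to the bundled file.
#' @return Data frame of class `comparator_specs`.
#' @export
comparator_specs <- function(path = system.file("extdata",
                                                "comparator_coefficients.csv",
                                                package = "wristmet")) {
  if (!nzchar(path) || !file.exists(path))
    wm_data_error("comparator coefficient file not found")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "input_kind", "form", "a", "b", "citation")
  miss <- setdiff(need, names(df))
  if (length(miss))
    wm_schema_error(sprintf("missing required column '%s'", miss[[1L]]))
  if (any(!nzchar(df$citation)))
    wm_data_error("every comparator spec must name its literature source")
  structure(df, class = c("comparator_specs", "data.frame"))
}

#' Evaluate a comparator MET equation
#'
#' @param name Equation name, matching a row of `specs`.
#' @param x Input value(s): ENMO in mg or counts per minute, depending on
#'   the spec's `input_kind`.
#' @param input_kind Optional declaration of what `x` is; an equation fed
#'   the wrong input kind raises an error.
#' @param specs A [comparator_specs()] table.
#' @param parity_floor Floor the output at 1.0 MET, matching the proposed
#'   method's resting floor? Default `FALSE` (the published equations are
#'   evaluated as printed).
#' @return MET values, same length as `x`.
#' @export
comparator_met <- function(name, x, input_kind = NULL,
                           specs = comparator_specs(), parity_floor = FALSE) {
  row <- specs[specs$name == name, , drop = FALSE]
  if (nrow(row) != 1L)
    wm_config_error(sprintf("unknown comparator spec '%s'", name))
  if (!is.null(input_kind) && !identical(input_kind, row$input_kind))
    wm_contract_error(sprintf("'%s' expects %s input, got %s",
                              name, row$input_kind, input_kind))
  met <- switch(row$form,
                linear = row$a + row$b * x,
                linear_vo2 = (row$a + row$b * x) / 3.5,
                power_vo2 = (row$a * x^row$b) / 3.5,
                wm_config_error(sprintf("unknown functional form '%s'",
                                        row$form)))
  if (isTRUE(parity_floor)) met <- pmax(met, 1.0)
  met
}

#' Read external per-window MET predictions of a baseline method
#'
#' Trained baseline models (e.g. random-forest/HMM behaviour classifiers)
#' are not re-implemented here; their outputs enter the agreement
#' analysis through this CSV (columns `window_start, met_pred,
#' method_name`).
#'
#' @param path CSV file path.
#' @return Data frame with one row per window.
#' @export
read_external_predictions_csv <- function(path) {
  if (!file.exists(path)) wm_data_error(sprintf("file not found: %s", path))
  raw <- read.csv(path)
  miss <- setdiff(c("window_start", "met_pred", "method_name"), names(raw))
  if (length(miss))
    wm_schema_error(sprintf("missing required column '%s'", miss[[1L]]))
  raw
}
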