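# Per-window features. The classifier branch uses 42 descriptive
# statistics (7 statistics x 6 channels); the regressor branch uses three
# signal-intensity features computed from the L2-normalised accelerometer
# channels -- the pooled-variance Km motion estimate, the root mean square
# of successive differences (RMSSD), and the dominant frequency of the
# band-passed acceleration magnitude -- plus demographics and their
# pairwise interactions.

WM_STATS <- c("median", "mean", "max", "min", "range", "sd", "rms")

#' The 42 descriptive statistics of a window
#'
#' For each of the six channels (ax, ay, az, gx, gy, gz), in order:
#' median, mean, maximum, minimum, range, sample standard deviation
#' (n - 1 denominator), and root mean square. Names are
#' `<channel>_<statistic>`.
#'
#' @param w A window (element of a [window_set()]), or a numeric matrix
#'   with the six channel columns.
#' @return Named numeric vector of length 42.
#' @export
statistical_features <- function(w) {
  m <- if (is.matrix(w)) w else w$samples
  if (nrow(m) < 2L)
    wm_contract_error("window must have at least 2 samples")
  out <- numeric(0)
  for (ch in WM_CHANNELS) {
    x <- m[, ch]
    v <- c(median(x), mean(x), max(x), min(x), max(x) - min(x), sd(x),
           sqrt(mean(x^2)))
    names(v) <- paste(ch, WM_STATS, sep = "_")
    out <- c(out, v)
  }
  out
}

#' L2-normalise the channels of a window
#'
#' Divides each channel vector by its Euclidean norm, smoothing
#' between-window scale differences before intensity-feature extraction
#' on the regression branch. All-zero channels pass through unchanged.
#'
#' @param w A window or numeric channel matrix.
#' @return Object of the same shape with unit-norm (or zero) channels.
#' @export
l2_normalize <- function(w) {
  m <- if (is.matrix(w)) w else w$samples
  if (nrow(m) == 0L) wm_contract_error("empty window")
  for (j in seq_len(ncol(m))) {
    nrm <- sqrt(sum(m[, j]^2))
    if (nrm > 0) m[, j] <- m[, j] / nrm
  }
  if (is.matrix(w)) m else { w$samples <- m; w }
}

#' Km motion estimate of a window's accelerometer signal
#'
#' The pooled-dispersion magnitude of the tri-axial acceleration,
#' `Km = sqrt( (1/(n-1)) * [ (Sxx + Syy + Szz) - (1/n)(Sx^2 + Sy^2 + Sz^2) ] )`
#' where `Sxx` is the sum of squared x samples and `Sx` their plain sum.
#' Algebraically this equals `sqrt(var(x) + var(y) + var(z))` with sample
#' variances, so a constant signal yields 0.
#'
#' @param w A window or numeric matrix with columns `ax, ay, az`.
#' @return Non-negative scalar.
#' @export
km_motion <- function(w) {
  m <- if (is.matrix(w)) w else w$samples
  n <- nrow(m)
  if (n < 2L) wm_contract_error("Km needs at least 2 samples")
  acc <- m[, WM_ACCEL, drop = FALSE]
  s2 <- sum(acc^2)
  s1 <- colSums(acc)
  val <- (s2 - sum(s1^2) / n) / (n - 1)
  sqrt(max(val, 0))
}

#' Root mean square of successive differences of a window's acceleration
#'
#' Adjacent-sample differences of each accelerometer axis are squared,
#' summed across the three axes, averaged, and square-rooted:
#' `RMSSD = sqrt( (1/m) * sum_i [ dx_i^2 + dy_i^2 + dz_i^2 ] )`.
#' The averaging divisor `m` is the number of adjacent pairs (`n - 1`) by
#' default; `scaling = "literal_n"` divides by `n` instead (some
#' formulations print the sample count as the divisor).
#'
#' @param w A window or numeric matrix with columns `ax, ay, az`.
#' @param scaling `"pairs"` (divide by n - 1, default) or `"literal_n"`.
#' @return Non-negative scalar.
#' @export
rmssd <- function(w, scaling = c("pairs", "literal_n")) {
  scaling <- match.arg(scaling)
  m <- if (is.matrix(w)) w else w$samples
  n <- nrow(m)
  if (n < 2L) wm_contract_error("RMSSD needs at least 2 samples")
  acc <- m[, WM_ACCEL, drop = FALSE]
  ssq <- sum(diff(acc)^2)
  div <- if (scaling == "pairs") n - 1 else n
  sqrt(ssq / div)
}

#' Band-pass filter specification
#' @param low,high Passband edges in Hz, `0 < low < high`.
#' @param order Butterworth filter order (default 4); applied zero-phase
#'   (forward-backward), doubling the effective order.
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.3, high = 8, order = 4) {
  if (!(low > 0 && high > low))
    wm_config_error("need 0 < low < high")
  structure(list(type = "butterworth_bandpass", low = low, high = high,
                 order = order),
            class = "filter_spec")
}

#' Dominant frequency of a signal within a physiological passband
#'
#' Applies a zero-phase Butterworth band-pass filter (default
#' 0.3--8 Hz, order 4, covering the typical frequency range of human
#' movement) and returns the frequency of the maximum-magnitude discrete
#' Fourier bin within the passband, excluding the DC bin. Resolution is
#' one FFT bin, i.e. `1 / window duration` Hz.
#'
#' @param x Numeric signal (a single channel, or the acceleration
#'   magnitude).
#' @param fs Sampling rate, Hz; must satisfy `spec$high < fs / 2`.
#' @param spec A [filter_spec()].
#' @return Frequency in Hz within `[spec$low, spec$high]`.
#' @export
dominant_frequency <- function(x, fs, spec = filter_spec()) {
  n <- length(x)
  if (n < fs) wm_contract_error("window must be at least 1 s long")
  if (spec$high >= fs / 2)
    wm_config_error("passband upper edge must be below fs/2")
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / (fs / 2),
                       type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  mag <- Mod(fft(xf))
  freqs <- (seq_len(n) - 1L) * fs / n
  band <- which(freqs >= spec$low & freqs <= spec$high & seq_len(n) > 1L &
                  freqs <= fs / 2)
  if (!length(band)) wm_contract_error("no FFT bins inside the passband")
  freqs[band[which.max(mag[band])]]
}

WM_DEMO_BASE <- c("age", "sex", "weight", "height", "bmi")

#' Demographic features with pairwise interactions
#'
#' Five base features -- age (years), sex (female = 0, male = 1), weight
#' (kg), height (cm), BMI (kg/m^2) -- followed by all 10 pairwise
#' products, named `a_x_b`, in a fixed order.
#'
#' @param demo One-row [demographics()] table.
#' @return Named numeric vector of length 15.
#' @export
demographic_features <- function(demo) {
  if (nrow(demo) != 1L)
    wm_contract_error("demographic_features expects exactly one participant row")
  base <- c(age = demo$age, sex = as.numeric(demo$sex == "male"),
            weight = demo$weight_kg, height = demo$height_cm, bmi = demo$bmi)
  names(base) <- WM_DEMO_BASE
  if (any(!is.finite(base)))
    wm_contract_error("incomplete demographics")
  pairs <- combn(WM_DEMO_BASE, 2)
  inter <- apply(pairs, 2, function(p) base[[p[1L]]] * base[[p[2L]]])
  names(inter) <- apply(pairs, 2, paste, collapse = "_x_")
  c(base, inter)
}

#' Assemble the feature vector of one window
#'
#' The classifier branch returns the 42 descriptive statistics of the raw
#' window. The regressor branch L2-normalises the window first, then
#' returns the three intensity features (`km`, `rmssd`, `dom_freq` of the
#' acceleration magnitude) followed by the 15 demographic features --
#' 18 values before feature selection. The gyroscope contributes to the
#' 42 statistics but not to the intensity features.
#'
#' @param w A window.
#' @param demo One-row [demographics()] table (regressor branch only).
#' @param branch `"classifier"` or `"regressor"`.
#' @param sampling_rate Hz (regressor branch; for the dominant frequency).
#' @param spec [filter_spec()] for the dominant frequency.
#' @param rmssd_scaling Passed to [rmssd()].
#' @return Named numeric feature vector.
#' @export
assemble_features <- function(w, demo = NULL,
                              branch = c("classifier", "regressor"),
                              sampling_rate = 20, spec = filter_spec(),
                              rmssd_scaling = "pairs") {
  branch <- match.arg(branch)
  if (branch == "classifier") return(statistical_features(w))
  if (is.null(demo))
    wm_contract_error("regressor branch needs demographics")
  wn <- l2_normalize(w)
  m <- if (is.matrix(wn)) wn else wn$samples
  magn <- sqrt(rowSums(m[, WM_ACCEL, drop = FALSE]^2))
  c(km = km_motion(m), rmssd = rmssd(m, scaling = rmssd_scaling),
    dom_freq = dominant_frequency(magn, sampling_rate, spec),
    demographic_features(demo))
}

#' Feature matrix over a window set
#'
#' @param ws A [window_set()].
#' @param demographics A [demographics()] table covering every
#'   participant in `ws` (regressor branch).
#' @param branch `"classifier"` or `"regressor"`.
#' @param ... Passed to [assemble_features()].
#' @return Data frame, one row per window, columns = feature names.
#' @export
feature_matrix <- function(ws, demographics = NULL,
                           branch = c("classifier", "regressor"), ...) {
  branch <- match.arg(branch)
  rows <- lapply(ws$windows, function(w) {
    demo <- NULL
    if (branch == "regressor") {
      demo <- demographics[demographics$participant_id == w$participant_id, ,
                           drop = FALSE]
      if (nrow(demo) != 1L)
        wm_contract_error(sprintf("no unique demographics row for '%s'",
                                  w$participant_id))
    }
    assemble_features(w, demo, branch, sampling_rate = ws$sampling_rate, ...)
  })
  as.data.frame(do.call(rbind, rows))
}
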