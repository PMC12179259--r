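# Signal preparation: handedness mirroring, head-trimming of each
# activity (the first minutes of gas-exchange data are unstable),
# sliding-window segmentation, and attachment of ground-truth MET labels.

#' Mirror a left-hand recording onto right-hand axes
#'
#' Watches worn on the left wrist see a mirrored movement pattern; to pool
#' participants, left-hand recordings are reflected through the sagittal
#' plane so they resemble right-hand wear. Under that reflection the
#' x acceleration flips sign while angular velocity, a pseudo-vector,
#' flips about the two axes lying in the mirror plane (gy, gz).
#' Right-handed input is returned unchanged. Applying the map twice
#' restores the original recording, and per-sample vector norms are
#' preserved.
#'
#' @param rec An [imu_recording()].
#' @param mirror_map Named vector of +/-1 per channel; the default negates
#'   `ax`, `gy` and `gz`.
#' @return An [imu_recording()]; left-hand input gains attribute
#'   `mirrored = TRUE` (toggled on repeat application).
#' @export
mirror_left_hand <- function(rec,
                             mirror_map = c(ax = -1, ay = 1, az = 1,
                                            gx = 1, gy = -1, gz = -1)) {
  handed <- attr(rec, "handedness")
  if (is.null(handed) || !handed %in% c("left", "right"))
    wm_contract_error("recording has unknown handedness")
  if (handed == "right") return(rec)
  if (!all(WM_CHANNELS %in% names(mirror_map)) ||
      !all(mirror_map[WM_CHANNELS] %in% c(-1, 1)))
    wm_config_error("mirror_map must assign +/-1 to all six channels")
  for (ch in WM_CHANNELS) rec[[ch]] <- rec[[ch]] * mirror_map[[ch]]
  attr(rec, "mirrored") <- !isTRUE(attr(rec, "mirrored"))
  rec
}

#' Mask out the first seconds of each annotated activity
#'
#' Breath-by-breath VO2 takes time to stabilise after an activity
#' transition, so the head of every activity (default 120 s) is excluded
#' from windowing. Activities shorter than `trim_s` contribute no retained
#' samples; samples outside all annotations are untouched by this mask
#' (annotation bounding is applied separately during segmentation).
#'
#' @param t Sample timestamps, seconds.
#' @param annotations An [activity_annotations()] table.
#' @param trim_s Seconds to discard at each activity start (default 120).
#' @return Logical vector over samples; `FALSE` where masked out.
#' @export
trim_activity_head <- function(t, annotations, trim_s = 120) {
  if (trim_s < 0) wm_contract_error("trim_s must be >= 0")
  keep <- rep(TRUE, length(t))
  if (trim_s == 0) return(keep)
  for (i in seq_len(nrow(annotations))) {
    s <- annotations$start_s[[i]]
    keep[t >= s & t < s + trim_s] <- FALSE
  }
  keep
}

new_window <- function(participant_id, start, size, samples,
                       activity_label = NA_character_,
                       intensity_class = NA_character_, met_true = NA_real_) {
  structure(list(participant_id = participant_id, start = start,
                 end = start + size, size = size, samples = samples,
                 activity_label = activity_label,
                 intensity_class = intensity_class, met_true = met_true),
            class = "wm_window")
}

#' Construct a window set
#' @param windows List of windows.
#' @param window_s Window length, seconds.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param sampling_rate Hz.
#' @return A list of class `window_set`.
#' @export
window_set <- function(windows, window_s, overlap = 0.5, sampling_rate = 20) {
  structure(list(windows = windows, window_s = window_s, overlap = overlap,
                 sampling_rate = sampling_rate),
            class = "window_set")
}

#' @export
length.window_set <- function(x) length(x$windows)

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d window(s) of %gs (overlap %g, %g Hz)\n",
              length(x$windows), x$window_s, x$overlap, x$sampling_rate))
  invisible(x)
}

#' @export
as.data.frame.window_set <- function(x, ...) {
  if (!length(x$windows)) {
    return(data.frame(participant_id = character(0), start = numeric(0),
                      end = numeric(0), size = numeric(0),
                      activity_label = character(0),
                      intensity_class = character(0), met_true = numeric(0)))
  }
  do.call(rbind, lapply(x$windows, function(w) {
    data.frame(participant_id = w$participant_id, start = w$start,
               end = w$end, size = w$size,
               activity_label = w$activity_label,
               intensity_class = w$intensity_class, met_true = w$met_true)
  }))
}

#' Cut a recording into fixed-length overlapping windows
#'
#' Windows are cut within contiguous retained segments only: when
#' `annotations` are supplied each annotated interval is a segment (so no
#' window spans an activity boundary or a rest period); otherwise segments
#' break wherever the timestamp gap exceeds `max_gap_periods` sample
#' periods (free-living streams). Window starts advance by
#' `window_s * (1 - overlap)`; trailing partial windows are discarded, so
#' a segment of duration D yields
#' `floor((D - window_s) / (window_s * (1 - overlap))) + 1` windows when
#' `D >= window_s` and none otherwise. A window of `window_s` seconds
#' holds `round(window_s * sampling_rate)` samples (e.g. 256 samples for
#' 12.8 s at 20 Hz).
#'
#' @param rec An [imu_recording()].
#' @param window_s Window length in seconds (> 0).
#' @param overlap Overlap fraction in `[0, 1)`; default 0.5.
#' @param annotations Optional [activity_annotations()]; when given,
#'   windows carry the activity label and intensity class.
#' @param mask Optional logical keep-mask over samples (see
#'   [trim_activity_head()]).
#' @param max_gap_periods Segment break threshold in sample periods
#'   (default 2), used when `annotations` is `NULL`.
#' @return A [window_set()].
#' @export
segment_windows <- function(rec, window_s, overlap = 0.5, annotations = NULL,
                            mask = NULL, max_gap_periods = 2) {
  if (window_s <= 0) wm_contract_error("window_s must be > 0")
  if (overlap < 0 || overlap >= 1)
    wm_contract_error("overlap must be in [0, 1)")
  fs <- attr(rec, "sampling_rate")
  pid <- attr(rec, "participant_id")
  t <- rec$t
  if (is.null(mask)) mask <- rep(TRUE, length(t))
  sig <- as.matrix(as.data.frame(unclass(rec)[WM_CHANNELS]))

  # index runs (first, last, label, intensity) of contiguous retained samples
  runs <- list()
  if (!is.null(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      inside <- which(t >= annotations$start_s[[i]] &
                        t < annotations$end_s[[i]] & mask)
      if (!length(inside)) next
      brk <- c(0L, which(diff(inside) > 1L), length(inside))
      for (j in seq_len(length(brk) - 1L)) {
        idx <- inside[(brk[[j]] + 1L):brk[[j + 1L]]]
        runs[[length(runs) + 1L]] <-
          list(idx = idx, label = annotations$label[[i]],
               intensity = annotations$intensity[[i]])
      }
    }
  } else {
    inside <- which(mask)
    if (length(inside)) {
      gap <- diff(t[inside]) > max_gap_periods / fs | diff(inside) > 1L
      brk <- c(0L, which(gap), length(inside))
      for (j in seq_len(length(brk) - 1L)) {
        idx <- inside[(brk[[j]] + 1L):brk[[j + 1L]]]
        runs[[length(runs) + 1L]] <-
          list(idx = idx, label = NA_character_, intensity = NA_character_)
      }
    }
  }

  n_samp <- round(window_s * fs)
  step <- max(1L, round(n_samp * (1 - overlap)))
  out <- list()
  for (r in runs) {
    n_run <- length(r$idx)
    if (n_run < n_samp) next
    starts <- seq.int(1L, n_run - n_samp + 1L, by = step)
    for (s0 in starts) {
      idx <- r$idx[s0:(s0 + n_samp - 1L)]
      out[[length(out) + 1L]] <-
        new_window(pid, t[idx[[1L]]], window_s, sig[idx, , drop = FALSE],
                   activity_label = r$label, intensity_class = r$intensity)
    }
  }
  window_set(out, window_s, overlap, fs)
}

#' Attach ground-truth MET labels to windows
#'
#' The per-sample MET series (held on the IMU clock) is aggregated within
#' each window, by default with the arithmetic mean. Windows with no
#' overlapping MET samples are dropped with a warning.
#'
#' @param ws A [window_set()].
#' @param met_series Data frame with columns `t` and `met`, aligned to the
#'   IMU clock and sorted by `t`.
#' @param aggregation `"mean"` or `"median"`.
#' @return A [window_set()] with `met_true` filled in.
#' @export
attach_met_labels <- function(ws, met_series, aggregation = c("mean", "median")) {
  aggregation <- match.arg(aggregation)
  agg <- if (aggregation == "mean") mean else median
  tt <- met_series$t
  mm <- met_series$met
  kept <- list()
  n_drop <- 0L
  for (w in ws$windows) {
    v <- mm[tt >= w$start & tt < w$end]
    if (!length(v)) {
      n_drop <- n_drop + 1L
      next
    }
    w$met_true <- agg(v)
    kept[[length(kept) + 1L]] <- w
  }
  if (n_drop > 0L)
    warning(sprintf("dropped %d window(s) with no MET coverage", n_drop),
            call. = FALSE)
  ws$windows <- kept
  ws
}

#' Combine window sets from several participants
#' @param ... `window_set` objects with identical window length, overlap
#'   and sampling rate.
#' @return A single [window_set()].
#' @export
c_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "window_set"))
    sets <- sets[[1L]]
  base <- sets[[1L]]
  for (s in sets[-1L]) {
    if (!isTRUE(all.equal(c(s$window_s, s$overlap, s$sampling_rate),
                          c(base$window_s, base$overlap, base$sampling_rate))))
      wm_contract_error("window sets have incompatible parameters")
    base$windows <- c(base$windows, s$windows)
  }
  base
}
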