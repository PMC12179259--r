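# Shared fixtures, built in code and cached for the session.

wm_cache <- new.env(parent = emptyenv())

wm_memo <- function(key, expr) {
  if (!exists(key, envir = wm_cache)) assign(key, expr, envir = wm_cache)
  get(key, envir = wm_cache)
}

# A 6-channel window matrix from a per-channel generator.
make_window_matrix <- function(n, gen = function(ch) rnorm(n)) {
  m <- sapply(c("ax", "ay", "az", "gx", "gy", "gz"), gen)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                   dimnames = list(NULL, c("ax", "ay", "az",
                                                           "gx", "gy", "gz")))
  m
}

# A short validated IMU recording with sinusoidal motion.
make_recording <- function(dur_s = 30, fs = 20, amp = 0.3, freq = 2,
                           pid = "P1", handedness = "right") {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  imu_recording(data.frame(
    t = t,
    ax = amp * sin(2 * pi * freq * t),
    ay = amp * cos(2 * pi * freq * t),
    az = 1 + 0.5 * amp * sin(2 * pi * freq * t),
    gx = 10 * sin(2 * pi * freq * t),
    gy = 5 * cos(2 * pi * freq * t),
    gz = rep(0, length(t))), pid, handedness, fs)
}

# The ten-participant study-conditions cohort (sigma_met = 0.1,
# amplitude-separated classes), its 60-s windows, and a LOPO run --
# computed once and shared by the contract, recovery and robustness
# tests.
wm_cohort10 <- function() wm_memo("cohort10", generate_cohort(10, seed = 1L))

wm_windows10 <- function() wm_memo("windows10", {
  coh <- wm_cohort10()
  windows_from_sessions(coh$sessions, 60)
})

wm_lopo10 <- function() wm_memo("lopo10", {
  coh <- wm_cohort10()
  lopo_evaluate(wm_windows10(), coh$demographics, seed = 42L)
})

wm_fit10 <- function() wm_memo("fit10", {
  coh <- wm_cohort10()
  wristmet(wm_windows10(), coh$demographics, seed = 42L)
})

# A small cohort for cheaper structural tests.
wm_cohort4 <- function() wm_memo("cohort4", generate_cohort(4, seed = 2L))

wm_windows4 <- function() wm_memo("windows4", {
  windows_from_sessions(wm_cohort4()$sessions, 60)
})
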