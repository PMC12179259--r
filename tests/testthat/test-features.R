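# Naive-loop oracle for the 42 descriptive statistics.
naive_stats <- function(m) {
  out <- c()
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) {
    x <- m[, ch]
    out <- c(out, median(x), mean(x), max(x), min(x), max(x) - min(x),
             sd(x), sqrt(sum(x^2) / length(x)))
  }
  out
}

# Naive-loop oracle for the successive-difference feature.
naive_rmssd <- function(m, div) {
  n <- nrow(m)
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + (m[i, "ax"] - m[i + 1, "ax"])^2 +
      (m[i, "ay"] - m[i + 1, "ay"])^2 + (m[i, "az"] - m[i + 1, "az"])^2
  }
  unname(sqrt(s / div))
}

test_that("the 42 statistics match a naive loop and handle constant channels", {
  set.seed(10)
  for (rep in 1:20) {
    m <- make_window_matrix(50)
    f <- statistical_features(m)
    expect_length(f, 42L)
    expect_equal(unname(f), naive_stats(m), tolerance = 1e-10)
  }

  const <- make_window_matrix(10, function(ch) rep(-3, 10))
  f <- statistical_features(const)
  expect_equal(unname(f[c("ax_median", "ax_mean", "ax_max", "ax_min")]),
               rep(-3, 4))
  expect_equal(unname(f[c("ax_range", "ax_sd")]), c(0, 0))
  expect_equal(unname(f["ax_rms"]), 3)

  two <- make_window_matrix(2, function(ch) c(1, 3))
  f2 <- statistical_features(two)
  expect_equal(unname(f2[c("ax_mean", "ax_range", "ax_rms")]),
               c(2, 2, sqrt(5)))

  expect_error(statistical_features(make_window_matrix(1)),
               class = "wm_contract_error")
})

test_that("L2 normalisation yields unit-norm channels and passes zero channels", {
  m <- make_window_matrix(2, function(ch) if (ch == "ax") c(3, 4) else c(0, 0))
  out <- l2_normalize(m)
  expect_equal(out[, "ax"], c(0.6, 0.8))
  expect_equal(out[, "ay"], c(0, 0))

  set.seed(4)
  r <- l2_normalize(make_window_matrix(30))
  expect_equal(unname(sqrt(colSums(r^2))), rep(1, 6))
})

test_that("Km equals the root of summed sample variances (algebraic identity)", {
  m <- make_window_matrix(2, function(ch) if (ch == "ax") c(1, -1) else c(0, 0))
  expect_equal(km_motion(m), sqrt(2))
  expect_equal(km_motion(make_window_matrix(5, function(ch) rep(2, 5))), 0)

  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:400, 1)
    m <- make_window_matrix(n, function(ch) rnorm(n, sd = runif(1, 0.01, 5)))
    expect_equal(km_motion(m),
                 sqrt(var(m[, "ax"]) + var(m[, "ay"]) + var(m[, "az"])),
                 tolerance = 1e-10)
  }
  expect_error(km_motion(make_window_matrix(1)), class = "wm_contract_error")
})

test_that("RMSSD matches a hand-evaluated case and the naive loop in both scalings", {
  m <- make_window_matrix(3, function(ch) if (ch == "ax") c(0, 1, 0) else rep(0, 3))
  expect_equal(rmssd(m), 1)                       # sqrt((1+1)/2)
  expect_equal(rmssd(m, scaling = "literal_n"), sqrt(2 / 3))
  expect_equal(rmssd(make_window_matrix(5, function(ch) rep(7, 5))), 0)

  set.seed(12)
  for (rep in 1:20) {
    n <- sample(2:200, 1)
    m <- make_window_matrix(n)
    expect_equal(rmssd(m), naive_rmssd(m, n - 1), tolerance = 1e-10)
    expect_equal(rmssd(m, scaling = "literal_n"), naive_rmssd(m, n),
                 tolerance = 1e-10)
    expect_gte(rmssd(m), 0)
  }
})

test_that("dominant frequency recovers a planted sinusoid within one FFT bin", {
  fs <- 20
  for (wsz in c(5, 10, 12.8, 15, 30, 40, 50, 60, 90)) {
    t <- seq(0, wsz - 1 / fs, by = 1 / fs)
    x <- sin(2 * pi * 2 * t)
    expect_lte(abs(dominant_frequency(x, fs) - 2), 1 / wsz + 1e-9)
  }

  # the larger-amplitude component wins
  t <- seq(0, 60 - 1 / 20, by = 1 / 20)
  x <- 1 * sin(2 * pi * 1 * t) + 3 * sin(2 * pi * 5 * t)
  expect_lte(abs(dominant_frequency(x, 20) - 5), 1 / 60 + 1e-9)

  # white noise always lands inside the passband
  set.seed(13)
  for (rep in 1:10) {
    f <- dominant_frequency(rnorm(600), 20)
    expect_gte(f, 0.3)
    expect_lte(f, 8)
  }

  expect_error(dominant_frequency(rnorm(10), 20), class = "wm_contract_error")
  expect_error(dominant_frequency(rnorm(100), 20, filter_spec(high = 12)),
               class = "wm_config_error")
})

test_that("demographic features are 5 bases plus 10 pairwise interactions", {
  demo <- demographics("A", 40, "female", 160, 100)
  f <- demographic_features(demo)
  expect_length(f, 15L)
  expect_equal(unname(f["age_x_weight"]), 4000)
  expect_equal(unname(f["sex"]), 0)
  expect_equal(unname(demographic_features(
    demographics("B", 40, "male", 160, 100))["sex"]), 1)
  expect_equal(unname(f["height_x_bmi"]), 160 * (100 / 1.6^2))
})

test_that("assembled feature vectors have the documented lengths and are deterministic", {
  w <- segment_windows(make_recording(60), 60)$windows[[1]]
  demo <- demographics("P1", 40, "male", 180, 100)

  cls <- assemble_features(w, branch = "classifier")
  expect_length(cls, 42L)

  reg <- assemble_features(w, demo, branch = "regressor")
  expect_length(reg, 18L)
  expect_named(reg[1:3], c("km", "rmssd", "dom_freq"))

  expect_identical(assemble_features(w, demo, branch = "regressor"), reg)

  # features are invariant to timestamp translation (they see samples only)
  w2 <- w; w2$start <- w$start + 1000; w2$end <- w$end + 1000
  expect_identical(assemble_features(w2, demo, branch = "regressor"), reg)
})
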