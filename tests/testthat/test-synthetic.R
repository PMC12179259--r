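test_that("session generation is reproducible and passes the ingest validators", {
  s1 <- generate_session(participant_seed = 77L)
  s2 <- generate_session(participant_seed = 77L)
  expect_identical(s1$imu$ax, s2$imu$ax)
  expect_identical(s1$calorimetry$vo2, s2$calorimetry$vo2)
  expect_identical(s1$demographics, s2$demographics)

  # every generated artifact survives a write/read round trip through the
  # strict readers
  tmp <- withr::local_tempdir()
  write_imu_csv(s1$imu, file.path(tmp, "imu.csv"))
  rec <- read_imu_csv(file.path(tmp, "imu.csv"))
  expect_equal(nrow(rec), nrow(s1$imu))
  write_calorimetry_csv(s1$calorimetry, file.path(tmp, "cal.csv"))
  expect_equal(nrow(read_calorimetry_csv(file.path(tmp, "cal.csv"))),
               nrow(s1$calorimetry))
  write_annotations_csv(s1$annotations, file.path(tmp, "ann.csv"))
  expect_equal(nrow(read_annotations_csv(file.path(tmp, "ann.csv"))), 12L)
  write_demographics_csv(s1$demographics, file.path(tmp, "demo.csv"))
  d <- read_demographics_csv(file.path(tmp, "demo.csv"))
  expect_gte(d$bmi, 30)
})

test_that("the latent-MET chain recovers activity intensity by construction", {
  proto <- default_protocol()
  sed <- proto$activities[proto$activities$intensity == "sedentary", ]
  expect_true(all(sed$motion_amp <= 0.02))
  expect_true(all(proto$activities$latent_met >= 1))
  # latent MET is strictly monotone in amplitude
  o <- order(proto$activities$motion_amp)
  expect_true(all(diff(proto$activities$latent_met[o]) > 0))

  s <- generate_session(participant_seed = 5L, sigma_met = 0.1)
  ws <- windows_from_session(s, 60)
  meta <- as.data.frame(ws)
  latent <- proto$activities$latent_met[
    match(meta$activity_label, proto$activities$label)]
  # window-mean ground truth stays close to the latent MET
  expect_lt(max(abs(meta$met_true - latent)), 3 * 0.1)

  # a sedentary-only protocol yields ground truth pinned near 1 MET
  sed_proto <- default_protocol()
  sed_proto$activities <- proto$activities[proto$activities$intensity ==
                                             "sedentary", ]
  sed_proto$activities$latent_met <- 1.0
  ssed <- generate_session(sed_proto, participant_seed = 6L, sigma_met = 0.1)
  m <- calorimetry_to_met_series(ssed$calorimetry, ssed$demographics)
  expect_true(all(abs(m$met - 1) <= 4 * 0.1))

  # a 2 Hz activity window shows a 2 Hz dominant frequency
  proto2 <- default_protocol()
  proto2$activities <- data.frame(label = "osc", intensity = "moderate",
                                  motion_freq = 2, latent_met = 3.5,
                                  motion_amp = 0.3, duration_s = 300)
  s2 <- generate_session(proto2, participant_seed = 7L)
  w <- windows_from_session(s2, 60)$windows[[1]]
  magn <- sqrt(rowSums(w$samples[, c("ax", "ay", "az")]^2))
  expect_lte(abs(dominant_frequency(magn, 20) - 2), 1 / 60 + 1e-9)
})

test_that("the frequency-driven protocol variant encodes MET in motion frequency", {
  proto <- default_protocol(met_driver = "frequency")
  ns <- proto$activities[proto$activities$intensity != "sedentary", ]
  expect_equal(unique(ns$motion_amp), 0.3)
  o <- order(ns$motion_freq)
  expect_true(all(diff(ns$latent_met[o]) > 0))
  expect_true(all(ns$motion_freq < 8))
})

test_that("free-living pairs plant recoverable disagreement excursions", {
  # zero noise, no excursions: agreement is exact, nothing flagged
  p0 <- generate_free_living_pair(100, seed = 8L, sigma = 0)
  r0 <- bland_altman(p0$a$met, p0$b$met)
  expect_true(all(r0$flag == "within"))

  # 10 planted 5-sigma over-excursions among 10,000 minutes are all caught
  idx <- c(10, 500, 1200, 2500, 3600, 4800, 6000, 7500, 9000, 9990)
  p <- generate_free_living_pair(10000, seed = 9L, sigma = 0.2,
                                 excursion_idx = idx)
  r <- bland_altman(p$a$met, p$b$met)
  expect_true(all(r$flag[idx] == "over"))
  expect_gte(sum(r$flag == "over"), 10L)

  # reproducibility
  q <- generate_free_living_pair(10000, seed = 9L, sigma = 0.2,
                                 excursion_idx = idx)
  expect_identical(p$a$met, q$a$met)

  expect_error(generate_free_living_pair(2), class = "wm_contract_error")
})
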