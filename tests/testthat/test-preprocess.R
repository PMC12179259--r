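test_that("handedness mirroring is an identity on right, an involution on left", {
  right <- make_recording(5, handedness = "right")
  expect_identical(mirror_left_hand(right), right)

  left <- make_recording(5, handedness = "left")
  once <- mirror_left_hand(left)
  expect_equal(once$ax, -left$ax)
  expect_equal(once$ay, left$ay)
  expect_equal(once$gy, -left$gy)
  expect_equal(once$gz, -left$gz)
  expect_true(attr(once, "mirrored"))

  twice <- mirror_left_hand(once)
  expect_equal(as.data.frame(unclass(twice)[c("t", "ax", "ay", "az", "gx",
                                              "gy", "gz")]),
               as.data.frame(unclass(left)[c("t", "ax", "ay", "az", "gx",
                                             "gy", "gz")]))

  # per-sample vector norms are preserved
  anorm <- function(r) sqrt(r$ax^2 + r$ay^2 + r$az^2)
  gnorm <- function(r) sqrt(r$gx^2 + r$gy^2 + r$gz^2)
  expect_equal(anorm(once), anorm(left))
  expect_equal(gnorm(once), gnorm(left))

  bad <- left
  attr(bad, "handedness") <- NULL
  expect_error(mirror_left_hand(bad), class = "wm_contract_error")
})

test_that("activity head trimming masks the configured head of each activity", {
  fs <- 20
  t <- seq(0, 400 - 1 / fs, by = 1 / fs)
  ann <- activity_annotations("walk", "light", 50, 350)

  keep <- trim_activity_head(t, ann, 120)
  # a 5-min activity trimmed by 2 min retains 180 s
  expect_equal(sum(keep & t >= 50 & t < 350) / fs, 180)
  expect_true(all(!keep[t >= 50 & t < 170]))
  expect_true(all(keep[t < 50]))          # outside annotations untouched

  expect_true(all(trim_activity_head(t, ann, 0)))

  short <- activity_annotations("s", "light", 0, 90)
  keep2 <- trim_activity_head(t, short, 120)
  rec <- imu_recording(data.frame(t = t, ax = 0, ay = 0, az = 1, gx = 0,
                                  gy = 0, gz = 0), "P", "right", fs)
  ws <- segment_windows(rec, 60, annotations = short, mask = keep2)
  expect_length(ws$windows, 0L)           # 90-s activity fully trimmed
})

test_that("window counts follow floor((D - w)/(w(1-o))) + 1 and starts advance by w/2", {
  rec <- make_recording(300)
  ws <- segment_windows(rec, 60, overlap = 0.5)
  expect_length(ws$windows, 9L)
  starts <- vapply(ws$windows, `[[`, numeric(1), "start")
  expect_equal(starts, seq(0, 240, by = 30))
  expect_equal(unique(diff(starts)), 30)

  expect_length(segment_windows(make_recording(59), 60)$windows, 0L)
  expect_length(segment_windows(make_recording(60), 60)$windows, 1L)
  expect_error(segment_windows(rec, -5), class = "wm_contract_error")
  expect_error(segment_windows(rec, 60, overlap = 1),
               class = "wm_contract_error")

  # sample count rule: 12.8 s at 20 Hz is exactly 256 samples
  w128 <- segment_windows(make_recording(30), 12.8)$windows[[1]]
  expect_equal(nrow(w128$samples), 256L)
})

test_that("windows never span annotation boundaries or free-living gaps", {
  rec <- make_recording(300)
  ann <- activity_annotations(c("a", "b"), c("light", "moderate"),
                              c(0, 150), c(150, 300))
  ws <- segment_windows(rec, 60, annotations = ann)
  meta <- as.data.frame(ws)
  for (i in seq_len(nrow(meta))) {
    j <- which(ann$start_s <= meta$start[i] & ann$end_s >= meta$end[i])
    expect_length(j, 1L)
    expect_equal(meta$activity_label[i], ann$label[j])
  }

  # free-living: a 2-s dropout splits the stream into two segments
  gap <- make_recording(180)
  keep <- gap$t < 80 | gap$t >= 82
  df <- as.data.frame(unclass(gap)[c("t", "ax", "ay", "az", "gx", "gy",
                                     "gz")])[keep, ]
  rec2 <- imu_recording(df, "P", "right", 20)
  ws2 <- segment_windows(rec2, 60)
  meta2 <- as.data.frame(ws2)
  expect_true(all(meta2$end <= 80 | meta2$start >= 82))
})

test_that("MET labels aggregate in-window samples and drop uncovered windows", {
  rec <- make_recording(60)
  ws <- segment_windows(rec, 60)

  const <- data.frame(t = rec$t, met = 2)
  expect_equal(attach_met_labels(ws, const)$windows[[1]]$met_true, 2)

  halves <- data.frame(t = rec$t, met = ifelse(rec$t < 30, 1, 3))
  expect_equal(attach_met_labels(ws, halves)$windows[[1]]$met_true, 2)
  expect_equal(attach_met_labels(ws, halves,
                                 aggregation = "median")$windows[[1]]$met_true,
               2)

  none <- data.frame(t = rec$t + 1000, met = 2)
  expect_warning(out <- attach_met_labels(ws, none), "no MET coverage")
  expect_length(out$windows, 0L)
})
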