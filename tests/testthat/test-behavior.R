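mk_pose <- function(pitch, fs = 29.97, valid = NULL)
  pose_series(pitch, fs, valid = valid)

test_that("pitch z-scoring is affine invariant and excludes invalid samples", {
  set.seed(30)
  n <- 2000
  pitch <- rnorm(n)
  z1 <- zscore_pitch(mk_pose(pitch))
  z2 <- zscore_pitch(mk_pose(3.2 * pitch + 0.7))
  expect_equal(as.numeric(z1), as.numeric(z2), tolerance = 1e-10)
  expect_equal(mean(z1), 0, tolerance = 1e-10)
  expect_equal(sd(z1), 1, tolerance = 1e-10)
  # invalid samples do not enter the moments and stay NA
  valid <- rep(TRUE, n); valid[1:100] <- FALSE
  spiked <- pitch; spiked[1:100] <- 1e4
  z3 <- zscore_pitch(mk_pose(spiked, valid = valid))
  expect_true(all(is.na(z3[1:100])))
  expect_equal(z3[101:n], z1[101:n] * sd(pitch) / sd(pitch[101:n]) +
                 (mean(pitch) - mean(pitch[101:n])) / sd(pitch[101:n]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(zscore_pitch(mk_pose(rep(1.5, n))), "variance")
  expect_error(zscore_pitch(mk_pose(rnorm(100))), "30 s")
})

test_that("face-up detection thresholds the z-score directionally", {
  set.seed(31)
  z <- rnorm(1e5)
  attr(z, "fs") <- 29.97
  up <- detect_face_up(z)
  expect_equal(mean(up), pnorm(2, lower.tail = FALSE), tolerance = 0.1)
  # threshold 0 splits symmetric noise in half
  expect_equal(mean(detect_face_up(z, threshold = 0)), 0.5,
               tolerance = 0.02)
  # negative camera convention flips the tail
  expect_equal(detect_face_up(z, direction = "negative"),
               (!is.na(z)) & (-z > 2), ignore_attr = TRUE)
  # NA (invalid) samples are never face-up
  z[1:10] <- NA
  expect_true(all(!detect_face_up(z)[1:10]))
})

test_that("event labeling partitions samples into exclusive dyad states", {
  fs <- 10
  up_a <- rep(FALSE, 100); up_b <- rep(FALSE, 100)
  up_a[11:30] <- TRUE; up_b[21:40] <- TRUE     # overlap 21:30
  ev <- label_events(up_a, up_b, fs = fs, min_duration_s = 0,
                     merge_gap_s = 0)
  expect_equal(which(ev$both_up), 21:30)
  expect_equal(which(ev$self_up_A), 11:20)
  expect_equal(which(ev$self_up_B), 31:40)
  # mutual exclusivity + partition
  states <- ev$both_up + ev$self_up_A + ev$self_up_B
  expect_true(all(states <= 1))
  expect_equal(which(states == 1), 11:40)
  # identical tracks: both only
  ev2 <- label_events(up_a, up_a, fs = fs, min_duration_s = 0,
                      merge_gap_s = 0)
  expect_equal(ev2$both_up, up_a)
  expect_true(!any(ev2$self_up_A) && !any(ev2$self_up_B))
  # swapping participants swaps self and other
  ev3 <- label_events(up_b, up_a, fs = fs, min_duration_s = 0,
                      merge_gap_s = 0)
  expect_equal(ev3$self_up_A, ev$self_up_B)
  expect_equal(ev3$self_up_B, ev$self_up_A)
  expect_equal(ev3$both_up, ev$both_up)
  expect_error(label_events(up_a, up_b[-1], fs = fs), "lengths differ")
})

test_that("morphology rules drop short runs and bridge short gaps", {
  fs <- 10
  up <- rep(FALSE, 200)
  up[11:13] <- TRUE                 # 0.3 s run: survives at 0.3 s minimum
  up[51:52] <- TRUE                 # 0.2 s run: dropped
  up[101:110] <- TRUE; up[112:120] <- TRUE   # 0.1 s gap: bridged
  ev <- label_events(up, up, fs = fs, min_duration_s = 0.3,
                     merge_gap_s = 0.2)
  expect_true(all(ev$up_A[11:13]))
  expect_true(all(!ev$up_A[51:52]))
  expect_true(all(ev$up_A[101:120]))
  labs <- ev$events[ev$events$label == "both_up", ]
  expect_equal(nrow(labs), 2)
  durations <- labs$offset_s - labs$onset_s
  expect_true(all(durations >= 0.3))
})

test_that("the design matrix applies resampling and the 5 s delay", {
  fs_pose <- 29.97
  n_pose <- round(200 * fs_pose)
  up_a <- rep(FALSE, n_pose); up_b <- rep(FALSE, n_pose)
  # one 3 s both-up event at t = 100 s
  idx <- which((seq_len(n_pose) - 1) / fs_pose >= 100 &
                 (seq_len(n_pose) - 1) / fs_pose < 103)
  up_a[idx] <- TRUE; up_b[idx] <- TRUE
  ev <- label_events(up_a, up_b, fs = fs_pose, min_duration_s = 0,
                     merge_gap_s = 0)
  des <- build_design(ev, n_y = 2000, target_fs = 10, delay_s = 5)
  support <- des$y_index[des$X[, "both_up"] > 0]
  t_support <- (support - 1) / 10
  expect_equal(min(t_support), 105, tolerance = 0.02)
  expect_equal(max(t_support), 108, tolerance = 0.02)
  expect_equal(length(support), 30, tolerance = 0.05)
  expect_true(all(des$X[, "constant"] == 1))
  # all-zero tracks keep only the constant column populated
  ev0 <- label_events(rep(FALSE, n_pose), rep(FALSE, n_pose),
                      fs = fs_pose)
  d0 <- build_design(ev0, n_y = 2000)
  expect_true(all(d0$X[, c("both_up", "self_up", "other_up")] == 0))
  expect_setequal(attr(d0, "empty_regressors"),
                  c("both_up", "self_up", "other_up"))
  # identity configuration: same rate, zero delay reproduces the tracks
  ev1 <- label_events(up_a, up_b, fs = fs_pose, min_duration_s = 0,
                      merge_gap_s = 0)
  d1 <- build_design(ev1, n_y = n_pose, target_fs = fs_pose, delay_s = 0)
  expect_equal(as.logical(d1$X[, "both_up"]), as.logical(up_a))
})
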