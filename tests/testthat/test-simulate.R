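test_that("simulator validates parameters", {
  expect_error(sim_params(duration = -5), "non-negative")
  expect_error(sim_params(coupling_pairs = data.frame(
    a = 1, b = 1, freq_hz = 0.09, amplitude = -1)), "non-negative")
  expect_error(sim_params(coupling_pairs = data.frame(
    a = 1, b = 1, freq_hz = 6, amplitude = 1)), "twice")
  expect_error(sim_params(coupling_pairs = data.frame(
    a = 30, b = 1, freq_hz = 0.09, amplitude = 1)), "montage")
  expect_error(simulate_dyad(sim_params(duration = 0)), "positive")
})

test_that("a fixed seed reproduces the simulation bit for bit", {
  p <- sim_params(n_channels = 3, duration = 60, seed = 99)
  s1 <- simulate_dyad(p)
  s2 <- simulate_dyad(p)
  expect_identical(s1$A$data, s2$A$data)
  expect_identical(s1$B$data, s2$B$data)
  expect_identical(s1$ground_truth$events, s2$ground_truth$events)
  ps1 <- simulate_pose(p, data.frame(onset_s = 10, offset_s = 13))
  ps2 <- simulate_pose(p, data.frame(onset_s = 10, offset_s = 13))
  expect_identical(ps1$pitch, ps2$pitch)
})

test_that("uncoupled channels are mutually independent", {
  p <- sim_params(n_channels = 4, duration = 300,
                  systemic_amplitude = 0, seed = 21)
  s <- simulate_dyad(p)
  M <- cbind(s$A$data$oxy, s$B$data$oxy)
  C <- cor(M)
  off <- abs(C[upper.tri(C)])
  # 1/f background has a small effective sample count, so sample
  # correlations of independent channels vanish only slowly with duration
  expect_lt(mean(off), 0.1)
  expect_lt(max(off), 0.35)
})

test_that("injected coupling elevates coherence only near its frequency", {
  # frozen Monte-Carlo null (200 uncoupled replicates, n = 3000 at 10 Hz,
  # default grid): band-mean q99 at the 0.0873 Hz band = 0.481
  null_q99 <- 0.481
  p <- sim_params(n_channels = 2, duration = 300,
                  coupling_pairs = data.frame(a = 1, b = 1,
                                              freq_hz = 0.09,
                                              amplitude = 3),
                  lock = "always", systemic_amplitude = 0, seed = 22)
  s <- simulate_dyad(p)
  g <- band_grid()
  k <- which.min(abs(g$frequencies - 0.09))
  bm_coupled <- band_mean_wtc(qwtc(s$A$data$oxy[, 1], s$B$data$oxy[, 1]))
  bm_uncoupled <- band_mean_wtc(qwtc(s$A$data$oxy[, 2],
                                     s$B$data$oxy[, 2]))
  expect_gt(bm_coupled[k], null_q99)
  expect_lt(bm_uncoupled[k], null_q99)
  # frequency localization (checked on bands 30..70 where the 300 s
  # record has solid COI support): the elevation peak falls within 2 grid
  # steps of the injected band, and elevation is confined to the
  # neighborhood set by the Morlet bandwidth (~f/6 per SD, 2.2 bands)
  # plus the 5-band scale-smoothing boxcar
  probe <- 30:70
  d <- bm_coupled - bm_uncoupled
  expect_lte(abs(probe[which.max(d[probe])] - k), 2)
  elevated <- probe[which(d[probe] > 0.25)]
  expect_true(length(elevated) > 0)
  expect_true(all(abs(elevated - k) <= 10))
})

test_that("pose traces calibrate to the Gaussian tail and recover events", {
  # pure noise: ~2.28% of z-scored samples beyond +2 SD
  p <- sim_params(duration = 3400, seed = 23)   # ~1e5 frames
  ps <- simulate_pose(p)
  up <- detect_face_up(zscore_pitch(ps))
  expect_equal(mean(up), pnorm(2, lower.tail = FALSE), tolerance = 0.15)
  # event recovery: mean detected fraction of event samples across seeded
  # runs (oracle: ground-truth mask comparison) is at least 95%
  set.seed(24)
  rec <- replicate(10, {
    prm <- sim_params(duration = 600)
    ev <- hypercoh:::generate_events(600, 1, 3, 1, 0.3)
    upep <- ev[ev$label %in% c("both_up", "self_up_A"), 1:2]
    pose <- simulate_pose(prm, upep)
    truth <- attr(pose, "up_mask")
    if (sum(truth) == 0) return(NA_real_)
    det <- detect_face_up(zscore_pitch(pose))
    sum(det & truth) / sum(truth)
  })
  expect_gte(mean(rec, na.rm = TRUE), 0.95)
  # degenerate and malformed inputs
  expect_length(simulate_pose(sim_params(duration = 0))$pitch, 0)
  expect_error(simulate_pose(p, data.frame(onset_s = -1, offset_s = 2)),
               "malformed")
  expect_error(simulate_pose(p, data.frame(onset_s = 5, offset_s = 4)),
               "malformed")
})

test_that("experiment simulation writes a loadable directory layout", {
  dir <- withr::local_tempdir()
  p <- sim_params(n_channels = 2, duration = 60)
  exp <- simulate_experiment(2, p, seed = 25, dir = dir)
  expect_length(exp$dyads, 2)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_experiment(dir)
  expect_length(back$dyads, 2)
  # crossed design: two sessions per condition per dyad
  conds <- vapply(back$dyads[[1]]$sessions, `[[`, character(1),
                  "condition")
  expect_equal(sum(conds == "COOP"), 2)
  expect_equal(sum(conds == "IND"), 2)
  sid <- names(exp$dyads[[1]]$sessions)[1]
  expect_equal(back$dyads[[1]]$sessions[[sid]]$A$data$oxy,
               exp$dyads[[1]]$sessions[[sid]]$A$data$oxy,
               tolerance = 1e-8)
  # pose traces accompany COOP sessions only
  coop_id <- names(conds)[conds == "COOP"][1]
  ind_id <- names(conds)[conds == "IND"][1]
  expect_s3_class(back$dyads[[1]]$sessions[[coop_id]]$pose$A,
                  "pose_series")
  expect_null(back$dyads[[1]]$sessions[[ind_id]]$pose)
})
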