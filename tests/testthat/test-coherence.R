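test_that("band grid reproduces the standard 91-band layout and edge cases", {
  g <- band_grid()
  expect_length(g$frequencies, 91)
  expect_equal(g$frequencies[1], 0.0072)
  expect_true(all(diff(g$frequencies) > 0))
  # last band within half a step of the upper edge
  expect_lte(g$frequencies[91], 3.68 * 2^(1 / 20))
  expect_equal(band_grid(1, 2, 1)$frequencies, c(1, 2))
  expect_length(band_grid(0.5, 0.5, 10)$frequencies, 1)
  expect_error(band_grid(-0.1, 1), "positive")
  expect_error(band_grid(0, 1), "positive")
})

test_that("pair enumeration covers identical and different channel pairs", {
  ps <- enumerate_pairs(20)
  expect_equal(nrow(ps$identical_pairs), 20)
  expect_equal(nrow(ps$different_pairs), 190)
  expect_equal(nrow(ps$identical_pairs) + nrow(ps$different_pairs), 210)
  # family sizes on the default grid
  expect_equal(210 * 91, 19110)
  expect_equal(190 * 91, 17290)
  ps1 <- enumerate_pairs(1)
  expect_equal(nrow(ps1$identical_pairs), 1)
  expect_equal(nrow(ps1$different_pairs), 0)
  ps3 <- enumerate_pairs(3)
  expect_equal(nrow(ps3$identical_pairs), 3)
  expect_equal(nrow(ps3$different_pairs), 3)
  expect_error(enumerate_pairs(0), "at least one")
})

test_that("Morlet CWT localizes, is linear, and shift-equivariant", {
  fs <- 10; n <- 2000
  g <- small_grid()
  tt <- (0:(n - 1)) / fs
  k_target <- 20
  f0 <- g$frequencies[k_target]
  x <- cos(2 * pi * f0 * tt)
  cw <- suppressWarnings(cwt_morlet(x, fs, g))
  mid <- 800:1200
  power <- rowMeans(Mod(cw$W[, mid])^2)
  expect_equal(which.max(power), k_target)
  # linearity
  cw3 <- suppressWarnings(cwt_morlet(3 * x, fs, g))
  expect_equal(cw3$W, 3 * cw$W, tolerance = 1e-10)
  # shift equivariance away from edges: shifting the input by d samples
  # shifts the coefficients by d
  set.seed(41)
  y <- rnorm(n)
  d <- 100
  y_shift <- c(rep(0, d), y[1:(n - d)])
  c1 <- suppressWarnings(cwt_morlet(y, fs, g))
  c2 <- suppressWarnings(cwt_morlet(y_shift, fs, g))
  # compare a high-frequency band (short support) in the interior
  hi <- length(g$frequencies)
  expect_equal(c2$W[hi, (500 + d):(1500 + d)], c1$W[hi, 500:1500],
               tolerance = 1e-3)
  expect_error(cwt_morlet(numeric(0), fs), "empty")
})

test_that("wavelet coherence obeys its algebraic identities", {
  set.seed(42)
  fs <- 10; n <- 2000
  g <- small_grid()
  x <- rnorm(n); y <- rnorm(n)
  # self-coherence is 1 inside the COI
  m_self <- qwtc(x, x, fs, g)
  expect_lt(max(abs(m_self$coherence[m_self$coi] - 1)), 1e-6)
  # symmetry, bounds, amplitude invariance
  m1 <- qwtc(x, y, fs, g)
  m2 <- qwtc(y, x, fs, g)
  expect_equal(m1$coherence, m2$coherence, tolerance = 1e-12)
  expect_true(all(m1$coherence >= 0 & m1$coherence <= 1))
  m3 <- qwtc(2.5 * x, 0.3 * y, fs, g)
  expect_equal(m1$coherence, m3$coherence, tolerance = 1e-9)
  expect_error(wtc(x, y[-1], fs), "lengths differ")
})

test_that("a common narrow-band signal is detected at the nearest band", {
  set.seed(43)
  fs <- 10; n <- 6000
  g <- small_grid()
  tt <- (0:(n - 1)) / fs
  s <- cos(2 * pi * 0.09 * tt)
  # SNR 1: signal and noise variance both 1/2-scaled
  x <- s + sqrt(2) * rnorm(n)
  y <- s + sqrt(2) * rnorm(n)
  bm <- band_mean_wtc(qwtc(x, y, fs, g))
  # the peak band sits within one 1/10-octave step of the injected
  # frequency (the signal falls between two grid bands)
  k <- which.min(abs(g$frequencies - 0.09))
  expect_lte(abs(which.max(bm) - k), 1)
})

test_that("band-mean coherence respects the COI mask", {
  g3 <- band_grid(0.05, 0.2, 1)   # 3 bands
  coh <- matrix(c(0.2, 0.2, 0.2, 0.2,
                  0.1, 0.3, 0.5, 0.7,
                  0.9, 0.9, 0.9, 0.9), nrow = 3, byrow = TRUE)
  coi <- matrix(c(TRUE, TRUE, TRUE, TRUE,
                  FALSE, TRUE, TRUE, FALSE,
                  FALSE, FALSE, FALSE, FALSE), nrow = 3, byrow = TRUE)
  map <- hypercoh:::new_wtc_map(coh, coi, fs = 1, grid = g3)
  bm <- band_mean_wtc(map)
  expect_equal(bm[1], 0.2)
  expect_equal(bm[2], mean(c(0.3, 0.5)))   # hand-computed partial mask
  expect_true(is.na(bm[3]))                # fully masked, never 0
  # constant coherence gives the constant back
  mapc <- hypercoh:::new_wtc_map(matrix(0.4, 3, 4),
                                 matrix(TRUE, 3, 4), 1, g3)
  expect_equal(band_mean_wtc(mapc), rep(0.4, 3))
})

test_that("coherence of independent noise matches the Monte-Carlo null", {
  # frozen null of per-pair band-mean WTC for independent white noise,
  # n = 3000 at 10 Hz on the default grid (200-replicate simulation):
  # band 37 (0.0873 Hz): mean 0.3152, sd 0.0672
  # band 57 (0.3492 Hz): mean 0.3166, sd 0.0313
  # band 72 (0.9877 Hz): mean 0.3158, sd 0.0219
  null_mean <- c(0.3152, 0.3166, 0.3158)
  null_sd <- c(0.0672, 0.0313, 0.0219)
  bands <- c(37, 57, 72)
  set.seed(44)
  n_pairs <- 12
  obs <- matrix(NA_real_, n_pairs, 3)
  for (i in seq_len(n_pairs)) {
    bm <- band_mean_wtc(qwtc(rnorm(3000), rnorm(3000), 10))
    obs[i, ] <- bm[bands]
  }
  dev <- abs(colMeans(obs) - null_mean)
  expect_true(all(dev < 4 * null_sd / sqrt(n_pairs)))
})

test_that("pair-level coherence merges orientations consistently", {
  set.seed(45)
  n <- 1500
  oxy_a <- matrix(rnorm(n * 2), n, 2)
  oxy_b <- matrix(rnorm(n * 2), n, 2)
  ha <- hb_series(oxy_a, -0.6 * oxy_a, 10, "A")
  hb <- hb_series(oxy_b, -0.6 * oxy_b, 10, "B")
  g <- small_grid()
  both <- suppressWarnings(
    wtc_for_pair(ha, hb, c(1, 2), grid = g,
                 orientation_policy = "keep_both"))
  expect_length(both, 2)
  avg <- suppressWarnings(wtc_for_pair(ha, hb, c(1, 2), grid = g))
  expect_equal(avg$coherence,
               (both[[1]]$coherence + both[[2]]$coherence) / 2,
               tolerance = 1e-12)
  # within-brain mode rejects identical pairs and works on different ones
  expect_error(wtc_for_pair(ha, pair = c(1, 1), mode = "within"), "differ")
  wm <- suppressWarnings(wtc_for_pair(ha, pair = c(1, 2), mode = "within",
                                      grid = g))
  expect_s3_class(wm, "wtc_map")
  # session-level band means agree with the pair-level computation
  bm <- suppressWarnings(session_band_means(ha, hb, grid = g))
  expect_equal(nrow(bm), 3)   # 2 identical + 1 different
  expect_equal(bm[3, ], band_mean_wtc(avg), tolerance = 1e-10)
})
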