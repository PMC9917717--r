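test_that("the gamma/log-link fit recovers generative coefficients", {
  # closed-form intercept on a constant response
  X0 <- cbind(constant = rep(1, 50))
  f0 <- suppressWarnings(fit_wtc_glm(rep(0.37, 50), X0))
  expect_equal(unname(coef(f0)["constant"]), log(0.37), tolerance = 1e-10)
  # generative recovery over seeded replicates
  set.seed(60)
  err <- replicate(10, {
    x <- rbinom(6000, 1, 0.1)
    mu <- exp(0.2 + 0.5 * x)
    y <- rgamma(6000, shape = 20, scale = mu / 20)
    coef(fit_wtc_glm(y, cbind(constant = 1, both_up = x)))["both_up"] - 0.5
  })
  expect_lt(max(abs(err)), 0.1)
  expect_lt(abs(mean(err)), 0.02)
  # zero samples are clipped and counted, the fit proceeds
  y <- rgamma(100, 5, 10); y[3] <- 0
  fz <- suppressWarnings(fit_wtc_glm(y, cbind(constant = rep(1, 100))))
  expect_equal(fz$n_clipped, 1)
  expect_true(fz$converged)
  # all-zero regressor yields an NA coefficient, not an error
  fa <- fit_wtc_glm(rgamma(100, 5, 10),
                    cbind(constant = 1, both_up = rep(0, 100),
                          self_up = rbinom(100, 1, 0.2)))
  expect_true(is.na(coef(fa)["both_up"]))
  expect_false(is.na(coef(fa)["self_up"]))
  expect_error(fit_wtc_glm(rgamma(10, 2), cbind(x = rep(1, 10))),
               "constant")
})

test_that("response scaling shifts only the intercept; columns permute", {
  set.seed(61)
  x1 <- rbinom(500, 1, 0.2); x2 <- rbinom(500, 1, 0.2)
  y <- rgamma(500, shape = 10, scale = exp(0.1 + 0.3 * x1 - 0.2 * x2) / 10)
  X <- cbind(constant = 1, both_up = x1, self_up = x2)
  b1 <- coef(fit_wtc_glm(y, X))
  b2 <- coef(fit_wtc_glm(7 * y, X))
  expect_equal(unname(b2["constant"] - b1["constant"]), log(7),
               tolerance = 1e-8)
  expect_equal(b2[c("both_up", "self_up")], b1[c("both_up", "self_up")],
               tolerance = 1e-8)
  Xp <- X[, c("constant", "self_up", "both_up")]
  bp <- coef(fit_wtc_glm(y, Xp))
  expect_equal(bp[c("both_up", "self_up")], b1[c("both_up", "self_up")],
               tolerance = 1e-10)
})

test_that("either-up combination averages and propagates missingness", {
  expect_equal(either_up_beta(0.4, 0.4), 0.4)
  expect_equal(either_up_beta(0.2, 0.6), 0.4)
  expect_equal(either_up_beta(NA, 0.6), 0.6)
  expect_equal(either_up_beta(0.2, NA), 0.2)
  expect_true(is.na(either_up_beta(NA_real_, NA_real_)))
})

test_that("the both-vs-either group contrast applies Bonferroni correctly", {
  b <- matrix(c(0.5, 0.4, 0.6, 0.3, 0.5), 5, 1)
  cc0 <- contrast_both_vs_either(b, b)
  expect_equal(cc0$t, 0)
  expect_equal(cc0$p, 1)
  # per-test threshold is alpha over the candidate count
  cc15 <- contrast_both_vs_either(b, b + 0.1, n_candidates = 15)
  expect_equal(cc15$p_threshold, 0.05 / 15, tolerance = 1e-12)
  # matches stats::t.test on the pairing
  set.seed(62)
  a <- rnorm(8, 0.5, 0.1); e <- rnorm(8, 0.3, 0.1)
  cc <- contrast_both_vs_either(cbind(a), cbind(e))
  ref <- t.test(a, e, paired = TRUE)
  expect_equal(cc$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cc$p, ref$p.value, tolerance = 1e-12)
  # under 3 complete dyads: untested
  few <- contrast_both_vs_either(cbind(c(1, 2, NA, NA)),
                                 cbind(c(1, 1, NA, NA)))
  expect_false(few$tested)
})

test_that("event-locked averaging reproduces segment means", {
  fs <- 10
  # constant series: flat average at the constant
  yc <- rep(0.42, 2000)
  el <- event_locked_wtc(yc, fs, onsets_s = c(50, 90, 130),
                         window_s = c(-5, 10))
  expect_true(all(abs(el$mean - 0.42) < 1e-12))
  expect_equal(el$n_events, 3)
  # ramp ending at each onset: locked average equals the direct
  # segment-mean oracle
  y <- rep(0.3, 3000)
  onsets <- c(60, 120, 180)
  for (t0 in onsets) {
    i0 <- round(t0 * fs) + 1
    y[(i0 - 50):i0] <- y[(i0 - 50):i0] + seq(0, 0.2, length.out = 51)
  }
  el2 <- event_locked_wtc(y, fs, onsets, window_s = c(-6, 4))
  oracle <- colMeans(do.call(rbind, lapply(onsets, function(t0) {
    i0 <- round(t0 * fs) + 1
    y[(i0 - 60):(i0 + 40)]
  })))
  expect_equal(el2$mean, oracle, tolerance = 1e-12)
  # baseline subtraction
  el3 <- event_locked_wtc(y, fs, onsets, window_s = c(-6, 4),
                          baseline = 0.3)
  expect_equal(el3$mean, oracle - 0.3, tolerance = 1e-12)
  # truncated windows are excluded and counted; zero events error
  el4 <- event_locked_wtc(y, fs, c(1, 120), window_s = c(-6, 4))
  expect_equal(el4$n_excluded, 1)
  expect_equal(el4$n_events, 1)
  expect_error(event_locked_wtc(y, fs, numeric(0)), "no events")
  expect_error(event_locked_wtc(y, fs, c(1, 2), window_s = c(-100, 400)),
               "truncated")
})
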