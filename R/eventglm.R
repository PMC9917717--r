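#' Event-related gamma GLM of a coherence time course
#'
#' Fits `E[Y] = exp(X beta)` with gamma errors by iteratively reweighted
#' least squares, linking the coherence time course of one
#' channel-pair/band cell to the behavioral boxcar regressors. Coherence
#' samples at or below zero are clipped to `clip` (gamma support is
#' strictly positive); values above 1 are left untouched apart from
#' numerical clipping in the coherence stage. All-zero regressors are
#' dropped from the fit and reported with an NA coefficient.
#'
#' @param y positive response series (band coherence over time).
#' @param X design matrix from [build_design()] (must contain a
#'   `constant` column).
#' @param clip lower clip for non-positive responses (default 1e-6).
#' @return object of class `wtc_glm`: coefficients (NA for dropped
#'   regressors), `converged`, `deviance`, `iter`, `dispersion` (Pearson
#'   chi-square / df), `n_clipped`, `n_obs`.
#' @export
fit_wtc_glm <- function(y, X, clip = 1e-6) {
  X <- as.matrix(X)
  if (!"constant" %in% colnames(X))
    stop("fit_wtc_glm: design must include a constant column")
  if (length(y) != nrow(X))
    stop("fit_wtc_glm: response and design lengths differ")
  n_clipped <- sum(y < clip)
  y <- pmax(y, clip)
  keep <- colnames(X) == "constant" | colSums(abs(X)) > 0
  dropped <- colnames(X)[!keep]
  Xf <- X[, keep, drop = FALSE]
  event_cols <- setdiff(colnames(Xf), "constant")
  if (length(event_cols) == 0)
    warning("fit_wtc_glm: no nonzero event regressor in the design")
  fit <- suppressWarnings(
    stats::glm.fit(Xf, y, family = stats::Gamma(link = "log"),
                   control = stats::glm.control(maxit = 100)))
  beta <- rep(NA_real_, ncol(X))
  names(beta) <- colnames(X)
  beta[keep] <- fit$coefficients
  mu <- fit$fitted.values
  df_res <- length(y) - sum(!is.na(fit$coefficients))
  dispersion <- if (df_res > 0) sum((y - mu)^2 / mu^2) / df_res else NA_real_
  structure(list(coefficients = beta,
                 converged = isTRUE(fit$converged) &&
                   all(is.finite(beta[keep])),
                 deviance = fit$deviance, iter = fit$iter,
                 dispersion = dispersion, n_clipped = n_clipped,
                 n_obs = length(y), dropped = dropped),
            class = "wtc_glm")
}

#' @export
print.wtc_glm <- function(x, ...) {
  cat(sprintf("<wtc_glm> gamma/log fit on %d samples (%s, %d IRLS iterations)\n",
              x$n_obs, if (x$converged) "converged" else "NOT converged",
              x$iter))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.wtc_glm <- function(object, ...) object$coefficients

#' @export
summary.wtc_glm <- function(object, ...) {
  cat(sprintf(
    "Gamma/log-link event GLM\n  n = %d (clipped: %d)\n  deviance = %.4g, dispersion = %.4g\n  converged: %s\n",
    object$n_obs, object$n_clipped, object$deviance, object$dispersion,
    object$converged))
  print(object$coefficients)
  invisible(object)
}

#' Combine self-up and other-up coefficients into either-up
#'
#' Self-up of one participant is other-up of the partner, so the two
#' coefficients describe the same dyadic state (exactly one face up) and
#' are combined as their mean. A missing component propagates: the
#' remaining one is returned; both missing gives NA.
#'
#' @param beta_self,beta_other coefficients from [fit_wtc_glm()].
#' @return the either-up coefficient.
#' @export
either_up_beta <- function(beta_self, beta_other) {
  v <- c(beta_self, beta_other)
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Group contrast of both-up vs either-up coefficients
#'
#' Paired two-tailed t-test of the per-dyad both-up vs either-up GLM
#' coefficients for each candidate cell, Bonferroni-corrected over the
#' number of candidates tested. Dyads missing either coefficient are
#' dropped pairwise; candidates with fewer than 3 complete dyads are
#' untested.
#'
#' @param beta_both,beta_either matrices dyads x candidates (or vectors
#'   for a single candidate).
#' @param n_candidates Bonferroni denominator; defaults to the number of
#'   candidate columns.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame per candidate: `n_dyads`, `mean_both`,
#'   `mean_either`, `t`, `p`, `p_threshold`, `significant`, `tested`.
#' @export
contrast_both_vs_either <- function(beta_both, beta_either,
                                    n_candidates = NULL, alpha = 0.05) {
  beta_both <- as.matrix(beta_both); beta_either <- as.matrix(beta_either)
  if (!all(dim(beta_both) == dim(beta_either)))
    stop("contrast_both_vs_either: coefficient matrices must share a shape")
  m <- ncol(beta_both)
  if (is.null(n_candidates)) n_candidates <- m
  thr <- alpha / n_candidates
  out <- data.frame(n_dyads = integer(m), mean_both = NA_real_,
                    mean_either = NA_real_, t = NA_real_, p = NA_real_,
                    p_threshold = thr, significant = FALSE, tested = FALSE)
  for (j in seq_len(m)) {
    a <- beta_both[, j]; b <- beta_either[, j]
    ok <- is.finite(a) & is.finite(b)
    n <- sum(ok)
    out$n_dyads[j] <- n
    if (n < 3) next
    d <- a[ok] - b[ok]
    sdd <- stats::sd(d)
    tv <- if (sdd == 0) {
      if (mean(d) == 0) 0 else Inf * sign(mean(d))
    } else mean(d) / (sdd / sqrt(n))
    pv <- 2 * stats::pt(-abs(tv), n - 1)
    out$mean_both[j] <- mean(a[ok])
    out$mean_either[j] <- mean(b[ok])
    out$t[j] <- tv
    out$p[j] <- pv
    out$significant[j] <- pv < thr
    out$tested[j] <- TRUE
  }
  out
}

#' Event-locked average of a coherence time course
#'
#' Extracts fixed-length segments of the band coherence series around each
#' event onset (time 0 = onset) and averages them, optionally subtracting
#' a baseline level (conventionally the grand-mean coherence over all
#' channel combinations at the band). Events whose window would run past
#' either end of the series are excluded and counted.
#'
#' @param y coherence series at rate `fs`.
#' @param fs sampling rate in Hz.
#' @param onsets_s event onset times in seconds.
#' @param window_s `c(before, after)` in seconds around the onset
#'   (default c(-10, 20)).
#' @param baseline optional scalar subtracted from the average.
#' @return list of class `event_locked`: `time_s`, `mean` (average
#'   course), `n_events` used, `n_excluded`, `baseline`.
#' @export
event_locked_wtc <- function(y, fs, onsets_s, window_s = c(-10, 20),
                             baseline = NULL) {
  if (length(onsets_s) == 0)
    stop("event_locked_wtc: no events supplied")
  lo <- round(window_s[1] * fs); hi <- round(window_s[2] * fs)
  rel <- lo:hi
  segs <- list()
  excluded <- 0L
  for (t0 in onsets_s) {
    i0 <- round(t0 * fs) + 1
    idx <- i0 + rel
    if (idx[1] < 1 || idx[length(idx)] > length(y)) {
      excluded <- excluded + 1L
      next
    }
    segs[[length(segs) + 1]] <- y[idx]
  }
  if (length(segs) == 0)
    stop("event_locked_wtc: every event window is truncated")
  avg <- colMeans(do.call(rbind, segs))
  if (!is.null(baseline)) avg <- avg - baseline
  structure(list(time_s = rel / fs, mean = avg,
                 n_events = length(segs), n_excluded = excluded,
                 baseline = baseline),
            class = "event_locked")
}

#' @export
print.event_locked <- function(x, ...) {
  cat(sprintf("<event_locked> %d events averaged (%d excluded), window %g..%g s\n",
              x$n_events, x$n_excluded, x$time_s[1],
              x$time_s[length(x$time_s)]))
  invisible(x)
}

#' @export
plot.event_locked <- function(x, ...) {
  plot(x$time_s, x$mean, type = "l", xlab = "time from onset (s)",
       ylab = "mean coherence", ...)
  abline(v = 0, lty = 2)
  invisible(x)
}
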