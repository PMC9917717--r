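#' Logarithmic frequency grid for wavelet analysis
#'
#' Builds the analysis frequency grid: frequencies spaced at
#' `1/steps_per_octave` octave intervals starting at `f_min`, extending to
#' `f_max` with half-step tolerance (the last band may exceed `f_max` by at
#' most a half step, so a grid whose span is an almost-integer number of
#' steps is not truncated by rounding error). The defaults reproduce the
#' standard 91-band grid from 0.0072 to 3.68 Hz used for 10 Hz fNIRS
#' recordings.
#'
#' @param f_min lowest band frequency in Hz.
#' @param f_max highest band frequency in Hz (inclusive up to half a step).
#' @param steps_per_octave number of bands per frequency doubling.
#' @return An object of class `band_grid`: a list with `frequencies` (Hz,
#'   strictly increasing), `f_min`, `f_max`, `steps_per_octave`.
#' @examples
#' g <- band_grid()
#' length(g$frequencies)  # 91
#' @export
band_grid <- function(f_min = 0.0072, f_max = 3.68, steps_per_octave = 10) {
  if (!is.numeric(f_min) || !is.numeric(f_max) || f_min <= 0 || f_max <= 0)
    stop("band_grid: frequencies must be positive numbers")
  if (f_max < f_min)
    stop("band_grid: f_max must be >= f_min")
  if (steps_per_octave < 1)
    stop("band_grid: steps_per_octave must be >= 1")
  k_max <- floor(steps_per_octave * log2(f_max / f_min) + 0.5)
  freqs <- f_min * 2^((0:k_max) / steps_per_octave)
  structure(list(frequencies = freqs, f_min = f_min, f_max = f_max,
                 steps_per_octave = steps_per_octave),
            class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf("<band_grid> %d bands, %.4g-%.4g Hz, %d steps/octave\n",
              length(x$frequencies), x$frequencies[1],
              x$frequencies[length(x$frequencies)], x$steps_per_octave))
  invisible(x)
}

# Morlet Fourier factor: frequency f corresponds to scale
# s = ff / f with ff = (omega0 + sqrt(2 + omega0^2)) / (4 pi).
morlet_fourier_factor <- function(omega0) {
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
}

morlet_scales <- function(grid, omega0 = 6) {
  morlet_fourier_factor(omega0) / grid$frequencies
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

#' Continuous Morlet wavelet transform
#'
#' FFT-based continuous wavelet transform with a Morlet mother wavelet at
#' the scales corresponding to a [band_grid()]. The series is mean-removed
#' and zero-padded to the next power of two; the padded region always falls
#' outside the cone of influence (COI).
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param grid a [band_grid()].
#' @param omega0 Morlet wavenumber (default 6).
#' @return A list with `W` (complex matrix, band x time), `scales` (s, per
#'   band), `coi_s` (numeric vector, per time sample: the largest scale in
#'   seconds whose e-folding time fits inside the record; a (band, t) cell
#'   is inside the COI iff `scales[band] <= coi_s[t]`), `fs`, `grid`,
#'   `omega0`.
#' @export
cwt_morlet <- function(x, fs, grid = band_grid(), omega0 = 6) {
  if (length(x) < 1) stop("cwt_morlet: empty series")
  if (anyNA(x)) stop("cwt_morlet: series contains NA")
  scales <- morlet_scales(grid, omega0)
  n <- length(x)
  efold <- sqrt(2) * max(scales)           # e-folding time at lowest band
  if ((n - 1) / fs < 2 * efold)
    warning("cwt_morlet: record shorter than two e-folding lengths at ",
            "f_min; lowest bands lie fully outside the COI")
  npad <- next_pow2(n)
  xf <- stats::fft(c(x - mean(x), rep(0, npad - n)))
  # angular frequencies of FFT bins, rad/s
  k <- c(0:(npad / 2), -((npad / 2 - 1):1))
  om <- 2 * pi * k * fs / npad
  pos <- om > 0
  # daughter wavelets in frequency domain (Torrence & Compo normalisation)
  H <- matrix(0, npad, length(scales))
  for (j in seq_along(scales)) {
    s <- scales[j]
    H[pos, j] <- sqrt(2 * pi * s * fs) * pi^(-0.25) *
      exp(-0.5 * (s * om[pos] - omega0)^2)
  }
  Wt <- stats::mvfft(H * xf, inverse = TRUE) / npad   # time x band
  W <- t(Wt[seq_len(n), , drop = FALSE])              # band x time
  tt <- (seq_len(n) - 1) / fs
  coi_s <- pmin(tt, tt[n] - tt) / sqrt(2)
  list(W = W, scales = scales, coi_s = coi_s, fs = fs, grid = grid,
       omega0 = omega0)
}

# Gaussian smoothing along time, SD = scale (seconds), per band.
# P: band x time (real or complex). FFT implementation with zero padding.
smooth_time <- function(P, scales, fs) {
  n <- ncol(P)
  # pad far enough that the widest Gaussian cannot wrap around
  npad <- next_pow2(n + ceiling(4 * max(scales) * fs))
  Z <- matrix(0+0i, npad, nrow(P))
  Z[seq_len(n), ] <- t(P)
  F <- stats::mvfft(Z)
  k <- c(0:(npad / 2), -((npad / 2 - 1):1))
  om <- 2 * pi * k * fs / npad
  for (j in seq_len(ncol(F)))
    F[, j] <- F[, j] * exp(-0.5 * (scales[j] * om)^2)
  S <- stats::mvfft(F, inverse = TRUE) / npad
  out <- t(S[seq_len(n), , drop = FALSE])
  if (is.complex(P)) out else Re(out)
}

# Boxcar smoothing across scales covering 0.6 of a scale decorrelation
# length (Grinsted convention): window of 2*round(0.3*steps_per_octave*2)-1
# bands... implemented as weight matrix with edge renormalisation.
smooth_scale <- function(P, steps_per_octave) {
  K <- nrow(P)
  dj <- 1 / steps_per_octave
  hw <- round(0.6 / (2 * dj))              # half-width in bands
  if (hw < 1 || K == 1) return(P)
  Wm <- matrix(0, K, K)
  for (k in seq_len(K)) {
    lo <- max(1, k - hw); hi <- min(K, k + hw)
    Wm[k, lo:hi] <- 1 / (hi - lo + 1)
  }
  Wm %*% P
}

# Full WTC smoothing operator: time-Gaussian (SD = scale) then scale boxcar.
wtc_smooth <- function(P, scales, fs, steps_per_octave) {
  smooth_scale(smooth_time(P, scales, fs), steps_per_octave)
}

coi_mask <- function(scales, coi_s) {
  outer(scales, coi_s, `<=`)
}

new_wtc_map <- function(coherence, coi, fs, grid, pair = NULL,
                        dyad_id = NULL) {
  structure(list(coherence = coherence, coi = coi, fs = fs, grid = grid,
                 pair = pair, dyad_id = dyad_id),
            class = "wtc_map")
}

#' @export
print.wtc_map <- function(x, ...) {
  cat(sprintf("<wtc_map> %d bands x %d samples at %g Hz", nrow(x$coherence),
              ncol(x$coherence), x$fs))
  if (!is.null(x$pair)) cat(sprintf(", pair (%s, %s)", x$pair[1], x$pair[2]))
  cat(sprintf("; %.1f%% of cells inside COI\n", 100 * mean(x$coi)))
  invisible(x)
}

#' @export
plot.wtc_map <- function(x, ...) {
  z <- x$coherence
  z[!x$coi] <- NA
  tt <- (seq_len(ncol(z)) - 1) / x$fs
  image(tt, log2(x$grid$frequencies), t(z), ylab = "log2 frequency (Hz)",
        xlab = "time (s)", zlim = c(0, 1), ...)
  invisible(x)
}

#' Wavelet transform coherence of two series
#'
#' Squared wavelet coherence following the standard smoothed-cross-spectrum
#' formulation: `R2 = |S(W_xy / s)|^2 / (S(|W_x|^2 / s) S(|W_y|^2 / s))`
#' where `S` smooths with a Gaussian of SD equal to the scale in time and a
#' boxcar spanning 0.6 scale decorrelation lengths across scales. Values
#' are clipped to [0, 1]; cells outside the cone of influence are flagged
#' by the `coi` mask (TRUE = valid).
#'
#' @param x,y equal-length numeric series.
#' @param fs sampling rate in Hz.
#' @param grid a [band_grid()].
#' @param omega0 Morlet wavenumber.
#' @return A `wtc_map`: list with `coherence` (band x time, in \[0, 1\]),
#'   `coi` (logical band x time, TRUE inside the cone of influence), `fs`,
#'   `grid`.
#' @export
wtc <- function(x, y, fs, grid = band_grid(), omega0 = 6) {
  if (length(x) != length(y))
    stop("wtc: series lengths differ (", length(x), " vs ", length(y), ")")
  cx <- cwt_morlet(x, fs, grid, omega0)
  cy <- cwt_morlet(y, fs, grid, omega0)
  wtc_from_cwt(cx, cy)
}

# WTC from two precomputed CWTs (shared backend; lets callers cache the
# per-channel transforms and smoothed autospectra across many pairs).
wtc_from_cwt <- function(cx, cy, Sxx = NULL, Syy = NULL) {
  scales <- cx$scales
  fs <- cx$fs
  spo <- cx$grid$steps_per_octave
  inv_s <- 1 / scales
  if (is.null(Sxx)) Sxx <- wtc_smooth(Mod(cx$W)^2 * inv_s, scales, fs, spo)
  if (is.null(Syy)) Syy <- wtc_smooth(Mod(cy$W)^2 * inv_s, scales, fs, spo)
  Sxy <- wtc_smooth(cx$W * Conj(cy$W) * inv_s, scales, fs, spo)
  R2 <- Mod(Sxy)^2 / (Sxx * Syy)
  R2[R2 < 0] <- 0
  R2[R2 > 1] <- 1
  new_wtc_map(R2, coi_mask(scales, cx$coi_s), fs, cx$grid)
}

# smoothed autospectrum of one precomputed CWT (for caching)
smoothed_autospectrum <- function(cw) {
  wtc_smooth(Mod(cw$W)^2 / cw$scales, cw$scales, cw$fs,
             cw$grid$steps_per_octave)
}

#' Per-band mean coherence inside the cone of influence
#'
#' Averages each frequency band of a `wtc_map` over the time samples inside
#' the cone of influence only. A band with no valid sample is `NA`, never
#' zero, and is excluded from downstream group statistics.
#'
#' @param map a `wtc_map`.
#' @return numeric vector, one mean per band (NA where fully masked).
#' @export
band_mean_wtc <- function(map) {
  stopifnot(inherits(map, "wtc_map"))
  K <- nrow(map$coherence)
  out <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    v <- map$coherence[k, map$coi[k, ]]
    if (length(v) > 0) out[k] <- mean(v)
  }
  out
}

#' Enumerate channel pairs of a dyad
#'
#' For `n` channels per participant the between-brain family contains `n`
#' identical pairs (i, i) and `n (n - 1) / 2` unordered different pairs
#' \{i, j\}; the within-brain family contains only the different pairs.
#' With the standard 20-channel montage this gives 20 + 190 = 210
#' between-brain and 190 within-brain pairs.
#'
#' @param n_channels channels per participant.
#' @return An object of class `pair_set`: list with data.frames
#'   `identical_pairs` and `different_pairs` (columns `a`, `b`, a <= b).
#' @export
enumerate_pairs <- function(n_channels) {
  if (n_channels < 1) stop("enumerate_pairs: need at least one channel")
  idp <- data.frame(a = seq_len(n_channels), b = seq_len(n_channels))
  if (n_channels > 1) {
    cmb <- utils::combn(n_channels, 2)
    dfp <- data.frame(a = cmb[1, ], b = cmb[2, ])
  } else {
    dfp <- data.frame(a = integer(0), b = integer(0))
  }
  structure(list(identical_pairs = idp, different_pairs = dfp),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d identical + %d different = %d pairs\n",
              nrow(x$identical_pairs), nrow(x$different_pairs),
              nrow(x$identical_pairs) + nrow(x$different_pairs)))
  invisible(x)
}

# all pairs of a pair_set as one data.frame with a kind column
pairs_table <- function(ps) {
  rbind(
    if (nrow(ps$identical_pairs)) cbind(ps$identical_pairs, kind = "identical"),
    if (nrow(ps$different_pairs)) cbind(ps$different_pairs, kind = "different")
  )
}

#' Coherence map for one channel pair of a dyad
#'
#' Between-brain mode: for an identical pair (i, i) this is WTC(A_i, B_i);
#' for a different pair \{i, j\} both orientations WTC(A_i, B_j) and
#' WTC(A_j, B_i) are computed and, under the default policy, their
#' coherence matrices are averaged into one unordered-pair map. Within-brain
#' mode computes WTC(A_i, A_j) inside participant A only.
#'
#' @param hb_a,hb_b [hb_series] of the two participants (aligned; `hb_b`
#'   ignored in within-brain mode).
#' @param pair integer vector (i, j).
#' @param chromophore "oxy" or "deoxy".
#' @param mode "between" or "within".
#' @param orientation_policy "average" (default) or "keep_both"; with
#'   "keep_both" a list of the two orientation maps is returned.
#' @param grid,omega0 passed to [wtc()].
#' @return a `wtc_map`, or a list of two for `orientation_policy =
#'   "keep_both"` on a different pair.
#' @export
wtc_for_pair <- function(hb_a, hb_b = NULL, pair, chromophore = "oxy",
                         mode = c("between", "within"),
                         orientation_policy = c("average", "keep_both"),
                         grid = band_grid(), omega0 = 6) {
  mode <- match.arg(mode)
  orientation_policy <- match.arg(orientation_policy)
  i <- pair[1]; j <- pair[2]
  if (mode == "within") {
    if (i == j) stop("wtc_for_pair: within-brain pairs must differ")
    m <- wtc(hb_a$data[[chromophore]][, i], hb_a$data[[chromophore]][, j],
             hb_a$fs, grid, omega0)
    m$pair <- c(i, j)
    return(m)
  }
  stopifnot(inherits(hb_b, "hb_series"))
  if (hb_a$fs != hb_b$fs ||
      nrow(hb_a$data[[chromophore]]) != nrow(hb_b$data[[chromophore]]))
    stop("wtc_for_pair: participants' series are not aligned")
  m1 <- wtc(hb_a$data[[chromophore]][, i], hb_b$data[[chromophore]][, j],
            hb_a$fs, grid, omega0)
  m1$pair <- c(i, j)
  if (i == j) return(m1)
  m2 <- wtc(hb_a$data[[chromophore]][, j], hb_b$data[[chromophore]][, i],
            hb_a$fs, grid, omega0)
  m2$pair <- c(j, i)
  if (orientation_policy == "keep_both") return(list(m1, m2))
  avg <- m1
  avg$coherence <- (m1$coherence + m2$coherence) / 2
  avg$coi <- m1$coi & m2$coi
  avg$pair <- sort(c(i, j))
  avg
}

# cwt_morlet with the short-record COI warning muffled (batch callers
# report record length once at a higher level)
cwt_quiet <- function(...) {
  withCallingHandlers(cwt_morlet(...), warning = function(w) {
    if (grepl("e-folding", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Band-mean WTC for every pair of a dyad session, with per-channel CWT and
# autospectrum caching. Returns a matrix (pairs x bands); row order follows
# pairs_table(enumerate_pairs(n_used)) restricted to `channels`.
# mode "between": unordered different pairs average both orientations.
session_band_means <- function(hb_a, hb_b = NULL, channels = NULL,
                               chromophore = "oxy",
                               mode = c("between", "within"),
                               grid = band_grid(), omega0 = 6) {
  mode <- match.arg(mode)
  X <- hb_a$data[[chromophore]]
  if (is.null(channels)) channels <- seq_len(ncol(X))
  fs <- hb_a$fs
  cw_a <- lapply(channels, function(ch) cwt_quiet(X[, ch], fs, grid, omega0))
  Sa <- lapply(cw_a, smoothed_autospectrum)
  if (mode == "between") {
    Y <- hb_b$data[[chromophore]]
    cw_b <- lapply(channels, function(ch) cwt_quiet(Y[, ch], fs, grid, omega0))
    Sb <- lapply(cw_b, smoothed_autospectrum)
  }
  ps <- enumerate_pairs(length(channels))
  pt <- if (mode == "between") pairs_table(ps) else
    cbind(ps$different_pairs, kind = "different")
  bm <- matrix(NA_real_, nrow(pt), length(grid$frequencies))
  for (r in seq_len(nrow(pt))) {
    i <- pt$a[r]; j <- pt$b[r]
    if (mode == "within") {
      m <- wtc_from_cwt(cw_a[[i]], cw_a[[j]], Sa[[i]], Sa[[j]])
    } else if (i == j) {
      m <- wtc_from_cwt(cw_a[[i]], cw_b[[i]], Sa[[i]], Sb[[i]])
    } else {
      m1 <- wtc_from_cwt(cw_a[[i]], cw_b[[j]], Sa[[i]], Sb[[j]])
      m2 <- wtc_from_cwt(cw_a[[j]], cw_b[[i]], Sa[[j]], Sb[[i]])
      m1$coherence <- (m1$coherence + m2$coherence) / 2
      m1$coi <- m1$coi & m2$coi
      m <- m1
    }
    bm[r, ] <- band_mean_wtc(m)
  }
  attr(bm, "pairs") <- data.frame(a = channels[pt$a], b = channels[pt$b],
                                  kind = pt$kind)
  attr(bm, "frequencies") <- grid$frequencies
  bm
}
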