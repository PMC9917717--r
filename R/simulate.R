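# run expr under a temporary RNG state seeded with `seed` (NULL = leave
# the global stream alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parameters of the dyadic fNIRS simulator
#'
#' Defines one simulated hyperscanning session: channel montage, sampling
#' rates, session length, which channel pairs carry injected narrow-band
#' coupling, how behavioral events are generated, and the noise model.
#' The hemoglobin background is 1/f-shaped noise plus white noise; the
#' functional component has negatively proportional oxy/deoxy
#' (`deoxy = k_f oxy`) and the shared systemic component positively
#' proportional (`deoxy = k_s oxy`), so hemodynamic modality separation is
#' exercised by construction.
#'
#' @param n_channels channels per participant (default 20).
#' @param fs_hb hemoglobin sampling rate, Hz (default 10).
#' @param fs_pose head-pose frame rate, Hz (default 29.97).
#' @param duration session length in seconds.
#' @param coupling_pairs data.frame with columns `a`, `b` (channel of
#'   participant A / B), `freq_hz`, `amplitude`: each row injects a shared
#'   narrow-band oscillation (drifting-phase sinusoid) into A's channel `a`
#'   and B's channel `b`.
#' @param lock when the coupling is active: `"always"`, `"both"` (only
#'   during both-up events) or `"either"` (only while exactly one
#'   participant is face-up).
#' @param event_rate_per_min dyad-level behavioral event rate (default 1
#'   per minute which, with 3 s events, puts each participant's face-up
#'   coverage near the few-percent range typical of naturalistic play).
#' @param event_dur_mean_s,event_dur_sd_s event duration distribution
#'   (normal, truncated below at 0.5 s).
#' @param p_both probability an event is both-up (else one participant).
#' @param excursion_sd pitch excursion amplitude during face-up events, in
#'   units of the baseline pitch SD.
#' @param response_delay_s hemodynamic delay-of-peak emulation: injected
#'   coupling lags the behavioral epochs by this many seconds (default 5;
#'   irrelevant in `"always"` mode).
#' @param systemic_amplitude strength of the shared systemic component.
#' @param noise_exponent spectral exponent of the 1/f background.
#' @param noise_sd SD of the additive white-noise floor.
#' @param k_f,k_s deoxy/oxy ratios of the functional and systemic parts.
#' @param seed RNG seed (NULL = use the current stream).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_channels = 20, fs_hb = 10, fs_pose = 29.97,
                       duration = 300,
                       coupling_pairs = data.frame(a = integer(0),
                                                   b = integer(0),
                                                   freq_hz = numeric(0),
                                                   amplitude = numeric(0)),
                       lock = c("always", "both", "either"),
                       event_rate_per_min = 1, event_dur_mean_s = 3,
                       event_dur_sd_s = 1, p_both = 0.3,
                       excursion_sd = 5, response_delay_s = 5,
                       systemic_amplitude = 0.5, noise_exponent = 1,
                       noise_sd = 0.5, k_f = -0.6, k_s = 0.5, seed = NULL) {
  lock <- match.arg(lock)
  if (duration < 0) stop("sim_params: duration must be non-negative")
  if (fs_hb <= 0 || fs_pose <= 0) stop("sim_params: rates must be positive")
  if (nrow(coupling_pairs) > 0) {
    if (any(coupling_pairs$amplitude < 0))
      stop("sim_params: coupling amplitudes must be non-negative")
    if (fs_hb <= 2 * max(coupling_pairs$freq_hz))
      stop("sim_params: fs_hb must exceed twice the highest coupling ",
           "frequency")
    if (any(coupling_pairs$a > n_channels | coupling_pairs$b > n_channels))
      stop("sim_params: coupling pair channel outside the montage")
  }
  if (systemic_amplitude < 0 || noise_sd < 0 || excursion_sd < 0)
    stop("sim_params: amplitudes must be non-negative")
  structure(list(n_channels = n_channels, fs_hb = fs_hb, fs_pose = fs_pose,
                 duration = duration, coupling_pairs = coupling_pairs,
                 lock = lock, event_rate_per_min = event_rate_per_min,
                 event_dur_mean_s = event_dur_mean_s,
                 event_dur_sd_s = event_dur_sd_s, p_both = p_both,
                 excursion_sd = excursion_sd,
                 response_delay_s = response_delay_s,
                 systemic_amplitude = systemic_amplitude,
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 k_f = k_f, k_s = k_s, seed = seed),
            class = "sim_params")
}

# 1/f^(exponent/2 in amplitude) spectrally shaped Gaussian noise, unit SD
colored_noise <- function(n, exponent) {
  if (n == 0) return(numeric(0))
  if (exponent == 0) return(stats::rnorm(n))
  npad <- next_pow2(n)
  w <- stats::rnorm(npad)
  wf <- stats::fft(w)
  k <- c(1, seq_len(npad - 1))            # avoid DC blow-up
  shape <- k^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(wf * shape, inverse = TRUE))[seq_len(n)] / npad
  s <- stats::sd(x)
  if (s == 0) rep(0, n) else (x - mean(x)) / s
}

# sequential non-overlapping dyad events: exponential gaps, truncated
# normal durations, label both_up / self_up_A / self_up_B
generate_events <- function(duration, rate_per_min, dur_mean, dur_sd,
                            p_both) {
  onset <- offset <- numeric(0)
  label <- character(0)
  t <- 0
  rate_s <- rate_per_min / 60
  if (rate_s <= 0) {
    return(data.frame(onset_s = onset, offset_s = offset, label = label,
                      stringsAsFactors = FALSE))
  }
  repeat {
    t <- t + stats::rexp(1, rate_s)
    d <- max(0.5, stats::rnorm(1, dur_mean, dur_sd))
    if (t + d >= duration) break
    onset <- c(onset, t)
    offset <- c(offset, t + d)
    u <- stats::runif(1)
    label <- c(label, if (u < p_both) "both_up"
               else if (u < p_both + (1 - p_both) / 2) "self_up_A"
               else "self_up_B")
    t <- t + d
  }
  data.frame(onset_s = onset, offset_s = offset, label = label,
             stringsAsFactors = FALSE)
}

# binary mask at rate fs from epochs (data.frame onset_s / offset_s)
epochs_to_mask <- function(epochs, n, fs) {
  m <- logical(n)
  if (is.null(epochs) || nrow(epochs) == 0) return(m)
  tt <- (seq_len(n) - 1) / fs
  for (r in seq_len(nrow(epochs)))
    m <- m | (tt >= epochs$onset_s[r] & tt < epochs$offset_s[r])
  m
}

# 1 s raised-cosine on/off ramps applied to a binary gate
ramp_gate <- function(mask, fs, ramp_s = 1) {
  w <- max(1, round(ramp_s * fs))
  kern <- 0.5 * (1 - cos(pi * seq_len(w) / (w + 1)))
  kern <- c(kern, rev(kern))
  kern <- kern / sum(kern)
  g <- stats::filter(as.numeric(mask), kern, sides = 2)
  g[is.na(g)] <- 0
  as.numeric(g)
}

#' Simulate one dyadic hyperscanning session
#'
#' Generates the two participants' oxy/deoxy series. Channels listed in
#' `coupling_pairs` share a narrow-band drifting-phase sinusoid during the
#' epochs dictated by the lock mode; a common systemic component (oxy and
#' deoxy positively proportional) is added to all channels of a
#' participant, while the functional part has negatively proportional
#' oxy/deoxy.
#'
#' @param params a [sim_params()].
#' @param condition condition tag stored in the output series.
#' @param dyad_id identifier used for participant/session ids.
#' @return list with `A`, `B` ([hb_series]) and `ground_truth` (list:
#'   `events` data.frame, `coupling_pairs`, `lock`, per-participant up
#'   epochs `up_A`, `up_B`).
#' @export
simulate_dyad <- function(params, condition = "COOP", dyad_id = "dyad1") {
  stopifnot(inherits(params, "sim_params"))
  if (params$duration <= 0)
    stop("simulate_dyad: duration must be positive")
  with_seed(params$seed, {
    n <- round(params$duration * params$fs_hb)
    nc <- params$n_channels
    events <- generate_events(params$duration, params$event_rate_per_min,
                              params$event_dur_mean_s, params$event_dur_sd_s,
                              params$p_both)
    gate_epochs <- switch(params$lock,
      always = data.frame(onset_s = 0, offset_s = params$duration),
      both = events[events$label == "both_up", , drop = FALSE],
      either = events[events$label != "both_up", , drop = FALSE])
    if (params$lock != "always" && nrow(gate_epochs) > 0) {
      # vascular response lags the behavioral event
      gate_epochs$onset_s <- gate_epochs$onset_s + params$response_delay_s
      gate_epochs$offset_s <- pmin(gate_epochs$offset_s +
                                     params$response_delay_s,
                                   params$duration)
      gate_epochs <- gate_epochs[gate_epochs$onset_s < params$duration, ,
                                 drop = FALSE]
    }
    gate <- ramp_gate(epochs_to_mask(gate_epochs, n, params$fs_hb),
                      params$fs_hb)
    tt <- (seq_len(n) - 1) / params$fs_hb
    mk_func <- function() {
      F <- matrix(0, n, nc)
      for (j in seq_len(nc))
        F[, j] <- colored_noise(n, params$noise_exponent) +
          params$noise_sd * stats::rnorm(n)
      F
    }
    F_a <- mk_func(); F_b <- mk_func()
    cp <- params$coupling_pairs
    if (nrow(cp) > 0) {
      for (r in seq_len(nrow(cp))) {
        drift <- cumsum(stats::rnorm(n, 0, 0.02))
        shared <- cos(2 * pi * cp$freq_hz[r] * tt + drift)
        F_a[, cp$a[r]] <- F_a[, cp$a[r]] + cp$amplitude[r] * gate * shared
        F_b[, cp$b[r]] <- F_b[, cp$b[r]] + cp$amplitude[r] * gate * shared
      }
    }
    mk_series <- function(F, pid) {
      S <- params$systemic_amplitude * colored_noise(n, params$noise_exponent)
      oxy <- F + S
      deoxy <- params$k_f * F + params$k_s * S
      hb_series(oxy, deoxy, params$fs_hb, participant_id = pid,
                session_id = paste0(dyad_id, "_", condition),
                condition = condition)
    }
    up_A <- events[events$label %in% c("both_up", "self_up_A"), 1:2]
    up_B <- events[events$label %in% c("both_up", "self_up_B"), 1:2]
    list(A = mk_series(F_a, paste0(dyad_id, "_A")),
         B = mk_series(F_b, paste0(dyad_id, "_B")),
         ground_truth = list(events = events,
                             coupling_pairs = cp, lock = params$lock,
                             up_A = up_A, up_B = up_B))
  })
}

#' Simulate a head-pose pitch trace with face-up excursions
#'
#' Gaussian baseline pitch noise at the video frame rate with positive
#' excursions of `excursion_sd` baseline-SD amplitude exactly during the
#' requested epochs.
#'
#' @param params a [sim_params()] (uses `fs_pose`, `duration`,
#'   `excursion_sd`, `seed`).
#' @param epochs data.frame with `onset_s`, `offset_s` (may be empty); all
#'   epochs must lie inside `[0, duration]` with onset < offset.
#' @param participant_id identifier.
#' @return a [pose_series]; ground-truth mask in attribute `up_mask`.
#' @export
simulate_pose <- function(params, epochs = NULL,
                          participant_id = NA_character_) {
  stopifnot(inherits(params, "sim_params"))
  n <- round(params$duration * params$fs_pose)
  if (!is.null(epochs) && nrow(epochs) > 0) {
    if (any(epochs$onset_s < 0 | epochs$offset_s > params$duration |
            epochs$onset_s >= epochs$offset_s))
      stop("simulate_pose: malformed epochs (outside [0, duration] or ",
           "onset >= offset)")
  }
  with_seed(params$seed, {
    pitch <- stats::rnorm(n)
    mask <- epochs_to_mask(epochs, n, params$fs_pose)
    pitch[mask] <- pitch[mask] + params$excursion_sd
    ps <- pose_series(pitch, params$fs_pose,
                      participant_id = participant_id)
    attr(ps, "up_mask") <- mask
    ps
  })
}
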