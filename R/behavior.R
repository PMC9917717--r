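#' Z-score a pitch trace
#'
#' Standardizes the pitch angle over the valid samples of the session so
#' the face-up threshold ignores between-participant differences in
#' absolute face height. Invalid samples are excluded from the moments and
#' stay invalid (NA) in the output.
#'
#' @param pose a [pose_series] with at least 30 s of valid samples.
#' @return numeric z-score series (NA at invalid samples) with attribute
#'   `fs`.
#' @export
zscore_pitch <- function(pose) {
  stopifnot(inherits(pose, "pose_series"))
  v <- pose$valid & is.finite(pose$pitch)
  if (sum(v) < 30 * pose$fs)
    stop("zscore_pitch: fewer than 30 s of valid samples")
  mu <- mean(pose$pitch[v])
  sdv <- stats::sd(pose$pitch[v])
  if (!is.finite(sdv) || sdv < 1e-12)
    stop("zscore_pitch: pitch variance is zero (degenerate input)")
  z <- rep(NA_real_, length(pose$pitch))
  z[v] <- (pose$pitch[v] - mu) / sdv
  attr(z, "fs") <- pose$fs
  z
}

#' Classify face-up samples by thresholding the z-scored pitch
#'
#' A sample is face-up when its z-scored pitch exceeds the threshold in
#' the face-raising direction (2 SD by default, the strict criterion that
#' selects roughly the upper 2.3% tail of Gaussian pitch noise). Invalid
#' samples are never face-up.
#'
#' @param z z-score series from [zscore_pitch()].
#' @param threshold detection threshold in SD units (default 2).
#' @param direction `"positive"` if raising the face increases pitch,
#'   `"negative"` for the opposite camera convention.
#' @return logical track, TRUE = face-up; attribute `fs` forwarded.
#' @export
detect_face_up <- function(z, threshold = 2,
                           direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  zz <- if (direction == "positive") z else -z
  up <- !is.na(zz) & zz > threshold
  attr(up, "fs") <- attr(z, "fs")
  up
}

# bridge sub-threshold gaps, then drop sub-minimum runs
clean_track <- function(up, fs, min_duration_s, merge_gap_s) {
  x <- up
  if (merge_gap_s > 0 && any(x)) {
    r <- rle(x)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    inner <- which(!r$values & seq_along(r$values) > 1 &
                     seq_along(r$values) < length(r$values))
    for (g in inner)
      if (r$lengths[g] < merge_gap_s * fs) x[starts[g]:ends[g]] <- TRUE
  }
  if (min_duration_s > 0 && any(x)) {
    r <- rle(x)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (g in which(r$values))
      if (r$lengths[g] < min_duration_s * fs) x[starts[g]:ends[g]] <- FALSE
  }
  x
}

mask_to_epochs <- function(mask, fs, label) {
  if (!any(mask))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(onset_s = (starts[keep] - 1) / fs,
             offset_s = ends[keep] / fs,
             label = label, stringsAsFactors = FALSE)
}

#' Label dyadic face-up events
#'
#' Combines the two participants' face-up tracks into the mutually
#' exclusive dyad-level labels: `both_up` (A and B up), `self_up_A` (only
#' A up, which is `other_up` from B's perspective) and `self_up_B`. Each
#' participant's track is first cleaned: gaps shorter than `merge_gap_s`
#' are bridged, then runs shorter than `min_duration_s` are dropped
#' (defaults suppress single-frame tracker jitter; set both to 0 to
#' disable).
#'
#' @param up_a,up_b logical face-up tracks from [detect_face_up()], equal
#'   length and rate.
#' @param fs track rate in Hz (taken from the `fs` attribute if absent).
#' @param min_duration_s minimum event duration kept (default 0.3).
#' @param merge_gap_s maximum gap bridged inside an event (default 0.2).
#' @return object of class `event_tracks`: list with `fs`, cleaned `up_A`,
#'   `up_B`, the label tracks `both_up`, `self_up_A`, `self_up_B`, and an
#'   `events` data.frame (onset_s, offset_s, label).
#' @export
label_events <- function(up_a, up_b, fs = NULL, min_duration_s = 0.3,
                         merge_gap_s = 0.2) {
  if (is.null(fs)) fs <- attr(up_a, "fs")
  fs_b <- attr(up_b, "fs")
  if (!is.null(fs_b) && !is.null(fs) && abs(fs_b - fs) > 1e-9)
    stop("label_events: track rates differ")
  if (length(up_a) != length(up_b))
    stop("label_events: track lengths differ")
  if (is.null(fs)) stop("label_events: fs unknown")
  A <- clean_track(as.logical(up_a), fs, min_duration_s, merge_gap_s)
  B <- clean_track(as.logical(up_b), fs, min_duration_s, merge_gap_s)
  both <- A & B
  self_a <- A & !B
  self_b <- B & !A
  ev <- rbind(mask_to_epochs(both, fs, "both_up"),
              mask_to_epochs(self_a, fs, "self_up_A"),
              mask_to_epochs(self_b, fs, "self_up_B"))
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(fs = fs, up_A = A, up_B = B, both_up = both,
                 self_up_A = self_a, self_up_B = self_b, events = ev),
            class = "event_tracks")
}

#' @export
print.event_tracks <- function(x, ...) {
  n <- length(x$both_up)
  cat(sprintf(
    "<event_tracks> %.1f s at %g Hz: %d both-up, %d self-up-A, %d self-up-B events\n",
    n / x$fs, x$fs, sum(x$events$label == "both_up"),
    sum(x$events$label == "self_up_A"), sum(x$events$label == "self_up_B")))
  invisible(x)
}

#' Build the event-related design matrix for the coherence GLM
#'
#' Resamples the boxcar regressors (`both_up`, `self_up`, `other_up` from
#' the chosen participant's perspective, plus a constant column) from the
#' video frame rate to the coherence sampling rate by nearest-sample
#' selection, and shifts the regressors forward by `delay_s` seconds to
#' account for the delay-of-peak of the hemodynamic response (a regressor
#' at output time t reads the behavioral track at t - delay). Output rows
#' whose shifted time falls before the session start or past the end of
#' the behavioral record are dropped from both sides of the regression;
#' `y_index` maps the remaining rows onto the coherence time base.
#'
#' @param events an `event_tracks` from [label_events()].
#' @param n_y length of the coherence series the design must align to.
#' @param target_fs coherence sampling rate (default 10 Hz).
#' @param delay_s delay-of-peak adjustment (default 5 s).
#' @param orientation `"A"` (self = A's solo events) or `"B"`.
#' @return list with `X` (matrix: columns `constant`, `both_up`,
#'   `self_up`, `other_up`) and `y_index` (integer rows of the coherence
#'   series the rows of `X` correspond to). Regressors that end up all
#'   zero are reported in attribute `empty_regressors`.
#' @export
build_design <- function(events, n_y, target_fs = 10, delay_s = 5,
                         orientation = c("A", "B")) {
  stopifnot(inherits(events, "event_tracks"))
  orientation <- match.arg(orientation)
  self <- if (orientation == "A") events$self_up_A else events$self_up_B
  other <- if (orientation == "A") events$self_up_B else events$self_up_A
  n_pose <- length(events$both_up)
  t_y <- (seq_len(n_y) - 1) / target_fs
  t_src <- t_y - delay_s
  src_idx <- round(t_src * events$fs) + 1
  keep <- src_idx >= 1 & src_idx <= n_pose
  src_idx <- src_idx[keep]
  X <- cbind(constant = 1,
             both_up = as.numeric(events$both_up[src_idx]),
             self_up = as.numeric(self[src_idx]),
             other_up = as.numeric(other[src_idx]))
  empty <- colnames(X)[-1][colSums(X[, -1, drop = FALSE]) == 0]
  structure(list(X = X, y_index = which(keep)),
            empty_regressors = empty)
}
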