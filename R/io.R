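#' Multichannel hemoglobin time series for one participant
#'
#' The substrate of all coherence computation: oxy- and deoxy-Hb
#' concentration-change matrices (time x channel) sampled at a fixed rate,
#' with participant/session/condition metadata. Sample `k` (0-based) lives
#' at time `k / fs` seconds from session start.
#'
#' @param oxy,deoxy numeric matrices time x channel, identical shape.
#' @param fs sampling rate in Hz (10 for the standard montage).
#' @param participant_id,session_id identifier strings.
#' @param condition task condition, `"COOP"` or `"IND"` (or NA).
#' @param channel_ids ordered channel identifiers (default 1..n).
#' @return object of class `hb_series`.
#' @export
hb_series <- function(oxy, deoxy, fs, participant_id = NA_character_,
                      session_id = NA_character_, condition = NA_character_,
                      channel_ids = NULL) {
  oxy <- as.matrix(oxy); deoxy <- as.matrix(deoxy)
  if (!all(dim(oxy) == dim(deoxy)))
    stop("hb_series: oxy and deoxy matrices must share one shape")
  if (!is.numeric(fs) || fs <= 0) stop("hb_series: fs must be positive")
  if (!is.na(condition) && !condition %in% c("COOP", "IND"))
    stop("hb_series: condition must be COOP or IND")
  if (is.null(channel_ids)) channel_ids <- seq_len(ncol(oxy))
  if (length(channel_ids) != ncol(oxy))
    stop("hb_series: channel_ids length does not match channel count")
  colnames(oxy) <- colnames(deoxy) <- paste0("ch", channel_ids)
  structure(list(data = list(oxy = oxy, deoxy = deoxy), fs = fs,
                 participant_id = participant_id, session_id = session_id,
                 condition = condition, channel_ids = channel_ids),
            class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf(
    "<hb_series> %s/%s [%s]: %d channels x %d samples at %g Hz (%.1f s)\n",
    x$participant_id, x$session_id, x$condition, ncol(x$data$oxy),
    nrow(x$data$oxy), x$fs, nrow(x$data$oxy) / x$fs))
  invisible(x)
}

#' Head-pose pitch series for one participant
#'
#' Pitch angle (radians, OpenFace world-coordinate convention) per video
#' frame, with a per-sample validity flag for tracking failures.
#'
#' @param pitch numeric vector, radians.
#' @param fs frame rate in Hz (29.97 for NTSC video).
#' @param valid logical vector; FALSE marks unusable (untracked) frames.
#' @param participant_id identifier.
#' @param timestamp optional explicit per-frame times (seconds).
#' @return object of class `pose_series`.
#' @export
pose_series <- function(pitch, fs, valid = NULL,
                        participant_id = NA_character_, timestamp = NULL) {
  n <- length(pitch)
  if (is.null(valid)) valid <- !is.na(pitch)
  if (length(valid) != n) stop("pose_series: valid flag length mismatch")
  if (is.null(timestamp)) timestamp <- (seq_len(n) - 1) / fs
  if (n > 1) {
    if (any(diff(timestamp) <= 0))
      stop("pose_series: timestamps must increase monotonically")
    fs_obs <- (n - 1) / (timestamp[n] - timestamp[1])
    if (abs(fs_obs - fs) > 0.01 * fs)
      stop(sprintf(
        "pose_series: declared fs %g Hz inconsistent with timestamps (%.3f Hz)",
        fs, fs_obs))
  }
  structure(list(pitch = pitch, fs = fs, valid = valid,
                 participant_id = participant_id, timestamp = timestamp,
                 frame = seq_len(n) - 1L),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> %s: %d frames at %g Hz (%.1f s), %d invalid\n",
              x$participant_id, length(x$pitch), x$fs,
              length(x$pitch) / x$fs, sum(!x$valid)))
  invisible(x)
}

# ---- native Hb table (TSV with '# key: value' front matter) --------------

#' Write an hb_series to the native delimited table format
#'
#' TSV with a `# key: value` front-matter header (fs, participant_id,
#' session_id, condition, channel_ids) followed by one `time_s` column and
#' one column per channel per chromophore (`oxy_ch*`, `deoxy_ch*`).
#'
#' @param hb an [hb_series].
#' @param path output file.
#' @param digits significant digits written (default 10).
#' @export
write_hb_table <- function(hb, path, digits = 10) {
  stopifnot(inherits(hb, "hb_series"))
  hdr <- c(
    paste0("# fs: ", format(hb$fs, digits = 12)),
    paste0("# participant_id: ", hb$participant_id),
    paste0("# session_id: ", hb$session_id),
    paste0("# condition: ", hb$condition),
    paste0("# channel_ids: ", paste(hb$channel_ids, collapse = ",")))
  n <- nrow(hb$data$oxy)
  df <- data.frame(time_s = (seq_len(n) - 1) / hb$fs)
  for (chrom in c("oxy", "deoxy")) {
    M <- hb$data[[chrom]]
    colnames(M) <- paste0(chrom, "_ch", hb$channel_ids)
    df <- cbind(df, M)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df[] <- lapply(df, function(v) signif(v, digits))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_front_matter <- function(path) {
  lines <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, 1)
    if (length(l) == 0 || !startsWith(l, "#")) break
    lines <- c(lines, l)
  }
  kv <- sub("^#\\s*", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  stats::setNames(as.list(vals), keys)
}

#' Read an hb_series from the native table format
#'
#' Validates the header, the presence of every declared channel column for
#' both chromophores, and data quality: a NaN run longer than one second in
#' any channel raises an error naming the channel.
#'
#' @param path file written by [write_hb_table()].
#' @return an [hb_series].
#' @export
read_hb_table <- function(path) {
  if (!file.exists(path)) stop("read_hb_table: no such file: ", path)
  hdr <- parse_front_matter(path)
  for (k in c("fs", "participant_id", "channel_ids"))
    if (is.null(hdr[[k]]))
      stop("read_hb_table: header is missing required key '", k, "'")
  fs <- as.numeric(hdr$fs)
  ch <- as.integer(strsplit(hdr$channel_ids, ",")[[1]])
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  mats <- list()
  for (chrom in c("oxy", "deoxy")) {
    want <- paste0(chrom, "_ch", ch)
    missing <- setdiff(want, names(df))
    if (length(missing) > 0)
      stop("read_hb_table: missing ", chrom, " channel column(s): ",
           paste(missing, collapse = ", "))
    mats[[chrom]] <- as.matrix(df[, want])
  }
  # data-quality screen: NaN runs longer than 1 s
  bad <- character(0)
  for (chrom in c("oxy", "deoxy")) {
    for (j in seq_len(ncol(mats[[chrom]]))) {
      r <- rle(!is.finite(mats[[chrom]][, j]))
      if (any(r$values & r$lengths > fs))
        bad <- c(bad, colnames(mats[[chrom]])[j])
    }
  }
  if (length(bad) > 0)
    stop("read_hb_table: NaN run longer than 1 s in channel(s): ",
         paste(bad, collapse = ", "))
  cond <- hdr$condition
  if (is.null(cond) || cond %in% c("NA", "")) cond <- NA_character_
  hb_series(mats$oxy, mats$deoxy, fs,
            participant_id = hdr$participant_id,
            session_id = if (is.null(hdr$session_id)) NA_character_
                         else hdr$session_id,
            condition = cond, channel_ids = ch)
}

# ---- OpenFace-style pose CSV ---------------------------------------------

#' Write a pose_series as an OpenFace-style CSV
#'
#' Columns: `frame`, `timestamp`, `success`, `pose_Rx` (pitch, radians).
#' Invalid samples are written with `success = 0`.
#'
#' @param pose a [pose_series].
#' @param path output file.
#' @export
write_pose_csv <- function(pose, path) {
  stopifnot(inherits(pose, "pose_series"))
  df <- data.frame(frame = pose$frame,
                   timestamp = signif(pose$timestamp, 10),
                   success = as.integer(pose$valid),
                   pose_Rx = signif(pose$pitch, 10))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a head-pose pitch trace from an OpenFace-style CSV
#'
#' Extracts the `pose_Rx` (pitch) column in radians. Frames with failed
#' tracking (`success == 0`, or non-finite pitch) are linearly interpolated
#' when the gap is at most `max_gap_s` seconds; longer gaps are marked
#' invalid and excluded from downstream z-scoring.
#'
#' @param path CSV with an OpenFace-style header (`frame`, `timestamp`,
#'   `pose_Rx`; `success` optional).
#' @param max_gap_s longest tracking gap bridged by interpolation (0.5 s).
#' @return a [pose_series].
#' @export
read_pose_csv <- function(path, max_gap_s = 0.5) {
  if (!file.exists(path)) stop("read_pose_csv: no such file: ", path)
  df <- utils::read.csv(path, check.names = TRUE)
  names(df) <- trimws(names(df))
  if (!"pose_Rx" %in% names(df))
    stop("read_pose_csv: no pose_Rx (pitch) column in ", path)
  pitch <- as.numeric(df$pose_Rx)
  ok <- is.finite(pitch)
  if ("success" %in% names(df)) ok <- ok & df$success != 0
  ts <- if ("timestamp" %in% names(df)) as.numeric(df$timestamp)
        else (seq_along(pitch) - 1) / 29.97
  n <- length(pitch)
  fs <- if (n > 1) (n - 1) / (ts[n] - ts[1]) else 29.97
  valid <- ok
  if (any(!ok) && any(ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    interp <- stats::approx(which(ok), pitch[ok], xout = seq_len(n),
                            rule = 1)$y
    for (g in which(!r$values)) {
      idx <- starts[g]:ends[g]
      gap_s <- r$lengths[g] / fs
      if (gap_s <= max_gap_s && !anyNA(interp[idx])) {
        pitch[idx] <- interp[idx]
        valid[idx] <- TRUE
      } else {
        valid[idx] <- FALSE
      }
    }
  }
  pose_series(pitch, fs, valid = valid, timestamp = ts)
}

# ---- event and results tables --------------------------------------------

#' Write an event table (onset_s, offset_s, label) as TSV
#' @param events data.frame with columns onset_s, offset_s, label.
#' @param path output file.
#' @export
write_event_tsv <- function(events, path) {
  stopifnot(all(c("onset_s", "offset_s", "label") %in% names(events)))
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_event_tsv()]
#' @param path TSV with columns onset_s, offset_s, label.
#' @return data.frame.
#' @export
read_event_tsv <- function(path) {
  if (!file.exists(path)) stop("read_event_tsv: no such file: ", path)
  df <- utils::read.delim(path)
  need <- c("onset_s", "offset_s", "label")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("read_event_tsv: missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Write a group-statistics results table as TSV
#'
#' One row per channel-channel-frequency cell: `chA`, `chB`, `band`,
#' `freq_hz`, `n_dyads`, `t`, `p`, `q`, `direction`.
#'
#' @param results data.frame from [condition_contrast()] + [storey_fdr()].
#' @param path output file.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- SNIRF (optional, via rhdf5) -----------------------------------------

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("SNIRF support requires the 'rhdf5' package")
}

#' Read an hb_series from a SNIRF file
#'
#' Supports two layouts of `/nirs/data1`: processed hemoglobin blocks
#' (`dataTypeLabel` "HbO"/"HbR" per measurement) mapped directly into an
#' [hb_series], and raw continuous-wave intensities (dataType 1, one
#' measurement per channel per wavelength) which are converted to optical
#' density (`-log(I / mean(I))`) and routed through [mbll()]. Any other
#' layout raises an unsupported-dialect error.
#'
#' @param path SNIRF (HDF5) file.
#' @param mbll used for the raw-intensity route; an [mbll_params()].
#' @return an [hb_series].
#' @export
read_snirf <- function(path, mbll = mbll_params()) {
  require_rhdf5()
  if (!file.exists(path)) stop("read_snirf: no such file: ", path)
  h <- tryCatch(rhdf5::h5ls(path), error = function(e)
    stop("read_snirf: cannot read HDF5 structure of ", path, ": ",
         conditionMessage(e)))
  if (!any(h$name == "data1"))
    stop("read_snirf: unsupported layout: no /nirs/data1 block")
  ts <- rhdf5::h5read(path, "/nirs/data1/dataTimeSeries")
  tt <- as.numeric(rhdf5::h5read(path, "/nirs/data1/time"))
  if (nrow(ts) != length(tt)) ts <- t(ts)
  fs <- 1 / stats::median(diff(tt))
  ml_names <- h$name[grepl("^measurementList\\d+$", h$name)]
  ml_names <- ml_names[order(as.integer(sub("measurementList", "", ml_names)))]
  ml <- lapply(ml_names, function(nm)
    rhdf5::h5read(path, paste0("/nirs/data1/", nm)))
  labels <- vapply(ml, function(m)
    if (!is.null(m$dataTypeLabel)) as.character(m$dataTypeLabel)
    else NA_character_, character(1))
  dtypes <- vapply(ml, function(m) as.numeric(m$dataType), numeric(1))
  src <- vapply(ml, function(m) as.integer(m$sourceIndex), integer(1))
  wl_idx <- vapply(ml, function(m)
    if (!is.null(m$wavelengthIndex)) as.integer(m$wavelengthIndex)
    else NA_integer_, integer(1))
  if (all(labels %in% c("HbO", "HbR"))) {
    chans <- sort(unique(src))
    pick <- function(lab) vapply(chans, function(ch)
      which(src == ch & labels == lab)[1], integer(1))
    io <- pick("HbO"); ir <- pick("HbR")
    if (anyNA(io) || anyNA(ir))
      stop("read_snirf: incomplete HbO/HbR measurement list")
    return(hb_series(ts[, io, drop = FALSE], ts[, ir, drop = FALSE], fs,
                     channel_ids = chans))
  }
  if (all(dtypes == 1) && !anyNA(wl_idx)) {
    chans <- sort(unique(src))
    od <- -log(sweep(ts, 2, colMeans(ts), "/"))
    i1 <- vapply(chans, function(ch) which(src == ch & wl_idx == 1)[1],
                 integer(1))
    i2 <- vapply(chans, function(ch) which(src == ch & wl_idx == 2)[1],
                 integer(1))
    if (anyNA(i1) || anyNA(i2))
      stop("read_snirf: incomplete wavelength coverage per channel")
    hbo <- mbll(od[, i1, drop = FALSE], od[, i2, drop = FALSE], mbll)
    return(hb_series(hbo$oxy, hbo$deoxy, fs, channel_ids = chans))
  }
  stop("read_snirf: unsupported SNIRF layout (need HbO/HbR labels or ",
       "raw CW intensities with wavelength indices)")
}

#' Write an hb_series as a minimal processed-Hb SNIRF file
#'
#' Emits the `/nirs/data1` layout with one HbO and one HbR measurement per
#' channel (`dataType` 99999, `dataTypeLabel` "HbO"/"HbR").
#'
#' @param hb an [hb_series].
#' @param path output file.
#' @export
write_snirf <- function(hb, path) {
  require_rhdf5()
  stopifnot(inherits(hb, "hb_series"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  n_ch <- length(hb$channel_ids)
  ts <- cbind(hb$data$oxy, hb$data$deoxy)
  rhdf5::h5write(ts, path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((seq_len(nrow(ts)) - 1) / hb$fs, path, "nirs/data1/time")
  for (j in seq_len(n_ch)) {
    for (lab in c("HbO", "HbR")) {
      k <- if (lab == "HbO") j else n_ch + j
      g <- sprintf("nirs/data1/measurementList%d", k)
      rhdf5::h5createGroup(path, g)
      rhdf5::h5write(hb$channel_ids[j], path, paste0(g, "/sourceIndex"))
      rhdf5::h5write(hb$channel_ids[j], path, paste0(g, "/detectorIndex"))
      rhdf5::h5write(99999L, path, paste0(g, "/dataType"))
      rhdf5::h5write(lab, path, paste0(g, "/dataTypeLabel"))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}
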