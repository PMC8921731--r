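#' Marker trajectory trial
#'
#' Time-indexed 3D marker trajectories at a fixed sampling rate, with
#' per-sample missing flags (occluded or invalid samples).
#'
#' @param data numeric array `frames x markers x 3` (mm).
#' @param marker_names character vector, one per marker.
#' @param rate sampling rate in Hz.
#' @param time optional time vector (s); defaults to `(0:(n-1))/rate`.
#'   Must be strictly increasing with spacing `1/rate`.
#' @param missing optional logical matrix `frames x markers`.
#' @return Object of class `marker_trial`.
#' @export
marker_trial <- function(data, marker_names, rate, time = NULL,
                         missing = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || dim(data)[3] != 3L) {
    stop_antkin("data must be a frames x markers x 3 array", "invalid_input")
  }
  nf <- dim(data)[1]; nm <- dim(data)[2]
  if (length(marker_names) != nm || anyDuplicated(marker_names)) {
    stop_antkin("marker_names must be unique, one per marker", "invalid_input")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop_antkin("rate must be a positive scalar (Hz)", "invalid_input")
  }
  if (is.null(time)) time <- (seq_len(nf) - 1) / rate
  if (length(time) != nf || any(diff(time) <= 0) ||
      (nf > 1 && max(abs(diff(time) - 1 / rate)) > 1e-4 / rate)) {
    stop_antkin("time must be strictly increasing with spacing 1/rate",
                "invalid_input")
  }
  if (is.null(missing)) missing <- matrix(FALSE, nf, nm)
  missing <- matrix(as.logical(missing), nf, nm)
  # coordinates must be finite wherever not flagged missing
  fin <- apply(is.finite(data), c(1, 2), all)
  if (any(!fin & !missing)) {
    stop_antkin("non-finite coordinates at samples not flagged missing",
                "invalid_input")
  }
  dimnames(data) <- list(NULL, marker_names, c("x", "y", "z"))
  colnames(missing) <- marker_names
  structure(
    list(data = data, marker_names = marker_names, rate = rate,
         time = as.numeric(time), missing = missing),
    class = "marker_trial"
  )
}

#' @export
print.marker_trial <- function(x, ...) {
  cat(sprintf(
    "<marker_trial> %d frames x %d markers at %g Hz (%.3f s), %d missing samples\n",
    n_frames(x), length(x$marker_names), x$rate,
    diff(range(x$time)), sum(x$missing)))
  invisible(x)
}

#' Number of frames in a trial
#' @param trial a [marker_trial()].
#' @return integer.
#' @export
n_frames <- function(trial) {
  stopifnot(inherits(trial, "marker_trial"))
  dim(trial$data)[1]
}

#' Extract one frame of a trial
#' @param trial a [marker_trial()].
#' @param i frame index (1-based).
#' @return named `markers x 3` matrix (mm); missing samples are `NA`.
#' @export
trial_frame <- function(trial, i) {
  stopifnot(inherits(trial, "marker_trial"))
  m <- trial$data[i, , , drop = TRUE]
  m <- matrix(m, length(trial$marker_names), 3,
              dimnames = list(trial$marker_names, c("x", "y", "z")))
  m[trial$missing[i, ], ] <- NA_real_
  m
}

#' Gait cycle window
#'
#' Half-open frame window `[start_index, end_index)` in 0-based frame
#' indices (so `gait_cycle(0, n)` is the whole trial).  Gait-cycle events
#' are supplied manually, matching identification from video: a cycle runs
#' from one lift-off of the left middle leg to the next.
#'
#' @param start_index,end_index integer frame indices, 0-based, half-open.
#' @param note free-text definition note.
#' @return Object of class `gait_cycle`.
#' @export
gait_cycle <- function(start_index, end_index, note = "") {
  start_index <- as.integer(start_index); end_index <- as.integer(end_index)
  if (is.na(start_index) || is.na(end_index) ||
      start_index < 0L || start_index >= end_index) {
    stop_antkin("need 0 <= start_index < end_index", "invalid_input")
  }
  structure(list(start_index = start_index, end_index = end_index,
                 note = note), class = "gait_cycle")
}

#' Crop a trial to a gait cycle
#'
#' Retains frames in the half-open window and re-zeroes time to the cycle
#' start.
#'
#' @param trial a [marker_trial()].
#' @param cycle a [gait_cycle()] (indices must lie within the trial).
#' @return a [marker_trial()].
#' @export
crop_cycle <- function(trial, cycle) {
  stopifnot(inherits(trial, "marker_trial"), inherits(cycle, "gait_cycle"))
  nf <- n_frames(trial)
  if (cycle$end_index > nf) {
    stop_antkin(sprintf("cycle end %d exceeds trial length %d",
                        cycle$end_index, nf), "invalid_input")
  }
  keep <- (cycle$start_index + 1L):cycle$end_index
  marker_trial(trial$data[keep, , , drop = FALSE], trial$marker_names,
               trial$rate, time = trial$time[keep] - trial$time[keep[1]],
               missing = trial$missing[keep, , drop = FALSE])
}

# zero-phase single-channel Butterworth pass: odd-reflection padding of
# 3 x order samples, steady-state initial conditions, forward then backward
filtfilt_channel <- function(x, b, a, pad) {
  one_pass <- function(x) {
    n <- length(x)
    p <- min(pad, n - 1L)
    xp <- if (p > 0) {
      c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    } else x
    y <- signal::filter(b, a, xp,
                        init.x = rep(xp[1], length(b) - 1),
                        init.y = rep(xp[1], length(a) - 1))
    as.numeric(y)[(p + 1):(p + n)]
  }
  rev(one_pass(rev(one_pass(x))))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth low-pass filter to
#' every marker coordinate channel.  The cascade doubles the effective
#' order and squares the magnitude response; phase lag, which would bias
#' joint-angle timing, cancels.  Edges are handled by odd-reflection
#' padding of `3 * order` samples with steady-state initial conditions.
#'
#' Missing samples are linearly interpolated before filtering when every
#' gap of a channel spans at most `max_gap` frames (the flags are then
#' cleared); channels with longer gaps are left unfiltered and flagged
#' entirely missing so downstream inverse kinematics excludes them.
#'
#' @param trial a [marker_trial()].
#' @param cutoff_hz low-pass cutoff frequency, Hz (default 5).
#' @param order filter order of each pass (default 4).
#' @param max_gap longest missing-data gap (frames) interpolated rather
#'   than excluded (default 10).
#' @return a filtered [marker_trial()] of identical length and rate.
#' @export
lowpass_filter <- function(trial, cutoff_hz = 5, order = 4, max_gap = 10) {
  stopifnot(inherits(trial, "marker_trial"))
  if (cutoff_hz <= 0 || cutoff_hz >= trial$rate / 2) {
    stop_antkin("cutoff must lie in (0, rate/2)", "invalid_parameter")
  }
  bf <- signal::butter(order, cutoff_hz / (trial$rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  nf <- n_frames(trial)
  data <- trial$data
  missing <- trial$missing
  excluded <- character(0)
  for (k in seq_along(trial$marker_names)) {
    miss <- missing[, k]
    if (all(miss)) {
      stop_antkin(sprintf("marker '%s' has no valid samples",
                          trial$marker_names[k]), "channel_error")
    }
    if (any(miss)) {
      gaps <- rle(miss)
      if (max(gaps$lengths[gaps$values]) > max_gap) {
        excluded <- c(excluded, trial$marker_names[k])
        missing[, k] <- TRUE
        next
      }
      ok <- which(!miss)
      for (j in 1:3) {
        data[, k, j] <- stats::approx(trial$time[ok], data[ok, k, j],
                                      xout = trial$time, rule = 2)$y
      }
      missing[, k] <- FALSE
    }
    for (j in 1:3) {
      data[, k, j] <- filtfilt_channel(data[, k, j], b, a, 3L * order)
    }
  }
  out <- marker_trial(data, trial$marker_names, trial$rate,
                      time = trial$time, missing = missing)
  attr(out, "excluded_markers") <- excluded
  out
}

#' Resample a trial to a lower rate
#'
#' Downsampling only (the conditioning pipeline low-passes first, then
#' decimates).  Integer rate ratios use exact index decimation (300 to
#' 100 Hz keeps every 3rd sample); non-integer ratios linearly interpolate
#' onto a uniform grid spanning the same interval.
#'
#' @param trial a [marker_trial()].
#' @param target_rate_hz target rate, Hz, at most the current rate.
#' @return a [marker_trial()] at the target rate.
#' @export
resample_trial <- function(trial, target_rate_hz) {
  stopifnot(inherits(trial, "marker_trial"))
  if (target_rate_hz > trial$rate + 1e-9) {
    stop_antkin("upsampling is not supported (target rate above current)",
                "invalid_parameter")
  }
  if (abs(target_rate_hz - trial$rate) < 1e-9) return(trial)
  ratio <- trial$rate / target_rate_hz
  nf <- n_frames(trial)
  if (abs(ratio - round(ratio)) < 1e-9) {
    keep <- seq(1L, nf, by = as.integer(round(ratio)))
    return(marker_trial(trial$data[keep, , , drop = FALSE],
                        trial$marker_names, target_rate_hz,
                        time = trial$time[keep],
                        missing = trial$missing[keep, , drop = FALSE]))
  }
  t_new <- seq(trial$time[1], trial$time[nf], by = 1 / target_rate_hz)
  nm <- length(trial$marker_names)
  data <- array(0, c(length(t_new), nm, 3))
  for (k in seq_len(nm)) {
    for (j in 1:3) {
      data[, k, j] <- stats::approx(trial$time, trial$data[, k, j],
                                    xout = t_new, rule = 2)$y
    }
  }
  nearest <- vapply(t_new, function(t) which.min(abs(trial$time - t)), 0L)
  marker_trial(data, trial$marker_names, target_rate_hz, time = t_new,
               missing = trial$missing[nearest, , drop = FALSE])
}

#' Write a trial as tab-separated TRC
#'
#' Standard TRC layout: three header lines (rates, frame and marker
#' counts, units), marker-name and coordinate-label lines, then one row
#' per frame with frame number, time and X/Y/Z columns per marker (mm).
#' Missing samples are written as blank fields.
#'
#' @param trial a [marker_trial()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trial, path) {
  stopifnot(inherits(trial, "marker_trial"))
  nf <- n_frames(trial); nm <- length(trial$marker_names)
  fmt_rate <- function(r) {
    if (abs(r - round(r)) < 1e-9) sprintf("%.1f", r) else
      sub("0+$", "", sprintf("%.6f", r))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%s\t%s\t%d\t%d\tmm\t%s\t1\t%d",
                     fmt_rate(trial$rate), fmt_rate(trial$rate), nf, nm,
                     fmt_rate(trial$rate), nf), con)
  writeLines(paste0("Frame#\tTime\t",
                    paste0(trial$marker_names, collapse = "\t\t\t"),
                    "\t\t"), con)
  writeLines(paste0("\t\t", paste0(
    vapply(seq_len(nm), function(k) sprintf("X%d\tY%d\tZ%d", k, k, k), ""),
    collapse = "\t"), ""), con)
  writeLines("", con)
  for (i in seq_len(nf)) {
    fields <- character(3 * nm)
    for (k in seq_len(nm)) {
      if (trial$missing[i, k]) {
        fields[(3 * k - 2):(3 * k)] <- ""
      } else {
        fields[(3 * k - 2):(3 * k)] <-
          sprintf("%.8f", trial$data[i, k, ])
      }
    }
    writeLines(paste(c(sprintf("%d", i), sprintf("%.8f", trial$time[i]),
                       fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a TRC trial
#'
#' Inverse of [write_trc()]; blank coordinate fields become missing flags.
#'
#' @param path TRC file path.
#' @return a [marker_trial()].
#' @export
read_trc <- function(path) {
  if (!file.exists(path)) {
    stop_antkin(sprintf("no such file: %s", path), "format_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6 || !grepl("^PathFileType", lines[1])) {
    stop_antkin("not a TRC file (missing PathFileType header)", "format_error")
  }
  hdr <- strsplit(lines[3], "\t")[[1]]
  if (length(hdr) < 5) stop_antkin("malformed TRC header line", "format_error")
  rate <- suppressWarnings(as.numeric(hdr[1]))
  nf <- suppressWarnings(as.integer(hdr[3]))
  nm <- suppressWarnings(as.integer(hdr[4]))
  units <- hdr[5]
  if (any(is.na(c(rate, nf, nm)))) {
    stop_antkin("malformed TRC header values", "format_error")
  }
  scale <- switch(tolower(units), mm = 1, m = 1000, cm = 10,
                  stop_antkin(sprintf("unknown TRC units '%s'", units),
                              "unit_error"))
  name_fields <- strsplit(lines[4], "\t")[[1]]
  marker_names <- name_fields[-(1:2)]
  marker_names <- marker_names[marker_names != ""]
  if (length(marker_names) != nm) {
    stop_antkin("TRC marker-name line disagrees with NumMarkers",
                "format_error")
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nf) {
    stop_antkin("TRC data rows fewer than NumFrames", "format_error")
  }
  body <- body[seq_len(nf)]
  data <- array(0, c(nf, nm, 3))
  missing <- matrix(FALSE, nf, nm)
  time <- numeric(nf)
  for (i in seq_len(nf)) {
    f <- strsplit(body[i], "\t")[[1]]
    length(f) <- 2 + 3 * nm
    time[i] <- as.numeric(f[2])
    vals <- suppressWarnings(as.numeric(f[-(1:2)]))
    for (k in seq_len(nm)) {
      v <- vals[(3 * k - 2):(3 * k)]
      if (any(is.na(v))) {
        missing[i, k] <- TRUE
      } else {
        data[i, k, ] <- v * scale
      }
    }
  }
  marker_trial(data, marker_names, rate, time = time, missing = missing)
}

#' Export trial trajectories as CSV
#'
#' One row per frame: time plus `<marker>_x/_y/_z` columns in mm;
#' missing samples are empty cells.
#'
#' @param trial a [marker_trial()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trial, path) {
  stopifnot(inherits(trial, "marker_trial"))
  nm <- length(trial$marker_names)
  cols <- list(time = trial$time)
  for (k in seq_len(nm)) {
    for (j in 1:3) {
      v <- trial$data[, k, j]
      v[trial$missing[, k]] <- NA_real_
      cols[[paste0(trial$marker_names[k], "_", c("x", "y", "z")[j])]] <- v
    }
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE, na = "")
  invisible(path)
}
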