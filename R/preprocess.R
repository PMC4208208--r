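# Sensor-stream conditioning. Measurement streams are held as `timed_series`
# objects: a timestamp vector plus a sample-by-channel value matrix. Three
# channel layouts are used:
#   kind "cop"     - 2 columns, ground-plane CoP in m (x, y)
#   kind "joints"  - 3 columns per named skeleton joint (m)
#   kind "posture" - 84 columns: 9 segments x 9 orientation-matrix entries
#                    (column-major) followed by the 3 root-origin components
# CoP and orientation/position streams are time stamped by their sensors on
# independent clocks; both are interpolated onto a shared uniform grid
# before static-window detection.

JOINT_NAMES <- c("head", "neck", "torso",
                 "r_shoulder", "l_shoulder", "r_elbow", "l_elbow",
                 "r_hand", "l_hand",
                 "r_hip", "l_hip", "r_knee", "l_knee", "r_foot", "l_foot")
# joints actually needed to reconstruct the 9-segment posture
REQUIRED_JOINTS <- setdiff(JOINT_NAMES, c("head", "torso"))
# proximal -> distal joint pair defining each limb segment's z-axis
LIMB_JOINTS <- list(
  `2` = c("r_shoulder", "r_elbow"), `3` = c("r_elbow", "r_hand"),
  `4` = c("l_shoulder", "l_elbow"), `5` = c("l_elbow", "l_hand"),
  `6` = c("r_hip", "r_knee"),       `7` = c("r_knee", "r_foot"),
  `8` = c("l_hip", "l_knee"),       `9` = c("l_knee", "l_foot"))

#' Construct a timed series
#'
#' @param timestamps Numeric vector of sample times in seconds,
#'   non-decreasing.
#' @param values Numeric matrix, one row per sample.
#' @param kind Channel semantics: `"cop"`, `"joints"`, `"posture"` or
#'   `"generic"`.
#' @param rate Sampling rate in Hz when the grid is uniform, else `NA`.
#' @return An object of class `timed_series`.
#' @export
timed_series <- function(timestamps, values, kind = "generic", rate = NA) {
  timestamps <- as.numeric(timestamps)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1)
  stopifnot(length(timestamps) == nrow(values))
  if (is.unsorted(timestamps)) stop("timestamps must be non-decreasing")
  if (anyNA(values)) stop("values contain NA after cleaning")
  structure(list(timestamps = timestamps, values = values, kind = kind,
                 rate = rate),
            class = "timed_series")
}

#' @export
print.timed_series <- function(x, ...) {
  cat(sprintf("<timed_series> kind '%s', %d samples x %d channels, %s\n",
              x$kind, nrow(x$values), ncol(x$values),
              if (is.na(x$rate)) sprintf("span %.2f s", diff(range(x$timestamps)))
              else sprintf("%.4g Hz", x$rate)))
  invisible(x)
}

#' Resample a timed series onto a uniform grid
#'
#' Linear interpolation of every channel onto an evenly spaced grid at the
#' requested rate, covering the (overlap of the) original time span.
#'
#' @param series A [timed_series()] with at least 2 samples.
#' @param rate Target rate in Hz.
#' @param t_start,t_end Optional grid bounds (s); default the series' span.
#' @return A uniformly sampled `timed_series` of the same kind.
#' @export
resample_series <- function(series, rate, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(series, "timed_series"), rate > 0)
  ts <- series$timestamps
  if (length(ts) < 2 || diff(range(ts)) < 1 / rate)
    stop("need at least two samples spanning one sample period")
  if (is.null(t_start)) t_start <- ts[1]
  if (is.null(t_end)) t_end <- ts[length(ts)]
  grid <- seq(t_start, t_end, by = 1 / rate)
  vals <- apply(series$values, 2, function(v)
    stats::approx(ts, v, xout = grid, rule = 2)$y)
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = length(grid))
  colnames(vals) <- colnames(series$values)
  timed_series(grid, vals, kind = series$kind, rate = rate)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward application of an order-`order` Butterworth low-pass
#' ([signal::filtfilt()]): zero net phase shift, squared magnitude response
#' (the gain at the cutoff is -3 dB twice, i.e. 1/2).
#'
#' @param series A uniformly sampled [timed_series()].
#' @param cutoff Cut-off frequency in Hz; must be below the Nyquist rate.
#' @param order Filter order (default 2).
#' @return A filtered `timed_series`.
#' @export
zero_phase_lowpass <- function(series, cutoff, order = 2) {
  stopifnot(inherits(series, "timed_series"))
  if (is.na(series$rate))
    stop("series must be uniformly sampled (resample first)")
  nyq <- series$rate / 2
  if (cutoff >= nyq)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, nyq))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  # odd-symmetric edge padding so the forward-backward startup transients
  # decay outside the retained span (long enough for the slowest pole)
  np <- nrow(series$values)
  L <- min(np - 1, ceiling(10 * series$rate / cutoff))
  vals <- apply(series$values, 2, function(v) {
    padded <- c(2 * v[1] - v[(L + 1):2], v, 2 * v[np] - v[(np - 1):(np - L)])
    signal::filtfilt(bf, padded)[(L + 1):(L + np)]
  })
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = length(series$timestamps))
  colnames(vals) <- colnames(series$values)
  timed_series(series$timestamps, vals, kind = series$kind,
               rate = series$rate)
}

# ---- posture-series packing ------------------------------------------------

#' Pack a list of postures into a posture timed series
#'
#' @param postures List of [posture()] objects.
#' @param timestamps Sample times (s); default taken from the postures.
#' @param rate Sampling rate (Hz) if uniform.
#' @return A `timed_series` of kind `"posture"` (84 channels).
#' @export
postures_to_series <- function(postures, timestamps = NULL, rate = NA) {
  stopifnot(is.list(postures), length(postures) >= 1)
  if (is.null(timestamps))
    timestamps <- vapply(postures, `[[`, numeric(1), "timestamp")
  vals <- t(vapply(postures, function(p)
    c(unlist(p$orientations, use.names = FALSE), p$root_origin),
    numeric(84)))
  timed_series(timestamps, vals, kind = "posture", rate = rate)
}

#' Extract one posture from a posture series
#'
#' Orientation matrices are re-orthonormalized by nearest-rotation
#' projection (interpolation and averaging leave them slightly off SO(3)).
#'
#' @param series A `timed_series` of kind `"posture"`.
#' @param i Row index.
#' @return A [posture()].
#' @export
series_to_posture <- function(series, i) {
  stopifnot(inherits(series, "timed_series"), series$kind == "posture")
  row_to_posture(series$values[i, ], series$timestamps[i])
}

row_to_posture <- function(v, timestamp = 0) {
  A <- lapply(1:9, function(s)
    nearest_rotation(matrix(v[(s - 1) * 9 + 1:9], 3, 3)))
  posture(A, v[82:84], timestamp, check = FALSE)
}

# ---- static-window detection ----------------------------------------------

#' Detect static windows in aligned posture and CoP streams
#'
#' Slides a window (default 1 s) over the shared uniform grid; a window is
#' static when the per-axis CoP standard deviation stays below
#' `cop_thresh_mm` and, for every segment, the standard deviation of the
#' geodesic angle from the window's mean orientation stays below
#' `orient_thresh_deg` (both strict). Overlapping static windows are merged,
#' a settle margin is trimmed from each end of the merged interval (the
#' onset and offset of a hold pass under the dispersion thresholds while
#' the subject is still slowly moving), and the measurements are averaged
#' over the remaining samples, so each held posture yields one window.
#'
#' @param orientations A `timed_series` of kind `"posture"`.
#' @param cop A `timed_series` of kind `"cop"` on the same grid.
#' @param window_s Window length in seconds (default 1).
#' @param orient_thresh_deg Orientation dispersion threshold in degrees
#'   (default 5).
#' @param cop_thresh_mm Per-axis CoP dispersion threshold in mm (default 3).
#' @param settle_s Margin trimmed from each end of a merged static interval
#'   in seconds (default 0.5); merged intervals left shorter than one
#'   window are dropped.
#' @return List of `static_window` objects with fields `start`, `end` (s),
#'   `sample_idx`, `mean_posture`, `mean_cop` (m), `cop_std_mm`,
#'   `max_orient_std_deg`.
#' @export
detect_static_windows <- function(orientations, cop, window_s = 1.0,
                                  orient_thresh_deg = 5.0,
                                  cop_thresh_mm = 3.0, settle_s = 0.5) {
  stopifnot(inherits(orientations, "timed_series"),
            orientations$kind == "posture",
            inherits(cop, "timed_series"), cop$kind == "cop")
  if (is.na(orientations$rate) || is.na(cop$rate) ||
      orientations$rate != cop$rate ||
      nrow(orientations$values) != nrow(cop$values) ||
      max(abs(orientations$timestamps - cop$timestamps)) > 1e-9)
    stop("orientation and CoP streams must share one uniform time grid")
  n <- nrow(cop$values)
  w <- round(window_s * cop$rate)
  if (w < 2 || n < w) {
    warning("streams shorter than one window; no static windows")
    return(list())
  }
  nw <- n - w + 1
  ok <- rolling_sd_ok(cop$values[, 1] * 1000, w, cop_thresh_mm) &
    rolling_sd_ok(cop$values[, 2] * 1000, w, cop_thresh_mm)
  # per-segment orientation dispersion, only where CoP already passes
  means <- vector("list", 9)
  for (s in 1:9) {
    cols <- (s - 1) * 9 + 1:9
    R <- orientations$values[, cols, drop = FALSE]
    # rolling mean of each matrix entry
    cs <- apply(rbind(0, R), 2, cumsum)
    Rm <- (cs[(w + 1):(n + 1), , drop = FALSE] -
             cs[1:nw, , drop = FALSE]) / w
    # project window means onto SO(3), then angle of each sample to its mean
    idx <- which(ok)
    if (length(idx) == 0) break
    Rm_proj <- Rm
    for (i in idx) Rm_proj[i, ] <- as.numeric(nearest_rotation(
      matrix(Rm[i, ], 3, 3)))
    ang2_sum <- numeric(nw)
    ang_sum <- numeric(nw)
    for (off in 0:(w - 1)) {
      tr <- rowSums(Rm_proj[idx, , drop = FALSE] *
                      R[idx + off, , drop = FALSE])
      ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2)))
      ang_sum[idx] <- ang_sum[idx] + ang
      ang2_sum[idx] <- ang2_sum[idx] + ang^2
    }
    sd_deg <- sqrt(pmax(ang2_sum - ang_sum^2 / w, 0) / (w - 1)) * 180 / pi
    ok <- ok & (sd_deg < orient_thresh_deg)
    means[[s]] <- Rm_proj
  }
  starts <- which(ok)
  if (length(starts) == 0) return(list())
  # merge overlapping windows: runs of starts closer than one window length
  breaks <- which(diff(starts) >= w)
  run_start <- starts[c(1, breaks + 1)]
  run_last <- starts[c(breaks, length(starts))]
  trim <- round(settle_s * cop$rate)
  out <- lapply(seq_along(run_start), function(k) {
    lo <- run_start[k] + trim
    hi <- run_last[k] + w - 1 - trim
    if (hi - lo + 1 < w) return(NULL)
    smp <- lo:hi
    vrow <- colMeans(orientations$values[smp, , drop = FALSE])
    mean_posture <- row_to_posture(vrow, orientations$timestamps[smp[1]])
    cop_mm_sd <- apply(cop$values[smp, , drop = FALSE] * 1000, 2, stats::sd)
    orient_sd <- vapply(1:9, function(s) {
      cols <- (s - 1) * 9 + 1:9
      Rm <- mean_posture$orientations[[s]]
      ang <- apply(orientations$values[smp, cols, drop = FALSE], 1,
                   function(v) rotation_angle(Rm, matrix(v, 3, 3)))
      stats::sd(ang) * 180 / pi
    }, numeric(1))
    structure(list(start = orientations$timestamps[smp[1]],
                   end = orientations$timestamps[smp[length(smp)]],
                   sample_idx = smp,
                   mean_posture = mean_posture,
                   mean_cop = colMeans(cop$values[smp, , drop = FALSE]),
                   cop_std_mm = cop_mm_sd,
                   max_orient_std_deg = max(orient_sd)),
              class = "static_window")
  })
  out[!vapply(out, is.null, logical(1))]
}

# TRUE at window starts where the rolling sample sd over w samples is
# strictly below thresh. Uses the centered two-pass identity on cumsums.
rolling_sd_ok <- function(x, w, thresh) {
  n <- length(x)
  nw <- n - w + 1
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  s <- cs[(w + 1):(n + 1)] - cs[1:nw]
  s2 <- cs2[(w + 1):(n + 1)] - cs2[1:nw]
  varw <- pmax(s2 - s^2 / w, 0) / (w - 1)
  sqrt(varw) < thresh
}

# ---- skeleton joints -> posture -------------------------------------------

#' Build a posture from named skeleton joint positions
#'
#' Limb orientations take their z-axis from the proximal-to-distal bone
#' direction, completed to a rotation by Gram-Schmidt against the global
#' z-axis (global x when the bone is vertical). The torso frame has z from
#' mid-hip toward the neck, y along the left-hip-to-right-hip direction
#' orthogonalized to z, and x = y x z. The root origin is the mid-hip point.
#'
#' @param joints Named list of length-3 numeric joint positions (m). Needs
#'   `neck`, `r_shoulder`, `l_shoulder`, `r_elbow`, `l_elbow`, `r_hand`,
#'   `l_hand`, `r_hip`, `l_hip`, `r_knee`, `l_knee`, `r_foot`, `l_foot`.
#' @param timestamp Time stamp in seconds.
#' @return A [posture()].
#' @export
joints_to_posture <- function(joints, timestamp = 0) {
  missing <- setdiff(REQUIRED_JOINTS, names(joints))
  if (length(missing))
    stop("missing joints: ", paste(missing, collapse = ", "))
  jt <- lapply(joints, as.numeric)
  midhip <- (jt$r_hip + jt$l_hip) / 2
  # torso frame
  zt <- jt$neck - midhip
  if (sqrt(sum(zt^2)) < 1e-9) stop("zero-length bone: mid_hip-neck")
  zt <- zt / sqrt(sum(zt^2))
  yraw <- jt$r_hip - jt$l_hip
  yt <- yraw - sum(yraw * zt) * zt
  if (sqrt(sum(yt^2)) < 1e-9) stop("zero-length bone: l_hip-r_hip")
  yt <- yt / sqrt(sum(yt^2))
  A <- vector("list", 9)
  A[[1]] <- unname(cbind(cross3(yt, zt), yt, zt))
  for (i in 2:9) {
    pr <- LIMB_JOINTS[[as.character(i)]]
    bone <- jt[[pr[2]]] - jt[[pr[1]]]
    bl <- sqrt(sum(bone^2))
    if (bl < 1e-9)
      stop("zero-length bone: ", pr[1], "-", pr[2], " (segment ",
           SEGMENT_NAMES[i], ")")
    A[[i]] <- frame_from_z(bone / bl)
  }
  posture(A, midhip, timestamp, check = FALSE)
}

# deterministic completion of a unit z-axis to a rotation matrix:
# x from Gram-Schmidt of the global z-axis (global x if parallel), y = z x x
frame_from_z <- function(z) {
  ref <- c(0, 0, 1)
  xr <- ref - sum(ref * z) * z
  if (sqrt(sum(xr^2)) < 1e-8) {
    ref <- c(1, 0, 0)
    xr <- ref - sum(ref * z) * z
  }
  x <- xr / sqrt(sum(xr^2))
  unname(cbind(x, cross3(z, x), z))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convert a skeleton-joint series to a posture series
#'
#' Applies [joints_to_posture()] sample by sample.
#'
#' @param joints A `timed_series` of kind `"joints"` (columns
#'   `<joint>_x/_y/_z`).
#' @return A `timed_series` of kind `"posture"`.
#' @export
joints_series_to_postures <- function(joints) {
  stopifnot(inherits(joints, "timed_series"), joints$kind == "joints")
  cn <- colnames(joints$values)
  n <- nrow(joints$values)
  vals <- matrix(0, n, 84)
  for (i in seq_len(n)) {
    row <- joints$values[i, ]
    jt <- list()
    for (j in JOINT_NAMES) {
      cols <- paste0(j, c("_x", "_y", "_z"))
      if (all(cols %in% cn)) jt[[j]] <- unname(row[cols])
    }
    p <- joints_to_posture(jt, joints$timestamps[i])
    vals[i, ] <- c(unlist(p$orientations, use.names = FALSE), p$root_origin)
  }
  timed_series(joints$timestamps, vals, kind = "posture", rate = joints$rate)
}

# ---- CSV readers / writers -------------------------------------------------

#' Read / write sensor streams as CSV
#'
#' Skeleton files have columns `time_s` and `<joint>_x/_y/_z` in meters for
#' the 15-joint schema; CoP files have `time_s`, `cop_x_m`, `cop_y_m` and an
#' optional `force_n`. Lines starting with `#` are metadata comments.
#'
#' @param path File path.
#' @param series A `timed_series` of the matching kind.
#' @param comment Optional character vector of metadata lines to prepend
#'   (written with a `#` prefix).
#' @return Readers return a `timed_series`; writers return `path`
#'   invisibly.
#' @name stream-io
NULL

#' @rdname stream-io
#' @export
read_skeleton_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"time_s" %in% names(df)) stop("skeleton file needs a time_s column")
  vals <- as.matrix(df[setdiff(names(df), "time_s")])
  timed_series(df$time_s, vals, kind = "joints", rate = infer_rate(df$time_s))
}

#' @rdname stream-io
#' @export
write_skeleton_csv <- function(series, path, comment = NULL) {
  stopifnot(inherits(series, "timed_series"), series$kind == "joints")
  df <- data.frame(time_s = series$timestamps)
  df <- cbind(df, as.data.frame(series$values))
  write_csv_commented(df, path, comment)
}

#' @rdname stream-io
#' @export
read_cop_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  req <- c("time_s", "cop_x_m", "cop_y_m")
  if (!all(req %in% names(df)))
    stop("CoP file needs columns ", paste(req, collapse = ", "))
  vals <- cbind(cop_x_m = df$cop_x_m, cop_y_m = df$cop_y_m)
  timed_series(df$time_s, vals, kind = "cop", rate = infer_rate(df$time_s))
}

#' @rdname stream-io
#' @export
write_cop_csv <- function(series, path, comment = NULL) {
  stopifnot(inherits(series, "timed_series"), series$kind == "cop")
  df <- data.frame(time_s = series$timestamps,
                   cop_x_m = series$values[, 1],
                   cop_y_m = series$values[, 2])
  write_csv_commented(df, path, comment)
}

write_csv_commented <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

infer_rate <- function(ts) {
  if (length(ts) < 3) return(NA)
  d <- diff(ts)
  if (max(d) - min(d) < 1e-6 * stats::median(d)) 1 / stats::median(d) else NA
}
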