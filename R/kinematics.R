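# Body-centred kinematics: body frame, protraction/retraction angles, and
# smoothed arena-frame body velocities.

#' Body frame time series
#'
#' The body frame is anchored at the root marker (posterior metathorax) and
#' oriented along the chord from the root marker to the prothorax marker.
#' Headings are in degrees (0 = arena +x, 90 = arena +y) and unwrapped
#' across frames so they can be differentiated.
#'
#' @param trial A `walker_trial` containing `pro` and `meta` markers.
#' @return Data frame `time_s`, `x_mm`, `y_mm` (root marker) and
#'   `heading_deg` (unwrapped).
#' @export
body_frame <- function(trial) {
  stopifnot(inherits(trial, "walker_trial"))
  for (m in c("pro", "meta"))
    if (is.null(trial$markers[[m]]))
      stop("trial is missing the '", m, "' thoracic marker")
  root <- trial$markers[["meta"]]
  pro <- trial$markers[["pro"]]
  v <- pro - root
  if (any(rowSums(v^2) < 1e-12, na.rm = TRUE))
    stop("coincident thoracic markers: body axis undefined")
  heading <- atan2(v[, 2], v[, 1]) * 180 / pi
  heading <- .unwrap_deg(heading)
  data.frame(time_s = trial$times_s, x_mm = root[, 1], y_mm = root[, 2],
             heading_deg = heading)
}

.unwrap_deg <- function(h) {
  if (length(h) < 2) return(h)
  d <- diff(h)
  d <- d - 360 * round(d / 360)
  c(h[1], h[1] + cumsum(d))
}

#' Protraction/retraction angle time courses
#'
#' For each leg, the angle between the line from the segment's thoracic
#' marker to the femoral marker and the perpendicular to the body axis on
#' that leg's side. Zero means the femur is orthogonal to the body axis;
#' positive angles mean the femur points forward. Front legs use the
#' prothorax marker, middle legs the mesothorax marker, hind legs the
#' metathorax root marker.
#'
#' @param trial A `walker_trial`.
#' @param body Output of [body_frame()] for the same trial.
#' @return Named list over legs of data frames `time_s`, `angle_deg`.
#' @export
protraction_angles <- function(trial, body) {
  stopifnot(inherits(trial, "walker_trial"))
  hr <- body$heading_deg * pi / 180
  ch <- cos(hr); sh <- sin(hr)
  out <- list()
  for (leg in leg_ids()) {
    fm <- trial$markers[[leg]]
    th <- trial$markers[[.leg_segment(leg)]]
    if (is.null(fm) || is.null(th))
      stop("trial is missing markers for leg ", leg)
    dx <- fm[, 1] - th[, 1]
    dy <- fm[, 2] - th[, 2]
    if (any(dx^2 + dy^2 < 1e-12, na.rm = TRUE))
      stop("zero-length femur vector for leg ", leg)
    # rotate into the body frame (x anterior, y left)
    bx <- dx * ch + dy * sh
    by <- -dx * sh + dy * ch
    ang <- if (.leg_side(leg) == "left") atan2(bx, by) else atan2(bx, -by)
    out[[leg]] <- data.frame(time_s = trial$times_s,
                             angle_deg = ang * 180 / pi)
  }
  out
}

#' Sliding median filter
#'
#' Centred moving median with an odd window; at the series edges the window
#' is truncated to the available samples, so the output has the same length
#' as the input.
#'
#' @param series Numeric vector.
#' @param window Odd window length in samples (>= 1).
#' @return Filtered vector of the same length.
#' @export
sliding_median <- function(series, window) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window %% 2 == 0)
    stop("window must be an odd sample count >= 1")
  if (window == 1) return(as.numeric(series))
  n <- length(series)
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i)
    stats::median(series[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Body velocities (forward, sideward, yaw)
#'
#' Finite-difference velocities between subsequent frames: the displacement
#' of the body-frame origin is projected onto the heading direction at the
#' earlier frame (Tx, forward) and its left normal (Ty, positive = leftward
#' shift), and the yaw rate (Rot, positive = counter-clockwise) is the
#' heading difference times the frame rate. All three are smoothed by a
#' sliding median filter whose window is `round(window_ms * rate / 1000)`
#' samples, forced odd (at 50 Hz the default 60 ms gives 3 samples).
#'
#' @param body Output of [body_frame()].
#' @param window_ms Median filter window in milliseconds (> 0).
#' @param frame_rate_hz Frame rate; defaults to the inverse median frame
#'   interval of `body$time_s`.
#' @return Data frame `time_s` (interval midpoints), `tx_mm_s`, `ty_mm_s`,
#'   `rot_deg_s`; one row fewer than `body`.
#' @export
body_velocities <- function(body, window_ms = 60, frame_rate_hz = NULL) {
  if (!is.numeric(window_ms) || window_ms <= 0) stop("window_ms must be > 0")
  n <- nrow(body)
  if (n < 2) stop("need at least 2 frames for velocities")
  if (is.null(frame_rate_hz))
    frame_rate_hz <- 1 / stats::median(diff(body$time_s))
  dx <- diff(body$x_mm); dy <- diff(body$y_mm)
  h0 <- body$heading_deg[-n] * pi / 180
  rate <- 1 / diff(body$time_s)
  tx <- (dx * cos(h0) + dy * sin(h0)) * rate
  ty <- (-dx * sin(h0) + dy * cos(h0)) * rate
  rot <- diff(body$heading_deg) * rate
  w <- median_window_samples(window_ms, frame_rate_hz)
  data.frame(time_s = (body$time_s[-n] + body$time_s[-1]) / 2,
             tx_mm_s = sliding_median(tx, w),
             ty_mm_s = sliding_median(ty, w),
             rot_deg_s = sliding_median(rot, w))
}

#' Median filter window size in samples
#'
#' @param window_ms Window in milliseconds.
#' @param frame_rate_hz Sampling rate in Hz.
#' @return Odd integer window length (>= 1).
#' @export
median_window_samples <- function(window_ms, frame_rate_hz) {
  w <- round(window_ms * frame_rate_hz / 1000)
  if (w %% 2 == 0) w <- w + 1
  max(1L, as.integer(w))
}
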