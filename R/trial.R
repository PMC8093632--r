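# The walking-trial container shared by the simulator, tracker and analysis.

#' Construct a walking trial
#'
#' A trial holds the time-stamped 2-D arena-frame trajectories of the nine
#' body markers for one walking bout, plus metadata.
#'
#' @param times_s Strictly increasing vector of sample times (s).
#' @param markers Named list over [marker_ids()] of n x 2 matrices of arena
#'   positions (mm, columns x and y); `NA` rows mark missing samples.
#' @param animal_id,cohort Metadata strings.
#' @param frame_rate_hz Sampling rate (Hz).
#' @return A `walker_trial` object.
#' @export
walker_trial <- function(times_s, markers, animal_id = "A1",
                         cohort = "synthetic", frame_rate_hz = 50) {
  times_s <- as.numeric(times_s)
  if (length(times_s) < 1 || any(!is.finite(times_s)))
    stop("times_s must be finite")
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  if (anyDuplicated(names(markers)))
    stop("duplicate marker label: ",
         names(markers)[duplicated(names(markers))][1])
  bad <- setdiff(names(markers), marker_ids())
  if (length(bad) > 0)
    stop("unknown marker_id: ", paste(bad, collapse = ", "))
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != length(times_s) || ncol(m) != 2)
      stop("each marker must have one (x, y) row per time sample")
    storage.mode(m) <- "double"
    colnames(m) <- c("x_mm", "y_mm")
    m
  })
  structure(list(animal_id = as.character(animal_id),
                 cohort = as.character(cohort),
                 frame_rate_hz = as.numeric(frame_rate_hz),
                 times_s = times_s, markers = markers),
            class = "walker_trial")
}

#' @export
print.walker_trial <- function(x, ...) {
  cat(sprintf("<walker_trial> animal %s (%s), %d frames @ %g Hz, %.2f s, markers: %s\n",
              x$animal_id, x$cohort, length(x$times_s), x$frame_rate_hz,
              diff(range(x$times_s)), paste(names(x$markers), collapse = " ")))
  invisible(x)
}

#' Geometric transforms of a trial
#'
#' Rotate (about the arena origin, counter-clockwise), translate, or mirror
#' (across the arena x axis, i.e. negate y) all marker trajectories of a
#' trial. Mirroring also swaps left and right femoral marker labels so the
#' result is again a physically consistent (mirror-image) walker.
#'
#' @param trial A `walker_trial`.
#' @param angle_deg Rotation angle, degrees ccw.
#' @param dx_mm,dy_mm Translation (mm).
#' @return The transformed `walker_trial`.
#' @export
rotate_trial <- function(trial, angle_deg) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  trial$markers <- lapply(trial$markers, function(m) {
    out <- m %*% t(R)
    colnames(out) <- colnames(m)
    out
  })
  trial
}

#' @rdname rotate_trial
#' @export
translate_trial <- function(trial, dx_mm, dy_mm) {
  trial$markers <- lapply(trial$markers, function(m) {
    m[, 1] <- m[, 1] + dx_mm
    m[, 2] <- m[, 2] + dy_mm
    m
  })
  trial
}

#' @rdname rotate_trial
#' @export
mirror_trial <- function(trial) {
  swap <- c(pro = "pro", meso = "meso", meta = "meta",
            L1 = "R1", L2 = "R2", L3 = "R3", R1 = "L1", R2 = "L2", R3 = "L3")
  m <- lapply(trial$markers, function(mm) {
    mm[, 2] <- -mm[, 2]
    mm
  })
  names(m) <- unname(swap[names(m)])
  trial$markers <- m[marker_ids()[marker_ids() %in% names(m)]]
  trial
}
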