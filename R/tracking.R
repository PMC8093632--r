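# Marker recovery from image stacks: threshold-based clustering of marker
# pixels, greedy nearest-neighbour tracking, and reconstruction of arena
# coordinates from the gantry stream.

#' Detect marker blobs in one frame
#'
#' Thresholds the image, labels connected components of supra-threshold
#' pixels and returns their intensity-weighted (sub-pixel) centroids,
#' sorted by descending pixel count.
#'
#' @param frame Grayscale image matrix (rows x cols, values 0-255).
#' @param intensity_threshold Pixels strictly above this value count as
#'   marker pixels.
#' @param min_pixels Minimum component size in pixels.
#' @return Data frame with columns `x_px`, `y_px` (sub-pixel image
#'   coordinates, x = column, y = row) and `n_pixels`; zero rows if nothing
#'   is detected.
#' @export
detect_markers <- function(frame, intensity_threshold = 50, min_pixels = 3) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  mask <- frame > intensity_threshold
  if (!any(mask))
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      n_pixels = integer(0)))
  lab <- EBImage::bwlabel(mask + 0)
  labs <- lab[mask]
  w <- as.numeric(frame[mask])
  rows <- row(frame)[mask]
  cols <- col(frame)[mask]
  npix <- tabulate(labs)
  keep <- which(npix >= min_pixels)
  if (length(keep) == 0)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      n_pixels = integer(0)))
  wsum <- vapply(keep, function(k) sum(w[labs == k]), numeric(1))
  cx <- vapply(keep, function(k) sum(w[labs == k] * cols[labs == k]),
               numeric(1)) / wsum
  cy <- vapply(keep, function(k) sum(w[labs == k] * rows[labs == k]),
               numeric(1)) / wsum
  out <- data.frame(x_px = cx, y_px = cy, n_pixels = npix[keep])
  out[order(-out$n_pixels), , drop = FALSE]
}

#' Track labelled markers through an image stack
#'
#' Nearest-neighbour tracking with greedy assignment: per frame, candidate
#' (label, detection) pairs are considered in ascending distance from each
#' label's last known position; each detection is used at most once and a
#' pair is accepted only within `max_jump_px`. Unmatched labels get a gap
#' flag and retain their last position for the next search. Labels are
#' initialised from an explicit label-to-position map for frame 1 (the
#' counterpart of manual first-frame labelling).
#'
#' @param frames List of grayscale image matrices.
#' @param initial_labels Named list/matrix of approximate `c(x_px, y_px)`
#'   positions in the first frame, one per marker label.
#' @param max_jump_px Maximum allowed frame-to-frame displacement (px); the default of 20 px sits well below the typical inter-marker spacing of the rendered walker (about 45 px).
#' @param intensity_threshold,min_pixels Passed to [detect_markers()].
#' @return A `marker_tracks` object: list with `labels`, `positions` (named
#'   list of n x 2 matrices of image coordinates, NA on gaps) and `gap`
#'   (n x k logical matrix).
#' @export
track_markers <- function(frames, initial_labels, max_jump_px = 20,
                          intensity_threshold = 50, min_pixels = 3) {
  if (length(frames) < 1) stop("empty image stack")
  labels <- names(initial_labels)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("initial_labels must be named by marker label")
  k <- length(labels)
  n <- length(frames)
  pos <- stats::setNames(lapply(labels, function(l)
    matrix(NA_real_, n, 2, dimnames = list(NULL, c("x_px", "y_px")))), labels)
  gap <- matrix(FALSE, n, k, dimnames = list(NULL, labels))
  last <- do.call(rbind, lapply(initial_labels, as.numeric))

  det0 <- detect_markers(frames[[1]], intensity_threshold, min_pixels)
  init_assign <- integer(k)
  for (i in seq_len(k)) {
    d <- sqrt((det0$x_px - last[i, 1])^2 + (det0$y_px - last[i, 2])^2)
    if (length(d) == 0 || min(d) > max_jump_px)
      stop("label '", labels[i], "' has no detection within max_jump_px ",
           "in the first frame")
    init_assign[i] <- which.min(d)
  }
  if (anyDuplicated(init_assign)) {
    dup <- init_assign[duplicated(init_assign)][1]
    stop("labels ", paste(labels[init_assign == dup], collapse = " and "),
         " initialised on the same detection")
  }

  for (f in seq_len(n)) {
    det <- if (f == 1) det0 else
      detect_markers(frames[[f]], intensity_threshold, min_pixels)
    assigned_det <- rep(FALSE, nrow(det))
    assigned_lab <- rep(FALSE, k)
    if (nrow(det) > 0) {
      d <- sqrt(outer(last[, 1], det$x_px, "-")^2 +
                  outer(last[, 2], det$y_px, "-")^2)
      ord <- order(d)
      for (o in ord) {
        if (d[o] > max_jump_px) break
        li <- (o - 1) %% k + 1
        di <- (o - 1) %/% k + 1
        if (assigned_lab[li] || assigned_det[di]) next
        assigned_lab[li] <- TRUE
        assigned_det[di] <- TRUE
        pos[[li]][f, ] <- c(det$x_px[di], det$y_px[di])
        last[li, ] <- c(det$x_px[di], det$y_px[di])
      }
    }
    gap[f, !assigned_lab] <- TRUE
  }
  structure(list(labels = labels, positions = pos, gap = gap),
            class = "marker_tracks")
}

#' Reconstruct arena coordinates from tracks and the gantry stream
#'
#' Combines per-frame image positions with the camera's arena position:
#' `arena = camera + mm_per_px * (centroid - image_centre)`, with the image
#' y axis flipped to arena north. Gaps propagate as missing samples and are
#' then filled by linear interpolation up to `max_gap_fill` consecutive
#' frames; longer gaps raise an error naming the marker and frame range.
#'
#' @param tracks A `marker_tracks` object (labels must be [marker_ids()]).
#' @param gantry Data frame (`frame`, `cam_x_mm`, `cam_y_mm`) covering all
#'   frames.
#' @param cal A [camera_calibration()].
#' @param frame_rate_hz Frame rate used to reconstruct time stamps.
#' @param max_gap_fill Longest gap (frames) bridged by interpolation.
#' @param animal_id,cohort Metadata for the resulting trial.
#' @return A `walker_trial` in arena coordinates.
#' @export
to_arena_coords <- function(tracks, gantry, cal, frame_rate_hz = 50,
                            max_gap_fill = 3, animal_id = "A1",
                            cohort = "tracked") {
  stopifnot(inherits(tracks, "marker_tracks"),
            inherits(cal, "camera_calibration"))
  n <- nrow(tracks$positions[[1]])
  if (nrow(gantry) < n) stop("gantry stream does not cover all frames")
  gantry <- gantry[order(gantry$frame), , drop = FALSE][seq_len(n), ]
  markers <- stats::setNames(lapply(tracks$labels, function(lab) {
    p <- tracks$positions[[lab]]
    sx <- (p[, 1] - cal$image_centre_px[1]) * cal$mm_per_px
    sy <- (p[, 2] - cal$image_centre_px[2]) * cal$mm_per_px
    if (cal$flip_y) sy <- -sy
    xy <- cbind(gantry$cam_x_mm + sx, gantry$cam_y_mm + sy)
    .fill_gaps(xy, max_gap_fill, lab)
  }), tracks$labels)
  walker_trial(times_s = (seq_len(n) - 1) / frame_rate_hz,
               markers = markers, animal_id = animal_id, cohort = cohort,
               frame_rate_hz = frame_rate_hz)
}

# Linear interpolation over interior NA runs of length <= max_gap.
.fill_gaps <- function(xy, max_gap, label) {
  miss <- is.na(xy[, 1]) | is.na(xy[, 2])
  if (!any(miss)) return(xy)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values)) {
    s <- starts[j]; e <- ends[j]
    if (s == 1 || e == nrow(xy))
      stop(sprintf("marker %s: unrecoverable gap at the stack edge (frames %d-%d)",
                   label, s - 1, e - 1))
    if (r$lengths[j] > max_gap)
      stop(sprintf("marker %s: gap of %d frames (frames %d-%d) exceeds max fill of %d",
                   label, r$lengths[j], s - 1, e - 1, max_gap))
    for (col in 1:2) {
      xy[s:e, col] <- xy[s - 1, col] +
        (xy[e + 1, col] - xy[s - 1, col]) * (seq_len(e - s + 1)) / (e - s + 2)
    }
  }
  xy
}
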