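# Idealized camera/gantry model: renders a trial into 8-bit grayscale frames
# with one Gaussian blob per marker, the camera following the walking body.

#' Camera calibration
#'
#' Maps image pixels (origin top-left, x right, y down) to arena mm
#' (x east, y north). The vertical image axis is flipped relative to the
#' arena by convention.
#'
#' @param mm_per_px Pixel pitch on the arena plane (mm/px), > 0.
#' @param image_size Frame size as `c(rows, cols)`; default 480 x 640.
#' @param flip_y Logical; image y runs downward while arena y runs north.
#' @return A `camera_calibration` list with the image centre precomputed.
#' @export
camera_calibration <- function(mm_per_px = 0.25, image_size = c(480, 640),
                               flip_y = TRUE) {
  if (!is.numeric(mm_per_px) || mm_per_px <= 0) stop("mm_per_px must be > 0")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 1))
    stop("image_size must be c(rows, cols)")
  structure(list(mm_per_px = as.numeric(mm_per_px), image_size = image_size,
                 image_centre_px = c((image_size[2] + 1) / 2,
                                     (image_size[1] + 1) / 2),
                 flip_y = isTRUE(flip_y)),
            class = "camera_calibration")
}

# arena (mm) -> image (px, c(x, y)); cam = camera arena position that frame
.arena_to_px <- function(xy_mm, cam_mm, cal) {
  sx <- (xy_mm[, 1] - cam_mm[1]) / cal$mm_per_px
  sy <- (xy_mm[, 2] - cam_mm[2]) / cal$mm_per_px
  if (cal$flip_y) sy <- -sy
  cbind(x_px = cal$image_centre_px[1] + sx,
        y_px = cal$image_centre_px[2] + sy)
}

#' Render a trial into an image stack plus gantry stream
#'
#' One 8-bit grayscale frame per time sample, with a Gaussian blob per
#' marker (peak 255). The camera follows the root (metathorax) marker with
#' optional Gaussian follow noise, emulating an experimenter tracking the
#' animal on a two-axis gantry; the returned gantry stream records the
#' camera's arena position per frame.
#'
#' @param trial A `walker_trial`.
#' @param camera List of camera parameters: `mm_per_px` (default 0.25),
#'   `image_size` (`c(480, 640)`), `blob_sigma_px` (default 1.5),
#'   `follow_noise_mm` (default 0).
#' @param seed Integer seed (used for the follow noise).
#' @return List with `frames` (list of integer matrices, 0-255), `gantry`
#'   (data.frame `frame`, `cam_x_mm`, `cam_y_mm`; 0-based frames) and
#'   `calibration` (the [camera_calibration()] used).
#' @export
render_frames <- function(trial, camera = list(), seed = 1) {
  stopifnot(inherits(trial, "walker_trial"))
  cam <- utils::modifyList(list(mm_per_px = 0.25, image_size = c(480, 640),
                                blob_sigma_px = 1.5, follow_noise_mm = 0),
                           camera)
  cal <- camera_calibration(cam$mm_per_px, cam$image_size)
  nr <- cal$image_size[1]; nc <- cal$image_size[2]
  sigma <- cam$blob_sigma_px
  rad <- max(2L, ceiling(4 * sigma))
  n <- length(trial$times_s)
  mk <- trial$markers

  withr::with_seed(as.integer(seed), {
    root <- mk[["meta"]]
    cam_pos <- root
    if (cam$follow_noise_mm > 0) {
      # manual gantry following is smooth: low-pass the tracking error over
      # ~0.5 s so the camera drifts around the animal instead of jittering
      w <- max(3L, 2L * (n %/% 40) + 1L)
      raw <- matrix(stats::rnorm(2 * n, 0, cam$follow_noise_mm * sqrt(w)),
                    ncol = 2)
      half <- (w - 1) / 2
      smooth1 <- function(v) vapply(seq_len(n), function(i)
        mean(v[max(1, i - half):min(n, i + half)]), numeric(1))
      cam_pos <- cam_pos + apply(raw, 2, smooth1)
    }
    frames <- vector("list", n)
    for (f in seq_len(n)) {
      img <- matrix(0, nr, nc)
      for (id in names(mk)) {
        px <- .arena_to_px(mk[[id]][f, , drop = FALSE], cam_pos[f, ], cal)
        cx <- px[1, 1]; cy <- px[1, 2]
        if (cx < 1 + rad || cx > nc - rad || cy < 1 + rad || cy > nr - rad)
          stop(sprintf("marker %s out of frame at frame index %d", id, f - 1))
        xs <- (round(cx) - rad):(round(cx) + rad)
        ys <- (round(cy) - rad):(round(cy) + rad)
        blob <- 255 * exp(-(outer((ys - cy)^2, (xs - cx)^2, "+")) /
                            (2 * sigma^2))
        img[ys, xs] <- img[ys, xs] + blob
      }
      frames[[f]] <- matrix(as.integer(pmin(255, round(img))), nr, nc)
    }
    list(frames = frames,
         gantry = data.frame(frame = seq_len(n) - 1L,
                             cam_x_mm = cam_pos[, 1], cam_y_mm = cam_pos[, 2]),
         calibration = cal)
  })
}
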