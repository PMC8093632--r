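# Blob detection, greedy nearest-neighbour tracking and arena
# reconstruction.

gauss_blob <- function(img, cx, cy, sigma = 1.5, peak = 255) {
  for (y in seq_len(nrow(img))) {
    img[y, ] <- img[y, ] +
      peak * exp(-((seq_len(ncol(img)) - cx)^2 + (y - cy)^2) / (2 * sigma^2))
  }
  matrix(as.integer(pmin(255, round(img))), nrow(img), ncol(img))
}

test_that("detection finds weighted centroids of supra-threshold clusters", {
  blank <- matrix(0L, 50, 60)
  expect_equal(nrow(detect_markers(blank)), 0)

  one <- gauss_blob(matrix(0, 300, 300), cx = 100, cy = 200)
  det <- detect_markers(one)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 100), 0.1)
  expect_lt(abs(det$y_px - 200), 0.1)

  two <- gauss_blob(gauss_blob(matrix(0, 100, 100), 30, 50), 60, 50)
  expect_equal(nrow(detect_markers(two)), 2)

  # sub-threshold noise below (threshold - 1) does not change detections
  set.seed(4)
  noisy <- two + matrix(sample(0:48, length(two), TRUE), nrow(two))
  det2 <- detect_markers(noisy, intensity_threshold = 50)
  expect_equal(nrow(det2), 2)
  expect_equal(det2$x_px, detect_markers(two)$x_px, tolerance = 0.2)
})

test_that("tracking follows a moving marker and flags gaps", {
  n <- 20
  frames <- lapply(seq_len(n), function(f)
    gauss_blob(matrix(0, 60, 80), cx = 10 + f, cy = 30))
  tr <- track_markers(frames, list(m = c(11, 30)), max_jump_px = 5)
  expect_false(any(tr$gap))
  expect_equal(tr$positions$m[, 1], 10 + seq_len(n), tolerance = 0.1)

  # marker vanishes for 2 frames, reappears within max_jump
  frames[[8]] <- matrix(0L, 60, 80)
  frames[[9]] <- matrix(0L, 60, 80)
  tr2 <- track_markers(frames, list(m = c(11, 30)), max_jump_px = 5)
  expect_equal(unname(which(tr2$gap[, "m"])), c(8, 9))
  expect_false(any(tr2$gap[10:n, "m"]))
})

test_that("two labels on one detection is an initialisation error", {
  f <- gauss_blob(matrix(0, 60, 80), 40, 30)
  expect_error(track_markers(list(f), list(a = c(40, 30), b = c(41, 30)),
                             max_jump_px = 5),
               "same detection")
})

test_that("greedy tracking of separated markers equals per-marker tracking", {
  n <- 15
  mk_frames <- function(keep = c(TRUE, TRUE)) {
    lapply(seq_len(n), function(f) {
      img <- matrix(0, 80, 80)
      if (keep[1]) img <- gauss_blob(img, 15 + f, 20)
      if (keep[2]) img <- gauss_blob(img, 60 - f, 60)
      if (is.integer(img)) img else
        matrix(as.integer(round(img)), nrow(img), ncol(img))
    })
  }
  both <- track_markers(mk_frames(), list(a = c(16, 20), b = c(59, 60)),
                        max_jump_px = 5)
  only_a <- track_markers(mk_frames(c(TRUE, FALSE)), list(a = c(16, 20)),
                          max_jump_px = 5)
  only_b <- track_markers(mk_frames(c(FALSE, TRUE)), list(b = c(59, 60)),
                          max_jump_px = 5)
  expect_equal(both$positions$a, only_a$positions$a)
  expect_equal(both$positions$b, only_b$positions$b)
})

test_that("arena reconstruction arithmetic and gap handling", {
  cal <- camera_calibration(mm_per_px = 0.5, image_size = c(480, 640))
  # one marker 10 px right of centre, camera at (10, 0)
  pos <- matrix(rep(c(cal$image_centre_px[1] + 10, cal$image_centre_px[2]),
                    each = 2), 2, 2)
  tracks <- structure(list(labels = "meta",
                           positions = list(meta = pos),
                           gap = matrix(FALSE, 2, 1)),
                      class = "marker_tracks")
  gantry <- data.frame(frame = 0:1, cam_x_mm = 10, cam_y_mm = 0)
  tr <- to_arena_coords(tracks, gantry, cal)
  expect_equal(unname(tr$markers$meta[1, ]), c(15, 0))

  # gap longer than max fill raises an informative error
  pos2 <- matrix(c(1:8, rep(30, 8)), 8, 2)
  pos2[3:7, ] <- NA
  tracks2 <- structure(list(labels = "meta", positions = list(meta = pos2),
                            gap = matrix(FALSE, 8, 1)),
                       class = "marker_tracks")
  gantry2 <- data.frame(frame = 0:7, cam_x_mm = 0, cam_y_mm = 0)
  expect_error(to_arena_coords(tracks2, gantry2, cal), "meta.*frames 2-6")
})

test_that("render -> track -> reconstruct recovers the simulated trial", {
  cfg <- walker_config(legs = default_legs(period_jitter_sd_s = 0.02))
  sim <- simulate_trial(cfg, 3, seed = 41)
  rnd <- render_frames(sim$trial, list(follow_noise_mm = 0.5), seed = 42)
  expect_equal(dim(rnd$frames[[1]]), c(480, 640))
  init <- lapply(marker_ids(), function(id) {
    m <- sim$trial$markers[[id]][1, ]
    c((m[1] - rnd$gantry$cam_x_mm[1]) / rnd$calibration$mm_per_px +
        rnd$calibration$image_centre_px[1],
      -(m[2] - rnd$gantry$cam_y_mm[1]) / rnd$calibration$mm_per_px +
        rnd$calibration$image_centre_px[2])
  })
  names(init) <- marker_ids()
  tracks <- track_markers(rnd$frames, init)
  expect_gte(mean(rowSums(tracks$gap) == 0), 0.99)
  rec <- to_arena_coords(tracks, rnd$gantry, rnd$calibration,
                         frame_rate_hz = cfg$frame_rate_hz)
  rms <- vapply(marker_ids(), function(id)
    sqrt(mean((rec$markers[[id]] - sim$trial$markers[[id]])^2)), numeric(1))
  expect_lt(max(rms), 0.5 * rnd$calibration$mm_per_px)
})

test_that("a static centred marker renders at the image centre", {
  trial <- walker_trial(times_s = c(0, 0.02),
                        markers = stats::setNames(lapply(marker_ids(),
                          function(i) matrix(0, 2, 2)), marker_ids()))
  # markers coincide at the arena origin; camera follows the root marker
  rnd <- render_frames(trial, list(), seed = 1)
  det <- detect_markers(rnd$frames[[1]])
  expect_equal(nrow(det), 1)  # nine coincident blobs merge into one
  expect_equal(det$x_px, rnd$calibration$image_centre_px[1], tolerance = 0.1)
  expect_equal(det$y_px, rnd$calibration$image_centre_px[2], tolerance = 0.1)
})
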