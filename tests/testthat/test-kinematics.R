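# Body frame, protraction angles, sliding median and body velocities.

# minimal hand-built trial: body axis along +x, femora placed explicitly
geom_trial <- function(femur_offsets) {
  base <- list(pro = c(30, 0), meso = c(15, 0), meta = c(0, 0))
  mk <- c(base, femur_offsets)
  walker_trial(times_s = c(0, 0.02),
               markers = lapply(mk, function(p) matrix(p, 2, 2, byrow = TRUE)))
}

test_that("protraction angle follows the stated geometric convention", {
  # lateral femur (perpendicular to body axis): angle 0 on both sides
  tr <- geom_trial(list(L1 = c(30, 12), L2 = c(15, 12), L3 = c(0, 12),
                        R1 = c(30, -12), R2 = c(15, -12), R3 = c(0, -12)))
  ang <- protraction_angles(tr, body_frame(tr))
  for (leg in leg_ids()) expect_equal(ang[[leg]]$angle_deg, c(0, 0))

  # femur parallel to the body axis, pointing anterior: +90 on both sides
  tr <- geom_trial(list(L1 = c(42, 0), L2 = c(27, 0), L3 = c(12, 0),
                        R1 = c(42, 0), R2 = c(27, 0), R3 = c(12, 0)))
  ang <- protraction_angles(tr, body_frame(tr))
  for (leg in leg_ids()) expect_equal(ang[[leg]]$angle_deg, c(90, 90))

  # 45 deg anterior of lateral on both sides: +45 each
  d <- 12 / sqrt(2)
  tr <- geom_trial(list(L1 = c(30 + d, d), L2 = c(15 + d, d), L3 = c(d, d),
                        R1 = c(30 + d, -d), R2 = c(15 + d, -d), R3 = c(d, -d)))
  ang <- protraction_angles(tr, body_frame(tr))
  for (leg in leg_ids()) expect_equal(ang[[leg]]$angle_deg, c(45, 45))
})

test_that("heading convention: +x is 0 deg, +y is 90 deg", {
  tr <- geom_trial(list(L1 = c(30, 12), L2 = c(15, 12), L3 = c(0, 12),
                        R1 = c(30, -12), R2 = c(15, -12), R3 = c(0, -12)))
  expect_equal(body_frame(tr)$heading_deg, c(0, 0))
  expect_equal(body_frame(rotate_trial(tr, 90))$heading_deg, c(90, 90))
})

test_that("angles are invariant to arena rotation and translation", {
  sim <- simulate_trial(coupled_config(jitter = 0.03), 6, seed = 51,
                        animal_id = "A1")
  ref <- protraction_angles(sim$trial, body_frame(sim$trial))
  for (tfm in list(function(t) rotate_trial(t, 117),
                   function(t) translate_trial(t, -310, 42))) {
    moved <- tfm(sim$trial)
    got <- protraction_angles(moved, body_frame(moved))
    for (leg in leg_ids())
      expect_equal(got[[leg]]$angle_deg, ref[[leg]]$angle_deg,
                   tolerance = 1e-9)
  }
  # rotation adds exactly the rotation angle to headings
  expect_equal(body_frame(rotate_trial(sim$trial, 117))$heading_deg,
               body_frame(sim$trial)$heading_deg + 117, tolerance = 1e-9)
})

test_that("mirroring swaps left/right angles and negates Ty and Rot", {
  cfg <- walker_config(legs = default_legs(period_jitter_sd_s = 0.03),
                       edges = default_edges(), vy_mm_s = 5, yaw_deg_s = 10)
  sim <- simulate_trial(cfg, 6, seed = 52)
  ref_ang <- protraction_angles(sim$trial, body_frame(sim$trial))
  mir <- mirror_trial(sim$trial)
  mir_ang <- protraction_angles(mir, body_frame(mir))
  expect_equal(mir_ang$L1$angle_deg, ref_ang$R1$angle_deg, tolerance = 1e-9)
  expect_equal(mir_ang$R3$angle_deg, ref_ang$L3$angle_deg, tolerance = 1e-9)

  vref <- body_velocities(body_frame(sim$trial), frame_rate_hz = 50)
  vmir <- body_velocities(body_frame(mir), frame_rate_hz = 50)
  expect_equal(vmir$tx_mm_s, vref$tx_mm_s, tolerance = 1e-9)
  expect_equal(vmir$ty_mm_s, -vref$ty_mm_s, tolerance = 1e-9)
  expect_equal(vmir$rot_deg_s, -vref$rot_deg_s, tolerance = 1e-9)
})

test_that("sliding median truncates its window at the edges", {
  expect_equal(sliding_median(c(5, 1, 9), 1), c(5, 1, 9))
  expect_equal(sliding_median(c(0, 100, 0), 3), c(50, 0, 50))
  expect_equal(sliding_median(rep(7, 10), 5), rep(7, 10))
  x <- c(1, 50, 2, 3, 80, 4)
  expect_equal(sliding_median(x, 3)[2:5],
               vapply(2:5, function(i) median(x[(i - 1):(i + 1)]), numeric(1)))
  expect_error(sliding_median(1:5, 2), "odd")
})

test_that("velocity recovery, filter width and sign conventions", {
  expect_equal(median_window_samples(60, 50), 3L)
  expect_equal(median_window_samples(60, 100), 7L)  # 6 samples forced odd
  expect_equal(median_window_samples(1, 50), 1L)

  # stationary trial: all velocities zero
  tr <- geom_trial(list(L1 = c(30, 12), L2 = c(15, 12), L3 = c(0, 12),
                        R1 = c(30, -12), R2 = c(15, -12), R3 = c(0, -12)))
  v <- body_velocities(body_frame(tr), frame_rate_hz = 50)
  expect_equal(unlist(v[, c("tx_mm_s", "ty_mm_s", "rot_deg_s")]),
               rep(0, 3), ignore_attr = TRUE)

  # configured (vx, vy, yaw) recovered on a noise-free simulation
  cfg <- walker_config(legs = default_legs(), edges = list(),
                       vx_mm_s = 30, vy_mm_s = -4, yaw_deg_s = 12)
  sim <- simulate_trial(cfg, 6, seed = 53)
  v <- body_velocities(body_frame(sim$trial), window_ms = 60,
                       frame_rate_hz = 50)
  core <- 3:(nrow(v) - 2)  # outside the filter edge region
  expect_equal(median(v$tx_mm_s[core]), 30, tolerance = 0.01 * 30)
  expect_lt(max(abs(v$ty_mm_s[core] - (-4))), 0.01 * 4 + 1e-6)
  expect_equal(median(v$rot_deg_s[core]), 12, tolerance = 0.01 * 12)
})

test_that("degenerate geometry is rejected", {
  mk <- list(pro = c(0, 0), meso = c(0, 0), meta = c(0, 0),
             L1 = c(1, 1), L2 = c(1, 1), L3 = c(1, 1),
             R1 = c(1, -1), R2 = c(1, -1), R3 = c(1, -1))
  tr <- walker_trial(0, lapply(mk, function(p) matrix(p, 1, 2)))
  expect_error(body_frame(tr), "coincident")
  expect_error(body_velocities(data.frame(time_s = 0, x_mm = 0, y_mm = 0,
                                          heading_deg = 0)), "2 frames")
})
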