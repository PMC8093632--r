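# Event-driven six-leg oscillator simulation with Cruse-rule coupling.
#
# Each leg alternates stance (angle runs linearly from AEP down to PEP) and
# swing (cosine-eased return from PEP to AEP). Cycle periods are drawn per
# cycle (Gaussian jitter). Rule 2 shortens the receiver's remaining stance
# when its sender touches down; rule 1 defers a receiver lift-off while its
# sender is in swing. The body translates/rotates with the configured
# velocity profile (explicit Euler at the frame rate) and the nine markers
# are placed from the body plan and the per-frame leg angles.

#' Simulate one walking trial
#'
#' Runs the coupled oscillator model and returns the marker-trajectory trial
#' together with its ground truth (all touch-down/lift-off events, realized
#' periods and the body pose time course).
#'
#' @param config A [walker_config()].
#' @param duration_s Trial duration in seconds; must be at least three times
#'   the longest configured leg period.
#' @param seed Integer seed; falls back to `config$seed`.
#' @param animal_id,cohort Metadata attached to the trial.
#' @return List with elements `trial` (a `walker_trial`) and `truth` (a
#'   `ground_truth` list: per-leg `touch_down_s`, `lift_off_s`,
#'   `aep_deg`, `pep_deg`, `periods_s`, plus `pose` with per-frame
#'   `x_mm`, `y_mm`, `heading_deg`).
#' @export
simulate_trial <- function(config, duration_s, seed = NULL,
                           animal_id = "A1", cohort = "synthetic") {
  stopifnot(inherits(config, "walker_config"))
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("simulate_trial needs a seed (argument or config$seed)")
  max_period <- max(vapply(config$legs, function(l) l$period_s, numeric(1)))
  if (!is.numeric(duration_s) || duration_s < 3 * max_period)
    stop(sprintf("duration_s must be at least 3 x the longest leg period (%g s)",
                 3 * max_period))
  for (l in config$legs)
    for (f in c("aep_deg", "pep_deg", "period_s", "stance_fraction"))
      if (!is.finite(l[[f]])) stop("non-finite leg config field: ", f)

  withr::with_seed(as.integer(seed), {
    ev <- .simulate_events(config, duration_s)
    angles <- .sample_leg_angles(config, ev$segments, duration_s)
    pose <- .integrate_pose(config, ncol(angles))
    markers <- .place_markers(config, pose, angles)
    times_s <- (seq_len(ncol(angles)) - 1) / config$frame_rate_hz
    trial <- walker_trial(times_s, markers, animal_id = animal_id,
                          cohort = cohort,
                          frame_rate_hz = config$frame_rate_hz)
    truth <- structure(list(legs = ev$truth, pose = pose,
                            lesion = config$lesion$site), class = "ground_truth")
    list(trial = trial, truth = truth)
  })
}

# Core event loop. Returns per-leg piecewise angle segments and ground truth.
.simulate_events <- function(config, duration_s) {
  legs <- config$legs
  ids <- leg_ids()
  n <- length(ids)
  phase <- character(n)          # "stance" | "swing"
  t_end <- numeric(n)            # scheduled end of current phase
  cur_period <- numeric(n)       # drawn period of the current cycle
  names(phase) <- names(t_end) <- names(cur_period) <- ids

  draw_period <- function(l)
    max(0.2 * l$period_s, l$period_s + stats::rnorm(1, 0, l$period_jitter_sd_s))

  # per-leg event record and angle segments
  td <- lo <- stats::setNames(vector("list", n), ids)
  segs <- stats::setNames(vector("list", n), ids)
  add_seg <- function(leg, t0, t1, a0, a1, type)
    segs[[leg]][[length(segs[[leg]]) + 1]] <<-
      list(t0 = t0, t1 = t1, a0 = a0, a1 = a1, type = type)
  seg_open_t <- numeric(n); names(seg_open_t) <- ids

  # random initial phase per leg: position each leg uniformly in its cycle
  for (leg in ids) {
    l <- legs[[leg]]
    p <- draw_period(l)
    cur_period[leg] <- p
    u <- stats::runif(1)
    if (u < l$stance_fraction) {
      # in stance, touched down at -u/stance_fraction * stance duration ago
      t_td <- -u * p                      # uniform over the stance span
      phase[leg] <- "stance"
      t_end[leg] <- t_td + l$stance_fraction * p
      seg_open_t[leg] <- t_td
    } else {
      t_lo <- -(u - l$stance_fraction) * p
      phase[leg] <- "swing"
      t_end[leg] <- t_lo + (1 - l$stance_fraction) * p
      seg_open_t[leg] <- t_lo
    }
  }

  edges <- config$edges
  out_edges <- stats::setNames(lapply(ids, function(s)
    Filter(function(e) e$sender == s, edges)), ids)
  rule1_senders <- stats::setNames(lapply(ids, function(r)
    vapply(Filter(function(e) e$receiver == r && e$rule1_enabled, edges),
           function(e) e$sender, character(1))), ids)

  pulse_t <- numeric(0); pulse_rcv <- character(0); pulse_str <- numeric(0)
  eps <- 1e-9

  repeat {
    ti <- which.min(t_end)
    t_leg <- unname(t_end[ti])
    t_pul <- if (length(pulse_t)) min(pulse_t) else Inf
    t_now <- min(t_leg, t_pul)
    if (t_now > duration_s) break

    if (t_pul <= t_leg) {
      pi_ <- which.min(pulse_t)
      rcv <- pulse_rcv[pi_]; str <- pulse_str[pi_]
      pulse_t <- pulse_t[-pi_]; pulse_rcv <- pulse_rcv[-pi_]
      pulse_str <- pulse_str[-pi_]
      if (phase[rcv] == "stance" && t_end[rcv] > t_pul)
        t_end[rcv] <- t_pul + (1 - str) * (t_end[rcv] - t_pul)
      next
    }

    leg <- ids[ti]; l <- legs[[leg]]
    if (phase[leg] == "stance") {
      # lift-off attempt, subject to rule 1
      holders <- rule1_senders[[leg]]
      holders <- holders[phase[holders] == "swing"]
      if (length(holders) > 0) {
        t_end[leg] <- max(t_end[holders]) + eps
        next
      }
      lo[[leg]] <- c(lo[[leg]], t_leg)
      add_seg(leg, seg_open_t[leg], t_leg, l$aep_deg, l$pep_deg, "stance")
      seg_open_t[leg] <- t_leg
      phase[leg] <- "swing"
      t_end[leg] <- t_leg + (1 - l$stance_fraction) * cur_period[leg]
    } else {
      # touch-down: new cycle begins
      td[[leg]] <- c(td[[leg]], t_leg)
      add_seg(leg, seg_open_t[leg], t_leg, l$pep_deg, l$aep_deg, "swing")
      seg_open_t[leg] <- t_leg
      phase[leg] <- "stance"
      p <- draw_period(l)
      cur_period[leg] <- p
      t_end[leg] <- t_leg + l$stance_fraction * p
      for (e in out_edges[[leg]]) {
        if (e$rule2_strength > 0) {
          pulse_t <- c(pulse_t, t_leg + e$rule2_latency_s)
          pulse_rcv <- c(pulse_rcv, e$receiver)
          pulse_str <- c(pulse_str, e$rule2_strength)
        }
      }
    }
  }

  # close the open segment of each leg out to the scheduled phase end
  for (leg in ids) {
    l <- legs[[leg]]
    if (phase[leg] == "stance")
      add_seg(leg, seg_open_t[leg], t_end[leg], l$aep_deg, l$pep_deg, "stance")
    else
      add_seg(leg, seg_open_t[leg], t_end[leg], l$pep_deg, l$aep_deg, "swing")
  }

  truth <- stats::setNames(lapply(ids, function(leg) {
    l <- legs[[leg]]
    tds <- td[[leg]][td[[leg]] >= 0 & td[[leg]] <= duration_s]
    los <- lo[[leg]][lo[[leg]] >= 0 & lo[[leg]] <= duration_s]
    list(leg_id = leg,
         touch_down_s = tds, lift_off_s = los,
         aep_deg = l$aep_deg, pep_deg = l$pep_deg,
         periods_s = diff(tds))
  }), ids)
  list(truth = truth, segments = segs)
}

# Sample the piecewise angle trajectories at the frame times; add noise.
.sample_leg_angles <- function(config, segments, duration_s) {
  rate <- config$frame_rate_hz
  times <- seq(0, duration_s, by = 1 / rate)
  out <- matrix(NA_real_, nrow = 6, ncol = length(times),
                dimnames = list(leg_ids(), NULL))
  for (leg in leg_ids()) {
    a <- rep(NA_real_, length(times))
    for (s in segments[[leg]]) {
      idx <- which(times >= s$t0 & times <= s$t1)
      if (length(idx) == 0) next
      u <- (times[idx] - s$t0) / max(s$t1 - s$t0, 1e-12)
      a[idx] <- if (s$type == "stance") {
        s$a0 + (s$a1 - s$a0) * u
      } else {
        s$a0 + (s$a1 - s$a0) * (1 - cos(pi * u)) / 2
      }
    }
    sd_n <- config$legs[[leg]]$angle_noise_sd_deg
    if (sd_n > 0) a <- a + stats::rnorm(length(a), 0, sd_n)
    out[leg, ] <- a
  }
  if (anyNA(out)) stop("internal: angle trajectory has uncovered frames")
  out
}

# Explicit Euler integration of the body pose at the frame rate.
.integrate_pose <- function(config, n_frames) {
  dt <- 1 / config$frame_rate_hz
  h <- numeric(n_frames); x <- numeric(n_frames); y <- numeric(n_frames)
  h[1] <- 0; x[1] <- 0; y[1] <- 0
  for (i in seq_len(n_frames - 1)) {
    hr <- h[i] * pi / 180
    x[i + 1] <- x[i] + (config$vx_mm_s * cos(hr) - config$vy_mm_s * sin(hr)) * dt
    y[i + 1] <- y[i] + (config$vx_mm_s * sin(hr) + config$vy_mm_s * cos(hr)) * dt
    h[i + 1] <- h[i] + config$yaw_deg_s * dt
  }
  data.frame(time_s = (seq_len(n_frames) - 1) * dt,
             x_mm = x, y_mm = y, heading_deg = h)
}

# Body-frame femur direction for a protraction angle (deg): 0 = lateral,
# positive = tilted anteriorly; left legs point +y, right legs -y.
.femur_dir <- function(angle_deg, side) {
  a <- angle_deg * pi / 180
  if (side == "left") cbind(sin(a), cos(a)) else cbind(sin(a), -cos(a))
}

# Place the nine markers in the arena frame from pose + leg angles.
.place_markers <- function(config, pose, angles) {
  n <- nrow(pose)
  hr <- pose$heading_deg * pi / 180
  ch <- cos(hr); sh <- sin(hr)
  to_arena <- function(bx, by)   # body -> arena, vectorized over frames
    cbind(x_mm = pose$x_mm + bx * ch - by * sh,
          y_mm = pose$y_mm + bx * sh + by * ch)
  th <- config$body$thoracic_marker_offsets
  markers <- list(pro = to_arena(th$pro[1], th$pro[2]),
                  meso = to_arena(th$meso[1], th$meso[2]),
                  meta = to_arena(th$meta[1], th$meta[2]))
  for (leg in leg_ids()) {
    anchor <- config$body$coxa_offsets[[leg]]
    dir <- .femur_dir(angles[leg, ], .leg_side(leg))
    bx <- anchor[1] + config$body$femur_length_mm * dir[, 1]
    by <- anchor[2] + config$body$femur_length_mm * dir[, 2]
    markers[[leg]] <- to_arena(bx, by)
  }
  markers
}

#' Generate a synthetic cohort
#'
#' Draws per-animal parameter offsets (Gaussian, independently per leg) and
#' simulates independent trials per animal. Deterministic under a fixed
#' seed.
#'
#' @param config Base [walker_config()] shared by the cohort.
#' @param n_animals Number of animals (>= 1).
#' @param trials_per_animal Trials simulated per animal.
#' @param between_animal_sd Named list of SDs for per-animal offsets on leg
#'   fields; recognised names: `aep_deg`, `pep_deg`, `period_s`. All default
#'   to 0 (identical animals).
#' @param duration_s Duration of each trial (s).
#' @param seed Integer seed for the whole cohort.
#' @param cohort Cohort label attached to every trial.
#' @return List of `list(trial, truth)` pairs, one per trial, with animal
#'   ids `"A1"`, `"A2"`, ...
#' @export
generate_cohort <- function(config, n_animals, trials_per_animal = 1,
                            between_animal_sd = list(), duration_s = 30,
                            seed = NULL, cohort = "synthetic") {
  stopifnot(inherits(config, "walker_config"))
  if (!is.numeric(n_animals) || n_animals < 1)
    stop("n_animals must be >= 1")
  sds <- utils::modifyList(list(aep_deg = 0, pep_deg = 0, period_s = 0),
                           as.list(between_animal_sd))
  if (any(unlist(sds) < 0)) stop("between_animal_sd values must be >= 0")
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("generate_cohort needs a seed")

  withr::with_seed(as.integer(seed), {
    animal_seeds <- sample.int(.Machine$integer.max, n_animals)
    res <- list()
    for (a in seq_len(n_animals)) {
      cfg_a <- config
      withr::with_seed(animal_seeds[a], {
        for (leg in leg_ids()) {
          l <- cfg_a$legs[[leg]]
          l$aep_deg <- l$aep_deg + stats::rnorm(1, 0, sds$aep_deg)
          l$pep_deg <- l$pep_deg + stats::rnorm(1, 0, sds$pep_deg)
          l$period_s <- max(0.1, l$period_s + stats::rnorm(1, 0, sds$period_s))
          if (l$aep_deg <= l$pep_deg) { # keep the working range valid
            mid <- (l$aep_deg + l$pep_deg) / 2
            l$aep_deg <- mid + 1; l$pep_deg <- mid - 1
          }
          cfg_a$legs[[leg]] <- l
        }
        trial_seeds <- sample.int(.Machine$integer.max, trials_per_animal)
      })
      for (k in seq_len(trials_per_animal)) {
        res[[length(res) + 1]] <- simulate_trial(
          cfg_a, duration_s, seed = trial_seeds[k],
          animal_id = paste0("A", a), cohort = cohort)
      }
    }
    res
  })
}
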