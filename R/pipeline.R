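# End-to-end orchestration: simulate two cohorts, (optionally) render and
# re-track the trials, run kinematics, step segmentation, phase coupling and
# the cohort comparison, and write all stage outputs plus a run manifest.

#' Per-trial analysis: angles, velocities, events, cycles
#'
#' Runs the kinematic stages on one trial.
#'
#' @param trial A `walker_trial`.
#' @param window_ms Velocity median-filter window (ms).
#' @param min_prominence_deg,min_separation_s Event detection thresholds.
#' @return List `body`, `angles`, `velocities`, `events`, `cycles`; the
#'   events and cycles data frames carry `animal_id` and `cohort` columns.
#' @export
analyze_trial <- function(trial, window_ms = 60, min_prominence_deg = 5,
                          min_separation_s = 0.1) {
  body <- body_frame(trial)
  angles <- protraction_angles(trial, body)
  vel <- body_velocities(body, window_ms = window_ms,
                         frame_rate_hz = trial$frame_rate_hz)
  events <- detect_events_all(angles,
                              min_prominence_deg = min_prominence_deg,
                              min_separation_s = min_separation_s)
  cycles <- do.call(rbind, lapply(leg_ids(), function(leg)
    step_cycles(events[events$leg_id == leg, ])))
  if (nrow(events) > 0) {
    events$animal_id <- trial$animal_id
    events$cohort <- trial$cohort
  }
  if (!is.null(cycles) && nrow(cycles) > 0) {
    cycles$animal_id <- trial$animal_id
    cycles$cohort <- trial$cohort
  }
  list(body = body, angles = angles, velocities = vel,
       events = events, cycles = cycles)
}

#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Two walker configs
#' define the cohorts to compare (typically a sham and a lesioned walker).
#'
#' @param config_a,config_b `walker_config`s for cohorts A and B.
#' @param n_animals,trials_per_animal,duration_s Cohort layout.
#' @param between_animal_sd Passed to [generate_cohort()].
#' @param render Logical: render frames and recover trials by tracking
#'   instead of using simulator marker output directly.
#' @param camera Camera parameters for [render_frames()] when rendering.
#' @param window_ms,min_prominence_deg,min_separation_s Analysis stage
#'   parameters.
#' @param pairs List of `c(receiver, sender)` leg pairs for phase coupling.
#' @param parameters Step parameters to compare between cohorts (columns of
#'   the cycle table).
#' @param B Bootstrap replicates.
#' @param seed Master seed (mandatory: every stochastic stage derives its
#'   seed from it).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config_a, config_b, n_animals = 5,
                            trials_per_animal = 2, duration_s = 30,
                            between_animal_sd = list(),
                            render = FALSE, camera = list(),
                            window_ms = 60, min_prominence_deg = 5,
                            min_separation_s = 0.1,
                            pairs = list(c("R1", "R2"), c("R2", "R3"),
                                         c("L1", "L2"), c("L2", "L3")),
                            parameters = c("period_s", "length_deg",
                                           "aep_deg", "pep_deg"),
                            B = 2000, seed = NULL, out_dir = NULL) {
  if (is.null(seed)) stop("pipeline_config: seed is mandatory")
  stopifnot(inherits(config_a, "walker_config"),
            inherits(config_b, "walker_config"))
  structure(list(config_a = config_a, config_b = config_b,
                 n_animals = n_animals, trials_per_animal = trials_per_animal,
                 duration_s = duration_s,
                 between_animal_sd = between_animal_sd,
                 render = isTRUE(render), camera = camera,
                 window_ms = window_ms,
                 min_prominence_deg = min_prominence_deg,
                 min_separation_s = min_separation_s,
                 pairs = pairs, parameters = parameters,
                 B = B, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optionally render + track) -> kinematics -> step
#' segmentation -> phase coupling -> balanced-bootstrap cohort comparison,
#' and returns all stage outputs together with a run manifest. Rerunning
#' with the same configuration reproduces the outputs exactly.
#'
#' @param pc A [pipeline_config()].
#' @return List `manifest`, `cohorts` (per-cohort per-trial analyses),
#'   `phases` (per cohort and pair), `phase_tests`, `estimates`,
#'   `comparisons`, `effect_table`.
#' @export
run_pipeline <- function(pc) {
  stopifnot(inherits(pc, "pipeline_config"))
  seeds <- withr::with_seed(pc$seed, sample.int(.Machine$integer.max, 4))
  log_stage <- function(...) message("[hexacoord] ", sprintf(...))

  log_stage("simulate: 2 cohorts x %d animals x %d trials",
            pc$n_animals, pc$trials_per_animal)
  cohorts <- list(
    A = generate_cohort(pc$config_a, pc$n_animals, pc$trials_per_animal,
                        pc$between_animal_sd, pc$duration_s,
                        seed = seeds[1], cohort = "A"),
    B = generate_cohort(pc$config_b, pc$n_animals, pc$trials_per_animal,
                        pc$between_animal_sd, pc$duration_s,
                        seed = seeds[2], cohort = "B"))

  get_trial <- function(sim, idx) {
    if (!pc$render) return(sim$trial)
    log_stage("render+track trial %d", idx)
    rnd <- render_frames(sim$trial, pc$camera, seed = seeds[3] + idx)
    init <- lapply(sim$trial$markers, function(m)
      .arena_to_px(m[1, , drop = FALSE], as.numeric(rnd$gantry[1, 2:3]),
                   rnd$calibration)[1, ])
    tr <- track_markers(rnd$frames, init)
    out <- to_arena_coords(tr, rnd$gantry, rnd$calibration,
                           frame_rate_hz = sim$trial$frame_rate_hz,
                           animal_id = sim$trial$animal_id,
                           cohort = sim$trial$cohort)
    out
  }

  log_stage("kinematics + step segmentation")
  analyses <- lapply(names(cohorts), function(cn) {
    lapply(seq_along(cohorts[[cn]]), function(i) {
      trial <- get_trial(cohorts[[cn]][[i]], i)
      analyze_trial(trial, pc$window_ms, pc$min_prominence_deg,
                    pc$min_separation_s)
    })
  })
  names(analyses) <- names(cohorts)

  log_stage("phase coupling for %d leg pairs", length(pc$pairs))
  phases <- lapply(analyses, function(anl) {
    evs <- lapply(anl, `[[`, "events")
    stats::setNames(lapply(pc$pairs, function(p)
      pair_phase_stats(evs, p[1], p[2])),
      vapply(pc$pairs, function(p) paste0(p[1], "_in_", p[2]), character(1)))
  })
  phase_tests <- stats::setNames(lapply(seq_along(pc$pairs), function(j) {
    pa <- phases$A[[j]]; pb <- phases$B[[j]]
    ww <- tryCatch(watson_williams(pa$per_animal$phi_deg,
                                   pb$per_animal$phi_deg),
                   error = function(e) list(F = NA, p = NA))
    ku <- tryCatch(kuiper_two_sample(pa$samples$phase_deg,
                                     pb$samples$phase_deg),
                   error = function(e) list(V = NA, p = NA))
    list(watson_williams = ww, kuiper = ku)
  }), names(phases$A))

  log_stage("balanced bootstrap (B = %d)", pc$B)
  cycles <- lapply(analyses, function(anl)
    do.call(rbind, lapply(anl, `[[`, "cycles")))
  estimates <- list()
  comparisons <- list()
  for (par in pc$parameters) {
    for (leg in leg_ids()) {
      per_cohort <- lapply(cycles, function(cy) {
        sub <- cy[cy$leg_id == leg, ]
        split(sub[[par]], sub$animal_id)
      })
      if (any(vapply(per_cohort, function(x)
        length(x) == 0 || any(lengths(x) == 0), logical(1)))) next
      ea <- bootstrap_median_ci(per_cohort$A, B = pc$B, seed = seeds[4],
                                parameter = par)
      eb <- bootstrap_median_ci(per_cohort$B, B = pc$B, seed = seeds[4] + 1,
                                parameter = par)
      key <- paste(par, leg, sep = ".")
      estimates[[key]] <- list(A = ea, B = eb)
      comparisons[[key]] <- compare_cohorts(ea, eb, label = leg)
    }
  }
  effect_table <- summarize_lesion_effects(comparisons)

  manifest <- list(package_version = as.character(utils::packageVersion("hexacoord")),
                   seed = pc$seed, stage_seeds = seeds,
                   n_trials = vapply(cohorts, length, integer(1)),
                   n_cycles = vapply(cycles, nrow, integer(1)),
                   rendered = pc$render,
                   parameters = pc$parameters,
                   pairs = vapply(pc$pairs, paste, character(1), collapse = ":"),
                   B = pc$B)

  res <- list(manifest = manifest, cohorts = analyses, phases = phases,
              phase_tests = phase_tests, estimates = estimates,
              comparisons = comparisons, effect_table = effect_table)

  if (!is.null(pc$out_dir)) .write_pipeline_outputs(res, cohorts, pc)
  res
}

.write_pipeline_outputs <- function(res, cohorts, pc) {
  dir.create(pc$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cn in names(cohorts)) {
    for (i in seq_along(cohorts[[cn]])) {
      write_trial(cohorts[[cn]][[i]]$trial,
                  file.path(pc$out_dir,
                            sprintf("trial_%s_%02d.csv", cn, i)))
    }
    cy <- do.call(rbind, lapply(res$cohorts[[cn]], `[[`, "cycles"))
    utils::write.csv(cy, file.path(pc$out_dir,
                                   sprintf("cycles_%s.csv", cn)),
                     row.names = FALSE)
    for (pair in names(res$phases[[cn]])) {
      ph <- res$phases[[cn]][[pair]]
      utils::write.csv(ph$histogram,
                       file.path(pc$out_dir,
                                 sprintf("rose_%s_%s.csv", cn, pair)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(cbind(parameter = rownames(res$effect_table),
                         res$effect_table),
                   file.path(pc$out_dir, "effect_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$manifest,
                       file.path(pc$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
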