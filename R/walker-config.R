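# Configuration objects for the six-leg oscillator walker.

#' Canonical leg identifiers
#'
#' Legs are named front to rear on each body side: `L1`, `L2`, `L3` (left
#' front, middle, hind) and `R1`, `R2`, `R3` (right).
#'
#' @return Character vector of the six leg ids.
#' @export
leg_ids <- function() c("L1", "L2", "L3", "R1", "R2", "R3")

#' Canonical marker identifiers
#'
#' Nine markers: three thoracic markers on the dorsal midline (`pro`, `meso`,
#' `meta`; `meta` is the root marker and body-frame origin) and six femoral
#' markers named after their legs (`L1` ... `R3`).
#'
#' @return Character vector of the nine marker ids.
#' @export
marker_ids <- function() c("pro", "meso", "meta", leg_ids())

.leg_segment <- function(leg_id) {
  # thoracic marker that anchors each leg's femur vector
  seg <- c(L1 = "pro", L2 = "meso", L3 = "meta",
           R1 = "pro", R2 = "meso", R3 = "meta")
  unname(seg[leg_id])
}

.leg_side <- function(leg_id) ifelse(substr(leg_id, 1, 1) == "L", "left", "right")

#' Per-leg oscillator configuration
#'
#' Describes one leg's intrinsic step cycle: angular working range between
#' the anterior extreme position (AEP, touch-down) and posterior extreme
#' position (PEP, lift-off), cycle period, stance fraction, and noise terms.
#' Protraction angles follow the convention that zero means the femur is
#' orthogonal to the body axis and positive angles point forward.
#'
#' @param leg_id One of `leg_ids()`.
#' @param aep_deg Touch-down (anterior extreme) angle in degrees.
#' @param pep_deg Lift-off (posterior extreme) angle in degrees; must be
#'   smaller than `aep_deg` (step length is `aep_deg - pep_deg`).
#' @param period_s Intrinsic step cycle period in seconds.
#' @param stance_fraction Fraction of the period spent in stance, in (0, 1).
#' @param period_jitter_sd_s SD of the per-cycle Gaussian period jitter (s).
#' @param angle_noise_sd_deg SD of additive per-frame angle noise (deg).
#' @return A `leg_config` list.
#' @export
leg_config <- function(leg_id, aep_deg, pep_deg, period_s,
                       stance_fraction = 0.65,
                       period_jitter_sd_s = 0,
                       angle_noise_sd_deg = 0) {
  if (!is.character(leg_id) || length(leg_id) != 1 || !leg_id %in% leg_ids())
    stop("leg_id must be one of: ", paste(leg_ids(), collapse = ", "))
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop(sprintf("leg %s: field '%s' must be a finite number", leg_id, nm))
    as.numeric(x)
  }
  aep_deg <- num1(aep_deg, "aep_deg")
  pep_deg <- num1(pep_deg, "pep_deg")
  period_s <- num1(period_s, "period_s")
  stance_fraction <- num1(stance_fraction, "stance_fraction")
  period_jitter_sd_s <- num1(period_jitter_sd_s, "period_jitter_sd_s")
  angle_noise_sd_deg <- num1(angle_noise_sd_deg, "angle_noise_sd_deg")
  if (aep_deg <= pep_deg)
    stop(sprintf("leg %s: aep_deg (%g) must exceed pep_deg (%g)",
                 leg_id, aep_deg, pep_deg))
  if (period_s <= 0)
    stop(sprintf("leg %s: period_s must be > 0", leg_id))
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop(sprintf("leg %s: stance_fraction must lie in (0, 1)", leg_id))
  if (period_jitter_sd_s < 0)
    stop(sprintf("leg %s: period_jitter_sd_s must be >= 0", leg_id))
  if (angle_noise_sd_deg < 0)
    stop(sprintf("leg %s: angle_noise_sd_deg must be >= 0", leg_id))
  structure(list(leg_id = leg_id, aep_deg = aep_deg, pep_deg = pep_deg,
                 period_s = period_s, stance_fraction = stance_fraction,
                 period_jitter_sd_s = period_jitter_sd_s,
                 angle_noise_sd_deg = angle_noise_sd_deg),
            class = "leg_config")
}

#' Coupling edge between two legs
#'
#' One directed sender-to-receiver coupling following the two classic
#' coordination rules. Rule 2: at each sender touch-down (plus a neural
#' latency) the receiver's remaining stance duration is shortened by
#' `rule2_strength` times the time remaining, promoting receiver swing onset
#' shortly after the sender takes on load. Rule 1: while the sender swings,
#' the receiver's lift-off is deferred.
#'
#' @param sender,receiver Distinct leg ids.
#' @param rule2_strength Fraction in \[0, 1\] of the receiver's remaining
#'   stance advanced at a sender touch-down; 0 disables rule 2 on this edge.
#' @param rule2_latency_s Latency in seconds between sender touch-down and
#'   the rule-2 effect on the receiver.
#' @param rule1_enabled Logical; whether sender swing suppresses receiver
#'   lift-off.
#' @return A `coupling_edge` list with an `id` of the form `"R2->R1"`.
#' @export
coupling_edge <- function(sender, receiver, rule2_strength = 0.6,
                          rule2_latency_s = 0.04, rule1_enabled = TRUE) {
  if (!sender %in% leg_ids()) stop("sender must be a leg id, got: ", sender)
  if (!receiver %in% leg_ids()) stop("receiver must be a leg id, got: ", receiver)
  if (identical(sender, receiver))
    stop("coupling edge: sender and receiver must differ (", sender, ")")
  if (!is.numeric(rule2_strength) || length(rule2_strength) != 1 ||
      !is.finite(rule2_strength) || rule2_strength < 0 || rule2_strength > 1)
    stop(sprintf("edge %s->%s: rule2_strength must lie in [0, 1]",
                 sender, receiver))
  if (!is.numeric(rule2_latency_s) || !is.finite(rule2_latency_s) ||
      rule2_latency_s < 0)
    stop(sprintf("edge %s->%s: rule2_latency_s must be >= 0", sender, receiver))
  structure(list(id = paste0(sender, "->", receiver),
                 sender = sender, receiver = receiver,
                 rule2_strength = as.numeric(rule2_strength),
                 rule2_latency_s = as.numeric(rule2_latency_s),
                 rule1_enabled = isTRUE(rule1_enabled)),
            class = "coupling_edge")
}

#' Default coupling topology
#'
#' Ipsilateral posterior-to-anterior edges (`L2->L1`, `L3->L2`, `R2->R1`,
#' `R3->R2`) carrying both rules, plus contralateral edges between homologous
#' legs with the left (intact-side in the lesion experiments) leg as sender
#' (`L1->R1`, `L2->R2`, `L3->R3`), rule 2 only.
#'
#' @param ipsi_strength,contra_strength Rule-2 strengths for the two edge
#'   classes.
#' @param rule2_latency_s Shared rule-2 latency (s).
#' @return List of `coupling_edge` objects.
#' @export
default_edges <- function(ipsi_strength = 0.6, contra_strength = 0.3,
                          rule2_latency_s = 0.04) {
  ipsi <- list(c("L2", "L1"), c("L3", "L2"), c("R2", "R1"), c("R3", "R2"))
  contra <- list(c("L1", "R1"), c("L2", "R2"), c("L3", "R3"))
  c(lapply(ipsi, function(p) coupling_edge(p[1], p[2], ipsi_strength,
                                           rule2_latency_s, TRUE)),
    lapply(contra, function(p) coupling_edge(p[1], p[2], contra_strength,
                                             rule2_latency_s, FALSE)))
}

#' Connective lesion specification
#'
#' A lesion of one thoracic connective removes neural information transfer
#' across it, silencing the coupling edges that cross the cut. `T2_right`
#' (cut between the pro- and mesothoracic ganglia on the right) severs the
#' ipsilateral `R2->R1` edge and the contralateral `L2->R2` edge;
#' `T3_right` (cut between the meso- and metathoracic ganglia) severs
#' `R3->R2`. Severed edges have rule-2 strength forced to 0 and rule 1
#' disabled.
#'
#' @param site One of `"none"`, `"T2_right"`, `"T3_right"`.
#' @param severed_edges Optional character vector of edge ids (`"A->B"`)
#'   overriding the default mapping.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(site = c("none", "T2_right", "T3_right"),
                        severed_edges = NULL) {
  site <- match.arg(site)
  if (is.null(severed_edges)) {
    severed_edges <- switch(site,
      none = character(0),
      T2_right = c("R2->R1", "L2->R2"),
      T3_right = "R3->R2")
  } else {
    severed_edges <- as.character(severed_edges)
    if (site == "none" && length(severed_edges) > 0)
      stop("lesion site 'none' must not sever any edges")
  }
  structure(list(site = site, severed_edges = severed_edges),
            class = "lesion_spec")
}

#' Body plan: marker geometry in the body frame
#'
#' Positions are in mm in the body frame (x anterior, y left); the
#' metathorax root marker is the origin and the prothorax marker lies
#' anterior to it. By default each leg's femur is anchored at its segment's
#' thoracic marker so that the configured protraction angle is exactly the
#' marker-line angle the analysis measures; displaced `coxa_offsets` are
#' allowed but then the measured angle is the marker-line angle, not the
#' anatomical thorax-coxa angle.
#'
#' @param thoracic_marker_offsets Named list (`pro`, `meso`, `meta`) of 2-D
#'   positions (mm).
#' @param coxa_offsets Named list (leg ids) of 2-D femur anchor positions
#'   (mm); defaults to each leg's segment marker position.
#' @param femur_length_mm Femur marker distance from its anchor (mm).
#' @return A `body_plan` list.
#' @export
body_plan <- function(thoracic_marker_offsets = list(pro = c(30, 0),
                                                     meso = c(15, 0),
                                                     meta = c(0, 0)),
                      coxa_offsets = NULL,
                      femur_length_mm = 12) {
  need <- c("pro", "meso", "meta")
  if (!all(need %in% names(thoracic_marker_offsets)))
    stop("thoracic_marker_offsets must name pro, meso and meta")
  th <- lapply(thoracic_marker_offsets[need], function(p) {
    p <- as.numeric(p)
    if (length(p) != 2 || any(!is.finite(p)))
      stop("thoracic marker offsets must be finite 2-D positions")
    p
  })
  if (!isTRUE(all.equal(th$meta, c(0, 0))))
    stop("the metathorax root marker must be the body-frame origin (0, 0)")
  if (th$pro[1] <= 0)
    stop("the prothorax marker must lie anterior to the root marker")
  if (is.null(coxa_offsets))
    coxa_offsets <- stats::setNames(
      lapply(leg_ids(), function(l) th[[.leg_segment(l)]]), leg_ids())
  if (!all(leg_ids() %in% names(coxa_offsets)))
    stop("coxa_offsets must name all six legs")
  coxa_offsets <- lapply(coxa_offsets[leg_ids()], as.numeric)
  if (!is.numeric(femur_length_mm) || femur_length_mm <= 0)
    stop("femur_length_mm must be > 0")
  structure(list(thoracic_marker_offsets = th,
                 coxa_offsets = coxa_offsets,
                 femur_length_mm = as.numeric(femur_length_mm)),
            class = "body_plan")
}

#' Default leg configurations
#'
#' Working ranges and periods representative of free, straight walking in a
#' stick insect: front legs sweep roughly 10-60 deg, middle legs -5-30 deg,
#' hind legs -25-5 deg, with cycle periods of 0.6-0.7 s.
#'
#' @param period_jitter_sd_s,angle_noise_sd_deg Noise terms applied to every
#'   leg.
#' @return Named list of six `leg_config` objects.
#' @export
default_legs <- function(period_jitter_sd_s = 0, angle_noise_sd_deg = 0) {
  base <- list(
    L1 = c(60, 10, 0.6), L2 = c(30, -5, 0.7), L3 = c(5, -25, 0.7),
    R1 = c(60, 10, 0.6), R2 = c(30, -5, 0.7), R3 = c(5, -25, 0.7))
  stats::setNames(lapply(leg_ids(), function(l) {
    b <- base[[l]]
    leg_config(l, b[1], b[2], b[3],
               period_jitter_sd_s = period_jitter_sd_s,
               angle_noise_sd_deg = angle_noise_sd_deg)
  }), leg_ids())
}

#' Assemble and validate a walker configuration
#'
#' Builds the full simulator configuration from parts (or from a flat
#' key-value list via [build_walker_config()]). The lesion is applied here:
#' every severed edge gets rule-2 strength 0 and rule 1 disabled.
#'
#' @param legs Named list of six `leg_config` objects, one per leg id.
#' @param edges List of `coupling_edge` objects.
#' @param lesion A `lesion_spec` (or a site string).
#' @param body A `body_plan`.
#' @param vx_mm_s,vy_mm_s Forward and sideward (positive = leftward) body
#'   translation velocity, mm/s.
#' @param yaw_deg_s Yaw rotation velocity, deg/s, positive counter-clockwise.
#' @param frame_rate_hz Sampling rate of the virtual camera (Hz).
#' @param seed Optional default seed used by [simulate_trial()] when no seed
#'   is passed explicitly.
#' @return A validated `walker_config`.
#' @export
walker_config <- function(legs = default_legs(),
                          edges = default_edges(),
                          lesion = lesion_spec("none"),
                          body = body_plan(),
                          vx_mm_s = 30, vy_mm_s = 0, yaw_deg_s = 0,
                          frame_rate_hz = 50, seed = NULL) {
  if (is.character(lesion)) lesion <- lesion_spec(lesion)
  if (!inherits(lesion, "lesion_spec")) stop("lesion must be a lesion_spec")
  if (!inherits(body, "body_plan")) stop("body must be a body_plan")
  if (length(legs) != 6)
    stop("exactly six legs are required, got ", length(legs))
  for (lg in legs)
    if (!inherits(lg, "leg_config")) stop("legs must be leg_config objects")
  got <- vapply(legs, function(l) l$leg_id, character(1))
  missing <- setdiff(leg_ids(), got)
  if (length(missing) > 0)
    stop("missing leg configuration for: ", paste(missing, collapse = ", "))
  legs <- stats::setNames(legs[match(leg_ids(), got)], leg_ids())
  for (e in edges)
    if (!inherits(e, "coupling_edge")) stop("edges must be coupling_edge objects")
  edge_ids <- vapply(edges, function(e) e$id, character(1))
  if (anyDuplicated(edge_ids))
    stop("duplicate coupling edge: ", edge_ids[duplicated(edge_ids)][1])
  unknown <- setdiff(lesion$severed_edges, edge_ids)
  if (length(unknown) > 0)
    warning("lesion severs edges absent from the topology: ",
            paste(unknown, collapse = ", "))
  edges <- lapply(edges, function(e) {
    if (e$id %in% lesion$severed_edges) {
      e$rule2_strength <- 0
      e$rule1_enabled <- FALSE
      e$severed <- TRUE
    } else e$severed <- FALSE
    e
  })
  names(edges) <- edge_ids
  for (nm in c("vx_mm_s", "vy_mm_s", "yaw_deg_s", "frame_rate_hz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("field '", nm, "' must be a finite number")
  }
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0")
  structure(list(legs = legs, edges = edges, lesion = lesion, body = body,
                 vx_mm_s = as.numeric(vx_mm_s), vy_mm_s = as.numeric(vy_mm_s),
                 yaw_deg_s = as.numeric(yaw_deg_s),
                 frame_rate_hz = as.numeric(frame_rate_hz), seed = seed),
            class = "walker_config")
}

#' Build a walker configuration from a flat key-value list
#'
#' Convenience constructor for scripted use and YAML/JSON configs. Unknown
#' keys raise an error; missing keys take the package defaults
#' (stance fraction 0.65, rule-2 latency 0.04 s, 50 Hz).
#'
#' @param raw_params Named list. Recognised keys: `legs` (named list of
#'   per-leg lists with fields of [leg_config()]), `edges` (list of lists
#'   with fields of [coupling_edge()]), `lesion` (site string or list with
#'   `site`/`severed_edges`), `body` (list with fields of [body_plan()]),
#'   `vx_mm_s`, `vy_mm_s`, `yaw_deg_s`, `frame_rate_hz`, `seed`,
#'   `period_jitter_sd_s`, `angle_noise_sd_deg`, `ipsi_strength`,
#'   `contra_strength`, `rule2_latency_s`.
#' @return A validated `walker_config`.
#' @export
build_walker_config <- function(raw_params = list()) {
  known <- c("legs", "edges", "lesion", "body", "vx_mm_s", "vy_mm_s",
             "yaw_deg_s", "frame_rate_hz", "seed", "period_jitter_sd_s",
             "angle_noise_sd_deg", "ipsi_strength", "contra_strength",
             "rule2_latency_s")
  unknown <- setdiff(names(raw_params), known)
  if (length(unknown) > 0)
    stop("unknown walker parameter(s): ", paste(unknown, collapse = ", "))
  p <- raw_params
  jit <- p$period_jitter_sd_s %||% 0
  anz <- p$angle_noise_sd_deg %||% 0
  legs <- if (is.null(p$legs)) {
    default_legs(jit, anz)
  } else {
    stats::setNames(lapply(names(p$legs), function(nm) {
      lp <- p$legs[[nm]]
      do.call(leg_config, c(list(leg_id = nm),
        lp[setdiff(names(lp), "leg_id")],
        if (is.null(lp$period_jitter_sd_s)) list(period_jitter_sd_s = jit),
        if (is.null(lp$angle_noise_sd_deg)) list(angle_noise_sd_deg = anz)))
    }), names(p$legs))
  }
  lat <- p$rule2_latency_s %||% 0.04
  edges <- if (is.null(p$edges)) {
    default_edges(ipsi_strength = p$ipsi_strength %||% 0.6,
                  contra_strength = p$contra_strength %||% 0.3,
                  rule2_latency_s = lat)
  } else {
    lapply(p$edges, function(ep) {
      if (inherits(ep, "coupling_edge")) return(ep)
      if (is.null(ep$rule2_latency_s)) ep$rule2_latency_s <- lat
      do.call(coupling_edge, ep[setdiff(names(ep), "id")])
    })
  }
  lesion <- p$lesion %||% "none"
  if (is.list(lesion) && !inherits(lesion, "lesion_spec"))
    lesion <- lesion_spec(lesion$site %||% "none", lesion$severed_edges)
  body <- p$body %||% body_plan()
  if (is.list(body) && !inherits(body, "body_plan"))
    body <- do.call(body_plan, body)
  walker_config(legs = legs, edges = edges, lesion = lesion, body = body,
                vx_mm_s = p$vx_mm_s %||% 30, vy_mm_s = p$vy_mm_s %||% 0,
                yaw_deg_s = p$yaw_deg_s %||% 0,
                frame_rate_hz = p$frame_rate_hz %||% 50,
                seed = p$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.walker_config <- function(x, ...) {
  cat("<walker_config>\n")
  cat(sprintf("  legs: %s\n", paste(names(x$legs), collapse = " ")))
  sev <- vapply(x$edges, function(e) isTRUE(e$severed), logical(1))
  cat(sprintf("  edges: %d (%d severed)\n", length(x$edges), sum(sev)))
  cat(sprintf("  lesion: %s\n", x$lesion$site))
  cat(sprintf("  body velocity: vx=%g mm/s, vy=%g mm/s, yaw=%g deg/s\n",
              x$vx_mm_s, x$vy_mm_s, x$yaw_deg_s))
  cat(sprintf("  frame rate: %g Hz\n", x$frame_rate_hz))
  invisible(x)
}
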