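# Segmentation of protraction-angle time courses into alternating AEP
# (touch-down, local maximum) and PEP (lift-off, local minimum) events, and
# per-cycle step parameters.

#' Detect AEP/PEP events in an angle time course
#'
#' Local maxima of the protraction angle are taken as anterior extreme
#' positions (AEP, touch-down) and local minima as posterior extreme
#' positions (PEP, lift-off). Candidate extrema are pruned by repeatedly
#' removing the adjacent max/min pair with the smallest angular excursion
#' until every adjacent pair differs by at least `min_prominence_deg` and is
#' separated by at least `min_separation_s`; this enforces strict AEP/PEP
#' alternation, and of two same-kind candidates the more extreme one
#' survives. Leading and trailing partial events are retained.
#'
#' Before extremum extraction the series is smoothed with a 5-sample
#' quadratic Savitzky-Golay filter (about 100 ms at 50 Hz). Unlike a plain
#' moving average, this smoothing reproduces locally quadratic peaks
#' exactly, so it suppresses frame-to-frame angle noise without clipping
#' the reversal extremes; set `smooth_window = 1` to disable it.
#'
#' @param series Data frame with `time_s` and `angle_deg` (one leg), as
#'   produced by [protraction_angles()].
#' @param leg_id Leg label attached to the events.
#' @param min_prominence_deg Minimum angular excursion between adjacent
#'   opposite-kind events (deg).
#' @param min_separation_s Minimum time between adjacent events (s).
#' @param smooth_window Odd length of the Savitzky-Golay pre-smoothing
#'   window in samples; 1 disables smoothing.
#' @return Data frame `leg_id`, `kind` (`"AEP"`/`"PEP"`), `time_s`,
#'   `angle_deg`, in time order; zero rows for flat series.
#' @export
detect_events <- function(series, leg_id = "L1", min_prominence_deg = 5,
                          min_separation_s = 0.1, smooth_window = 5) {
  t <- series$time_s
  a <- series$angle_deg
  if (length(a) < 3) stop("series must have at least 3 samples")
  if (smooth_window > 1) {
    if (smooth_window %% 2 == 0) stop("smooth_window must be odd")
    if (length(a) > smooth_window)
      a <- signal::sgolayfilt(a, p = 2, n = smooth_window)
  }
  empty_ev <- data.frame(leg_id = character(0), kind = character(0),
                         time_s = numeric(0), angle_deg = numeric(0))
  if (diff(range(a)) < min_prominence_deg) return(empty_ev)
  idx <- .local_extrema(a)
  if (length(idx$i) == 0)
    return(data.frame(leg_id = character(0), kind = character(0),
                      time_s = numeric(0), angle_deg = numeric(0)))
  i <- idx$i; kind <- idx$kind

  # prune: drop the weakest adjacent pair until prominence/separation hold
  repeat {
    if (length(i) < 2) break
    d_ang <- abs(diff(a[i]))
    d_t <- diff(t[i])
    bad <- which(d_ang < min_prominence_deg | d_t < min_separation_s)
    if (length(bad) == 0) break
    j <- bad[which.min(d_ang[bad])]       # weakest offending pair (j, j+1)
    drop <- c(j, j + 1)
    # removing an interior pair merges its neighbours, which are same-kind:
    # keep the more extreme of the two
    i <- i[-drop]; kind <- kind[-drop]
    rep_i <- which(diff(match(kind, c("AEP", "PEP"))) == 0)
    while (length(rep_i) > 0) {
      j2 <- rep_i[1]
      keep_first <- if (kind[j2] == "AEP") a[i[j2]] >= a[i[j2 + 1]]
      else a[i[j2]] <= a[i[j2 + 1]]
      rm <- if (keep_first) j2 + 1 else j2
      i <- i[-rm]; kind <- kind[-rm]
      rep_i <- which(diff(match(kind, c("AEP", "PEP"))) == 0)
    }
  }
  data.frame(leg_id = rep(leg_id, length(i)), kind = kind,
             time_s = t[i], angle_deg = a[i])
}

# All strict local extrema; plateaus contribute their midpoint.
.local_extrema <- function(a) {
  n <- length(a)
  d <- diff(a)
  s <- sign(d)
  # carry the sign over flat runs so plateau edges are detected
  nz <- which(s != 0)
  if (length(nz) == 0) return(list(i = integer(0), kind = character(0)))
  s_filled <- s
  last <- 0
  for (k in seq_along(s_filled)) {
    if (s_filled[k] == 0) s_filled[k] <- last else last <- s_filled[k]
  }
  turns <- which(diff(s_filled) != 0)
  i <- integer(0); kind <- character(0)
  for (k in turns) {
    # extremum lies between the change of slope; take the extreme sample
    lo <- k; hi <- k + 1
    if (s_filled[k] > 0) {
      cand <- lo:min(n, hi)
      j <- cand[which.max(a[cand])]
      i <- c(i, j); kind <- c(kind, "AEP")
    } else {
      cand <- lo:min(n, hi)
      j <- cand[which.min(a[cand])]
      i <- c(i, j); kind <- c(kind, "PEP")
    }
  }
  # enforce alternation among raw candidates (plateaus can duplicate)
  if (length(i) > 1) {
    keep <- rep(TRUE, length(i))
    for (k in 2:length(i)) {
      prev <- max(which(keep[1:(k - 1)]))
      if (kind[k] == kind[prev]) {
        better <- if (kind[k] == "AEP") a[i[k]] > a[i[prev]] else a[i[k]] < a[i[prev]]
        if (better) keep[prev] <- FALSE else keep[k] <- FALSE
      }
    }
    i <- i[keep]; kind <- kind[keep]
  }
  list(i = i, kind = kind)
}

#' Assemble step cycles from alternating events
#'
#' One cycle per AEP-PEP-AEP triple: the cycle starts at a touch-down
#' (AEP), runs through the following lift-off (PEP) and ends at the next
#' touch-down, matching the phase-reference convention that a reference
#' cycle is the interval between two subsequent AEPs. Partial cycles at the
#' ends are discarded.
#'
#' @param events Data frame from [detect_events()] (one leg; strictly
#'   alternating kinds).
#' @return Data frame with one row per cycle: `leg_id`, `aep_time_s`,
#'   `aep_deg`, `pep_time_s`, `pep_deg`, `next_aep_time_s`, `period_s`,
#'   `length_deg`, `stance_s`, `swing_s`.
#' @export
step_cycles <- function(events) {
  empty <- data.frame(leg_id = character(0), aep_time_s = numeric(0),
                      aep_deg = numeric(0), pep_time_s = numeric(0),
                      pep_deg = numeric(0), next_aep_time_s = numeric(0),
                      period_s = numeric(0), length_deg = numeric(0),
                      stance_s = numeric(0), swing_s = numeric(0))
  if (nrow(events) < 3) return(empty)
  if (is.unsorted(events$time_s, strictly = TRUE))
    stop("event times must be strictly increasing")
  k <- events$kind
  if (any(k[-1] == k[-length(k)]))
    stop("events must strictly alternate between AEP and PEP")
  aep_i <- which(k == "AEP")
  aep_i <- aep_i[aep_i + 2 <= nrow(events)]
  if (length(aep_i) == 0) return(empty)
  aep <- events[aep_i, ]
  pep <- events[aep_i + 1, ]
  nxt <- events[aep_i + 2, ]
  data.frame(leg_id = aep$leg_id,
             aep_time_s = aep$time_s, aep_deg = aep$angle_deg,
             pep_time_s = pep$time_s, pep_deg = pep$angle_deg,
             next_aep_time_s = nxt$time_s,
             period_s = nxt$time_s - aep$time_s,
             length_deg = aep$angle_deg - pep$angle_deg,
             stance_s = pep$time_s - aep$time_s,
             swing_s = nxt$time_s - pep$time_s)
}

#' Detect events for every leg of a trial
#'
#' Convenience wrapper running [detect_events()] over the six angle series.
#'
#' @param angles Named list from [protraction_angles()].
#' @param ... Passed to [detect_events()].
#' @return Single data frame of events over all legs.
#' @export
detect_events_all <- function(angles, ...) {
  do.call(rbind, lapply(names(angles), function(leg)
    detect_events(angles[[leg]], leg_id = leg, ...)))
}
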