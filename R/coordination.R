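# Phase of receiver-leg lift-off within sender-leg reference cycles, mean
# phase vectors, and the circular tests used for cohort comparison.

#' Phase of events within a reference cycle
#'
#' The reference cycle of the sender leg is the interval between two
#' subsequent touch-down events (AEPs). Each receiver lift-off time `t`
#' falling in `[AEP_k, AEP_{k+1})` gets phase
#' `360 * (t - AEP_k) / (AEP_{k+1} - AEP_k)` degrees, so phase 0 means the
#' receiver lifted off exactly when the sender touched down. Lift-offs
#' outside every reference interval are dropped; their count is attached as
#' the `n_dropped` attribute.
#'
#' @param event_times Receiver lift-off times (s).
#' @param reference_aeps Strictly increasing sender touch-down times (s),
#'   at least 2.
#' @return Numeric vector of phases in `[0, 360)`, attribute `n_dropped`.
#' @export
phase_in_reference <- function(event_times, reference_aeps) {
  reference_aeps <- as.numeric(reference_aeps)
  if (length(reference_aeps) < 2)
    stop("need at least 2 reference touch-down times")
  if (is.unsorted(reference_aeps, strictly = TRUE))
    stop("reference touch-down times must be strictly increasing")
  t <- as.numeric(event_times)
  k <- findInterval(t, reference_aeps)
  ok <- k >= 1 & k < length(reference_aeps)
  ph <- 360 * (t[ok] - reference_aeps[k[ok]]) /
    (reference_aeps[k[ok] + 1] - reference_aeps[k[ok]])
  ph <- ph %% 360
  attr(ph, "n_dropped") <- sum(!ok)
  ph
}

#' Mean phase vector
#'
#' Circular mean direction and mean resultant length of a phase sample:
#' the mean of the unit vectors `(cos, sin)` of the phases; `phi_deg` is its
#' direction mapped to `[0, 360)` and `r` its length. `r = 1` means all
#' phases coincide; `r = 0` means no mean direction exists, in which case
#' `phi_deg` is reported as `NA`.
#'
#' @param phases_deg Non-empty numeric vector of phases (deg).
#' @return List `phi_deg`, `r`, `n`.
#' @export
mean_vector <- function(phases_deg) {
  p <- as.numeric(phases_deg)
  p <- p[is.finite(p)]
  if (length(p) == 0) stop("mean_vector: empty phase sample")
  a <- p * pi / 180
  C <- mean(cos(a)); S <- mean(sin(a))
  r <- sqrt(C^2 + S^2)
  phi <- if (r < 1e-12) NA_real_ else (atan2(S, C) * 180 / pi) %% 360
  list(phi_deg = phi, r = min(1, r), n = length(p))
}

#' Per-animal phase statistics and pooled histogram
#'
#' Circular statistics are computed on per-animal means: each animal
#' contributes one mean phase vector (phi, R, n); the pooled histogram over
#' all retained samples (15-degree bins, 24 bins) serves rose-plot display
#' only.
#'
#' @param samples Data frame with columns `animal_id` and `phase_deg`.
#' @return List with `per_animal` (data frame `animal_id`, `phi_deg`, `r`,
#'   `n`) and `histogram` (data frame `bin_start_deg`, `count`).
#' @export
per_animal_phase_stats <- function(samples) {
  if (nrow(samples) == 0) stop("no phase samples")
  ids <- unique(samples$animal_id)
  per <- do.call(rbind, lapply(ids, function(id) {
    mv <- mean_vector(samples$phase_deg[samples$animal_id == id])
    data.frame(animal_id = id, phi_deg = mv$phi_deg, r = mv$r, n = mv$n)
  }))
  bins <- seq(0, 345, by = 15)
  cnt <- tabulate(findInterval(samples$phase_deg %% 360, seq(0, 360, by = 15),
                               rightmost.closed = FALSE), nbins = 24)
  list(per_animal = per,
       histogram = data.frame(bin_start_deg = bins, count = cnt))
}

# Fisher's approximation of the von Mises concentration for resultant r.
.kappa_est <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' One-way circular ANOVA comparing the mean directions of two groups of
#' angles, with the standard concentration-based correction factor
#' `K = 1 + 3 / (8 kappa)` applied to the F statistic; `p` is the upper
#' tail of `F(1, N - 2)`. Intended for small groups of per-animal mean
#' phases.
#'
#' @param group_a_deg,group_b_deg Angle vectors (deg), at least 2 each.
#' @return List `F`, `p`, `df1`, `df2`, `kappa`.
#' @export
watson_williams <- function(group_a_deg, group_b_deg) {
  a <- as.numeric(group_a_deg) * pi / 180
  b <- as.numeric(group_b_deg) * pi / 180
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  R1 <- sqrt(sum(cos(a))^2 + sum(sin(a))^2)
  R2 <- sqrt(sum(cos(b))^2 + sum(sin(b))^2)
  Rt <- sqrt(sum(cos(c(a, b)))^2 + sum(sin(c(a, b)))^2)
  denom <- N - R1 - R2
  if (denom < 1e-10)
    stop("degenerate sample: all angles within each group are identical; ",
         "the Watson-Williams F is undefined for exact ties")
  rw <- (R1 + R2) / N
  kk <- .kappa_est(rw)
  K <- 1 + 3 / (8 * kk)
  Fstat <- K * (N - 2) * (R1 + R2 - Rt) / denom
  Fstat <- max(0, Fstat)
  p <- stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)
  list(F = Fstat, p = p, df1 = 1, df2 = N - 2, kappa = kk)
}

#' Two-sample Kuiper test on circular data
#'
#' Rotation-invariant two-sample test comparing the circular distributions
#' of two phase samples. The statistic is `V = max(F1 - F2) + max(F2 - F1)`
#' over the empirical distribution functions evaluated at the pooled
#' sample; on the circle this value does not depend on the choice of
#' origin. The p value uses the asymptotic series
#' `Q(lambda) = 2 * sum_j (4 j^2 lambda^2 - 1) exp(-2 j^2 lambda^2)` with
#' `lambda = (sqrt(Ne) + 0.155 + 0.24 / sqrt(Ne)) * V` and effective size
#' `Ne = n1 n2 / (n1 + n2)`.
#'
#' @param samples_a_deg,samples_b_deg Angle vectors (deg), at least 5 each.
#' @return List `V`, `p`, `n1`, `n2`.
#' @export
kuiper_two_sample <- function(samples_a_deg, samples_b_deg) {
  a <- sort(as.numeric(samples_a_deg) %% 360)
  b <- sort(as.numeric(samples_b_deg) %% 360)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 5 || n2 < 5) stop("each sample needs at least 5 values")
  pooled <- sort(unique(c(a, b)))
  Fa <- vapply(pooled, function(x) sum(a <= x), numeric(1)) / n1
  Fb <- vapply(pooled, function(x) sum(b <= x), numeric(1)) / n2
  dplus <- max(c(0, Fa - Fb))
  dminus <- max(c(0, Fb - Fa))
  V <- dplus + dminus
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  p <- .kuiper_fpp(lambda)
  list(V = V, p = p, n1 = n1, n2 = n2)
}

# Asymptotic Kuiper false-positive probability Q(lambda).
.kuiper_fpp <- function(lambda) {
  if (lambda < 0.4) return(1)
  j <- 1:120
  q <- 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, q))
}

#' Phase coupling summary for one leg pair
#'
#' Runs the full phase analysis for a (receiver, sender) pair over a set of
#' trials: per trial, receiver lift-off times are phased within the
#' sender's AEP-to-AEP reference cycles; samples are pooled per animal and
#' summarised by per-animal mean vectors.
#'
#' @param events_by_trial List of per-trial event data frames (from
#'   [detect_events_all()]), each with an `animal_id` attribute or an
#'   `animal_id` column.
#' @param receiver,sender Leg ids.
#' @return List as returned by [per_animal_phase_stats()], plus `samples`.
#' @export
pair_phase_stats <- function(events_by_trial, receiver, sender) {
  rows <- lapply(events_by_trial, function(ev) {
    aid <- if (!is.null(ev$animal_id)) ev$animal_id[1] else
      attr(ev, "animal_id") %||% "A1"
    lo <- ev$time_s[ev$leg_id == receiver & ev$kind == "PEP"]
    ref <- ev$time_s[ev$leg_id == sender & ev$kind == "AEP"]
    if (length(ref) < 2 || length(lo) == 0) return(NULL)
    ph <- phase_in_reference(lo, ref)
    if (length(ph) == 0) return(NULL)
    data.frame(animal_id = aid, phase_deg = as.numeric(ph))
  })
  samples <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(samples) || nrow(samples) == 0)
    stop(sprintf("no phase samples for pair %s in %s", receiver, sender))
  out <- per_animal_phase_stats(samples)
  out$samples <- samples
  out$pair <- paste0(receiver, " in ", sender)
  out
}
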