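# Shared fixture builders and independent statistical oracles.

# Walker with no coupling at all (empty edge list) -- the deterministic
# uncoupled limit when jitter is 0.
uncoupled_config <- function(jitter = 0, noise = 0, ...) {
  walker_config(legs = default_legs(period_jitter_sd_s = jitter,
                                    angle_noise_sd_deg = noise),
                edges = list(), ...)
}

# Walker with a single tunable ipsilateral chain plus default contralaterals.
coupled_config <- function(ipsi_strength = 0.9, jitter = 0.05, noise = 0,
                           lesion = "none", ...) {
  walker_config(legs = default_legs(period_jitter_sd_s = jitter,
                                    angle_noise_sd_deg = noise),
                edges = default_edges(ipsi_strength = ipsi_strength,
                                      contra_strength = 0.3),
                lesion = lesion, ...)
}

# Phase sample of receiver lift-offs in sender AEP cycles from ground truth.
truth_pair_phases <- function(truth, receiver = "R1", sender = "R2") {
  phase_in_reference(truth$legs[[receiver]]$lift_off_s,
                     truth$legs[[sender]]$touch_down_s)
}

# --- independent oracles -------------------------------------------------

# Watson-Williams F and p, transcribed directly from the published formulas
# (per-group resultant lengths, Fisher kappa of the weighted mean resultant,
# K = 1 + 3/(8 kappa), F ~ F(1, N - 2)); written with explicit loops so it
# shares no code with the package implementation.
oracle_watson_williams <- function(a_deg, b_deg) {
  res_len <- function(x) {
    cs <- 0; sn <- 0
    for (v in x * pi / 180) { cs <- cs + cos(v); sn <- sn + sin(v) }
    sqrt(cs^2 + sn^2)
  }
  n1 <- length(a_deg); n2 <- length(b_deg); N <- n1 + n2
  R1 <- res_len(a_deg); R2 <- res_len(b_deg); Rt <- res_len(c(a_deg, b_deg))
  rw <- (R1 + R2) / N
  kappa <- if (rw < 0.53) {
    2 * rw + rw^3 + 5 * rw^5 / 6
  } else if (rw < 0.85) {
    -0.4 + 1.39 * rw + 0.43 / (1 - rw)
  } else {
    1 / (rw^3 - 4 * rw^2 + 3 * rw)
  }
  Fs <- (1 + 3 / (8 * kappa)) * (N - 2) * (R1 + R2 - Rt) / (N - R1 - R2)
  list(F = Fs, p = stats::pf(Fs, 1, N - 2, lower.tail = FALSE))
}

# Two-sample Kuiper V by brute force: evaluate the circular EDF difference
# for every rotation origin placed at each pooled data point and take
# max(D+) + max(D-) computed on the rotated (linearized) samples. The
# statistic must not depend on the origin; the oracle returns the set of
# per-origin values so tests can assert that too.
oracle_kuiper_v <- function(a_deg, b_deg) {
  a <- a_deg %% 360; b <- b_deg %% 360
  origins <- sort(unique(c(a, b)))
  v_per_origin <- vapply(origins, function(o) {
    ar <- sort((a - o) %% 360); br <- sort((b - o) %% 360)
    ev <- sort(unique(c(ar, br)))
    Fa <- vapply(ev, function(x) mean(ar <= x), numeric(1))
    Fb <- vapply(ev, function(x) mean(br <= x), numeric(1))
    max(c(0, Fa - Fb)) + max(c(0, Fb - Fa))
  }, numeric(1))
  list(V = max(v_per_origin), per_origin = v_per_origin)
}

# Kuiper asymptotic tail probability, re-transcribed.
oracle_kuiper_p <- function(V, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  if (lam < 0.4) return(1)
  s <- 0
  for (j in 1:120) s <- s + (4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2)
  min(1, max(0, 2 * s))
}
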