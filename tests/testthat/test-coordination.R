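# Phase computation, mean vectors, per-animal statistics and the circular
# tests, checked against independent oracles.

test_that("phase semantics within the sender reference cycle", {
  ref <- c(0, 1, 2, 3)
  # lift-off exactly at a sender touch-down -> phase 0
  expect_equal(as.numeric(phase_in_reference(1, ref)), 0)
  # midpoint -> 180; quarter -> 90
  expect_equal(as.numeric(phase_in_reference(c(0.5, 1.25), ref)), c(180, 90))
  # lift-offs outside any reference interval are dropped and counted
  ph <- phase_in_reference(c(-0.5, 0.5, 3.5), ref)
  expect_equal(as.numeric(ph), 180)
  expect_equal(attr(ph, "n_dropped"), 2)
  expect_error(phase_in_reference(0.5, 1), "at least 2")
})

test_that("phases are invariant to time shift and uniform time rescaling", {
  set.seed(71)
  ref <- cumsum(runif(30, 0.5, 1.5))
  ev <- sort(runif(50, min(ref), max(ref)))
  base <- as.numeric(phase_in_reference(ev, ref))
  expect_equal(as.numeric(phase_in_reference(ev + 17.3, ref + 17.3)), base)
  expect_equal(as.numeric(phase_in_reference(ev * 4.2, ref * 4.2)), base,
               tolerance = 1e-9)
})

test_that("mean vector: closed forms and degenerate symmetry", {
  mv <- mean_vector(rep(60, 5))
  expect_equal(mv$phi_deg, 60)
  expect_equal(mv$r, 1)

  mv4 <- mean_vector(c(0, 90, 180, 270))
  expect_equal(mv4$r, 0)
  expect_true(is.na(mv4$phi_deg))

  mv2 <- mean_vector(c(0, 90))
  expect_equal(mv2$phi_deg, 45)
  expect_equal(mv2$r, cos(45 * pi / 180), tolerance = 1e-12)
  expect_error(mean_vector(numeric(0)), "empty")
})

test_that("r stays in [0, 1] and is 1 only for identical phases", {
  set.seed(72)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1), 0, 360)
    r <- mean_vector(p)$r
    expect_gte(r, 0); expect_lte(r, 1)
    if (max(p) - min(p) > 1) expect_lt(r, 1)
  }
})

test_that("per-animal statistics and the pooled 15-degree histogram", {
  s <- data.frame(animal_id = c("a", "a", "b", "b"),
                  phase_deg = c(0, 90, 10, 10))
  st <- per_animal_phase_stats(s)
  expect_equal(nrow(st$per_animal), 2)
  expect_equal(st$per_animal$phi_deg[st$per_animal$animal_id == "a"], 45)
  expect_equal(st$per_animal$r[st$per_animal$animal_id == "b"], 1)
  expect_equal(nrow(st$histogram), 24)
  expect_equal(sum(st$histogram$count), 4)
  expect_equal(st$histogram$count[st$histogram$bin_start_deg == 0], 3)
  expect_equal(st$histogram$count[st$histogram$bin_start_deg == 90], 1)

  # two identical animals give identical entries
  s2 <- data.frame(animal_id = rep(c("x", "y"), each = 3),
                   phase_deg = rep(c(10, 40, 70), 2))
  st2 <- per_animal_phase_stats(s2)$per_animal
  expect_equal(st2$phi_deg[1], st2$phi_deg[2])
  expect_equal(st2$r[1], st2$r[2])
})

test_that("Watson-Williams agrees with the reference-formula oracle", {
  set.seed(73)
  cases <- list(
    list(a = c(10, 20, 30), b = c(15, 25, 40, 50)),
    list(a = rnorm(5, 0, 8) %% 360, b = (90 + rnorm(5, 0, 8)) %% 360),
    list(a = rnorm(8, 200, 25) %% 360, b = rnorm(6, 210, 25) %% 360))
  for (cs in cases) {
    got <- watson_williams(cs$a, cs$b)
    ora <- oracle_watson_williams(cs$a, cs$b)
    expect_equal(got$F, ora$F, tolerance = 1e-6)
    expect_equal(got$p, ora$p, tolerance = 1e-6)
  }
  # identical groups: no direction difference
  ww <- watson_williams(c(10, 20, 30), c(10, 20, 30))
  expect_lt(ww$F, 1e-10)
  expect_equal(ww$p, 1, tolerance = 1e-6)
  # tight groups 90 deg apart separate decisively
  expect_lt(watson_williams(cases[[2]]$a, cases[[2]]$b)$p, 0.01)
  # order within groups does not matter
  expect_equal(watson_williams(rev(cases[[3]]$a), sample(cases[[3]]$b))$F,
               watson_williams(cases[[3]]$a, cases[[3]]$b)$F)
  expect_error(watson_williams(10, c(1, 2)), "at least 2")
  expect_error(watson_williams(c(5, 5, 5), c(5, 5)), "identical")
})

test_that("Kuiper two-sample test agrees with the brute-force oracle", {
  set.seed(74)
  cases <- list(
    list(a = rnorm(20, 0, 10) %% 360, b = runif(25, 0, 360)),
    list(a = runif(15, 0, 360), b = runif(15, 0, 360)),
    list(a = rnorm(30, 120, 30) %% 360, b = rnorm(30, 140, 30) %% 360))
  for (cs in cases) {
    got <- kuiper_two_sample(cs$a, cs$b)
    ora <- oracle_kuiper_v(cs$a, cs$b)
    expect_equal(got$V, ora$V, tolerance = 1e-6)
    # the statistic does not depend on the rotation origin
    expect_lt(diff(range(ora$per_origin)), 1e-9)
    expect_equal(got$p, oracle_kuiper_p(got$V, length(cs$a), length(cs$b)),
                 tolerance = 1e-6)
  }
  # identical samples: V = 0, p = 1
  x <- runif(10, 0, 360)
  k0 <- kuiper_two_sample(x, x)
  expect_equal(k0$V, 0)
  expect_equal(k0$p, 1)
  # joint rotation leaves the test unchanged
  k1 <- kuiper_two_sample(cases[[1]]$a, cases[[1]]$b)
  k2 <- kuiper_two_sample((cases[[1]]$a + 77) %% 360,
                          (cases[[1]]$b + 77) %% 360)
  expect_equal(k1$V, k2$V, tolerance = 1e-9)
  # tight vs uniform separates decisively
  set.seed(75)
  expect_lt(kuiper_two_sample(rnorm(50, 0, 10) %% 360,
                              runif(50, 0, 360))$p, 0.01)
  expect_error(kuiper_two_sample(1:3, 1:10), "at least 5")
})

test_that("per-animal R drops after lesion across seeded replicates", {
  wins <- 0
  for (seed in 1:10) {
    intact <- simulate_trial(coupled_config(0.9, jitter = 0.05), 60,
                             seed = seed)
    lesioned <- simulate_trial(coupled_config(0.9, jitter = 0.05,
                                              lesion = "T2_right"), 60,
                               seed = seed + 1000)
    ri <- mean_vector(truth_pair_phases(intact$truth))$r
    rl <- mean_vector(truth_pair_phases(lesioned$truth))$r
    if (ri > rl) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
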