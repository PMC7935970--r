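# Dissociation-gated phosphorylation kinetics.

test_that("free substrate follows the closed-form exponential exactly", {
  p <- kinetic_params(kon = 0, koff = 0, kp = 0.2)
  tc <- simulate_solution(p, c(B = 50), seq(0, 30, 0.25))
  expect_lt(max(abs(tc$B - 50 * exp(-0.2 * tc$time))), 1e-6)
  expect_lt(max(abs(tc$Bp - 50 * (1 - exp(-0.2 * tc$time)))), 1e-6)
  f <- fit_decay(tc$time, tc$B)
  expect_equal(f$k, 0.2, tolerance = 1e-6)
})

test_that("without enzymes the system relaxes to the dimer equilibrium", {
  p <- kinetic_params(kon = 2, koff = 1, kp = 0)
  tc <- simulate_solution(p, c(A = 10, B = 6), seq(0, 200, 1))
  d_star <- oracle_dimer_eq(10, 6, 1 / 2)
  expect_equal(tail(tc$AB, 1), d_star, tolerance = 1e-6)
  expect_equal(tail(tc$A, 1), 10 - d_star, tolerance = 1e-6)
  # Keq = kon/koff determines the endpoint, not the path
  p2 <- kinetic_params(kon = 20, koff = 10, kp = 0)
  tc2 <- simulate_solution(p2, c(A = 10, B = 6), seq(0, 200, 1))
  expect_equal(tail(tc2$AB, 1), d_star, tolerance = 1e-6)
})

test_that("with kinase only, all B-family mass ends phosphorylated", {
  p <- kinetic_params(kon = 10, koff = 2, kp = 0.3)
  tc <- simulate_solution(p, c(A = 20, B = 20), seq(0, 6000, 20))
  expect_equal(tail(tc$Bp, 1), 20, tolerance = 1e-4)
  expect_lt(attr(tc, "conservation_drift"), 1e-6)
})

test_that("conservation holds to 1e-6 over random parameters and modes", {
  set.seed(23)
  for (rep in 1:100) {
    p <- kinetic_params(kon = runif(1, 0.1, 30), koff = runif(1, 0.01, 30),
                        kp = runif(1, 0, 1), kdp = runif(1, 0, 0.5))
    init <- c(A = runif(1, 0, 60), B = runif(1, 0, 60),
              AB = runif(1, 0, 10), Bp = runif(1, 0, 20))
    tc <- simulate_solution(p, init, seq(0, 50, 1))
    expect_lt(attr(tc, "conservation_drift"), 1e-6)
  }
  # event-carrying modes conserve too
  p <- preset_kinetics("slb_tether")
  tc <- simulate_tether(p, attr(p, "init"), seq(0, 60, 1),
                        events = list(list(time = 5, type = "kinase"),
                                      list(time = 40, type = "phosphatase")))
  expect_lt(attr(tc, "conservation_drift"), 1e-6)
  pa <- preset_kinetics("slb_avidity")
  ta <- simulate_avidity(pa, attr(pa, "init"), seq(0, 45, 1),
                         events = attr(pa, "events"))
  expect_lt(attr(ta, "conservation_drift"), 1e-6)
})

test_that("deterministic ODE agrees with a Gillespie simulation", {
  sets <- list(c(kon = 0.5, koff = 1, kp = 0.3, A = 2, B = 2),
               c(kon = 1, koff = 0.3, kp = 0.15, A = 3, B = 1.5),
               c(kon = 0, koff = 0, kp = 0.4, A = 0, B = 3))
  set.seed(77)
  times <- seq(0, 15, 2.5)
  for (s in sets) {
    p <- kinetic_params(kon = s["kon"], koff = s["koff"], kp = s["kp"])
    tc <- simulate_solution(p, c(A = s[["A"]], B = s[["B"]]), times)
    ssa <- oracle_gillespie(s["kon"], s["koff"], s["kp"], s[["A"]], s[["B"]],
                            times, omega = 60, nruns = 12)
    btot <- s[["B"]]
    # Monte-Carlo error: a few percent of total at these copy numbers
    expect_lt(max(abs(ssa[, "Bp"] - tc$Bp)), 0.08 * btot)
    expect_lt(max(abs(ssa[, "AB"] - tc$AB)), 0.08 * btot)
  }
})

test_that("effective_rate limits: no complex, fast exchange", {
  # Keq -> 0: rate is kp itself
  p0 <- kinetic_params(kon = 1e-6, koff = 100, kp = 0.2)
  expect_equal(effective_rate(p0, c(A = 50, B = 50)), 0.2, tolerance = 0.01)
  # fast-exchange limit: kp * free-B fraction within 5%
  Kd <- 1
  pf <- kinetic_params(kon = 200, koff = 200 * Kd, kp = 0.05)
  d <- oracle_dimer_eq(20, 20, Kd)
  f_free <- (20 - d) / 20
  expect_equal(effective_rate(pf, c(A = 20, B = 20)), 0.05 * f_free,
               tolerance = 0.05) # 5% relative (expect_equal scales by target)
})

test_that("effective_rate is monotone in Keq and in total concentration", {
  kon <- 10
  keff_by_kd <- vapply(c(0.05, 0.2, 1, 5), function(Kd) {
    effective_rate(kinetic_params(kon = kon, koff = kon * Kd, kp = 0.2),
                   c(A = 25, B = 25))
  }, numeric(1))
  # stronger binding (higher Keq = 1/Kd) slows the reaction
  expect_true(all(diff(keff_by_kd) > 0))
  keff_by_conc <- vapply(c(50, 10, 2, 0.5), function(C) {
    effective_rate(kinetic_params(kon = kon, koff = kon * 0.34, kp = 0.2),
                   c(A = C, B = C))
  }, numeric(1))
  expect_true(all(diff(keff_by_conc) > 0))
})

test_that("tripling the kinase multiplies the rate by at most 3", {
  p1 <- preset_kinetics("hplc_complex_25C")
  k1 <- effective_rate(p1, attr(p1, "init"))
  p3 <- p1
  p3$kinase_scale <- 3
  k3 <- effective_rate(p3, attr(p1, "init"))
  expect_gt(k3, k1)
  expect_lt(k3 / k1, 3)
  # in the dissociation-nonlimiting regime the scaling is linear
  pf1 <- kinetic_params(kon = 1e-6, koff = 100, kp = 0.1)
  pf3 <- kinetic_params(kon = 1e-6, koff = 100, kp = 0.1, kinase_scale = 3)
  expect_equal(effective_rate(pf3, c(A = 10, B = 10)) /
                 effective_rate(pf1, c(A = 10, B = 10)), 3, tolerance = 0.02)
})

test_that("tether mode: equilibrium hold, kinase release, phosphatase recapture", {
  p <- preset_kinetics("slb_tether")
  init <- attr(p, "init")
  # no events: cargo signal constant at binding equilibrium
  hold <- simulate_tether(p, init, seq(0, 30, 1))
  expect_lt(diff(range(hold$cargo_membrane)) /
              max(hold$cargo_membrane), 1e-6)
  expect_equal(fit_constant(hold$time, hold$anchor_membrane)$se, 0)
  # kinase event: release fits the calibrated rate within 2x
  rel <- simulate_tether(p, init, attr(p, "times"), events = attr(p, "events"))
  fit <- fit_rise(rel$time, rel$cargo_membrane)
  expect_gt(fit$k, 0.07 / 2)
  expect_lt(fit$k, 0.07 * 2)
  expect_true(all(diff(rel$cargo_membrane) < 1e-9))
  # anchor channel flat throughout
  expect_lt(diff(range(rel$anchor_membrane)), 1e-12)
  # phosphatase reverses: signal rises above the post-kinase minimum
  p_rev <- p
  p_rev$kdp <- 0.3
  rev <- simulate_tether(p_rev, init, seq(0, 140, 1),
                         events = list(list(time = 0, type = "kinase"),
                                       list(time = 70, type = "phosphatase")))
  post_min <- min(rev$cargo_membrane[rev$time <= 70])
  expect_gt(tail(rev$cargo_membrane, 1), post_min * 1.2)
  expect_error(simulate_tether(p, init, 0:10,
                               events = list(list(time = -5, type = "kinase"))),
               "before")
  expect_error(simulate_tether(p, init, 0:10,
                               events = list(list(time = 1, type = "boil"))),
               "unknown event type")
})

test_that("avidity mode: monomer baseline, avidity retention, switching", {
  pa <- preset_kinetics("slb_avidity")
  base <- kinetic_params(kon = pa$kon, koff = pa$koff, k1on = pa$k1on,
                         k1off = pa$k1off, avidity_factor = 1, kp = 0)
  mono_frac <- pa$k1on / (pa$k1on + pa$k1off)
  # either protein alone: negligible membrane fraction (<= 5%)
  alone <- simulate_avidity(pa, c(A = 1), seq(0, 30, 1))
  expect_lt(tail(alone$membrane_A, 1), 0.05)
  expect_equal(tail(alone$membrane_A, 1), mono_frac, tolerance = 1e-3)
  # avidity_factor = 1: no enhancement over the monomer baseline
  null_av <- simulate_avidity(base, c(A = 1, B = 1), seq(0, 30, 1))
  expect_equal(tail(null_av$membrane_A, 1), mono_frac, tolerance = 1e-3)
  # with avidity, both-present membrane fraction exceeds the single case
  both <- simulate_avidity(pa, c(A = 1, B = 1), seq(0, 30, 1))
  expect_gt(tail(both$membrane_A, 1), 1.2 * tail(alone$membrane_A, 1))
  # kinase event releases both; zero-noise fit recovers 0.10 within 20%
  rel <- simulate_avidity(pa, attr(pa, "init"), attr(pa, "times"),
                          events = attr(pa, "events"))
  kA <- fit_rise(rel$time, rel$membrane_A)$k
  kB <- fit_rise(rel$time, rel$membrane_B)$k
  expect_equal(kA, 0.10, tolerance = 0.2)
  expect_equal(kB, 0.10, tolerance = 0.2)
  # phosphatase partially restores membrane signal
  p_rev <- pa
  p_rev$kdp <- 0.3
  rev <- simulate_avidity(p_rev, attr(pa, "init"), seq(0, 120, 1),
                          events = list(list(time = 0, type = "kinase"),
                                        list(time = 60, type = "phosphatase")))
  post_min <- min(rev$membrane_B[rev$time <= 60])
  expect_gt(tail(rev$membrane_B, 1), post_min * 1.2)
})

test_that("observable mappings: CD endpoints, HPLC conservation, pipeline consistency", {
  p <- preset_kinetics("hplc_complex_25C")
  init <- attr(p, "init")
  d0 <- oracle_dimer_eq(50, 50, p$koff / p$kon)
  y0 <- c(A = 50 - d0, B = 50 - d0, AB = d0, Bp = 0)
  tc <- simulate_solution(p, y0, seq(0, 600, 2))
  # all-dimer state maps to the folded MRE endpoint
  obs0 <- observables(tc[1, , drop = FALSE], list(mode = "cd", ab_ref = d0))
  expect_equal(obs0$mre222, -33000, tolerance = 1)
  # HPLC areas: substrate + product conserved at zero noise
  hp <- observables(tc, list(mode = "hplc", scale = 2))
  expect_lt(diff(range(hp$substrate_area + hp$product_area)), 1e-4)
  # full pipeline reproduces effective_rate within fit tolerance
  k_pipe <- fit_rise(hp$time, hp$product_area)$k
  k_eff <- effective_rate(p, init, times = seq(0, 600, 2))
  expect_equal(k_pipe, k_eff, tolerance = 0.01)
  expect_error(observables(tc, list(mode = "cd", species = "XY")), "unknown species")
  expect_error(observables(tc, list(mode = "nope")), "unknown observable")
})

test_that("invalid inputs are rejected", {
  expect_error(kinetic_params(kon = -1), "non-negative")
  expect_error(kinetic_params(avidity_factor = 0.5), "avidity_factor")
  p <- kinetic_params()
  expect_error(simulate_solution(p, c(B = -1), 0:5), "non-negative")
  expect_error(simulate_solution(p, c(Z = 1), 0:5), "unknown species")
})

test_that("YAML parameter files round-trip", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "params:", "  kon: 10", "  koff: 3.4", "  kp: 0.2",
    "init:", "  A: 50", "  B: 50",
    "times: {from: 0, to: 10, by: 1}",
    "events:", "- time: 2", "  type: kinase"), path)
  cfg <- read_kinetics_yaml(path)
  expect_equal(cfg$params$koff, 3.4)
  expect_equal(cfg$init[["A"]], 50)
  expect_equal(cfg$times, 0:10)
  expect_equal(cfg$events[[1]]$type, "kinase")
})
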