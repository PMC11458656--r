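library(deSolve)

test_that("profile solver agrees with the ODE oracle on random systems", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    cl <- runif(1, 1, 40)
    vc <- runif(1, 3, 60)
    # include both deep-peripheral (vp >> vc) and shallow (vp << vc)
    vp <- if (i %% 2 == 0) runif(1, 200, 3000) else runif(1, 1, 10)
    q <- runif(1, 2, 80)
    ktr <- runif(1, 0.2, 5)
    n_abs <- sample(1:3, 1)
    tt <- c(0.5, 1, 2, 4, 8, 12, 20)
    ind <- list(cl = cl, vc = vc, vp = vp, q = q, ktr = ktr)
    got <- solve_profile(ind, regimen(500, n_doses = 2), tt,
                         n_abs = n_abs)$conc
    want <- ode_oracle(cl, vc, vp, q, ktr, n_abs, c(0, 12), c(500, 500), tt)
    # relative to the profile scale: terminal-phase values can underflow
    # the ODE integrator's absolute tolerance
    worst <- max(worst,
                 max(abs(got - want) / pmax(abs(want), 1e-6 * max(want))))
  }
  expect_lt(worst, 1e-6)
})

test_that("repeated-eigenvalue regimes stay accurate", {
  # disposition eigenvalue colliding with the chain rate: ktr chosen equal
  # to the elimination micro-rate constant
  cl <- 16; vc <- 20; vp <- 40; q <- 10
  ktr <- cl / vc
  tt <- c(0.5, 1, 2, 4, 8, 12)
  got <- solve_profile(list(cl = cl, vc = vc, vp = vp, q = q, ktr = ktr),
                       regimen(500), tt, n_abs = 3)$conc
  want <- ode_oracle(cl, vc, vp, q, ktr, 3, 0, 500, tt)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("profiles are linear in dose and obey superposition", {
  p <- ref_params()
  ind <- as.list(add_typical_parameters(one_subject(weight = 40,
                                                    albumin = 33), p))
  tt <- seq(0.5, 24, by = 0.5)
  one <- solve_profile(ind, regimen(500), tt, params = p)$conc
  # dose scaling
  tripled <- solve_profile(ind, regimen(1500), tt, params = p)$conc
  expect_equal(tripled, 3 * one, tolerance = 1e-9)
  # superposition of two shifted single doses
  two <- solve_profile(ind, regimen(500, n_doses = 2), tt, params = p)$conc
  shifted <- c(rep(0, sum(tt <= 12)), one[tt + 12 <= max(tt)])
  expect_equal(two, one + shifted[seq_along(tt)], tolerance = 1e-9)
})

test_that("zero-dose and pre-dose concentrations are zero", {
  p <- ref_params()
  ind <- as.list(add_typical_parameters(one_subject(), p))
  none <- solve_profile(ind, NULL, c(1, 5, 10), params = p)
  expect_equal(none$conc, c(0, 0, 0))
  late <- solve_profile(ind, regimen(500, start = 6), c(2, 4, 6, 8),
                        params = p)
  # samples at and before the dose time are pre-dose
  expect_equal(late$conc[1:3], c(0, 0, 0))
  expect_gt(late$conc[4], 0)
})

test_that("mass balance holds in the noise-free system", {
  p <- ref_params()
  ind <- as.list(add_typical_parameters(one_subject(weight = 25,
                                                    albumin = 30), p))
  ind$f_occ <- 0.8
  st <- mpadose:::profile_states(ind, regimen(500, n_doses = 3),
                                 c(1, 6, 13, 25, 40), params = p)
  dosed <- 0.8 * 500 * c(1, 1, 2, 3, 3) # doses given by each time
  in_system <- rowSums(st)
  expect_equal(in_system, dosed, tolerance = 1e-6)
  # eliminated amount grows monotonically
  expect_true(all(diff(st[, "eliminated"]) > 0))
})

test_that("steady-state AUC equals F x dose / CL and the trapezoid limit", {
  expect_equal(steady_state_auc(list(cl = 12.5, f_occ = 1), 750), 60)
  expect_equal(steady_state_auc(list(cl = 12.5, f_occ = 1), 0), 0)
  p <- ref_params()
  ind <- as.list(add_typical_parameters(one_subject(weight = 40,
                                                    albumin = 33), p))
  ind$f_occ <- 1.3
  analytic <- steady_state_auc(ind, 500)
  # superpose doses to steady state, then trapezoid over one interval
  n_dose <- 120
  tt <- seq(12 * (n_dose - 1), 12 * n_dose, by = 0.05)
  prof <- solve_profile(ind, regimen(500, n_doses = n_dose), tt, params = p)
  trap <- sum(diff(prof$time) * (head(prof$conc, -1) + tail(prof$conc, -1)) / 2)
  expect_equal(trap, analytic, tolerance = 0.005)
  expect_error(steady_state_auc(list(cl = -2, f_occ = 1), 100), "positive")
})

test_that("solver input validation rejects malformed calls", {
  p <- ref_params()
  ind <- as.list(add_typical_parameters(one_subject(), p))
  expect_error(solve_profile(ind, regimen(500), c(2, 1), params = p),
               "increasing")
  expect_error(solve_profile(ind, regimen(500), c(-1, 2), params = p),
               "non-negative")
  bad <- tibble::tibble(time = c(5, 1), amt = c(100, 100), occ = 1L)
  expect_error(solve_profile(ind, bad, c(1, 2), params = p), "ordered")
})

test_that("all-zero variability makes runs seed-independent", {
  pop <- generate_population(5, seed = 1)
  a <- simulate_trial(pop, "licensed", params = fixed_params(), seed = 1)
  b <- simulate_trial(pop, "licensed", params = fixed_params(), seed = 999)
  expect_equal(a$auc, b$auc)
})
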