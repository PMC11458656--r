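# MAP estimation: recovery, priors, shrinkage, dose recommendation

test_that("noise-free rich curves recover individual clearance", {
  p <- ref_params()
  for (i in 1:5) {
    nf <- noise_free_dataset(pop_seed = 100 + i, ind_seed = 200 + i)
    # data generated without residual error: fit with a matching,
    # numerically small residual variance
    fit <- map_fit(nf$data, p, sigma2 = 1e-10)
    expect_lt(abs(fit$ind$cl - nf$ind$cl) / nf$ind$cl, 0.02)
  }
})

test_that("a flat prior with rich noise-free data gives the exact individual", {
  flat <- mpa_params(omega2_cl = 1e6, omega2_vc = 1e6, omega2_q = 1e6,
                     omega2_iov_f = 1e6)
  nf <- noise_free_dataset(pop_seed = 103, ind_seed = 203,
                           times = c(0.5, 1, 2, 3, 4, 6, 8, 10, 12),
                           params = mpa_params())
  fit <- map_fit(nf$data, flat, sigma2 = 1e-10)
  expect_lt(abs(fit$ind$cl - nf$ind$cl) / nf$ind$cl, 1e-3)
  expect_lt(abs(fit$ind$vc - nf$ind$vc) / nf$ind$vc, 1e-3)
  expect_lt(abs(fit$auc - nf$ind$f_occ[[1]][1] * 500 / nf$ind$cl) /
              (nf$ind$f_occ[[1]][1] * 500 / nf$ind$cl), 1e-3)
})

test_that("no usable observations return the population-typical individual", {
  p <- ref_params()
  ds <- tibble::tibble(
    id = 1L, time = 0, amt = 500, dv = NA_real_, evid = 1L, mdv = 1L,
    occ = 1L, weight = 70, height = 170, albumin = 35
  )
  fit <- map_fit(ds, p)
  expect_equal(unname(fit$eta), c(0, 0, 0))
  expect_equal(fit$ind$cl, 16.0)
  expect_equal(fit$ind$f_occ[[1]], 1)
})

test_that("all-zero concentrations are flagged ill-posed", {
  ds <- tibble::tibble(
    id = 1L, time = c(0, 2, 4), amt = c(500, NA, NA),
    dv = c(NA, 0, 0), evid = c(1L, 0L, 0L), mdv = c(1L, 0L, 0L),
    occ = 1L, weight = 70, height = 170, albumin = 35
  )
  expect_warning(fit <- map_fit(ds, ref_params()), "ill-posed")
  expect_equal(unname(fit$eta), c(0, 0, 0))
})

test_that("the returned mode never does worse than the prior mode", {
  p <- ref_params()
  for (i in 1:4) {
    pop <- generate_population(1, seed = 400 + i)
    ds <- suppressMessages(
      simulate_dataset(pop, regimen(500), sampling_design("limited"), p,
                       seed = 500 + i))
    fit <- map_fit(ds, p)
    expect_lte(fit$objective, fit$objective_prior_mode)
    expect_true(all(fit$ipred$ipred > 0))
  }
})

test_that("estimated random effects shrink toward zero as the prior tightens", {
  p <- ref_params()
  nf <- noise_free_dataset(pop_seed = 105, ind_seed = 205)
  norms <- sapply(c(1, 0.3, 0.1, 0.03, 0.01), function(fac) {
    pf <- mpa_params(omega2_cl = fac * p$omega2_cl,
                     omega2_vc = fac * p$omega2_vc,
                     omega2_q = fac * p$omega2_q,
                     omega2_iov_f = fac * p$omega2_iov_f)
    fit <- map_fit(nf$data, pf)
    sqrt(sum(fit$eta^2) + sum(fit$kappa^2))
  })
  expect_true(all(diff(norms) < 1e-6))
  expect_lt(norms[length(norms)], 0.1 * norms[1])
})

test_that("dose recommendation inverts dose = CL x AUC", {
  expect_equal(recommend_dose(list(cl = 16.0), target_auc = 45,
                              rounding = 1), 720)
  expect_equal(recommend_dose(list(cl = 16.0), target_auc = 45), 750)
  # fixed point: target equal to achieved AUC returns the current dose
  p0 <- fixed_params()
  nf <- noise_free_dataset(pop_seed = 106, ind_seed = 206, params = p0)
  fit <- map_fit(nf$data, p0, sigma2 = 1e-8)
  expect_equal(recommend_dose(fit, target_auc = fit$auc, rounding = 1),
               500, tolerance = 1e-4)
  # monotone in clearance and in target
  d <- sapply(c(5, 10, 20, 40), function(cl) {
    recommend_dose(list(cl = cl), target_auc = 45, rounding = 1)
  })
  expect_true(all(diff(d) > 0))
  d2 <- sapply(c(30, 45, 60), function(t) {
    recommend_dose(list(cl = 16), target_auc = t, rounding = 1)
  })
  expect_true(all(diff(d2) > 0))
})

test_that("MAP fits expose tidy and glance summaries", {
  p <- ref_params()
  pop <- generate_population(2, seed = 61)
  ds <- suppressMessages(
    simulate_dataset(pop, regimen(500), sampling_design("full"), p,
                     seed = 62))
  fits <- map_fit_many(ds, p)
  expect_equal(nrow(fits), 2)
  expect_true(all(c("id", "cl", "auc", "fit") %in% names(fits)))
  td <- tidy(fits$fit[[1]])
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_true("eta_cl" %in% td$term)
  gl <- glance(fits$fit[[1]])
  expect_equal(gl$n_obs, 7) # the pre-dose sample carries no information
  expect_output(print(fits$fit[[1]]), "mpa_map_fit")
})
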