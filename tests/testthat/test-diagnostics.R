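test_that("goodness-of-fit table reproduces its definitions", {
  p <- ref_params()
  pop <- generate_population(3, seed = 71)
  noise_free <- mpa_params(sigma2_prop = 0) # observations equal the model
  ds <- simulate_dataset(pop, regimen(500), sampling_design("full"),
                         noise_free, seed = 72)
  fits <- map_fit_many(ds, p, sigma2 = 1e-8)
  g <- gof(ds, p, fits)
  # on self-simulated noise-free data the individual fit interpolates
  expect_lt(max(abs(g$dv - g$ipred) / g$dv), 1e-3)
  expect_lt(max(abs(g$iwres)), 0.01)
  # population prediction equals the typical-profile recomputation
  s1 <- ds[ds$id == 1 & ds$evid == 0 & ds$time > 0, ]
  typ <- add_typical_parameters(
    tibble::tibble(weight = s1$weight[1], albumin = s1$albumin[1]), p)
  pred <- solve_profile(typ, regimen(500), s1$time, params = p)$conc
  expect_equal(g$pred[g$id == 1], pred, tolerance = 1e-9)
})

test_that("weighted residuals are exact at a constructed displacement", {
  p <- mpa_params(sigma2_prop = 0.1^2)
  nf <- noise_free_dataset(pop_seed = 73, ind_seed = 74)
  fit <- map_fit(nf$data, mpa_params(), sigma2 = 1e-10)
  displaced <- nf$data
  obs <- displaced$evid == 0L
  displaced$dv[obs] <- fit$ipred$ipred * 1.1
  g <- gof(displaced, p, fits = setNames(list(fit), "1"))
  expect_equal(g$iwres, rep(1, nrow(g)), tolerance = 1e-6)
})

test_that("prediction correction is the identity when PRED is constant", {
  p <- ref_params()
  # identical covariates and one bin per sampling time: within each bin
  # every PRED is equal, so correction must not alter the observations
  subs <- tibble::tibble(id = 1:6, weight = 40, height = 140, albumin = 33)
  ds <- suppressMessages(
    simulate_dataset(subs, regimen(500), sampling_design("full"), p,
                     seed = 75))
  edges <- c(0.5, 1.5, 2.5, 3.5, 5, 7, 10, 13)
  v <- pcvpc(ds, p, n_sim = 5, bins = edges, seed = 76)
  obs <- ds[ds$evid == 0 & ds$time > 0, ]
  med_bins <- v$bins[v$bins$pctl == 0.5, ]
  expect_equal(nrow(med_bins), 7)
  for (i in seq_len(nrow(med_bins))) {
    in_bin <- obs$time >= med_bins$tad_lo[i] & obs$time < med_bins$tad_hi[i]
    expect_equal(med_bins$observed[i], median(obs$dv[in_bin]))
  }
})

test_that("single-replicate bands collapse and seeds reproduce", {
  p <- ref_params()
  pop <- generate_population(8, seed = 77)
  ds <- suppressMessages(
    simulate_dataset(pop, regimen(500), sampling_design("full"), p,
                     seed = 78))
  v1 <- pcvpc(ds, p, n_sim = 1, bins = 4, seed = 79)
  expect_equal(v1$bins$sim_lo, v1$bins$sim_hi)
  va <- pcvpc(ds, p, n_sim = 20, bins = 4, seed = 80)
  vb <- pcvpc(ds, p, n_sim = 20, bins = 4, seed = 80)
  expect_identical(va$bins, vb$bins)
  # within each bin the band quantiles are ordered across percentiles
  for (b in unique(va$bins$bin)) {
    sub <- va$bins[va$bins$bin == b, ]
    sub <- sub[order(sub$pctl), ]
    expect_true(all(diff(sub$sim_lo) >= 0))
    expect_true(all(diff(sub$sim_hi) >= 0))
  }
  expect_s3_class(autoplot(va), "ggplot")
  expect_output(print(va), "prediction-corrected")
})

test_that("sparse bins are merged rather than reported", {
  p <- ref_params()
  pop <- generate_population(4, seed = 81)
  ds <- suppressMessages(
    simulate_dataset(pop, regimen(500), sampling_design("limited"), p,
                     seed = 82))
  # 8 requested bins but only two distinct post-dose times: bins collapse
  v <- pcvpc(ds, p, n_sim = 3, bins = 8, seed = 83)
  expect_true(all(v$bins$n_obs >= 2))
})
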