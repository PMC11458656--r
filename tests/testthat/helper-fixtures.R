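# shared fixtures: tiny populations and an independent ODE oracle

ref_params <- function(...) mpa_params(...)

# parameters with all variability switched off
fixed_params <- function(...) {
  mpa_params(omega2_cl = 0, omega2_vc = 0, omega2_q = 0,
             omega2_iov_f = 0, sigma2_prop = 0, ...)
}

one_subject <- function(weight = 70, height = 170, albumin = 35, id = 1L) {
  tibble::tibble(id = id, age = 15, sex = "male",
                 weight = weight, height = height, albumin = albumin,
                 bsa = dubois_bsa(weight, height))
}

# independent solution of the compartmental system by stiff-safe numeric
# ODE integration (deSolve), used as the oracle for the matrix-exponential
# solver
ode_oracle <- function(cl, vc, vp, q, ktr, n_abs, dose_time, dose_amt,
                       times) {
  deriv <- function(t, y, p) {
    a <- y[1:n_abs]
    cen <- y[n_abs + 1]
    per <- y[n_abs + 2]
    da <- -ktr * a + ktr * c(0, a[-n_abs])[1:n_abs]
    dcen <- ktr * a[n_abs] - (cl / vc + q / vc) * cen + q / vp * per
    dper <- q / vc * cen - q / vp * per
    list(c(da, dcen, dper))
  }
  y0 <- stats::setNames(rep(0, n_abs + 2), paste0("y", 1:(n_abs + 2)))
  evts <- data.frame(var = "y1", time = dose_time, value = dose_amt,
                     method = "add")
  allt <- sort(unique(c(0, times, dose_time)))
  out <- deSolve::ode(y0, allt, deriv, NULL, events = list(data = evts),
                      rtol = 1e-11, atol = 1e-13)
  out[match(times, out[, 1]), 1 + n_abs + 1] / vc
}

# single-subject dataset holding noise-free observations of a known
# individual; returns list(data, ind)
noise_free_dataset <- function(pop_seed, ind_seed, dose = 500,
                               times = c(1, 2, 3, 4, 6, 8, 12),
                               params = mpa_params()) {
  pop <- generate_population(1, seed = pop_seed)
  ind <- draw_individual_parameters(pop, params, n_occasions = 1,
                                    seed = ind_seed)
  conc <- solve_profile(ind, regimen(dose), times, params = params)$conc
  k <- length(times)
  data <- tibble::tibble(
    id = 1L, time = c(0, times), amt = c(dose, rep(NA_real_, k)),
    dv = c(NA_real_, conc), evid = c(1L, rep(0L, k)),
    mdv = c(1L, rep(0L, k)), occ = 1L,
    weight = pop$weight, height = pop$height, albumin = pop$albumin
  )
  list(data = data, ind = ind)
}
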