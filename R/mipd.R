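#' MAP-Bayes estimation of individual PK parameters
#'
#' Estimates a subject's random effects by maximizing the posterior built
#' from the population model (log-normal priors with the published
#' variances) and the proportional-error likelihood of the observed
#' concentrations.  The objective minimized over the random effects with
#' non-zero variance is
#'
#' -2 log posterior = sum_j \[ (y_j - f_j)^2 / (sigma2 f_j^2) +
#'   log(sigma2 f_j^2) \] + sum_k eta_k^2 / omega2_k +
#'   sum_m kappa_m^2 / omega2_IOV
#'
#' where `f_j` are the model-predicted concentrations.  Optimization is
#' multi-start (the prior mode plus `n_starts - 1` jittered starts) with a
#' quasi-Newton local search.  This is the engine for model-informed
#' precision dosing: the fitted clearance and occasion bioavailability
#' give the individual steady-state AUC, and [recommend_dose()] inverts
#' dose = CL x target AUC.
#'
#' Observations at or before the first dose (where the prediction is
#' identically zero) carry no information under a proportional error and
#' are dropped.  A subject whose remaining concentrations are all zero is
#' ill-posed for this error model: the prior mode is returned with a
#' warning.  With no usable observations at all the prior mode (the
#' population-typical individual) is returned.
#'
#' @param obs A single-subject dataset tibble in the format of
#'   [read_dataset()] / [simulate_dataset()] (dose rows `evid` 1,
#'   observation rows `evid` 0 with `dv` in mg/L, covariates `weight` and
#'   `albumin` on each row).
#' @param params An [mpa_params()] object (priors and error variance).
#' @param sigma2 Residual proportional variance used in the likelihood;
#'   defaults to `params$sigma2_prop`.
#' @param n_starts Number of optimization starts (>= 1; the first is the
#'   prior mode).
#' @param start_seed Seed for the jittered starts.
#' @param reltol Relative convergence tolerance on the objective.
#' @return An object of class `mpa_map_fit`: a list with elements `eta`
#'   (named posterior-mode etas), `kappa` (per occasion), `ind`
#'   (individual parameter tibble incl. `f_occ`), `ipred` (tibble of
#'   time/ipred at the used observations), `auc` (individual steady-state
#'   AUC at the subject's last dose amount), `dose` (that amount),
#'   `objective`, `objective_prior_mode`, `convergence`, `n_obs`.
#'   Methods: [tidy()], [glance()], `print()`.
#' @examples
#' pop <- generate_population(1, seed = 3)
#' ds <- simulate_dataset(pop, regimen(500), sampling_design("full"),
#'                        seed = 4)
#' fit <- map_fit(ds)
#' glance(fit)
#' recommend_dose(fit, target_auc = 45)
#' @export
map_fit <- function(obs, params = mpa_params(),
                    sigma2 = params$sigma2_prop,
                    n_starts = 5L, start_seed = 1L, reltol = 1e-10) {
  stopifnot(inherits(params, "mpa_params"))
  obs <- validate_dataset(obs)
  if (length(unique(obs$id)) != 1L) {
    abort("`obs` must contain exactly one subject; see map_fit_many()")
  }
  if (!all(c("weight", "albumin") %in% names(obs))) {
    abort("`obs` must carry weight and albumin columns")
  }
  check_positive(sigma2, "sigma2")

  cov1 <- obs[1, ]
  doses <- obs |> filter(.data$evid == 1L)
  if (nrow(doses) == 0) abort("`obs` has no dose events")
  y_all <- obs |> filter(.data$evid == 0L, .data$mdv == 0L)
  first_dose <- min(doses$time)
  y <- y_all |> filter(.data$time > first_dose)

  occs <- sort(unique(doses$occ))
  n_occ <- length(occs)
  doses$occ <- match(doses$occ, occs)

  # random effects with non-zero prior variance
  eta_names <- c("eta_cl", "eta_vc", "eta_q")
  eta_var <- c(params$omega2_cl, params$omega2_vc, params$omega2_q)
  use_eta <- eta_var > 0
  use_kappa <- params$omega2_iov_f > 0
  kap_var <- rep(params$omega2_iov_f, if (use_kappa) n_occ else 0)
  free_var <- c(eta_var[use_eta], kap_var)
  n_eta <- sum(use_eta)
  n_free <- length(free_var)

  typ <- add_typical_parameters(
    tibble(weight = cov1$weight, albumin = cov1$albumin), params)

  build_ind <- function(x) {
    eta <- numeric(3)
    eta[use_eta] <- x[seq_len(n_eta)]
    kappa <- if (use_kappa) x[n_eta + seq_len(n_occ)] else numeric(n_occ)
    list(cl = typ$cl * exp(eta[1]), vc = typ$vc * exp(eta[2]),
         vp = typ$vp, q = typ$q * exp(eta[3]), ktr = typ$ktr,
         f_occ = exp(kappa), eta = setNames(eta, eta_names),
         kappa = kappa)
  }

  predict_conc <- function(ind, times) {
    profile_conc_cpp(ind$cl, ind$vc, ind$vp, ind$q, ind$ktr, params$n_abs,
                     doses$time, doses$amt * ind$f_occ[doses$occ], times)
  }

  objective <- function(x) {
    ind <- build_ind(x)
    f <- tryCatch(pmax(predict_conc(ind, y$time), 1e-12),
                  error = function(e) NULL)
    if (is.null(f)) return(Inf) # overflowing random effects
    sum((y$dv - f)^2 / (sigma2 * f^2) + log(sigma2 * f^2)) +
      sum(x^2 / free_var)
  }

  ill_posed <- nrow(y) > 0 && all(y$dv == 0)
  if (ill_posed) {
    warn("all concentrations are zero: ill-posed under a proportional error; returning the prior mode")
  }

  if (nrow(y) == 0 || ill_posed || n_free == 0) {
    x_hat <- numeric(n_free)
    obj <- if (nrow(y) > 0 && !ill_posed) objective(x_hat) else 0
    conv <- 0L
  } else {
    obj0 <- objective(numeric(n_free))
    starts <- list(numeric(n_free))
    # data-informed start: eta_cl from the trapezoidal AUC of the
    # observed curve (AUC ~ dose/CL), other effects at their prior mode
    if (use_eta[1] && nrow(y) >= 3) {
      auc_tr <- sum(diff(y$time) * (utils::head(y$dv, -1) +
                                      utils::tail(y$dv, -1)) / 2)
      if (auc_tr > 0) {
        s <- numeric(n_free)
        s[1] <- log(pmax(sum(doses$amt) / auc_tr, 1e-3) / typ$cl)
        starts <- c(starts, list(s))
      }
    }
    if (n_starts > length(starts)) {
      jit <- with_optional_seed(start_seed, {
        lapply(seq_len(n_starts - length(starts)), function(i) {
          # jitter on the prior scale, capped so extreme (or flat) priors
          # cannot launch starts into overflow territory
          rnorm(n_free, 0, pmin(sqrt(free_var), 1.5))
        })
      })
      starts <- c(starts, jit)
    }
    # residual vector of the penalized least-squares core: weighted data
    # residuals plus prior residuals.  Dropping the log-variance term
    # makes the problem a plain nonlinear least squares that a
    # Levenberg-Marquardt step solves reliably; the full objective is
    # then polished by a quasi-Newton step.
    residuals_fn <- function(x) {
      ind <- build_ind(x)
      f <- tryCatch(pmax(predict_conc(ind, y$time), 1e-12),
                    error = function(e) NULL)
      if (is.null(f)) return(rep(1e10, nrow(y) + length(x)))
      c((y$dv - f) / (sqrt(sigma2) * f), x / sqrt(free_var))
    }
    fits <- list()
    for (s in starts) {
      cand <- list(list(par = s, value = objective(s), convergence = 99L))
      lm_fit <- tryCatch(
        minpack.lm::nls.lm(
          s, fn = residuals_fn,
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (!is.null(lm_fit)) {
        cand <- c(cand, list(list(par = lm_fit$par,
                                  value = objective(lm_fit$par),
                                  convergence = 0L)))
      }
      polish_from <- if (is.null(lm_fit)) s else lm_fit$par
      pol <- tryCatch(
        optim(polish_from, objective, method = "BFGS",
              control = list(reltol = reltol, maxit = 1000)),
        error = function(e) NULL)
      if (!is.null(pol)) cand <- c(cand, list(pol))
      fits <- c(fits, cand)
    }
    vals <- vapply(fits, function(f) f$value, numeric(1))
    vals[!is.finite(vals)] <- Inf
    best <- fits[[which.min(vals)]]
    # the returned mode never does worse than the prior mode
    if (best$value <= obj0) {
      x_hat <- best$par; obj <- best$value; conv <- best$convergence
    } else {
      x_hat <- numeric(n_free); obj <- obj0; conv <- 0L
    }
  }

  ind <- build_ind(x_hat)
  ipred <- if (nrow(y) > 0 && !ill_posed) {
    tibble(time = y$time, dv = y$dv,
           ipred = as.numeric(predict_conc(ind, y$time)))
  } else {
    tibble(time = numeric(), dv = numeric(), ipred = numeric())
  }
  last_occ <- doses$occ[which.max(doses$time)]
  dose_amt <- doses$amt[which.max(doses$time)]
  structure(
    list(
      id = cov1$id,
      eta = ind$eta, kappa = ind$kappa,
      ind = tibble(cl = ind$cl, vc = ind$vc, vp = ind$vp, q = ind$q,
                   ktr = ind$ktr, f_occ = list(ind$f_occ)),
      ipred = ipred,
      dose = dose_amt,
      auc = ind$f_occ[last_occ] * dose_amt / ind$cl,
      objective = obj,
      objective_prior_mode = if (nrow(y) > 0 && !ill_posed)
        objective(numeric(n_free)) else obj,
      convergence = conv,
      n_obs = nrow(y),
      params = params, sigma2 = sigma2
    ),
    class = "mpa_map_fit"
  )
}

#' @export
print.mpa_map_fit <- function(x, ...) {
  cat(sprintf("<mpa_map_fit> subject %s: %d observation(s)\n",
              format(x$id), x$n_obs))
  cat(sprintf("  CL/F %.3g L/h, Vc/F %.3g L, Q/F %.3g L/h, F_occ %s\n",
              x$ind$cl, x$ind$vc, x$ind$q,
              paste(signif(x$ind$f_occ[[1]], 3), collapse = "/")))
  cat(sprintf("  AUC(0-12) at %g mg: %.3g mg·h/L; -2 log posterior %.4g\n",
              x$dose, x$auc, x$objective))
  invisible(x)
}

#' @rdname map_fit
#' @param x,object An `mpa_map_fit` object.
#' @param ... Unused.
#' @export
tidy.mpa_map_fit <- function(x, ...) {
  bind_rows(
    tibble(term = names(x$eta), estimate = unname(x$eta),
           type = "random effect"),
    tibble(term = paste0("kappa_", seq_along(x$kappa)),
           estimate = x$kappa, type = "random effect"),
    tibble(term = c("cl", "vc", "vp", "q", "ktr"),
           estimate = c(x$ind$cl, x$ind$vc, x$ind$vp, x$ind$q, x$ind$ktr),
           type = "individual parameter")
  )
}

#' @rdname map_fit
#' @export
glance.mpa_map_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, objective = x$objective,
         convergence = x$convergence, cl = x$ind$cl, auc = x$auc)
}

#' @rdname map_fit
#' @param data A multi-subject dataset tibble.
#' @export
map_fit_many <- function(data, params = mpa_params(), ...) {
  data <- validate_dataset(data)
  ids <- unique(data$id)
  fits <- lapply(ids, function(i) {
    map_fit(data[data$id == i, ], params = params, ...)
  })
  names(fits) <- as.character(ids)
  out <- bind_rows(lapply(fits, glance))
  out$id <- ids
  out$fit <- fits
  select(out, "id", dplyr::everything())
}

#' Recommend a follow-up MMF dose from a MAP fit
#'
#' Inverts the steady-state relationship dose = CL x AUC at the
#' individual clearance: the twice-daily dose expected to put the
#' subject's AUC(0-12) at `target_auc`.  The bioavailability of the
#' future occasion is taken at its prior mode (multiplier 1).
#'
#' @param fit An `mpa_map_fit` object (or a list with an element `ind`
#'   holding `cl`, or a bare named list with `cl`).
#' @param target_auc Target AUC(0-12) in mg.h/L.
#' @param rounding Tablet rounding unit (mg); 1 leaves the dose
#'   unrounded.
#' @param mode Rounding mode, see [round_dose()].
#' @return Twice-daily dose in mg MMF.
#' @examples
#' recommend_dose(list(cl = 16), target_auc = 45, rounding = 1)  # 720
#' @export
recommend_dose <- function(fit, target_auc = 45, rounding = 250,
                           mode = "nearest") {
  cl <- if (inherits(fit, "mpa_map_fit")) fit$ind$cl else fit$cl
  if (is.null(cl)) abort("`fit` must carry an individual clearance")
  check_positive(cl, "cl")
  if (!is.finite(target_auc) || target_auc < 0) {
    abort("`target_auc` must be non-negative")
  }
  round_dose(cl * target_auc, unit = rounding, mode = mode)
}
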