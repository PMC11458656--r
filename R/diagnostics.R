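#' Goodness-of-fit table
#'
#' For every observation: the population prediction PRED (all random
#' effects at zero), the individual prediction IPRED from a MAP fit, the
#' individual weighted residual IWRES = (DV - IPRED) / (IPRED x sigma)
#' under the proportional error model, and the time after the most recent
#' dose.  IWRES is used here in place of linearization-based conditional
#' residuals; its diagnostic contract is the same — on data simulated
#' from the model it is centred on zero with unit spread.
#'
#' @param data A dataset tibble ([read_dataset()] format).
#' @param params An [mpa_params()] object.
#' @param fits Optional: a named list of `mpa_map_fit` objects (names =
#'   subject ids) or the result of [map_fit_many()]; fitted on the fly
#'   when omitted.
#' @return A tibble with columns `id`, `time`, `tad`, `dv`, `pred`,
#'   `ipred`, `iwres`.
#' @export
gof <- function(data, params = mpa_params(), fits = NULL) {
  data <- validate_dataset(data)
  if (is.null(fits)) fits <- map_fit_many(data, params = params)
  if (is.data.frame(fits)) fits <- setNames(fits$fit, as.character(fits$id))
  sigma <- sqrt(params$sigma2_prop)
  ids <- unique(data$id)
  missing_fit <- setdiff(as.character(ids), names(fits))
  if (length(missing_fit) > 0) {
    abort(paste("no fit supplied for subject(s):",
                paste(missing_fit, collapse = ", ")))
  }
  rows <- lapply(ids, function(i) {
    sub <- data[data$id == i, ]
    doses <- sub[sub$evid == 1L, ]
    yobs <- sub[sub$evid == 0L & sub$mdv == 0L & sub$time > min(doses$time), ]
    if (nrow(yobs) == 0) return(NULL)
    typ <- add_typical_parameters(
      tibble(weight = sub$weight[1], albumin = sub$albumin[1]), params)
    pred <- solve_profile(typ, doses, yobs$time, params = params)$conc
    fit <- fits[[as.character(i)]]
    ip <- fit$ipred
    ipred <- ip$ipred[match(yobs$time, ip$time)]
    tad <- time_after_dose(yobs$time, doses$time)
    tibble(id = i, time = yobs$time, tad = tad, dv = yobs$dv,
           pred = pred, ipred = ipred,
           iwres = (yobs$dv - ipred) / (ipred * sigma))
  })
  bind_rows(rows)
}

# time since the most recent dose given strictly before each time
time_after_dose <- function(times, dose_times) {
  prev <- findInterval(times, sort(dose_times), left.open = TRUE)
  prev[prev < 1L] <- 1L
  times - sort(dose_times)[prev]
}

#' Prediction-corrected visual predictive check
#'
#' Compares percentiles of the observed concentrations with those of
#' datasets simulated from the model under full inter-individual,
#' inter-occasion and residual variability.  Before comparison every
#' observed and simulated concentration is prediction-corrected: scaled by
#' median(PRED in its bin) / PRED of its record, which removes the
#' variability explained by dose and covariates.  Binning is
#' quantile-based on time after dose; bins with fewer than two
#' observations are merged with their neighbor.
#'
#' @param data A dataset tibble with dose and observation rows.
#' @param params An [mpa_params()] object.
#' @param n_sim Number of simulated replicate datasets.
#' @param bins Number of time-after-dose bins, or an explicit numeric
#'   vector of bin edges.
#' @param probs The observation percentiles followed (default 5th, 50th,
#'   95th).
#' @param ci Width of the simulated confidence band per percentile.
#' @param seed Optional integer seed.
#' @return An object of class `mpa_vpc`: a list with `bins` (per bin and
#'   percentile: observed value, lower/upper simulated band), `n_sim`,
#'   `probs`, `ci`.  Use [autoplot()] to draw it.
#' @examples
#' pop <- generate_population(20, seed = 5)
#' ds <- simulate_dataset(pop, regimen(500), sampling_design("full"),
#'                        seed = 6)
#' v <- pcvpc(ds, n_sim = 50, seed = 7)
#' head(v$bins)
#' @export
pcvpc <- function(data, params = mpa_params(), n_sim = 1000, bins = 8,
                  probs = c(0.05, 0.5, 0.95), ci = 0.95, seed = NULL) {
  data <- validate_dataset(data)
  n_sim <- as.integer(n_sim)
  if (is.na(n_sim) || n_sim < 1L) abort("`n_sim` must be >= 1")

  # per-subject structure: doses, usable observations, typical prediction
  ids <- unique(data$id)
  subs <- lapply(ids, function(i) {
    sub <- data[data$id == i, ]
    doses <- sub[sub$evid == 1L, ]
    if (nrow(doses) == 0) abort(sprintf("subject %s has no dose events", i))
    yobs <- sub[sub$evid == 0L & sub$mdv == 0L &
                  sub$time > min(doses$time), ]
    if (nrow(yobs) == 0) return(NULL)
    typ <- add_typical_parameters(
      tibble(weight = sub$weight[1], albumin = sub$albumin[1]), params)
    occs <- sort(unique(doses$occ))
    doses$occ <- match(doses$occ, occs)
    pred <- solve_profile(typ, doses, yobs$time, params = params)$conc
    list(typ = typ, doses = doses, n_occ = length(occs),
         time = yobs$time, dv = yobs$dv, pred = pred,
         tad = time_after_dose(yobs$time, doses$time))
  })
  subs <- subs[!vapply(subs, is.null, logical(1))]
  if (length(subs) == 0) abort("no usable observations")

  obs <- tibble(
    sub = rep(seq_along(subs), vapply(subs, function(s) length(s$time), 0L)),
    tad = unlist(lapply(subs, `[[`, "tad")),
    dv = unlist(lapply(subs, `[[`, "dv")),
    pred = unlist(lapply(subs, `[[`, "pred"))
  )

  # quantile bins on time after dose, small bins merged with neighbors
  if (length(bins) == 1L) {
    edges <- unique(quantile(obs$tad, probs = seq(0, 1, length.out = bins + 1),
                             names = FALSE))
  } else {
    edges <- sort(unique(bins))
  }
  bin_of <- function(tad) {
    b <- findInterval(tad, edges, rightmost.closed = TRUE)
    pmin(pmax(b, 1L), length(edges) - 1L)
  }
  obs$bin <- bin_of(obs$tad)
  cnt <- table(factor(obs$bin, levels = seq_len(length(edges) - 1L)))
  while (any(cnt < 2) && length(edges) > 2) {
    small <- which(cnt < 2)[1]
    drop_edge <- if (small == length(cnt)) small else small + 1L
    edges <- edges[-drop_edge]
    obs$bin <- bin_of(obs$tad)
    cnt <- table(factor(obs$bin, levels = seq_len(length(edges) - 1L)))
  }

  med_pred <- tapply(obs$pred, obs$bin, median)
  corr <- as.numeric(med_pred[as.character(obs$bin)]) / obs$pred
  pc_obs <- obs$dv * corr

  bin_levels <- sort(unique(obs$bin))
  obs_pct <- t(vapply(bin_levels, function(b) {
    quantile(pc_obs[obs$bin == b], probs = probs, names = FALSE)
  }, numeric(length(probs))))

  sig <- sqrt(params$sigma2_prop)
  sim_pct <- with_optional_seed(seed, {
    reps <- lapply(seq_len(n_sim), function(r) {
      dv_sim <- unlist(lapply(subs, function(s) {
        eta_cl <- rnorm(1, 0, sqrt(params$omega2_cl))
        eta_vc <- rnorm(1, 0, sqrt(params$omega2_vc))
        eta_q <- rnorm(1, 0, sqrt(params$omega2_q))
        f_occ <- exp(rnorm(s$n_occ, 0, sqrt(params$omega2_iov_f)))
        f <- profile_conc_cpp(
          s$typ$cl * exp(eta_cl), s$typ$vc * exp(eta_vc), s$typ$vp,
          s$typ$q * exp(eta_q), s$typ$ktr, params$n_abs,
          s$doses$time, s$doses$amt * f_occ[s$doses$occ], s$time)
        pmax(f * (1 + rnorm(length(f), 0, sig)), 0)
      }))
      pc_sim <- dv_sim * corr
      t(vapply(bin_levels, function(b) {
        quantile(pc_sim[obs$bin == b], probs = probs, names = FALSE)
      }, numeric(length(probs))))
    })
    simplify2array(reps) # bins x probs x n_sim
  })
  alpha <- (1 - ci) / 2
  lo <- apply(sim_pct, c(1, 2), quantile, probs = alpha, names = FALSE)
  hi <- apply(sim_pct, c(1, 2), quantile, probs = 1 - alpha, names = FALSE)

  bins_tbl <- tidyr::expand_grid(
    bin = seq_along(bin_levels), pctl = probs) |>
    arrange(.data$bin, .data$pctl)
  k <- nrow(bins_tbl)
  bins_tbl$tad_lo <- edges[bin_levels][bins_tbl$bin]
  bins_tbl$tad_hi <- edges[bin_levels + 1L][bins_tbl$bin]
  bins_tbl$tad_mid <- (bins_tbl$tad_lo + bins_tbl$tad_hi) / 2
  bins_tbl$n_obs <- as.integer(cnt[bin_levels])[bins_tbl$bin]
  ix <- cbind(bins_tbl$bin, match(bins_tbl$pctl, probs))
  bins_tbl$observed <- obs_pct[ix]
  bins_tbl$sim_lo <- lo[ix]
  bins_tbl$sim_hi <- hi[ix]
  structure(list(bins = bins_tbl, n_sim = n_sim, probs = probs, ci = ci),
            class = "mpa_vpc")
}

#' @export
print.mpa_vpc <- function(x, ...) {
  cat(sprintf(
    "<mpa_vpc> prediction-corrected VPC: %d bins, %d simulations, %g%% bands\n",
    length(unique(x$bins$bin)), x$n_sim, 100 * x$ci))
  cov <- x$bins |>
    mutate(inside = .data$observed >= .data$sim_lo &
             .data$observed <= .data$sim_hi)
  cat(sprintf("  observed percentiles inside their band: %d / %d\n",
              sum(cov$inside), nrow(cov)))
  invisible(x)
}

#' @export
autoplot.mpa_vpc <- function(object, ...) {
  b <- object$bins |>
    mutate(pctl = factor(paste0(100 * .data$pctl, "th")))
  ggplot2::ggplot(b, ggplot2::aes(x = .data$tad_mid)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$sim_lo, ymax = .data$sim_hi,
                   fill = .data$pctl), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$pctl)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$pctl)) +
    ggplot2::labs(x = "time after dose (h)",
                  y = "prediction-corrected MPA (mg/L)",
                  colour = "percentile", fill = "percentile") +
    ggplot2::theme_bw()
}
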