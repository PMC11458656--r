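#' Blood-sampling designs
#'
#' The sampling schemes used for MPA monitoring: the full 8-sample AUC
#' curve at 0, 1, 2, 3, 4, 6, 8 and 12 h after dosing, the limited
#' 3-sample curve at 0, 0.5 and 2 h, and a trough-only design.
#'
#' @param label One of `"full"`, `"limited"`, `"trough"`.
#' @return A tibble with a `time` column (hours after dose) and attribute
#'   `label`.
#' @examples
#' sampling_design("limited")
#' @export
sampling_design <- function(label = c("full", "limited", "trough")) {
  label <- match.arg(label)
  times <- switch(label,
    full = c(0, 1, 2, 3, 4, 6, 8, 12),
    limited = c(0, 0.5, 2),
    trough = 0
  )
  structure(tibble(time = times), label = label)
}

#' Simulate a sparse-sampling PK dataset from the population model
#'
#' Draws individual parameters for each subject (inter-individual
#' variability on CL/F, Vc/F and Q/F; one bioavailability multiplier per
#' occasion in the regimen), solves the concentration profile, samples it
#' according to `design` relative to the first dose of each observed
#' occasion, and adds proportional residual error
#' DV = f x (1 + eps), eps ~ N(0, sigma2_prop).  Negative noisy values are
#' truncated at zero (a message reports how many).
#'
#' The result is a NONMEM-style rectangular table: dose rows (`evid` 1,
#' `amt` in mg MMF, `dv` missing) interleaved with observation rows
#' (`evid` 0, `mdv` 0, `dv` in mg/L MPA), with occasion index and the
#' subject covariates on every row.  The generating truth (individual
#' parameters and noise-free predictions) is attached as attribute
#' `"truth"` so recovery studies can compare estimates against it.
#'
#' @param subjects Tibble with columns `id`, `weight`, `height`,
#'   `albumin` (e.g. from [generate_population()]).
#' @param doses A regimen tibble (see [regimen()]) applied to every
#'   subject.
#' @param design A [sampling_design()] (or any tibble with a `time`
#'   column of hours after dose).
#' @param params An [mpa_params()] object.
#' @param seed Optional integer seed.
#' @param observe_occasions Which occasions get a sampling curve:
#'   `"last"` (default) or `"all"`.
#' @return A tibble of dataset records with attribute `"truth"`.
#' @examples
#' pop <- generate_population(3, seed = 1)
#' ds <- simulate_dataset(pop, regimen(500), sampling_design("full"),
#'                        mpa_params(), seed = 2)
#' attr(ds, "truth")
#' @export
simulate_dataset <- function(subjects, doses, design, params = mpa_params(),
                             seed = NULL,
                             observe_occasions = c("last", "all")) {
  observe_occasions <- match.arg(observe_occasions)
  subjects <- as_tibble(subjects)
  if (!all(c("id", "weight", "albumin") %in% names(subjects))) {
    abort("`subjects` needs columns id, weight, albumin")
  }
  if (is.null(subjects$height)) subjects$height <- NA_real_
  ev <- validate_doses(doses)
  if (nrow(ev) == 0) abort("`doses` must contain at least one dose event")
  n_occ <- max(ev$occ)
  obs_occ <- if (observe_occasions == "last") n_occ else seq_len(n_occ)

  with_optional_seed(seed, {
    ind_tbl <- draw_individual_parameters(subjects, params,
                                          n_occasions = n_occ)
    rows <- purrr::map(seq_len(nrow(ind_tbl)), function(i) {
      ind <- ind_tbl[i, ]
      obs_time <- sort(unique(unlist(lapply(obs_occ, function(k) {
        min(ev$time[ev$occ == k]) + design$time
      }))))
      f <- solve_profile(ind, ev, obs_time, params = params)$conc
      eps <- rnorm(length(f), 0, sqrt(params$sigma2_prop))
      dose_rows <- tibble(
        id = ind$id, time = ev$time, amt = ev$amt, dv = NA_real_,
        evid = 1L, mdv = 1L, occ = ev$occ
      )
      occ_of_obs <- findInterval(obs_time, ev$time[!duplicated(ev$occ)])
      occ_of_obs[occ_of_obs < 1L] <- 1L
      obs_rows <- tibble(
        id = ind$id, time = obs_time, amt = NA_real_,
        dv = f * (1 + eps), evid = 0L, mdv = 0L,
        occ = ev$occ[!duplicated(ev$occ)][occ_of_obs]
      )
      # pre-dose samples sort ahead of a dose given at the same time
      rec <- bind_rows(dose_rows, obs_rows) |>
        arrange(.data$time, .data$evid) |>
        mutate(weight = ind$weight, height = ind$height,
               albumin = ind$albumin, fpred = NA_real_)
      rec$fpred[rec$evid == 0L] <- f
      rec
    })
    out <- bind_rows(rows)
    n_neg <- sum(out$dv < 0, na.rm = TRUE)
    if (n_neg > 0) {
      inform(sprintf("%d negative simulated concentration(s) truncated at 0",
                     n_neg))
      out$dv[!is.na(out$dv) & out$dv < 0] <- 0
    }
    fpred <- out$fpred
    out$fpred <- NULL
    attr(out, "truth") <- ind_tbl
    attr(out, "fpred") <- fpred[!is.na(fpred)]
    out
  })
}
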