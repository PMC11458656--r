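#' Simulate a concentration-time profile for one individual
#'
#' Solves the structural model — dose bolus into the first of `n_abs`
#' sequential absorption compartments, transfer at rate `ktr` through the
#' chain into the central compartment, two-compartment disposition with
#' elimination from the central compartment — for a set of dose events and
#' returns the MPA plasma concentration (central amount / Vc) at the
#' requested times.  The linear constant-coefficient system is propagated
#' with the matrix exponential, which is exact and robust to the repeated
#' eigenvalue introduced by the equal transfer rates of the absorption
#' chain.
#'
#' Each dose amount is multiplied by the bioavailability multiplier of its
#' occasion (`f_occ[occ]`).  An observation that coincides with a dose
#' time is taken just before the dose (a pre-dose sample), so the
#' concentration at a time with no earlier dose is 0.
#'
#' @param ind A one-row data frame or named list with individual
#'   parameters `cl`, `vc`, `vp`, `q`, `ktr` and optionally `f_occ`
#'   (vector, or list-column holding one, of per-occasion bioavailability
#'   multipliers; default all 1).
#' @param doses A regimen tibble (see [regimen()]) with columns `time`,
#'   `amt`, `occ`.
#' @param times Numeric vector of observation times (h, >= 0), strictly
#'   increasing.
#' @param params An [mpa_params()] object supplying `n_abs`; alternatively
#'   give `n_abs` directly.
#' @param n_abs Number of absorption compartments; overrides `params`.
#' @return A tibble with columns `time` and `conc` (mg/L), of class
#'   `mpa_profile`.
#' @examples
#' p <- mpa_params()
#' ind <- add_typical_parameters(
#'   tibble::tibble(weight = 40, albumin = 33), p)
#' solve_profile(ind, regimen(500, n_doses = 2), times = 0:24, params = p)
#' @export
solve_profile <- function(ind, doses, times, params = mpa_params(),
                          n_abs = NULL) {
  ip <- as_individual(ind)
  n_abs <- as.integer(n_abs %||% params$n_abs)
  if (is.na(n_abs) || n_abs < 1L) abort("`n_abs` must be >= 1")
  ev <- validate_doses(doses, n_occ = length(ip$f_occ))
  if (length(times) == 0 || any(!is.finite(times)) || any(times < 0)) {
    abort("`times` must be non-negative and finite")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing")
  }
  amt_eff <- ev$amt * ip$f_occ[ev$occ]
  conc <- profile_conc_cpp(ip$cl, ip$vc, ip$vp, ip$q, ip$ktr, n_abs,
                           ev$time, amt_eff, times)
  structure(
    tibble(time = times, conc = as.numeric(conc)),
    class = c("mpa_profile", class(tibble())))
}

# Full state trajectories (absorption chain, central, peripheral and the
# cumulative eliminated amount); used by mass-balance checks.
profile_states <- function(ind, doses, times, params = mpa_params(),
                           n_abs = NULL) {
  ip <- as_individual(ind)
  n_abs <- as.integer(n_abs %||% params$n_abs)
  ev <- validate_doses(doses, n_occ = length(ip$f_occ))
  amt_eff <- ev$amt * ip$f_occ[ev$occ]
  st <- profile_states_cpp(ip$cl, ip$vc, ip$vp, ip$q, ip$ktr, n_abs,
                           ev$time, amt_eff, times)
  colnames(st) <- c(paste0("abs", seq_len(n_abs)), "central", "peripheral",
                    "eliminated")
  st
}

#' Steady-state AUC over one dosing interval
#'
#' For a linear model the steady-state AUC over one interval equals the
#' absorbed amount divided by clearance, independent of the absorption and
#' distribution parameters: AUC(0-tau) = F_occ x dose / CL.
#'
#' @param ind Individual parameters as in [solve_profile()] (only `cl` and
#'   `f_occ` are used).
#' @param dose Dose per interval (mg MMF, >= 0).
#' @param occasion Occasion index selecting the bioavailability
#'   multiplier.
#' @return AUC over one dosing interval (mg.h/L).
#' @examples
#' steady_state_auc(list(cl = 12.5, f_occ = 1), dose = 750)  # 60
#' @export
steady_state_auc <- function(ind, dose, occasion = 1L) {
  ip <- as_individual(ind, need = "cl")
  if (any(!is.finite(dose)) || any(dose < 0)) {
    abort("`dose` must be non-negative and finite")
  }
  occasion <- as.integer(occasion)
  if (occasion < 1L || occasion > length(ip$f_occ)) {
    abort("`occasion` outside the occasions of `ind`")
  }
  ip$f_occ[occasion] * dose / ip$cl
}

# Coerce a one-row data frame / named list of individual parameters into a
# plain list with a validated f_occ vector.
as_individual <- function(ind, need = c("cl", "vc", "vp", "q", "ktr")) {
  if (is.data.frame(ind)) {
    if (nrow(ind) != 1L) abort("`ind` must describe exactly one individual")
    ind <- as.list(ind)
    if (!is.null(ind$f_occ)) ind$f_occ <- ind$f_occ[[1]]
  }
  if (is.null(ind$f_occ)) ind$f_occ <- 1
  if (is.null(ind$cl)) {
    abort("individual parameters need `cl`, `vc`, `vp`, `q`, `ktr`")
  }
  for (nm in need) {
    v <- ind[[nm]]
    if (is.null(v) || !is.finite(v) || v <= 0) {
      abort(sprintf("individual parameter `%s` must be positive", nm))
    }
  }
  if (any(!is.finite(ind$f_occ)) || any(ind$f_occ <= 0)) {
    abort("`f_occ` multipliers must be positive")
  }
  ind
}

validate_doses <- function(doses, n_occ = NULL) {
  if (is.null(doses) || nrow(as_tibble(doses)) == 0) {
    return(tibble(time = numeric(), amt = numeric(), occ = integer()))
  }
  doses <- as_tibble(doses)
  if (!all(c("time", "amt") %in% names(doses))) {
    abort("`doses` needs columns time and amt")
  }
  if (is.null(doses$occ)) doses$occ <- 1L
  if (any(!is.finite(doses$time)) || any(doses$time < 0)) {
    abort("dose times must be non-negative and finite")
  }
  if (is.unsorted(doses$time)) {
    abort("dose events must be ordered in time")
  }
  if (any(!is.finite(doses$amt)) || any(doses$amt < 0)) {
    abort("dose amounts must be non-negative")
  }
  if (!is.null(n_occ) &&
      (any(doses$occ < 1) || any(doses$occ > n_occ))) {
    abort("dose occasion index outside the occasions of `ind`")
  }
  doses
}
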