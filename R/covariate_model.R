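#' Body surface area by the Dubois formula
#'
#' BSA (m^2) = 0.007184 x weight^0.425 x height^0.725.
#'
#' @param weight Body weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @return BSA in m^2, vectorized.
#' @examples
#' dubois_bsa(70, 170)
#' @export
dubois_bsa <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  0.007184 * weight^0.425 * height^0.725
}

#' Typical (population) parameter values at given covariates
#'
#' `typical_clearance()` evaluates the clearance covariate model
#' CL/F = theta_cl x (weight/70)^0.75 x (albumin/ref)^theta_alb.
#' `typical_disposition()` evaluates the allometric equations for the
#' remaining structural parameters: Vc/F and Vp/F scale linearly with
#' weight, Q/F with weight^0.75 and the absorption transfer rate ktr with
#' weight^-0.25.
#'
#' @param params An [mpa_params()] object.
#' @param weight Body weight (kg), vectorized.
#' @param albumin Serum albumin (g/L), vectorized.
#' @return `typical_clearance()`: CL/F in L/h.  `typical_disposition()`: a
#'   tibble with columns `vc`, `vp`, `q`, `ktr`.
#' @examples
#' p <- mpa_params()
#' typical_clearance(p, 70, 35)        # 16.0 L/h at the reference
#' typical_disposition(p, weight = 70) # published typical values
#' @export
typical_clearance <- function(params, weight, albumin) {
  stopifnot(inherits(params, "mpa_params"))
  check_positive(weight, "weight")
  check_positive(albumin, "albumin")
  params$theta_cl *
    (weight / params$ref_weight)^params$allo_flow *
    (albumin / params$ref_albumin)^params$theta_alb
}

#' @rdname typical_clearance
#' @export
typical_disposition <- function(params, weight) {
  stopifnot(inherits(params, "mpa_params"))
  check_positive(weight, "weight")
  w <- weight / params$ref_weight
  tibble(
    vc  = params$vc * w^params$allo_volume,
    vp  = params$vp * w^params$allo_volume,
    q   = params$q * w^params$allo_flow,
    ktr = params$ktr * w^params$allo_rate
  )
}

#' Add typical and individual model parameters to a subject table
#'
#' `add_typical_parameters()` appends the typical CL/F, Vc/F, Vp/F, Q/F and
#' ktr implied by each subject's weight and albumin.
#' `draw_individual_parameters()` additionally draws the log-normal random
#' effects: eta on CL/F, Vc/F and Q/F (Vp/F and ktr carry no
#' inter-individual variability in the published model), and one kappa per
#' occasion on relative bioavailability F, returned as a list-column
#' `f_occ` of per-occasion multipliers.
#'
#' @param subjects A data frame with columns `weight` and `albumin`
#'   (and any others, preserved).
#' @param params An [mpa_params()] object.
#' @param n_occasions Number of occasions for which to draw bioavailability
#'   multipliers.
#' @param seed Optional integer seed; draws are reproducible given a seed
#'   and leave the global RNG state untouched.
#' @return The input as a tibble with columns `cl`, `vc`, `vp`, `q`, `ktr`
#'   (individual values for `draw_individual_parameters()`), plus
#'   `eta_cl`, `eta_vc`, `eta_q` and list-column `f_occ` for the drawing
#'   variant.
#' @examples
#' pop <- generate_population(5, seed = 1)
#' add_typical_parameters(pop, mpa_params())
#' draw_individual_parameters(pop, mpa_params(), n_occasions = 2, seed = 1)
#' @export
add_typical_parameters <- function(subjects, params) {
  stopifnot(inherits(params, "mpa_params"))
  subjects <- as_tibble(subjects)
  disp <- typical_disposition(params, subjects$weight)
  subjects |>
    mutate(
      cl = typical_clearance(params, .data$weight, .data$albumin),
      vc = disp$vc, vp = disp$vp, q = disp$q, ktr = disp$ktr
    )
}

#' @rdname add_typical_parameters
#' @export
draw_individual_parameters <- function(subjects, params, n_occasions = 1L,
                                       seed = NULL) {
  stopifnot(inherits(params, "mpa_params"))
  n_occasions <- as.integer(n_occasions)
  if (is.na(n_occasions) || n_occasions < 1L) {
    abort("`n_occasions` must be an integer >= 1")
  }
  out <- add_typical_parameters(subjects, params)
  n <- nrow(out)
  draws <- with_optional_seed(seed, {
    list(
      eta_cl = rnorm(n, 0, sqrt(params$omega2_cl)),
      eta_vc = rnorm(n, 0, sqrt(params$omega2_vc)),
      eta_q  = rnorm(n, 0, sqrt(params$omega2_q)),
      kappa  = matrix(rnorm(n * n_occasions, 0, sqrt(params$omega2_iov_f)),
                      nrow = n)
    )
  })
  out |>
    mutate(
      eta_cl = draws$eta_cl,
      eta_vc = draws$eta_vc,
      eta_q  = draws$eta_q,
      cl = .data$cl * exp(.data$eta_cl),
      vc = .data$vc * exp(.data$eta_vc),
      q  = .data$q * exp(.data$eta_q),
      f_occ = lapply(seq_len(n), function(i) exp(draws$kappa[i, ]))
    )
}

# shared validators -------------------------------------------------------

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite", name))
  }
  invisible(x)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream;
# with seed = NULL the global stream is used (and advanced).  Relies on
# lazy evaluation: the promise is forced only after the seed is set.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
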