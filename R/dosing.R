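#' Round a dose to the available tablet size
#'
#' MMF tablets come in 250-mg steps, so computed doses are rounded to a
#' multiple of `unit`.  The default mode rounds to the nearest multiple
#' with ties broken upwards, reflecting a preference for slightly elevated
#' over slightly reduced exposure; `"up"` and `"down"` always round to the
#' next multiple in that direction.
#'
#' @param dose Dose(s) in mg, non-negative.
#' @param unit Rounding unit in mg (default 250).
#' @param mode One of `"nearest"` (ties up), `"up"`, `"down"`.
#' @return Rounded dose(s), multiples of `unit`.
#' @examples
#' round_dose(780)        # 750
#' round_dose(625)        # tie -> 750
#' round_dose(410, mode = "up")
#' @export
round_dose <- function(dose, unit = 250, mode = c("nearest", "up", "down")) {
  mode <- match.arg(mode)
  if (any(!is.finite(dose)) || any(dose < 0)) {
    abort("`dose` must be non-negative and finite")
  }
  check_positive(unit, "unit")
  k <- switch(mode,
    nearest = floor(dose / unit + 0.5), # ties rounded up
    up = ceiling(dose / unit),
    down = floor(dose / unit)
  )
  k * unit
}

#' Licensed BSA-based MMF starting dose
#'
#' The licensed pediatric regimen is 1200 mg/m^2/day of MMF divided over
#' two daily doses; the twice-daily dose is 600 mg/m^2 x BSA, rounded to
#' the available tablet size.
#'
#' @param bsa Body surface area in m^2 (> 0), vectorized.
#' @param rounding Tablet rounding unit in mg; see [round_dose()].
#' @param mode Rounding mode passed to [round_dose()].
#' @return Twice-daily dose(s) in mg MMF.
#' @examples
#' licensed_dose(1.3)   # 780 mg -> 750 mg
#' licensed_dose(dubois_bsa(70, 170))
#' @export
licensed_dose <- function(bsa, rounding = 250, mode = "nearest") {
  check_positive(bsa, "bsa")
  round_dose(600 * bsa, unit = rounding, mode = mode)
}

#' Weight-band dosing charts
#'
#' `published_chart()` returns the optimized MMF starting-dose chart for
#' pediatric kidney-transplant recipients: below 20 kg, 250 mg; 20 to
#' under 40 kg, 500 mg; 40 to under 60 kg, 750 mg; 60 to 90 kg, 1000 mg,
#' all twice daily.  `chart_dose()` looks weights up in a chart;
#' `derive_chart()` rebuilds a chart from the clearance model and a target
#' AUC via dose = CL/F x target AUC at a representative weight per band.
#'
#' A chart is a tibble with columns `weight_low` (inclusive),
#' `weight_high` (exclusive; the final band includes its upper bound) and
#' `dose_mg` (twice-daily dose).
#'
#' @return `published_chart()` / `derive_chart()`: a chart tibble.
#'   `chart_dose()`: twice-daily dose(s) in mg.
#' @examples
#' chart <- published_chart()
#' chart_dose(chart, c(15, 45, 75))
#' derive_chart(mpa_params(), target_auc = 45)
#' @export
published_chart <- function() {
  tibble(
    weight_low = c(10, 20, 40, 60),
    weight_high = c(20, 40, 60, 90),
    dose_mg = c(250, 500, 750, 1000)
  )
}

#' @rdname published_chart
#' @param chart A chart tibble.
#' @param weight Body weight(s) in kg.
#' @param out_of_range `"error"` to fail on weights outside the chart,
#'   `"na"` to return `NA` for them.
#' @export
chart_dose <- function(chart, weight,
                       out_of_range = c("error", "na")) {
  out_of_range <- match.arg(out_of_range)
  validate_chart(chart)
  check_positive(weight, "weight")
  lo <- min(chart$weight_low)
  hi <- max(chart$weight_high)
  # last band closed above so the stated upper limit is dosable
  idx <- findInterval(weight, c(chart$weight_low, hi),
                      rightmost.closed = TRUE)
  bad <- weight < lo | weight > hi
  if (any(bad)) {
    if (out_of_range == "error") {
      abort(sprintf(
        "weight(s) outside the chart range [%g, %g] kg: %s",
        lo, hi, paste(signif(weight[bad], 4), collapse = ", ")
      ))
    }
    idx[bad] <- NA_integer_
  }
  chart$dose_mg[idx]
}

#' @rdname published_chart
#' @param params An [mpa_params()] object.
#' @param bands Numeric vector of band edges in kg (length >= 2,
#'   strictly increasing).
#' @param target_auc Target steady-state AUC over one dosing interval
#'   (mg.h/L).
#' @param albumin Albumin value (g/L) at which the typical clearance is
#'   evaluated.
#' @param rounding Tablet rounding unit in mg; use 1 for unrounded doses.
#' @param representative Weight representing each band: its midpoint or
#'   one of its edges.
#' @param mode Rounding mode passed to [round_dose()].
#' @export
derive_chart <- function(params, bands = c(10, 20, 40, 60, 90),
                         target_auc = 45, albumin = 33, rounding = 250,
                         representative = c("midpoint", "lower", "upper"),
                         mode = "nearest") {
  stopifnot(inherits(params, "mpa_params"))
  representative <- match.arg(representative)
  if (length(bands) < 2L || any(diff(bands) <= 0)) {
    abort("`bands` must be strictly increasing edges of length >= 2")
  }
  if (!is.finite(target_auc) || target_auc < 0) {
    abort("`target_auc` must be non-negative and finite")
  }
  lo <- bands[-length(bands)]
  hi <- bands[-1]
  w_rep <- switch(representative,
    midpoint = (lo + hi) / 2,
    lower = lo,
    upper = hi
  )
  cl <- typical_clearance(params, w_rep, albumin)
  tibble(
    weight_low = lo,
    weight_high = hi,
    dose_mg = round_dose(cl * target_auc, unit = rounding, mode = mode)
  )
}

validate_chart <- function(chart) {
  need <- c("weight_low", "weight_high", "dose_mg")
  if (!all(need %in% names(chart))) {
    abort("a chart needs columns weight_low, weight_high, dose_mg")
  }
  ord <- order(chart$weight_low)
  chart <- chart[ord, ]
  if (any(chart$weight_high <= chart$weight_low)) {
    abort("chart bands must have weight_high > weight_low")
  }
  if (nrow(chart) > 1 &&
      any(abs(chart$weight_low[-1] -
              chart$weight_high[-nrow(chart)]) > 1e-9)) {
    abort("chart bands must be contiguous and non-overlapping")
  }
  invisible(chart)
}

#' Build a twice-daily dosing regimen table
#'
#' A regimen is a tibble of dose events with columns `time` (h), `amt`
#' (mg MMF) and `occ` (occasion index).  By default all doses belong to a
#' single occasion.
#'
#' @param dose Dose per administration (mg MMF).
#' @param n_doses Number of administrations.
#' @param interval Dosing interval (h).
#' @param start Time of the first dose (h).
#' @param occ Occasion index, recycled, or one value per dose.
#' @return A regimen tibble.
#' @examples
#' regimen(500, n_doses = 6)        # 3 days of twice-daily 500 mg
#' @export
regimen <- function(dose, n_doses = 1L, interval = 12, start = 0, occ = 1L) {
  if (any(!is.finite(dose)) || any(dose < 0)) {
    abort("`dose` must be non-negative and finite")
  }
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) abort("`n_doses` must be >= 1")
  if (start < 0) abort("`start` must be non-negative")
  tibble(
    time = start + interval * (seq_len(n_doses) - 1),
    amt = rep_len(dose, n_doses),
    occ = rep_len(as.integer(occ), n_doses)
  )
}
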