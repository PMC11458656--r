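# Parametric pediatric growth reference: median height (cm) and weight
# (kg) by age and sex, linearly interpolated between whole years.  Values
# are rounded medians from standard European/North-American growth
# references; around the medians the generator places a 4% CV normal
# spread on height and a 17% CV log-normal spread on weight (adjusted for
# the subject's height, see below), which reproduces the weight range seen
# in school-age transplant cohorts.
growth_reference <- tibble::tibble(
  age = rep(3:18, 2),
  sex = rep(c("male", "female"), each = 16),
  height = c(
    96.1, 103.3, 110.0, 116.0, 121.7, 127.3, 132.6, 137.8,
    143.1, 149.1, 156.0, 163.2, 169.0, 172.9, 175.2, 176.1,
    95.1, 102.7, 109.4, 115.1, 120.8, 126.6, 132.5, 138.6,
    145.0, 151.2, 157.1, 160.4, 162.1, 162.8, 163.1, 163.3
  ),
  weight = c(
    14.3, 16.3, 18.4, 20.7, 23.1, 25.8, 28.7, 31.9,
    35.7, 40.0, 45.0, 50.4, 55.5, 60.1, 63.5, 65.9,
    13.9, 15.9, 17.9, 20.2, 22.8, 25.8, 29.1, 32.9,
    37.4, 42.1, 46.4, 49.8, 52.0, 53.5, 54.4, 55.0
  )
)

median_growth <- function(age, sex) {
  ref <- growth_reference
  out_h <- numeric(length(age))
  out_w <- numeric(length(age))
  for (s in c("male", "female")) {
    idx <- sex == s
    if (!any(idx)) next
    r <- ref[ref$sex == s, ]
    out_h[idx] <- stats::approx(r$age, r$height, xout = age[idx], rule = 2)$y
    out_w[idx] <- stats::approx(r$age, r$weight, xout = age[idx], rule = 2)$y
  }
  list(height = out_h, weight = out_w)
}

#' Generate a virtual pediatric population
#'
#' Samples virtual subjects with the demographic structure assumed by the
#' dose-optimization analysis: age uniform over `age_range`, sex Bernoulli
#' with probability `sex_ratio` of male, height from a sex-specific growth
#' reference (median by age, 4% CV normal spread), weight from the
#' weight-for-age median rescaled by the squared height ratio (so that
#' taller-than-median children are proportionally heavier) with a
#' log-normal 17% CV spread, and serum albumin from a truncated normal
#' distribution (bounds 20-55 g/L).  Heights are truncated to 90-200 cm
#' and weights to 10-100 kg.  Body surface area is computed with the
#' Dubois formula.
#'
#' Defaults mirror the virtual-trial population: 3-18 years, mean albumin
#' 33 g/L with 21% CV.
#'
#' @param n Number of subjects (>= 1).
#' @param age_range Numeric length-2, years; must lie within (0, 25).
#' @param albumin_mean Mean serum albumin (g/L).
#' @param albumin_cv Albumin coefficient of variation as a fraction in
#'   (0, 1).
#' @param sex_ratio Probability of male sex.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `id`, `age`, `sex`, `height`, `weight`,
#'   `albumin`, `bsa`.
#' @examples
#' pop <- generate_population(1000, seed = 42)
#' mean(pop$albumin)
#' range(pop$bsa)
#' @export
generate_population <- function(n,
                                age_range = c(3, 18),
                                albumin_mean = 33,
                                albumin_cv = 0.21,
                                sex_ratio = 0.5,
                                seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("`n` must be an integer >= 1")
  if (length(age_range) != 2L || any(!is.finite(age_range)) ||
      age_range[1] > age_range[2] || age_range[1] <= 0 || age_range[2] >= 25) {
    abort("`age_range` must be an ordered pair within (0, 25)")
  }
  if (!is.finite(albumin_cv) || albumin_cv <= 0 || albumin_cv >= 1) {
    abort("`albumin_cv` must lie in (0, 1)")
  }
  check_positive(albumin_mean, "albumin_mean")

  with_optional_seed(seed, {
    age <- runif(n, age_range[1], age_range[2])
    sex <- ifelse(rbinom(n, 1, sex_ratio) == 1, "male", "female")
    med <- median_growth(age, sex)
    height <- rnorm(n, med$height, 0.04 * med$height)
    height <- pmin(pmax(height, 90), 200)
    weight <- med$weight * (height / med$height)^2 * exp(rnorm(n, 0, 0.17))
    weight <- pmin(pmax(weight, 10), 100)
    albumin <- rtruncnorm(n, albumin_mean, albumin_cv * albumin_mean, 20, 55)
    tibble(
      id = seq_len(n), age = age, sex = sex,
      height = height, weight = weight, albumin = albumin,
      bsa = dubois_bsa(weight, height)
    )
  })
}

# truncated normal by rejection; bounds are a few SD from the mean here so
# acceptance is high and the loop terminates quickly
rtruncnorm <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}
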