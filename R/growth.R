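# Doubling arithmetic and the exponential growth law.
#
# Everything downstream reduces to one identity: a sphere grown from a single
# cell of diameter c to diameter d has undergone N = 3 * log2(d / c) volume
# doublings, and each doubling takes one TVDT.

#' Tumor volume doubling time
#'
#' Wraps a TVDT (days for tumor *volume* to double) with range validation.
#' The model is calibrated for TVDTs between 10 and 310 days; values in
#' (270, 310] are accepted but flagged as beyond the subtype bands.
#'
#' @param tvdt_days tumor volume doubling time, days.
#' @return An object of class `bcmets_rate`.
#' @examples
#' growth_rate(88)
#' @export
growth_rate <- function(tvdt_days) {
  if (!is.numeric(tvdt_days) || length(tvdt_days) != 1 || !is.finite(tvdt_days))
    stop_bcmets("tvdt_days must be a finite numeric scalar", "bcmets_domain_error")
  if (tvdt_days < 10 || tvdt_days > 310)
    stop_bcmets(
      sprintf("TVDT %.4g d outside the supported range [10, 310] days", tvdt_days),
      "bcmets_out_of_model"
    )
  structure(
    list(tvdt_days = tvdt_days, beyond_bands = tvdt_days > 270),
    class = "bcmets_rate"
  )
}

#' @export
print.bcmets_rate <- function(x, ...) {
  cat(sprintf("TVDT: %.4g days%s\n", x$tvdt_days,
              if (isTRUE(x$beyond_bands)) " (beyond subtype bands)" else ""))
  invisible(x)
}

as_tvdt_days <- function(rate) {
  if (inherits(rate, "bcmets_rate")) rate$tvdt_days else growth_rate(rate)$tvdt_days
}

#' Volume-doubling count of a tumor of given diameter
#'
#' Number of volume doublings N = 3 * log2(d / cell_diameter) a sphere has
#' undergone growing from a single cell to diameter `d`.
#'
#' @param d diameter, mm (vectorized).
#' @param constants a [model_constants()] object.
#' @return doubling count(s), dimensionless.
#' @examples
#' doublings_from_diameter(15.1) # 31.68, prints as 31.7
#' @export
doublings_from_diameter <- function(d, constants = model_constants()) {
  if (any(!is.finite(d)) || any(d < constants$cell_diameter))
    stop_bcmets("diameter below the single-cell diameter", "bcmets_domain_error")
  3 * log2(d / constants$cell_diameter)
}

#' Diameter after a given number of doublings
#'
#' Exact inverse of [doublings_from_diameter()].
#'
#' @param n volume-doubling count (vectorized), must be >= 0.
#' @inheritParams doublings_from_diameter
#' @return diameter, mm.
#' @export
diameter_from_doublings <- function(n, constants = model_constants()) {
  if (any(!is.finite(n)) || any(n < 0))
    stop_bcmets("doubling count must be non-negative", "bcmets_domain_error")
  constants$cell_diameter * 2^(n / 3)
}

#' Cell count after a given number of doublings
#'
#' 2^n, real-valued; 40 doublings is the ~1.1e12-cell lethal burden.
#'
#' @param n volume-doubling count (vectorized), must be >= 0.
#' @return cell count, dimensionless.
#' @export
cell_count_from_doublings <- function(n) {
  if (any(!is.finite(n)) || any(n < 0))
    stop_bcmets("doubling count must be non-negative", "bcmets_domain_error")
  2^n
}

#' Grow a tumor exponentially
#'
#' Diameter after `t` days of exponential volume growth at the given TVDT:
#' volume doubles every `tvdt_days`, so `d0 * 2^(t / (3 * tvdt_days))`.
#'
#' @param d0 starting diameter, mm.
#' @param rate a [growth_rate()] or a plain TVDT in days.
#' @param t elapsed time, days (vectorized), must be >= 0.
#' @return diameter at time `t`, mm.
#' @examples
#' grow(1, growth_rate(30), 90) # one diameter doubling -> 2 mm
#' @export
grow <- function(d0, rate, t) {
  if (any(d0 <= 0)) stop_bcmets("starting diameter must be positive", "bcmets_domain_error")
  if (any(t < 0)) stop_bcmets("elapsed time must be non-negative", "bcmets_domain_error")
  d0 * 2^(t / (3 * as_tvdt_days(rate)))
}

#' Time to accumulate a number of doublings
#'
#' `n * tvdt_days`: the time for `n` volume doublings at a fixed TVDT.
#'
#' @param n volume-doubling count (vectorized), must be >= 0.
#' @inheritParams grow
#' @return duration, days.
#' @export
duration_days <- function(n, rate) {
  if (any(n < 0)) stop_bcmets("doubling count must be non-negative", "bcmets_domain_error")
  n * as_tvdt_days(rate)
}

#' A dated tumor diameter measurement
#'
#' @param exam_date calendar date (coerced with [as.Date()]).
#' @param diameter tumor diameter, mm, > 0.
#' @return An object of class `bcmets_measurement`.
#' @export
tumor_measurement <- function(exam_date, diameter) {
  exam_date <- as.Date(exam_date)
  if (is.na(exam_date))
    stop_bcmets("exam_date is not a valid date", "bcmets_domain_error")
  if (!is.numeric(diameter) || length(diameter) != 1 || !is.finite(diameter) || diameter <= 0)
    stop_bcmets("diameter must be a positive finite scalar (mm)", "bcmets_domain_error")
  structure(list(exam_date = exam_date, diameter = diameter),
            class = "bcmets_measurement")
}

#' Estimate TVDT from two dated measurements
#'
#' Schwartz-type estimator: with diameters d1 < d2 measured dt days apart,
#' TVDT = dt / (3 * log2(d2 / d1)). Exact inverse of [grow()] under the
#' exponential law.
#'
#' @param m1,m2 [tumor_measurement()] objects, `m2` later and larger than `m1`.
#' @return A [growth_rate()].
#' @examples
#' m1 <- tumor_measurement("2020-01-01", 1)
#' m2 <- tumor_measurement("2020-03-31", 2)
#' tvdt_from_measurements(m1, m2) # 90 d / 3 doublings = TVDT 30 d
#' @export
tvdt_from_measurements <- function(m1, m2) {
  stopifnot(inherits(m1, "bcmets_measurement"), inherits(m2, "bcmets_measurement"))
  dt <- as.numeric(m2$exam_date - m1$exam_date)
  if (dt <= 0)
    stop_bcmets("second examination must be after the first", "bcmets_estimation_error")
  if (m2$diameter <= m1$diameter)
    stop_bcmets(
      "no growth between examinations: TVDT is not estimable from a non-increasing diameter pair",
      "bcmets_estimation_error"
    )
  growth_rate(dt / (3 * log2(m2$diameter / m1$diameter)))
}

#' Convert days to years
#'
#' @param t duration, days (vectorized), must be >= 0.
#' @param constants a [model_constants()] object (supplies days per year).
#' @return duration, years.
#' @export
years <- function(t, constants = model_constants()) {
  if (any(t < 0)) stop_bcmets("duration must be non-negative", "bcmets_domain_error")
  t / constants$days_per_year
}
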