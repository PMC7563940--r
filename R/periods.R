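# Scenario calculators for the four natural-history periods of a secondary
# distant metastasis (sdMTS):
#   MTS-I   : first metastatic cell seeded -> primary-tumor (PT) resection
#   MTS-II  : resection -> metastasis reaches the 9 mm detection threshold
#   visible : 9 mm -> lethal burden (40 doublings)
#   survival: MTS-II + visible (post-surgery lifetime bound)
#
# Two seeding anchors coexist by design. MTS-I is measured from the moment
# the PT passes the 1 mm seeding diameter, i.e. its 3*log2(100) = 19.93th
# doubling; MTS-II assumes the lesion was seeded at the PT's *integer* 20th
# doubling, so at surgery it has accumulated N_pt - 20 doublings. This pair
# is the unique combination that reproduces the published period tables.

#' Scenario inputs for the period calculators
#'
#' @param d_pt_at_surgery PT diameter at resection, mm; must exceed the
#'   seeding threshold (default 1 mm).
#' @param band a `bcmets_band` (supplies the metastasis TVDT range).
#' @param constants a [model_constants()].
#' @return An object of class `bcmets_scenario_inputs`.
#' @export
scenario_inputs <- function(d_pt_at_surgery, band, constants = model_constants()) {
  stopifnot(inherits(band, "bcmets_band"))
  if (!is.numeric(d_pt_at_surgery) || length(d_pt_at_surgery) != 1 ||
      !is.finite(d_pt_at_surgery) || d_pt_at_surgery <= constants$pt_seeding_diameter)
    stop_bcmets(
      sprintf("PT diameter at surgery must exceed the %g mm seeding threshold",
              constants$pt_seeding_diameter),
      "bcmets_domain_error"
    )
  structure(list(d_pt_at_surgery = d_pt_at_surgery, band = band, constants = constants),
            class = "bcmets_scenario_inputs")
}

new_period_set <- function(mts1, mts2, visible, tvdt, scenario) {
  structure(
    list(mts1_years = mts1, mts2_years = mts2, visible_years = visible,
         survival_years = mts2 + visible, tvdt_mts_days = tvdt, scenario = scenario),
    class = "bcmets_period_set"
  )
}

#' @export
print.bcmets_period_set <- function(x, ...) {
  cat(sprintf("Metastasis periods (%s scenario, TVDT_MTS = %g d)\n",
              x$scenario, x$tvdt_mts_days))
  cat(sprintf("  non-visible MTS-I:  %6.2f y\n", round_half_up(x$mts1_years)))
  cat(sprintf("  non-visible MTS-II: %6.2f y\n", round_half_up(x$mts2_years)))
  cat(sprintf("  visible MTS:        %6.2f y\n", round_half_up(x$visible_years)))
  cat(sprintf("  survival:           %6.2f y\n", round_half_up(x$survival_years)))
  invisible(x)
}

# Core period arithmetic at a fixed metastasis TVDT T (days).
# earliest: lesion already at the seeding diameter (1 mm) when the PT is
#           resected -- the fastest possible post-surgery course.
# latest:   lesion seeded at the PT's 20th doubling, so it has grown
#           N_pt - 20 doublings by surgery; MTS-I spans the PT's growth from
#           the 1 mm seeding size to its resection size.
periods_at <- function(d_pt, tvdt_days, scenario = c("earliest", "latest"),
                       constants = model_constants()) {
  scenario <- match.arg(scenario)
  n_pt <- doublings_from_diameter(d_pt, constants)
  n_seed <- doublings_from_diameter(constants$pt_seeding_diameter, constants)
  n_det <- doublings_from_diameter(constants$mts_detection_diameter, constants)
  if (scenario == "latest" && n_pt <= constants$seeding_doubling_index)
    stop_bcmets("PT below seeding size: no metastatic history to compute",
                "bcmets_domain_error")
  yrs <- function(n) years(duration_days(n, tvdt_days), constants)
  if (scenario == "earliest") {
    new_period_set(
      mts1 = yrs(n_seed),
      mts2 = yrs(n_det - n_seed),
      visible = yrs(constants$lethal_doubling_count - n_det),
      tvdt = tvdt_days, scenario = scenario
    )
  } else {
    new_period_set(
      mts1 = yrs(n_pt - n_seed),
      mts2 = yrs(n_det - (n_pt - constants$seeding_doubling_index)),
      visible = yrs(constants$lethal_doubling_count - n_det),
      tvdt = tvdt_days, scenario = scenario
    )
  }
}

#' Earliest (fastest) metastasis scenario
#'
#' The most pessimistic course: the metastasis is already at the 1 mm seeding
#' diameter when the PT is resected and grows at the band's *minimum* TVDT.
#' MTS-I is the lesion's own growth time from one cell to 1 mm; MTS-II is the
#' remaining growth to the 9 mm detection threshold.
#'
#' @param inputs a [scenario_inputs()].
#' @return A `bcmets_period_set`.
#' @examples
#' reg <- subtype_registry()
#' earliest_scenario(scenario_inputs(15.1, reg$bands$V))
#' @export
earliest_scenario <- function(inputs) {
  stopifnot(inherits(inputs, "bcmets_scenario_inputs"))
  periods_at(inputs$d_pt_at_surgery, inputs$band$tvdt_mts_range[1],
             "earliest", inputs$constants)
}

#' Latest (slowest) metastasis scenario
#'
#' The most optimistic course: the metastasis was seeded when the PT passed
#' 1 mm (its 20th doubling) and grows at the band's *maximum* TVDT, so it is
#' smallest at surgery and takes longest to surface.
#'
#' @inheritParams earliest_scenario
#' @return A `bcmets_period_set`.
#' @examples
#' reg <- subtype_registry()
#' latest_scenario(scenario_inputs(15.1, reg$bands$V)) # MTS-II 6.56 y etc.
#' @export
latest_scenario <- function(inputs) {
  stopifnot(inherits(inputs, "bcmets_scenario_inputs"))
  periods_at(inputs$d_pt_at_surgery, inputs$band$tvdt_mts_range[2],
             "latest", inputs$constants)
}

#' Post-surgery latency window for late-seeded metastases
#'
#' Metastatic cells are shed continuously from the PT's 20th doubling up to
#' the moment of resection. At a fixed TVDT `T` this spreads the post-surgery
#' MTS-II latency over an interval: the low end is the lesion seeded first
#' (largest at surgery), the high end a single cell seeded at resection,
#' which needs the full doubling count to 9 mm. The diagnostic "(+)"
#' extension rows are built from this window; its chained diagnosis period is
#' the seeding spread `(N_pt - N_seed) * T`.
#'
#' @param d_pt PT diameter at resection, mm.
#' @param rate a [growth_rate()] or plain TVDT in days.
#' @param constants a [model_constants()].
#' @return list with `mts2_low`, `mts2_high` (years) and `width_years`
#'   (the seeding spread used as the chained diagnosis period).
#' @export
seeded_at_surgery_window <- function(d_pt, rate, constants = model_constants()) {
  tvdt <- as_tvdt_days(rate)
  n_pt <- doublings_from_diameter(d_pt, constants)
  n_seed <- doublings_from_diameter(constants$pt_seeding_diameter, constants)
  n_det <- doublings_from_diameter(constants$mts_detection_diameter, constants)
  if (n_pt <= constants$seeding_doubling_index)
    stop_bcmets("PT below seeding size", "bcmets_domain_error")
  yrs <- function(n) years(duration_days(n, tvdt), constants)
  list(
    mts2_low = yrs(n_det - (n_pt - constants$seeding_doubling_index)),
    mts2_high = yrs(n_det),
    width_years = yrs(n_pt - n_seed)
  )
}

#' Whole-natural-history doubling identity
#'
#' The PT's doublings at surgery, plus the metastasis's post-surgery
#' non-visible doublings (seeded at the 20th PT doubling), plus its visible
#' doublings to the lethal burden, telescope to the fixed whole-history
#' span: N_pt + (N_det - (N_pt - 20)) + (40 - N_det) = 60 for every PT size.
#'
#' @param d_pt PT diameter at resection, mm (vectorized).
#' @param constants a [model_constants()].
#' @return the whole-history doubling count (60 under defaults).
#' @export
whole_history_identity <- function(d_pt, constants = model_constants()) {
  n_pt <- doublings_from_diameter(d_pt, constants)
  n_det <- doublings_from_diameter(constants$mts_detection_diameter, constants)
  n_pt + (n_det - (n_pt - constants$seeding_doubling_index)) +
    (constants$lethal_doubling_count - n_det)
}
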