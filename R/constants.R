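#' Kinetic model constants
#'
#' Fixed anchors of the exponential natural-history model. A tumor is treated
#' as a sphere grown from a single cell of diameter `cell_diameter`; its
#' volume doubles once per TVDT, so a diameter doubling equals three volume
#' doublings. The defaults encode the standard natural-history bookkeeping:
#' metastatic seeding starts when the primary tumor (PT) passes ~1 mm
#' (its 20th volume doubling), a distant metastasis becomes detectable by
#' multimodal imaging at 9 mm, and the lethal burden is reached after 40
#' doublings (~1.1e12 cells, ~102 mm sphere). Seeding (20) plus lethal (40)
#' doublings span the whole 60-doubling natural history.
#'
#' @param cell_diameter diameter of a single tumor cell, mm.
#' @param mts_detection_diameter diameter at which a distant metastasis is
#'   detectable, mm.
#' @param pt_seeding_diameter PT diameter at which metastatic seeding begins,
#'   mm. At the default cell size this is the PT's 19.93th doubling; the
#'   companion integer anchor is `seeding_doubling_index`.
#' @param seeding_doubling_index integer doubling index of the PT at which the
#'   first metastatic cell is shed (default 20).
#' @param lethal_doubling_count volume doublings from one cell to the lethal
#'   burden (default 40).
#' @param whole_history_doublings doubling span of the whole natural history
#'   (default 60; must equal seeding index + lethal count).
#' @param days_per_year calendar conversion, days (default 365.25).
#' @param linear_phase_theta shape constant of the late linear growth phase;
#'   carried for completeness, unused by the exponential regime.
#' @return An object of class `bcmets_constants` (a validated list).
#' @examples
#' cst <- model_constants()
#' doublings_from_diameter(15.1, cst) # ~31.7 doublings at surgery
#' @export
model_constants <- function(cell_diameter = 0.01,
                            mts_detection_diameter = 9.0,
                            pt_seeding_diameter = 1.0,
                            seeding_doubling_index = 20,
                            lethal_doubling_count = 40,
                            whole_history_doublings = 60,
                            days_per_year = 365.25,
                            linear_phase_theta = 1) {
  c <- list(
    cell_diameter = cell_diameter,
    mts_detection_diameter = mts_detection_diameter,
    pt_seeding_diameter = pt_seeding_diameter,
    seeding_doubling_index = seeding_doubling_index,
    lethal_doubling_count = lethal_doubling_count,
    whole_history_doublings = whole_history_doublings,
    days_per_year = days_per_year,
    linear_phase_theta = linear_phase_theta
  )
  if (!all(vapply(c, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE)))
    stop_bcmets("all model constants must be finite numeric scalars", "bcmets_domain_error")
  if (seeding_doubling_index + lethal_doubling_count != whole_history_doublings)
    stop_bcmets(
      "seeding_doubling_index + lethal_doubling_count must equal whole_history_doublings",
      "bcmets_domain_error"
    )
  if (cell_diameter <= 0 || !(cell_diameter < pt_seeding_diameter) ||
      !(pt_seeding_diameter < mts_detection_diameter))
    stop_bcmets(
      "diameters must satisfy 0 < cell_diameter < pt_seeding_diameter < mts_detection_diameter",
      "bcmets_domain_error"
    )
  if (days_per_year <= 0)
    stop_bcmets("days_per_year must be positive", "bcmets_domain_error")
  structure(c, class = "bcmets_constants")
}

#' @export
print.bcmets_constants <- function(x, ...) {
  cat("Natural-history model constants\n")
  cat(sprintf("  cell diameter:        %.3g mm\n", x$cell_diameter))
  cat(sprintf("  seeding threshold:    %.3g mm (doubling index %g)\n",
              x$pt_seeding_diameter, x$seeding_doubling_index))
  cat(sprintf("  detection threshold:  %.3g mm\n", x$mts_detection_diameter))
  cat(sprintf("  lethal burden:        %g doublings (~%.3g cells)\n",
              x$lethal_doubling_count, 2^x$lethal_doubling_count))
  cat(sprintf("  whole history:        %g doublings\n", x$whole_history_doublings))
  cat(sprintf("  days per year:        %g\n", x$days_per_year))
  invisible(x)
}
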