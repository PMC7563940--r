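# Assembly of a full diagnostic column for one primary-tumor subtype:
# the chained post-surgery windows during which metastases of each growth
# band can newly surface, the late-seeding "(+)" extension, and the total
# after which the patient is considered healthy.
#
# A column for PT subtype s contains: the rapid band (metastases may always
# grow rapidly), every band at least as fast as s's own, and one "(+)"
# extension at s's band-edge TVDT (absent for subtype I). The structure is
# data (registry config), not re-derivation.

#' Band windows of a diagnostic column
#'
#' Builds the ordered (fastest first) list of post-surgery detection windows
#' for a PT of the given subtype. The rapid window spans the earliest-scenario
#' MTS-II at the band's minimum TVDT to the latest-scenario MTS-II at its
#' maximum; each slower band contributes its latest-scenario MTS-II range;
#' the "(+)" row is the late-seeding window of
#' [seeded_at_surgery_window()] at the column's edge TVDT.
#'
#' @param subtype PT band id, one of `"I"`..`"V"`.
#' @param d_pt PT diameter at surgery, mm.
#' @param registry a [subtype_registry()].
#' @param constants a [model_constants()].
#' @return data.frame with one row per window: `band_id`, `tvdt_min`,
#'   `tvdt_max`, `mts2_low`, `mts2_high`, `plus_width`, `is_plus_row`,
#'   `screening_interval_months`.
#' @export
band_windows_for_column <- function(subtype, d_pt = 15.1,
                                    registry = subtype_registry(),
                                    constants = model_constants()) {
  subtype <- match.arg(subtype, c("I", "II", "III", "IV", "V"))
  col_cfg <- registry$columns[[subtype]]
  if (is.null(col_cfg))
    stop_bcmets(sprintf("registry has no column structure for subtype %s", subtype),
                "bcmets_config_error")
  band_order <- names(registry$bands) # fastest first in the shipped config
  rows <- list()
  for (id in col_cfg$mts_bands) {
    b <- registry$bands[[id]]
    tmin <- b$tvdt_mts_range[1]
    tmax <- b$tvdt_mts_range[2]
    if (id == col_cfg$mts_bands[[1]]) {
      # rapid window: earliest scenario at the fast edge, latest at the slow
      lo <- periods_at(d_pt, tmin, "earliest", constants)$mts2_years
    } else {
      lo <- periods_at(d_pt, tmin, "latest", constants)$mts2_years
    }
    hi <- periods_at(d_pt, tmax, "latest", constants)$mts2_years
    rows[[length(rows) + 1L]] <- data.frame(
      band_id = id, tvdt_min = tmin, tvdt_max = tmax,
      mts2_low = lo, mts2_high = hi, plus_width = NA_real_,
      is_plus_row = FALSE,
      screening_interval_months = b$screening_interval_months
    )
  }
  if (!is.null(col_cfg$plus_at)) {
    w <- seeded_at_surgery_window(d_pt, growth_rate(col_cfg$plus_at), constants)
    # the "(+)" row sits in the block of the next slower band and inherits
    # that block's examination interval
    own_pos <- match(subtype, band_order)
    slower <- registry$bands[[band_order[min(own_pos + 1L, length(band_order))]]]
    rows[[length(rows) + 1L]] <- data.frame(
      band_id = paste0(col_cfg$plus_at, "(+)"),
      tvdt_min = col_cfg$plus_at, tvdt_max = col_cfg$plus_at,
      mts2_low = w$mts2_low, mts2_high = w$mts2_high, plus_width = w$width_years,
      is_plus_row = TRUE,
      screening_interval_months = slower$screening_interval_months
    )
  }
  do.call(rbind, rows)
}

#' Chain diagnosis periods across the windows of a column
#'
#' The rapid window's diagnosis period is its own width; each subsequent
#' band's period is its MTS-II high minus the previous band's high (the
#' incremental time in which its metastases can newly surface); the "(+)"
#' row's period is the seeding spread. In `"printed-parity"` mode every
#' window bound is first rounded half-up to 2 decimals, reproducing the
#' published sums digit-for-digit; the default `"unrounded"` mode chains
#' full-precision values.
#'
#' @param windows data.frame from [band_windows_for_column()].
#' @param mode `"unrounded"` (default) or `"printed-parity"`.
#' @return `windows` with a `diagnosis_period_years` column appended.
#' @export
chain_diagnosis_periods <- function(windows, mode = c("unrounded", "printed-parity")) {
  mode <- match.arg(mode)
  rnd <- if (mode == "printed-parity") function(x) round_half_up(x, 2) else identity
  lo <- rnd(windows$mts2_low)
  hi <- rnd(windows$mts2_high)
  wd <- rnd(windows$plus_width)
  n <- nrow(windows)
  per <- numeric(n)
  prev_hi <- NA_real_
  for (k in seq_len(n)) {
    if (windows$is_plus_row[k]) {
      per[k] <- wd[k]
    } else if (k == 1L) {
      per[k] <- hi[k] - lo[k]
    } else {
      if (hi[k] <= prev_hi)
        stop_bcmets("window MTS-II highs must increase along the chain",
                    "bcmets_assembly_error")
      per[k] <- hi[k] - prev_hi
    }
    if (!windows$is_plus_row[k]) prev_hi <- hi[k]
  }
  windows$diagnosis_period_years <- per
  windows
}

#' Assemble a full diagnostic column
#'
#' Convenience wrapper: windows, chained periods and total for one PT
#' subtype. The total is the considered-healthy horizon: a patient with no
#' detected metastases by then is no longer expected to manifest any from
#' the resected PT.
#'
#' @inheritParams band_windows_for_column
#' @inheritParams chain_diagnosis_periods
#' @return An object of class `bcmets_diagnostic_column`: list with
#'   `subtype`, `d_pt`, `mode`, `windows` (chained data.frame),
#'   `total_diagnosis_years`, `pt_doublings`, `constants`.
#' @examples
#' col <- diagnostic_column("V")
#' round_half_up(col$total_diagnosis_years) # 10.65 unrounded / 10.64 parity
#' @export
diagnostic_column <- function(subtype, d_pt = 15.1,
                              registry = subtype_registry(),
                              constants = model_constants(),
                              mode = c("unrounded", "printed-parity")) {
  mode <- match.arg(mode)
  w <- band_windows_for_column(subtype, d_pt, registry, constants)
  w <- chain_diagnosis_periods(w, mode)
  structure(
    list(subtype = subtype, d_pt = d_pt, mode = mode, windows = w,
         total_diagnosis_years = sum(w$diagnosis_period_years),
         pt_doublings = doublings_from_diameter(d_pt, constants),
         constants = constants),
    class = "bcmets_diagnostic_column"
  )
}

#' Total diagnosis period of a column
#'
#' @param column a [diagnostic_column()].
#' @return total period, years (the considered-healthy horizon).
#' @export
total_diagnosis_period <- function(column) {
  stopifnot(inherits(column, "bcmets_diagnostic_column"))
  column$total_diagnosis_years
}

#' @export
print.bcmets_diagnostic_column <- function(x, ...) {
  cat(sprintf("Diagnostic column, PT subtype %s, d_PT = %g mm (%s chaining)\n",
              x$subtype, x$d_pt, x$mode))
  w <- x$windows
  for (k in seq_len(nrow(w))) {
    cat(sprintf("  %-7s TVDT %3g-%3g d  window %5.2f-%5.2f y  period %5.2f y  every %d mo\n",
                w$band_id[k], w$tvdt_min[k], w$tvdt_max[k],
                round_half_up(w$mts2_low[k]), round_half_up(w$mts2_high[k]),
                round_half_up(w$diagnosis_period_years[k]),
                w$screening_interval_months[k]))
  }
  cat(sprintf("  total diagnosis period (considered healthy after): %.2f y\n",
              round_half_up(x$total_diagnosis_years)))
  invisible(x)
}

fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))
fmt_range <- function(lo, hi) paste0(fmt2(lo), "-", fmt2(hi))

#' Render diagnostic columns as a flat table
#'
#' Emits one row per (subtype, window) with every published quantity as a
#' 2-decimal half-up formatted string, mirroring the tabulated layout:
#' PT diameter and doubling count, the per-band MTS-I/MTS-II/visible/survival
#' ranges, the chained diagnosis period, the screening interval and the
#' column total. The late-seeding "(+)" rows carry only their MTS-II window
#' and period; their MTS-I and visible-period cells have no reconstruction
#' under the model constants and are rendered as `"unreconstructed"`.
#'
#' @param columns a list of [diagnostic_column()] objects (or a single one).
#' @return data.frame of formatted cells, one row per window.
#' @export
render_table <- function(columns) {
  if (inherits(columns, "bcmets_diagnostic_column")) columns <- list(columns)
  if (length(columns) == 0) return(data.frame())
  out <- list()
  for (col in columns) {
    cst <- col$constants
    w <- col$windows
    for (k in seq_len(nrow(w))) {
      if (w$is_plus_row[k]) {
        mts1 <- visible <- survival <- "unreconstructed"
      } else {
        pe_lo <- periods_at(col$d_pt, w$tvdt_min[k],
                            if (k == 1L) "earliest" else "latest", cst)
        pe_hi <- periods_at(col$d_pt, w$tvdt_max[k], "latest", cst)
        mts1 <- fmt_range(pe_lo$mts1_years, pe_hi$mts1_years)
        visible <- fmt_range(pe_lo$visible_years, pe_hi$visible_years)
        survival <- fmt_range(pe_lo$survival_years, pe_hi$survival_years)
      }
      out[[length(out) + 1L]] <- data.frame(
        subtype = col$subtype,
        d_pt_mm = fmt2(col$d_pt),
        pt_log_v = sprintf("%.1f", round_half_up(col$pt_doublings, 1)),
        band = w$band_id[k],
        tvdt_mts_days = if (w$is_plus_row[k]) w$band_id[k]
                        else paste0(w$tvdt_min[k], "-", w$tvdt_max[k]),
        d_mts_mm = fmt2(cst$mts_detection_diameter),
        non_visible_mts1_years = mts1,
        non_visible_mts2_years = fmt_range(w$mts2_low[k], w$mts2_high[k]),
        visible_mts_years = visible,
        survival_years = survival,
        diagnosis_period_years = fmt2(w$diagnosis_period_years[k]),
        screening_months = paste0(w$screening_interval_months[k], " mo"),
        total_diagnosis_years = fmt2(col$total_diagnosis_years)
      )
    }
  }
  do.call(rbind, out)
}
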