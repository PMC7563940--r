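# The two-examinations-in, prognosis-out application contract: estimate the
# growth rate from paired measurements, place the tumor in a subtype band,
# and emit the prognosis category, earliest-manifestation time and a
# personalized surveillance plan.

t_stage_from_diameter <- function(d) {
  if (d <= 1) NA_character_
  else if (d <= 5) "T1a"
  else if (d <= 10) "T1b"
  else if (d <= 20) "T1c"
  else if (d <= 50) "T2"
  else "T3"
}

#' A patient record: two dated measurements plus receptor status
#'
#' @param patient_id identifier (character scalar).
#' @param first_exam,second_exam [tumor_measurement()] objects; the second
#'   must be later. The second examination is taken as the pre-surgery
#'   measurement: its diameter is the PT size at resection.
#' @param receptor_status optional [receptor_status()]; used as a cross-check
#'   against the kinetic band.
#' @param stage_t optional T category (`"T1a"`..`"T3"`); derived from the
#'   second diameter when absent, validated against it when present.
#' @return An object of class `bcmets_patient_record`.
#' @export
patient_record <- function(patient_id, first_exam, second_exam,
                           receptor_status = NULL, stage_t = NULL) {
  stopifnot(inherits(first_exam, "bcmets_measurement"),
            inherits(second_exam, "bcmets_measurement"))
  if (!is.null(receptor_status))
    stopifnot(inherits(receptor_status, "bcmets_receptor_status"))
  if (second_exam$exam_date <= first_exam$exam_date)
    stop_bcmets("second examination must be after the first", "bcmets_domain_error")
  derived <- t_stage_from_diameter(second_exam$diameter)
  if (is.null(stage_t)) {
    stage_t <- derived
  } else {
    stage_t <- match.arg(stage_t, c("T1a", "T1b", "T1c", "T2", "T3"))
    if (!identical(stage_t, derived))
      stop_bcmets(
        sprintf("stage %s inconsistent with diameter %g mm (expected %s)",
                stage_t, second_exam$diameter, derived),
        "bcmets_domain_error"
      )
  }
  structure(
    list(patient_id = as.character(patient_id),
         first_exam = first_exam, second_exam = second_exam,
         receptor_status = receptor_status, stage_t = stage_t),
    class = "bcmets_patient_record"
  )
}

#' Run the full prognosis for one patient record
#'
#' Estimates the TVDT from the two measurements, assigns the subtype band
#' from the measured kinetics (receptor-based classification, when available,
#' is a cross-check: a mismatch is a warning, or an error in strict mode),
#' and derives the prognosis category (band I favorable, II-IV mid-favorable,
#' V unfavorable), the earliest possible manifestation time (the rapid-band
#' earliest-scenario MTS-II latency) and the surveillance plan with its
#' considered-healthy horizon.
#'
#' @param record a [patient_record()].
#' @param registry a [subtype_registry()].
#' @param constants a [model_constants()].
#' @param strict error (rather than warn) on kinetic/receptor band mismatch.
#' @param surgery_date resection date; defaults to the second examination
#'   date (the pre-surgery measurement).
#' @param interval_source,mode passed to [build_plan()] /
#'   [diagnostic_column()].
#' @return An object of class `bcmets_prognosis_report`.
#' @examples
#' rec <- patient_record("p1",
#'   tumor_measurement("2020-01-06", 8.0),
#'   tumor_measurement("2020-09-04", 15.1),
#'   receptor_status("-", "-", "-", 30))
#' run_prognosis(rec)$prognosis_category # "unfavorable" (triple-negative)
#' @export
run_prognosis <- function(record, registry = subtype_registry(),
                          constants = model_constants(), strict = FALSE,
                          surgery_date = NULL,
                          interval_source = c("table", "narrative"),
                          mode = c("unrounded", "printed-parity")) {
  stopifnot(inherits(record, "bcmets_patient_record"))
  interval_source <- match.arg(interval_source)
  mode <- match.arg(mode)
  rate <- tvdt_from_measurements(record$first_exam, record$second_exam)
  band <- band_for_tvdt(rate, registry)
  mismatch <- NULL
  if (!is.null(record$receptor_status)) {
    rec_band <- suppressWarnings(classify(record$receptor_status, registry))
    if (!identical(rec_band$band_id, band$band_id)) {
      mismatch <- sprintf(
        "measured TVDT %.1f d places the tumor in band %s but receptor status suggests band %s; the kinetic band drives the schedule",
        rate$tvdt_days, band$band_id, rec_band$band_id)
      if (strict) stop_bcmets(mismatch, "bcmets_band_mismatch")
      warning(mismatch, call. = FALSE)
    }
  }
  d_pt <- record$second_exam$diameter
  column <- diagnostic_column(band$band_id, d_pt, registry, constants, mode)
  surgery_date <- surgery_date %||% record$second_exam$exam_date
  plan <- build_plan(column, surgery_date, interval_source, registry = registry)
  rapid <- registry$bands[[column$windows$band_id[1]]]
  earliest_mts2 <- periods_at(d_pt, rapid$tvdt_mts_range[1], "earliest", constants)$mts2_years
  structure(
    list(
      patient_id = record$patient_id,
      tvdt_pt_days = rate$tvdt_days,
      beyond_bands = isTRUE(attr(band, "out_of_band")),
      subtype_band = band$band_id,
      subtype_label = band$label,
      prognosis_category = band$prognosis_app_label,
      months_to_earliest_manifestation = earliest_mts2 * 12,
      healthy_after_years = column$total_diagnosis_years,
      band_mismatch = mismatch,
      stage_t = record$stage_t,
      column = column,
      plan = plan,
      constants = constants
    ),
    class = "bcmets_prognosis_report"
  )
}

#' @export
print.bcmets_prognosis_report <- function(x, ...) {
  cat(sprintf("Prognosis for %s (stage %s)\n", x$patient_id, x$stage_t))
  cat(sprintf("  TVDT_PT: %.1f days -> band %s (%s)%s\n", x$tvdt_pt_days,
              x$subtype_band, x$subtype_label,
              if (x$beyond_bands) " [beyond subtype bands]" else ""))
  cat(sprintf("  prognosis: %s\n", x$prognosis_category))
  cat(sprintf("  earliest manifestation: %.1f months after surgery\n",
              x$months_to_earliest_manifestation))
  cat(sprintf("  considered healthy after %.2f years\n",
              round_half_up(x$healthy_after_years)))
  if (!is.null(x$band_mismatch)) cat("  note:", x$band_mismatch, "\n")
  invisible(x)
}

record_csv_header <- c("patient_id", "date1", "d1_mm", "date2", "d2_mm",
                       "er", "pr", "her2", "ki67")

parse_record_row <- function(row) {
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (length(v) != 1 || is.na(v))
      stop_bcmets(sprintf("%s is not a number: '%s'", what, x), "bcmets_bad_input")
    v
  }
  m1 <- tumor_measurement(row$date1, num(row$d1_mm, "d1_mm"))
  m2 <- tumor_measurement(row$date2, num(row$d2_mm, "d2_mm"))
  if (m2$diameter <= m1$diameter)
    stop_bcmets("diameter did not increase between examinations", "bcmets_domain_error")
  status <- NULL
  has <- function(x) !is.null(x) && !is.na(x) && nzchar(as.character(x))
  if (has(row$her2) && (has(row$er) || has(row$pr))) {
    status <- receptor_status(
      er = if (has(row$er)) row$er else "unknown",
      pr = if (has(row$pr)) row$pr else "unknown",
      her2 = row$her2,
      ki67_percent = num(row$ki67, "ki67")
    )
  }
  patient_record(row$patient_id, m1, m2, status)
}

#' Read patient records from CSV or JSON
#'
#' CSV columns: `patient_id,date1,d1_mm,date2,d2_mm,er,pr,her2,ki67`
#' (ISO-8601 dates, mm with dot decimal, receptor columns `+`/`-`/empty).
#' JSON: an array of objects with the same fields. Malformed rows are
#' collected -- with their line number and the reason -- in the `errors`
#' attribute of the result; valid rows are still returned.
#'
#' @param path input file.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return list of [patient_record()] objects with attribute `errors`
#'   (data.frame `line`, `patient_id`, `reason`).
#' @export
read_patient_records <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  raw <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", check.names = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(record_csv_header, names(raw))
  if (length(missing_cols))
    stop_bcmets(paste("input is missing columns:", paste(missing_cols, collapse = ", ")),
                "bcmets_bad_input")
  records <- list()
  errors <- list()
  for (i in seq_len(nrow(raw))) {
    res <- tryCatch(parse_record_row(as.list(raw[i, ])), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        line = i + 1L, # header is line 1
        patient_id = as.character(raw$patient_id[i]),
        reason = conditionMessage(res)
      )
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  attr(records, "errors") <- if (length(errors)) do.call(rbind, errors)
                             else data.frame(line = integer(), patient_id = character(),
                                             reason = character())
  records
}

#' Write patient records to CSV
#'
#' Inverse of [read_patient_records()]: the write-read round trip is
#' lossless.
#'
#' @param records list of [patient_record()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_records <- function(records, path) {
  rows <- lapply(records, function(r) {
    s <- r$receptor_status
    data.frame(
      patient_id = r$patient_id,
      date1 = format(r$first_exam$exam_date), d1_mm = r$first_exam$diameter,
      date2 = format(r$second_exam$exam_date), d2_mm = r$second_exam$diameter,
      er = if (is.null(s)) "" else s$er,
      pr = if (is.null(s)) "" else s$pr,
      her2 = if (is.null(s)) "" else s$her2,
      ki67 = if (is.null(s)) "" else s$ki67_percent
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

report_to_list <- function(report) {
  plan <- report$plan
  list(
    patient_id = report$patient_id,
    stage_t = report$stage_t,
    tvdt_pt_days = report$tvdt_pt_days,
    subtype_band = report$subtype_band,
    subtype_label = report$subtype_label,
    prognosis_category = report$prognosis_category,
    months_to_earliest_manifestation = report$months_to_earliest_manifestation,
    healthy_after_years = report$healthy_after_years,
    band_mismatch = report$band_mismatch,
    # constants embedded so any report can be audited against the model
    constants = unclass(report$constants),
    plan = list(
      surgery_date = if (is.null(plan$surgery_date)) NULL else format(plan$surgery_date),
      healthy_date = if (is.null(plan$healthy_date)) NULL else format(plan$healthy_date),
      entries = lapply(plan$entries, function(e) list(
        band_id = e$band_id,
        window_start_years = e$window_start,
        window_end_years = e$window_end,
        interval_months = e$interval_months,
        exam_dates = if (is.null(e$exam_dates)) NULL else format(e$exam_dates)
      ))
    )
  )
}

#' Write a prognosis report (or a list of them) as JSON
#'
#' Deterministic: identical record and configuration give byte-identical
#' output (no timestamps are embedded).
#'
#' @param report a `bcmets_prognosis_report` or a list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_prognosis_report <- function(report, path) {
  x <- if (inherits(report, "bcmets_prognosis_report")) report_to_list(report)
       else lapply(report, report_to_list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
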