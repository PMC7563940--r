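# Personalized surveillance calendars: one examination block per diagnostic
# window, stepped at the band's recommended interval, ending at the
# considered-healthy horizon.

#' Build a surveillance plan from a diagnostic column
#'
#' One schedule entry per band window. The first (rapid) entry starts at the
#' rapid window's MTS-II low — before that no metastasis can have reached the
#' detection threshold — and each later entry starts where the previous one
#' ends, so the plan is gap-free up to the considered-healthy horizon.
#' Within an entry, examinations step by the band's interval from the window
#' start; an exam is always scheduled at the window start and the last exam
#' is the first one at or past the window end (conservative coverage).
#'
#' @param column a [diagnostic_column()].
#' @param surgery_date date of PT resection; if `NULL` the plan is
#'   relative-time only (no calendar dates).
#' @param interval_source `"table"` or `"narrative"`, see
#'   [screening_interval()]. The plan uses the intervals stored in the
#'   column's windows when `"table"`; `"narrative"` swaps band I's 12 months
#'   for 9.
#' @param stepping `"calendar"` (whole-month date arithmetic, clamped to
#'   month end) or `"exact-day"` (interval x 30.44 days).
#' @param registry registry used to resolve narrative intervals.
#' @return An object of class `bcmets_plan`: list with `surgery_date`,
#'   `entries` (list of schedule entries), `healthy_after_years`,
#'   `healthy_date`.
#' @examples
#' plan <- build_plan(diagnostic_column("V"), surgery_date = "2020-08-19")
#' plan$healthy_after_years # 10.65 (prints 10.64 under parity chaining)
#' @export
build_plan <- function(column, surgery_date = NULL,
                       interval_source = c("table", "narrative"),
                       stepping = c("calendar", "exact-day"),
                       registry = subtype_registry()) {
  stopifnot(inherits(column, "bcmets_diagnostic_column"))
  interval_source <- match.arg(interval_source)
  stepping <- match.arg(stepping)
  if (!is.null(surgery_date)) surgery_date <- as.Date(surgery_date)
  cst <- column$constants
  w <- column$windows
  entries <- list()
  start <- w$mts2_low[1]
  for (k in seq_len(nrow(w))) {
    interval <- w$screening_interval_months[k]
    if (interval_source == "narrative") {
      # narrative recommendation differs only where the registry says so
      bid <- sub("\\(\\+\\)$", "", w$band_id[k])
      if (bid %in% names(registry$bands))
        interval <- screening_interval(registry$bands[[bid]], "narrative")
      else if (w$is_plus_row[k]) {
        # plus row inherits its block's (next slower band's) interval
        blk <- Filter(function(b) b$screening_interval_months == interval,
                      registry$bands)
        if (length(blk)) interval <- screening_interval(blk[[1]], "narrative")
      }
    }
    end <- start + w$diagnosis_period_years[k]
    dur_months <- (end - start) * 12
    n_steps <- if (dur_months <= 0) 0L else ceiling(dur_months / interval - 1e-9)
    offsets <- seq(0L, n_steps) * interval
    exam_dates <- NULL
    if (!is.null(surgery_date)) {
      first_exam <- surgery_date + round(start * cst$days_per_year)
      exam_dates <- if (stepping == "calendar") {
        do.call(c, lapply(offsets, function(m) add_months(first_exam, as.integer(m))))
      } else {
        first_exam + round(offsets * 30.44)
      }
    }
    entries[[k]] <- list(
      band_id = w$band_id[k],
      window_start = start, window_end = end,
      interval_months = as.integer(interval),
      exam_offsets_months = offsets,
      exam_dates = exam_dates
    )
    start <- end
  }
  healthy_after <- column$total_diagnosis_years
  structure(
    list(
      surgery_date = surgery_date,
      entries = entries,
      healthy_after_years = healthy_after,
      healthy_date = if (is.null(surgery_date)) NULL
                     else surgery_date + round(healthy_after * cst$days_per_year),
      subtype = column$subtype
    ),
    class = "bcmets_plan"
  )
}

#' Total number of scheduled examinations in a plan
#'
#' @param plan a [build_plan()] result.
#' @return integer exam count (deterministic given the plan).
#' @export
exam_count <- function(plan) {
  stopifnot(inherits(plan, "bcmets_plan"))
  sum(vapply(plan$entries, function(e) length(e$exam_offsets_months), 0L))
}

#' @export
print.bcmets_plan <- function(x, ...) {
  cat(sprintf("Surveillance plan (PT subtype %s)%s\n", x$subtype,
              if (is.null(x$surgery_date)) " [relative time]"
              else paste0(", surgery ", format(x$surgery_date))))
  for (e in x$entries) {
    cat(sprintf("  %-7s %5.2f-%5.2f y post-surgery, every %d mo (%d exams)\n",
                e$band_id, round_half_up(e$window_start), round_half_up(e$window_end),
                e$interval_months, length(e$exam_offsets_months)))
  }
  cat(sprintf("  considered healthy after %.2f y%s\n",
              round_half_up(x$healthy_after_years),
              if (is.null(x$healthy_date)) "" else paste0(" (", format(x$healthy_date), ")")))
  invisible(x)
}

#' Examination list of a plan as a data.frame
#'
#' @param plan a [build_plan()] result.
#' @return data.frame with `band_id`, `exam_number`, `offset_months` (from
#'   the entry's window start) and, when the plan is anchored to a surgery
#'   date, `exam_date`.
#' @export
plan_exams <- function(plan) {
  stopifnot(inherits(plan, "bcmets_plan"))
  rows <- lapply(plan$entries, function(e) {
    d <- data.frame(
      band_id = e$band_id,
      exam_number = seq_along(e$exam_offsets_months),
      window_start_years = e$window_start,
      offset_months = e$exam_offsets_months
    )
    if (!is.null(e$exam_dates)) d$exam_date <- e$exam_dates
    d
  })
  do.call(rbind, rows)
}

#' Export a plan as an iCalendar file
#'
#' Writes one all-day VEVENT per scheduled examination (RFC 5545). Requires
#' a plan anchored to a surgery date.
#'
#' @param plan a [build_plan()] result with calendar dates.
#' @param path output `.ics` path.
#' @return `path`, invisibly.
#' @export
write_ical <- function(plan, path) {
  stopifnot(inherits(plan, "bcmets_plan"))
  if (is.null(plan$surgery_date))
    stop_bcmets("plan has no surgery date; cannot export calendar dates",
                "bcmets_domain_error")
  stamp <- "19700101T000000Z" # fixed DTSTAMP keeps output byte-reproducible
  lines <- c("BEGIN:VCALENDAR", "VERSION:2.0", "PRODID:-//bcmets//surveillance//EN")
  for (e in plan$entries) {
    for (i in seq_along(e$exam_dates)) {
      d <- format(e$exam_dates[i], "%Y%m%d")
      lines <- c(
        lines,
        "BEGIN:VEVENT",
        sprintf("UID:bcmets-%s-%s-%d", plan$subtype, gsub("[^A-Za-z0-9]", "", e$band_id), i),
        sprintf("DTSTAMP:%s", stamp),
        sprintf("DTSTART;VALUE=DATE:%s", d),
        sprintf("SUMMARY:Multimodal examination (band %s, every %d months)",
                e$band_id, e$interval_months),
        "END:VEVENT"
      )
    }
  }
  lines <- c(lines, "END:VCALENDAR")
  writeLines(lines, path, sep = "\r\n")
  invisible(path)
}
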