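# The five ER/PR/HER2/Ki-67 subtype groups and their TVDT bands.
#
# Band definitions ship as a YAML config (inst/extdata/subtype_bands.yaml) so
# a run can override them; the loader validates the partition of [10, 270].

#' Receptor and proliferation status of a tumor
#'
#' @param er,pr estrogen / progesterone receptor status: `"+"`, `"-"` or
#'   `"unknown"`. Hormone-receptor (HR) positivity is derived: HR+ if either
#'   ER or PR is positive.
#' @param her2 HER2 status, `"+"` or `"-"` (must be known).
#' @param ki67_percent Ki-67 labelling index, percent in \[0, 100\].
#' @return An object of class `bcmets_receptor_status`.
#' @examples
#' receptor_status("+", "-", "-", 10) # HR+/HER2-, low Ki-67 -> luminal A
#' @export
receptor_status <- function(er = "unknown", pr = "unknown", her2, ki67_percent) {
  tri <- function(x, what) {
    x <- as.character(x)
    if (!x %in% c("+", "-", "unknown"))
      stop_bcmets(sprintf("%s must be '+', '-' or 'unknown'", what), "bcmets_domain_error")
    x
  }
  er <- tri(er, "er"); pr <- tri(pr, "pr")
  her2 <- as.character(her2)
  if (!her2 %in% c("+", "-"))
    stop_bcmets("her2 must be '+' or '-'", "bcmets_domain_error")
  if (!is.numeric(ki67_percent) || length(ki67_percent) != 1 ||
      is.na(ki67_percent) || ki67_percent < 0 || ki67_percent > 100)
    stop_bcmets("ki67_percent must be a number in [0, 100]", "bcmets_domain_error")
  if (er == "unknown" && pr == "unknown")
    stop_bcmets("at least one of er/pr must be known", "bcmets_domain_error")
  structure(
    list(er = er, pr = pr, her2 = her2, ki67_percent = ki67_percent,
         hr_positive = er == "+" || pr == "+"),
    class = "bcmets_receptor_status"
  )
}

new_band <- function(b) {
  b$band_id <- as.character(b$band_id)
  structure(b, class = "bcmets_band")
}

#' @export
print.bcmets_band <- function(x, ...) {
  cat(sprintf("Subtype band %s: %s (%s)\n", x$band_id, x$label, x$receptor_rule))
  cat(sprintf("  growth class: %s; TVDT %g-%g d; screening every %d mo; prognosis %s\n",
              x$growth_class, x$tvdt_mts_range[1], x$tvdt_mts_range[2],
              x$screening_interval_months, x$prognosis_table_label))
  invisible(x)
}

#' Load the subtype-band registry
#'
#' Reads band definitions (five ER/PR/HER2/Ki-67 groups with TVDT ranges,
#' prognosis labels and screening intervals) and the per-subtype column
#' structure from a YAML config. The default config shipped with the package
#' encodes the standard five-group partition of TVDT \[10, 270\] days:
#' triple-negative (V, rapid, 10-135 d), HER2-positive (IV, 136-165),
#' luminal B HER2- (III, 166-195), luminal B HER2+ (II, 196-230) and
#' luminal A (I, very slow, 231-270).
#'
#' @param path path to a YAML registry config; default: the packaged config.
#' @return An object of class `bcmets_registry`: a list with `bands` (named
#'   list of `bcmets_band`, fastest first) and `columns` (per-subtype window
#'   structure used by [diagnostic_column()]).
#' @export
subtype_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "subtype_bands.yaml", package = "bcmets")
  cfg <- yaml::read_yaml(path)
  bands <- lapply(cfg$bands, function(b) {
    b$tvdt_pt_range <- as.numeric(b$tvdt_pt_range)
    b$tvdt_mts_range <- as.numeric(b$tvdt_mts_range)
    b$tvdt_pt_display_range <- as.numeric(b$tvdt_pt_display_range %||% b$tvdt_pt_range)
    b$mean_tvdt_mts_range <- as.numeric(b$mean_tvdt_mts_range)
    b$screening_interval_months <- as.integer(b$screening_interval_months)
    b$screening_interval_months_narrative <-
      as.integer(b$screening_interval_months_narrative %||% b$screening_interval_months)
    new_band(b)
  })
  names(bands) <- vapply(bands, `[[`, "", "band_id")
  reg <- structure(list(bands = bands, columns = cfg$columns), class = "bcmets_registry")
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  bands <- reg$bands
  if (!setequal(names(bands), c("I", "II", "III", "IV", "V")))
    stop_bcmets("registry must define bands I..V", "bcmets_config_error")
  # bands ordered fastest (shortest TVDT) first must tile [10, 270] on
  # integer days with no overlap or gap
  ord <- order(vapply(bands, function(b) b$tvdt_mts_range[1], 0))
  rngs <- lapply(bands[ord], `[[`, "tvdt_mts_range")
  if (rngs[[1]][1] != 10 || rngs[[length(rngs)]][2] != 270)
    stop_bcmets("band TVDT ranges must span [10, 270] days", "bcmets_config_error")
  for (k in seq_len(length(rngs) - 1)) {
    if (rngs[[k + 1]][1] != rngs[[k]][2] + 1)
      stop_bcmets("band TVDT ranges must partition [10, 270] without gap or overlap",
                  "bcmets_config_error")
  }
  invisible(reg)
}

#' @export
print.bcmets_registry <- function(x, ...) {
  cat("Subtype-band registry (", length(x$bands), " bands)\n", sep = "")
  for (b in x$bands) print(b)
  invisible(x)
}

#' Classify a tumor into a subtype band from receptor status
#'
#' Standard surrogate molecular classification: HR+/HER2- with Ki-67 < 14%
#' is luminal A (band I); HR+/HER2+ is luminal B HER2+ (II); HR+/HER2- with
#' Ki-67 >= 14% is luminal B HER2- (III); HR-/HER2+ is HER2-positive (IV);
#' HR-/HER2- is triple-negative (V). Triple-negative with Ki-67 < 14% is an
#' unusual combination; it still maps to band V, with a warning.
#'
#' @param status a [receptor_status()].
#' @param registry a [subtype_registry()].
#' @return The matching `bcmets_band`.
#' @examples
#' classify(receptor_status("+", "+", "-", 10)) # band I, luminal A
#' @export
classify <- function(status, registry = subtype_registry()) {
  stopifnot(inherits(status, "bcmets_receptor_status"))
  hi_ki67 <- status$ki67_percent >= 14
  id <-
    if (status$hr_positive) {
      if (status$her2 == "+") "II" else if (hi_ki67) "III" else "I"
    } else {
      if (status$her2 == "+") "IV" else "V"
    }
  if (id == "V" && !hi_ki67)
    warning("triple-negative tumor with Ki-67 < 14%: classified as band V (rapid), ",
            "but the band definition expects Ki-67 >= 14%", call. = FALSE)
  registry$bands[[id]]
}

#' Find the subtype band containing a measured TVDT
#'
#' The printed band edges are integer days, treated as closed intervals; a
#' real-valued TVDT is rounded to the nearest day before lookup. TVDTs in
#' (270, 310] fall beyond the slowest band and are assigned band I with an
#' `out_of_band` attribute.
#'
#' @param rate a [growth_rate()] or a plain TVDT in days.
#' @param registry a [subtype_registry()].
#' @return The matching `bcmets_band`; attribute `out_of_band` is TRUE for
#'   TVDTs above 270 d.
#' @examples
#' band_for_tvdt(88)$band_id # "V": rapid, triple-negative range
#' @export
band_for_tvdt <- function(rate, registry = subtype_registry()) {
  tvdt <- as_tvdt_days(rate)
  if (tvdt < 10)
    stop_bcmets("TVDT below 10 days is outside the model", "bcmets_out_of_model")
  day <- round(tvdt)
  if (day > 270) {
    if (tvdt > 310)
      stop_bcmets("TVDT above 310 days is outside the model", "bcmets_out_of_model")
    band <- registry$bands[["I"]]
    attr(band, "out_of_band") <- TRUE
    return(band)
  }
  for (b in registry$bands) {
    if (day >= b$tvdt_mts_range[1] && day <= b$tvdt_mts_range[2]) {
      attr(b, "out_of_band") <- FALSE
      return(b)
    }
  }
  stop_bcmets("no band contains the TVDT; registry is mis-configured", "bcmets_config_error")
}

#' Recommended multimodal-examination interval for a band
#'
#' Two published sources disagree for the slowest band: the tabulated
#' screening times give 12 months for band I while the narrative
#' recommendation is every nine months. Both are exposed; `"table"` is the
#' default.
#'
#' @param band a `bcmets_band`.
#' @param source `"table"` (default) or `"narrative"`.
#' @return interval in months (integer).
#' @export
screening_interval <- function(band, source = c("table", "narrative")) {
  source <- match.arg(source)
  stopifnot(inherits(band, "bcmets_band"))
  if (source == "table") band$screening_interval_months
  else band$screening_interval_months_narrative
}
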