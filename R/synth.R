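# Synthetic patient-record generator: exponential growth between two exam
# dates with multiplicative measurement noise. Makes the whole pipeline
# testable end-to-end (TVDT recovery, band classification, report I/O)
# without any clinical data.

ki67_range_for_band <- list(
  I = c(3, 13), II = c(14, 60), III = c(14, 60), IV = c(14, 90), V = c(14, 95)
)

receptor_for_band <- function(band_id, ki67) {
  switch(band_id,
    I = receptor_status("+", "+", "-", ki67),
    II = receptor_status("+", "+", "+", ki67),
    III = receptor_status("+", "-", "-", ki67),
    IV = receptor_status("-", "-", "+", ki67),
    V = receptor_status("-", "-", "-", ki67)
  )
}

#' Generate synthetic patient records
#'
#' Each record draws a subtype band uniformly, a PT TVDT uniformly within the
#' band's range, an initial diameter uniform on 5-15 mm and an
#' inter-examination gap uniform on 60-365 days; the second diameter is the
#' exponential-growth prediction times lognormal measurement noise
#' (`sigma` on the log scale, default 0.05 -- multiplicative error typical of
#' caliper/ultrasound sizing). Receptor status is drawn consistent with the
#' band. Output is reproducible under a fixed seed and leaves the caller's
#' RNG state untouched.
#'
#' @param n number of records (>= 1).
#' @param seed integer RNG seed.
#' @param registry a [subtype_registry()].
#' @param constants a [model_constants()].
#' @param sigma lognormal noise standard deviation on the diameter
#'   (0 = noiseless).
#' @param start_date first-exam dates are drawn within a year of this date.
#' @return list of [patient_record()] objects with attribute `truth`:
#'   data.frame of the drawn `band_id`, `tvdt_days`, `gap_days`, `d1_mm`,
#'   `d2_true_mm` per record.
#' @examples
#' recs <- synth_generate(3, seed = 1)
#' attr(recs, "truth")$band_id
#' @export
synth_generate <- function(n, seed, registry = subtype_registry(),
                           constants = model_constants(), sigma = 0.05,
                           start_date = "2019-01-01") {
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  start_date <- as.Date(start_date)
  band_ids <- names(registry$bands)
  records <- vector("list", n)
  truth <- data.frame(band_id = character(n), tvdt_days = numeric(n),
                      gap_days = numeric(n), d1_mm = numeric(n),
                      d2_true_mm = numeric(n))
  for (i in seq_len(n)) {
    bid <- sample(band_ids, 1)
    b <- registry$bands[[bid]]
    tvdt <- stats::runif(1, b$tvdt_pt_range[1], b$tvdt_pt_range[2])
    d1 <- stats::runif(1, 5, 15)
    gap <- round(stats::runif(1, 60, 365))
    d2_true <- grow(d1, tvdt, gap)
    noise <- if (sigma > 0) stats::rlnorm(1, 0, sigma) else 1
    d2 <- d2_true * noise
    kr <- ki67_range_for_band[[bid]]
    ki67 <- stats::runif(1, kr[1], kr[2])
    date1 <- start_date + sample.int(365, 1) - 1L
    records[[i]] <- patient_record(
      sprintf("synth-%04d", i),
      tumor_measurement(date1, d1),
      tumor_measurement(date1 + gap, d2),
      receptor_for_band(bid, ki67)
    )
    truth$band_id[i] <- bid
    truth$tvdt_days[i] <- tvdt
    truth$gap_days[i] <- gap
    truth$d1_mm[i] <- d1
    truth$d2_true_mm[i] <- d2_true
  }
  attr(records, "truth") <- truth
  records
}
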