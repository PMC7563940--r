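# Shared fixtures: one registry/constants instance per test run, and the
# day-stepped brute-force oracle used to cross-check closed-form periods.

reg <- subtype_registry()
cst <- model_constants()

# Brute-force threshold-crossing time: evaluate the growth trajectory on a
# one-day grid and find the first day the lesion reaches the target
# diameter. Independent of the closed-form doubling-count arithmetic it
# cross-checks.
days_to_reach_bruteforce <- function(d0, target, tvdt_days) {
  tmax <- ceiling(3 * tvdt_days * log2(target / d0)) + 10
  traj <- grow(d0, tvdt_days, 0:tmax)
  which(traj >= target)[1] - 1
}

# A five-record CSV spanning all bands, written fresh for IO tests.
write_example_csv <- function(path) {
  file.copy(system.file("extdata", "example_patients.csv", package = "bcmets"),
            path, overwrite = TRUE)
  path
}
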