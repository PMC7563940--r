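test_that("doubling count from diameter matches the sphere-from-one-cell law", {
  # 15.1 mm PT has undergone ~31.7 volume doublings
  expect_equal(round_half_up(doublings_from_diameter(15.1, cst), 1), 31.7)
  expect_equal(doublings_from_diameter(0.01, cst), 0)
  # doubling the diameter multiplies volume by 8: exactly 3 doublings
  expect_equal(doublings_from_diameter(0.02, cst), 3)
  expect_equal(doublings_from_diameter(9.0, cst), 3 * log2(900), tolerance = 1e-12)
  expect_error(doublings_from_diameter(0.005, cst), class = "bcmets_domain_error")
})

test_that("diameter/doublings are exact inverses and doubling adds 3", {
  expect_equal(diameter_from_doublings(0, cst), 0.01)
  expect_equal(diameter_from_doublings(40, cst), 0.01 * 2^(40 / 3), tolerance = 1e-12)
  for (d in c(0.05, 1, 9, 15.1, 50)) {
    expect_equal(diameter_from_doublings(doublings_from_diameter(d, cst), cst), d,
                 tolerance = 1e-12)
    expect_equal(doublings_from_diameter(2 * d, cst) - doublings_from_diameter(d, cst),
                 3, tolerance = 1e-12)
  }
  expect_error(diameter_from_doublings(-1, cst), class = "bcmets_domain_error")
  # strictly increasing
  ds <- sort(runif(50, 0.02, 100))
  expect_true(all(diff(doublings_from_diameter(ds, cst)) > 0))
})

test_that("cell count is 2^n", {
  expect_equal(cell_count_from_doublings(0), 1)
  expect_equal(cell_count_from_doublings(10), 1024)
  expect_equal(cell_count_from_doublings(40), 2^40)
  expect_error(cell_count_from_doublings(-2), class = "bcmets_domain_error")
})

test_that("exponential growth law doubles volume every TVDT", {
  # 3 volume doublings in 90 d at TVDT 30 -> diameter doubles
  expect_equal(grow(1, growth_rate(30), 90), 2, tolerance = 1e-12)
  expect_equal(grow(7.3, growth_rate(100), 0), 7.3)
  # 1 mm seeding size grows to the 15.1 mm surgical size in
  # (N_pt - N_seed) * TVDT = 11.7495 * 135 = 1586.2 days
  n_span <- doublings_from_diameter(15.1, cst) - doublings_from_diameter(1, cst)
  expect_equal(grow(1, growth_rate(135), n_span * 135), 15.1, tolerance = 1e-9)
})

test_that("duration is doublings times TVDT and converts to years", {
  expect_equal(duration_days(19.932, growth_rate(10)), 199.32)
  expect_equal(duration_days(0, growth_rate(77)), 0)
  expect_equal(round_half_up(years(duration_days(19.932, growth_rate(10)), cst)), 0.55)
  expect_equal(round_half_up(years(duration_days(10.559, growth_rate(135)), cst)), 3.90)
  expect_equal(years(365.25, cst), 1)
  expect_equal(round_half_up(years(2397.5, cst)), 6.56)
  # linear in both arguments
  expect_equal(duration_days(3 * 1.7, growth_rate(50)), 3 * duration_days(1.7, growth_rate(50)))
  expect_equal(duration_days(1.7, growth_rate(100)), 2 * duration_days(1.7, growth_rate(50)))
})

test_that("TVDT estimator inverts the growth law", {
  m1 <- tumor_measurement("2020-01-01", 1)
  m2 <- tumor_measurement("2020-03-31", 2)
  expect_equal(tvdt_from_measurements(m1, m2)$tvdt_days, 30, tolerance = 1e-12)
  # the two-point estimate on any simulated trajectory recovers the rate
  set.seed(11)
  for (i in 1:50) {
    tvdt <- runif(1, 10, 270)
    d0 <- runif(1, 2, 12)
    dt <- round(runif(1, 40, 600))
    d1 <- grow(d0, growth_rate(tvdt), dt)
    est <- tvdt_from_measurements(
      tumor_measurement("2020-01-01", d0),
      tumor_measurement(as.Date("2020-01-01") + dt, d1)
    )
    expect_equal(est$tvdt_days, tvdt, tolerance = 1e-9)
  }
})

test_that("degenerate measurement pairs are estimation errors", {
  m1 <- tumor_measurement("2020-01-01", 10)
  expect_error(tvdt_from_measurements(m1, tumor_measurement("2020-02-01", 10)),
               class = "bcmets_estimation_error")
  expect_error(tvdt_from_measurements(m1, tumor_measurement("2020-02-01", 8)),
               class = "bcmets_estimation_error")
  expect_error(tvdt_from_measurements(m1, tumor_measurement("2020-01-01", 12)),
               class = "bcmets_estimation_error")
})

test_that("TVDT bounds are enforced with a beyond-band flag in (270, 310]", {
  expect_error(growth_rate(9), class = "bcmets_out_of_model")
  expect_error(growth_rate(311), class = "bcmets_out_of_model")
  expect_false(growth_rate(270)$beyond_bands)
  expect_true(growth_rate(290)$beyond_bands)
})

test_that("model constants validate their identities", {
  expect_error(model_constants(seeding_doubling_index = 21),
               class = "bcmets_domain_error")
  expect_error(model_constants(cell_diameter = 2), class = "bcmets_domain_error")
  expect_equal(cst$seeding_doubling_index + cst$lethal_doubling_count,
               cst$whole_history_doublings)
})
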