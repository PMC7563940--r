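test_that("rapid-band scenarios reproduce the published period set", {
  si <- scenario_inputs(15.1, reg$bands$V, cst)
  late <- latest_scenario(si)
  expect_equal(round_half_up(late$mts1_years), 4.34)
  expect_equal(round_half_up(late$mts2_years), 6.56)
  expect_equal(round_half_up(late$visible_years), 3.90)
  expect_equal(round_half_up(late$survival_years), 10.47)
  early <- earliest_scenario(si)
  expect_equal(round_half_up(early$mts1_years), 0.55)
  expect_equal(round_half_up(early$mts2_years), 0.26)
  expect_equal(round_half_up(early$visible_years), 0.29)
  expect_equal(round_half_up(early$survival_years), 0.55)
})

test_that("slower-band scenario cells match the published column values", {
  late_iv <- latest_scenario(scenario_inputs(15.1, reg$bands$IV, cst))
  expect_equal(round_half_up(late_iv$mts2_years), 8.02)
  expect_equal(round_half_up(late_iv$survival_years), 12.79)
  late_i <- latest_scenario(scenario_inputs(15.1, reg$bands$I, cst))
  expect_equal(round_half_up(late_i$mts1_years), 8.69)
  # earliest scenario at a slower band: lesion at 1 mm growing at the band
  # minimum, (N_det - N_seed) * 136 d
  early_iv <- earliest_scenario(scenario_inputs(15.1, reg$bands$IV, cst))
  expect_equal(round_half_up(early_iv$mts2_years), 3.54)
})

test_that("survival is exactly MTS-II plus visible in both scenarios", {
  for (b in reg$bands) {
    si <- scenario_inputs(15.1, b, cst)
    for (p in list(earliest_scenario(si), latest_scenario(si)))
      expect_identical(p$survival_years, p$mts2_years + p$visible_years)
  }
})

test_that("late-seeding window has the seeding-spread width", {
  w <- seeded_at_surgery_window(15.1, growth_rate(135), cst)
  expect_equal(round_half_up(w$mts2_low), 6.56)
  # high end: a single cell seeded at resection needs the full doubling
  # count to detection
  expect_equal(w$mts2_high,
               years(doublings_from_diameter(9, cst) * 135, cst), tolerance = 1e-12)
  expect_equal(round_half_up(w$width_years), 4.34)
  expect_equal(round_half_up(seeded_at_surgery_window(15.1, growth_rate(230), cst)$width_years),
               7.40)
})

test_that("whole-history identity telescopes to 60 doublings for any PT size", {
  set.seed(7)
  d_pts <- runif(100, 1.1, 80)
  expect_equal(whole_history_identity(d_pts, cst), rep(60, 100), tolerance = 1e-12)
  expect_equal(whole_history_identity(15.1, cst), 60)
})

test_that("periods are monotone in TVDT and PT size in the expected directions", {
  # every period scales linearly (hence strictly increases) with TVDT
  p_at <- function(T) latest_scenario(
    scenario_inputs(15.1, local({b <- reg$bands$V; b$tvdt_mts_range <- c(T, T); b}), cst))
  ts <- c(20, 60, 135, 200, 270)
  m1 <- vapply(ts, function(T) p_at(T)$mts1_years, 0)
  m2 <- vapply(ts, function(T) p_at(T)$mts2_years, 0)
  vis <- vapply(ts, function(T) p_at(T)$visible_years, 0)
  expect_true(all(diff(m1) > 0) && all(diff(m2) > 0) && all(diff(vis) > 0))
  # larger PT: longer pre-surgery seeding period, shorter residual latency
  d_pts <- c(5, 10, 15.1, 30)
  at_d <- lapply(d_pts, function(d) latest_scenario(scenario_inputs(d, reg$bands$V, cst)))
  expect_true(all(diff(vapply(at_d, `[[`, 0, "mts1_years")) > 0))
  expect_true(all(diff(vapply(at_d, `[[`, 0, "mts2_years")) < 0))
})

test_that("closed-form periods agree with a day-stepped simulation oracle", {
  set.seed(42)
  for (i in 1:100) {
    d_pt <- runif(1, 2, 40)
    tvdt <- runif(1, 10, 270)
    n_pt <- doublings_from_diameter(d_pt, cst)
    if (n_pt <= 20) next
    # lesion size at surgery under the latest scenario: N_pt - 20 doublings
    d_at_surgery <- diameter_from_doublings(n_pt - 20, cst)
    mts2_days <- (doublings_from_diameter(9, cst) - (n_pt - 20)) * tvdt
    vis_days <- (40 - doublings_from_diameter(9, cst)) * tvdt
    expect_lt(abs(days_to_reach_bruteforce(d_at_surgery, 9, tvdt) - mts2_days), 1)
    expect_lt(abs(days_to_reach_bruteforce(9, diameter_from_doublings(40, cst), tvdt)
                  - vis_days), 1)
  }
})

test_that("degenerate inputs raise domain errors", {
  expect_error(scenario_inputs(0.9, reg$bands$V, cst), class = "bcmets_domain_error")
  # PT below its 20th doubling has no seeded metastasis yet
  small <- scenario_inputs(1.01, reg$bands$V, cst)
  expect_error(latest_scenario(small), class = "bcmets_domain_error")
  expect_error(seeded_at_surgery_window(1.01, growth_rate(135), cst),
               class = "bcmets_domain_error")
})
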