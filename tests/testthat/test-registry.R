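test_that("receptor classification is total and single-valued", {
  # every combination of HR status x HER2 x Ki-67 side maps to exactly one band
  cases <- expand.grid(er = c("+", "-"), pr = c("+", "-"), her2 = c("+", "-"),
                       ki67 = c(5, 14, 40), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    s <- receptor_status(cases$er[i], cases$pr[i], cases$her2[i], cases$ki67[i])
    b <- suppressWarnings(classify(s, reg))
    expect_s3_class(b, "bcmets_band")
    hr <- cases$er[i] == "+" || cases$pr[i] == "+"
    expected <-
      if (hr && cases$her2[i] == "+") "II"
      else if (hr && cases$ki67[i] < 14) "I"
      else if (hr) "III"
      else if (cases$her2[i] == "+") "IV"
      else "V"
    expect_identical(b$band_id, expected)
  }
})

test_that("surrogate subtype rules match the standard definitions", {
  expect_identical(classify(receptor_status("+", "+", "-", 10), reg)$band_id, "I")
  expect_identical(classify(receptor_status("-", "-", "-", 30), reg)$band_id, "V")
  # Ki-67 boundary: 14 counts as >= 14
  expect_identical(classify(receptor_status("+", "-", "+", 14), reg)$band_id, "II")
  expect_identical(classify(receptor_status("+", "-", "-", 14), reg)$band_id, "III")
  # unknown single receptor still classifiable when the other is known
  expect_identical(classify(receptor_status("unknown", "+", "-", 10), reg)$band_id, "I")
  expect_error(receptor_status("unknown", "unknown", "-", 10),
               class = "bcmets_domain_error")
  # triple-negative with low Ki-67: still band V, with a warning
  expect_warning(b <- classify(receptor_status("-", "-", "-", 10), reg),
                 "Ki-67 < 14")
  expect_identical(b$band_id, "V")
})

test_that("TVDT-to-band lookup uses closed integer bands with no gaps", {
  expect_identical(band_for_tvdt(growth_rate(88), reg)$band_id, "V")
  expect_identical(band_for_tvdt(growth_rate(135), reg)$band_id, "V")
  expect_identical(band_for_tvdt(growth_rate(136), reg)$band_id, "IV")
  expect_identical(band_for_tvdt(growth_rate(165), reg)$band_id, "IV")
  expect_identical(band_for_tvdt(growth_rate(166), reg)$band_id, "III")
  expect_identical(band_for_tvdt(growth_rate(196), reg)$band_id, "II")
  expect_identical(band_for_tvdt(growth_rate(231), reg)$band_id, "I")
  expect_identical(band_for_tvdt(growth_rate(250), reg)$band_id, "I")
  # real-valued TVDTs round to the nearest day before lookup
  expect_identical(band_for_tvdt(growth_rate(135.4), reg)$band_id, "V")
  expect_identical(band_for_tvdt(growth_rate(135.6), reg)$band_id, "IV")
  # every integer day in [10, 270] lands in the band that contains it
  for (t in 10:270) {
    b <- band_for_tvdt(growth_rate(t), reg)
    expect_true(t >= b$tvdt_mts_range[1] && t <= b$tvdt_mts_range[2])
    expect_false(attr(b, "out_of_band"))
  }
})

test_that("TVDTs beyond the slowest band flag out-of-band instead of failing", {
  b <- band_for_tvdt(growth_rate(290), reg)
  expect_identical(b$band_id, "I")
  expect_true(attr(b, "out_of_band"))
  expect_error(band_for_tvdt(growth_rate(10) , reg), NA)
  expect_error(growth_rate(5), class = "bcmets_out_of_model")
})

test_that("screening intervals differ between table and narrative only for band I", {
  expect_equal(screening_interval(reg$bands$V, "table"), 3L)
  expect_equal(screening_interval(reg$bands$IV, "table"), 5L)
  expect_equal(screening_interval(reg$bands$III, "table"), 6L)
  expect_equal(screening_interval(reg$bands$II, "table"), 8L)
  expect_equal(screening_interval(reg$bands$I, "table"), 12L)
  expect_equal(screening_interval(reg$bands$I, "narrative"), 9L)
  for (id in c("II", "III", "IV", "V"))
    expect_equal(screening_interval(reg$bands[[id]], "narrative"),
                 screening_interval(reg$bands[[id]], "table"))
})

test_that("registry configs that break the TVDT partition are rejected", {
  bad <- yaml::read_yaml(system.file("extdata", "subtype_bands.yaml", package = "bcmets"))
  bad$bands[[2]]$tvdt_mts_range <- c(140, 165) # gap at 136-139
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f)
  expect_error(subtype_registry(f), class = "bcmets_config_error")
})
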