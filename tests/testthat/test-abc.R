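ladder <- c(5e3, 2e4, 8e4, 2.5e5)

test_that("exact power-law bead sets fit with unit slope and r = 1", {
  bs <- abc_bead_set(ladder, 3.2 * ladder, blank_median_intensity = 500)
  cal <- fit_abc_regression(bs)
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  expect_equal(cal$intercept, log10(3.2), tolerance = 1e-12)
  expect_equal(cal$r_coefficient, 1)
})

test_that("a two-population fit passes through both points", {
  bs <- abc_bead_set(c(1e3, 1e5), c(40, 9000), blank_median_intensity = 10)
  cal <- fit_abc_regression(bs)
  expect_equal(10^(cal$intercept + cal$slope * log10(1e3)), 40, tolerance = 1e-9)
  expect_equal(10^(cal$intercept + cal$slope * log10(1e5)), 9000, tolerance = 1e-9)
  expect_error(abc_bead_set(1e3, 40, 10), "at least 2")
  expect_error(abc_bead_set(c(1e3, 1e3), c(40, 50), 10), "increasing")
})

test_that("r stays above 0.99 under 3% multiplicative noise", {
  set.seed(401)
  noisy <- 2 * ladder * rlnorm(4, 0, sqrt(log(1 + 0.03^2)))
  cal <- fit_abc_regression(abc_bead_set(ladder, noisy, 100))
  expect_gt(cal$r_coefficient, 0.99)
})

test_that("the blank's ABC equivalent defines the limit of detection", {
  # blank generated exactly on the fitted curve at ABC 100
  bs <- abc_bead_set(ladder, 5 * ladder, blank_median_intensity = 5 * 100)
  cal <- fit_abc_regression(bs)
  lod <- lod_from_blank(cal, bs$blank_median_intensity)
  expect_equal(lod$lod, 100, tolerance = 1e-9)
  expect_true(lod$extrapolated)   # 100 sits below the 5e3 ladder floor
  on_range <- lod_from_blank(cal, 5 * 1e4)
  expect_false(on_range$extrapolated)
  expect_error(lod_from_blank(structure(list(slope = 0, intercept = 1,
                                             abc_range = c(1, 2)),
                                        class = "abc_calibration"), 10),
               "slope")
})

test_that("generative round trip recovers the blank ABC with k*SD option", {
  bs <- abc_bead_set(ladder, 5 * ladder, blank_median_intensity = 5 * 80,
                     blank_sd = 5 * 10)
  cal <- fit_abc_regression(bs)
  # median + 2 SD corresponds to intensity 5 * 100 -> ABC 100
  lod <- lod_from_blank(cal, bs$blank_median_intensity, k = 2,
                        blank_sd = bs$blank_sd)
  expect_equal(lod$lod, 100, tolerance = 1e-9)
})

test_that("intensity to ABC is the exact monotone inverse of the fit", {
  bs <- abc_bead_set(ladder, 7 * ladder, blank_median_intensity = 70)
  cal <- fit_abc_regression(bs)
  expect_equal(intensity_to_abc(7 * ladder, cal), ladder, tolerance = 1e-9)
  expect_true(all(diff(predict(cal, c(10, 100, 1000))) > 0))
  # log-midpoint intensity maps to the geometric mean of neighbouring ABCs
  mid <- sqrt((7 * ladder[1]) * (7 * ladder[2]))
  expect_equal(intensity_to_abc(mid, cal), sqrt(ladder[1] * ladder[2]),
               tolerance = 1e-9)
  expect_error(intensity_to_abc(-5, cal), "positive")
})

test_that("LoD ranking is invariant to common intensity rescaling", {
  set.seed(402)
  # five fluorophores with increasing blank autofluorescence -> increasing LoD
  blanks <- c(50, 120, 300, 800, 2000)
  sets <- lapply(seq_along(blanks), function(i)
    abc_bead_set(ladder, 4 * ladder, blank_median_intensity = 4 * blanks[i]))
  names(sets) <- paste0("FL", seq_along(blanks))
  tab <- abc_lod_table(sets)
  expect_equal(tab$fluorophore, paste0("FL", 1:5))
  expect_equal(tab$lod_abc, blanks, tolerance = 1e-9)
  # rescale every intensity (gains differ between machines): order unchanged
  sets2 <- lapply(sets, function(s)
    abc_bead_set(s$assigned_abc, s$median_intensity * 37,
                 s$blank_median_intensity * 37))
  names(sets2) <- names(sets)
  expect_equal(abc_lod_table(sets2)$fluorophore, tab$fluorophore)
  expect_equal(abc_lod_table(sets2)$lod_abc, tab$lod_abc, tolerance = 1e-9)
})

test_that("a simulated ABC ladder file round-trips through the regression", {
  tab <- generate_bead_file("abc_ladder", n_per_population = 3000, seed = 403)
  meds <- tapply(tab$CD9, tab$true_abc, median)
  blank <- meds[["0"]]
  pops <- meds[names(meds) != "0"]
  bs <- abc_bead_set(as.numeric(names(pops)), as.numeric(pops),
                     blank_median_intensity = blank)
  cal <- fit_abc_regression(bs)
  expect_gt(cal$r_coefficient, 0.999)
  expect_equal(cal$slope, 1, tolerance = 0.02)
  lod <- lod_from_blank(cal, blank)
  # blank is pure autofluorescence (median 50) with unit gain per antibody
  expect_equal(lod$lod, 50, tolerance = 0.15)
})
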