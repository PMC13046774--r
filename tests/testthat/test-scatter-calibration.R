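opt <- optical_config()
nist_d <- c(80, 101, 125, 151)

bead_sigma <- vapply(nist_d, function(d)
  effective_scattering_cross_section(polystyrene_bead(d), opt)$sigma_effective,
  numeric(1))

make_beads <- function(intensity) {
  bead_reference(as.character(nist_d), nist_d, median_intensity = intensity)
}

grid_coarse <- seq(30, 600, by = 2)

test_that("offset-only fit is exact on noise-free constructed intensities", {
  cal <- fit_scatter_calibration(make_beads(10^2.5 * bead_sigma), opt,
                                 grid = grid_coarse)
  expect_equal(unname(coef(cal)[["log_offset"]]), 2.5, tolerance = 1e-12)
  expect_lt(max(abs(cal$per_bead_residuals)), 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_false(any(cal$outlier))
})

test_that("offset is recovered within 2% under 5% multiplicative noise", {
  set.seed(101)
  noisy <- 10^2.5 * bead_sigma *
    rlnorm(length(bead_sigma), 0, sqrt(log(1 + 0.05^2)))
  cal <- fit_scatter_calibration(make_beads(noisy), opt, grid = grid_coarse)
  expect_equal(unname(coef(cal)[["log_offset"]]), 2.5, tolerance = 0.02)
})

test_that("a grossly miscalibrated bead is flagged as an outlier", {
  set.seed(102)
  intens <- 10^2.5 * bead_sigma *
    rlnorm(length(bead_sigma), 0, sqrt(log(1 + 0.02^2)))
  intens[2] <- intens[2] * 10
  cal <- fit_scatter_calibration(make_beads(intens), opt, grid = grid_coarse)
  expect_true(cal$outlier[["101"]])
  expect_false(any(cal$outlier[c("80", "125", "151")]))
  # the corrupted bead's residual dominates the well-behaved ones
  others <- cal$per_bead_residuals[c("80", "125", "151")]
  expect_gt(abs(cal$per_bead_residuals[["101"]]), max(abs(others)))
})

test_that("fit rejects degenerate bead sets", {
  expect_error(bead_reference("a", 100, median_intensity = -1), "positive")
  b <- make_beads(10^2.5 * bead_sigma)[1, ]
  expect_error(fit_scatter_calibration(b, opt), "at least 2")
  dup <- bead_reference(c("a", "b", "c"), c(100, 100, 150),
                        median_intensity = c(10, 20, 100))
  expect_warning(fit_scatter_calibration(dup, opt, grid = grid_coarse),
                 "identical diameters")
})

test_that("intensity -> diameter inverts the forward model within 1 nm", {
  cal <- fit_scatter_calibration(make_beads(10^2.5 * bead_sigma), opt,
                                 grid = seq(30, 600, by = 1))
  for (d in c(60, 120, 200, 450)) {
    sig <- effective_scattering_cross_section(ev_default_model(d), opt)$sigma_effective
    res <- intensity_to_diameter(10^2.5 * sig, cal)
    expect_equal(res$flag, "ok")
    expect_equal(res$diameter, d, tolerance = 1 / d)
  }
})

test_that("out-of-range intensities are flagged, and sizing is monotone", {
  cal <- fit_scatter_calibration(make_beads(10^2.5 * bead_sigma), opt,
                                 grid = grid_coarse)
  res0 <- intensity_to_diameter(0, cal)
  expect_equal(res0$flag, "below_range")
  expect_true(is.na(res0$diameter))
  lo <- min(cal$inversion_table$sigma)
  expect_equal(intensity_to_diameter(10^2.5 * lo / 10, cal)$flag, "below_range")
  hi <- max(cal$inversion_table$sigma[seq_len(cal$monotone_prefix)])
  expect_equal(intensity_to_diameter(10^2.5 * hi * 10, cal)$flag, "above_range")
  intens <- 10^2.5 * bead_sigma[1:3]    # increasing, all within the grid
  d <- predict(cal, intens)$diameter
  expect_true(all(diff(d) > 0))
})

test_that("rescaling all intensities shifts the offset and nothing else", {
  cal1 <- fit_scatter_calibration(make_beads(10^2.5 * bead_sigma), opt,
                                  grid = grid_coarse)
  cal2 <- fit_scatter_calibration(make_beads(10^2.5 * bead_sigma * 50), opt,
                                  grid = grid_coarse)
  expect_equal(cal2$log_offset - cal1$log_offset, log10(50), tolerance = 1e-12)
  d1 <- predict(cal1, 10^2.5 * bead_sigma)$diameter
  d2 <- predict(cal2, 10^2.5 * bead_sigma * 50)$diameter
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("noise floor converts to a minimum resolvable diameter", {
  sig100 <- effective_scattering_cross_section(ev_default_model(100), opt)$sigma_effective
  cal <- fit_scatter_calibration(make_beads(10^2.5 * bead_sigma), opt,
                                 grid = grid_coarse,
                                 noise_floor_intensity = 10^2.5 * sig100)
  expect_equal(cal$min_resolvable_diameter, 100, tolerance = 0.03)
  below <- intensity_to_diameter(10^2.5 * sig100 * 0.5, cal)
  expect_equal(below$flag, "below_range")
})

test_that("scatter-equivalent diameter behaves as an identity and is monotone", {
  d_self <- scatter_equivalent_diameter(ev_default_model(150), opt,
                                        model = ev_default_model)
  expect_equal(d_self, 150, tolerance = 0.1 / 150)
  e80 <- scatter_equivalent_diameter(polystyrene_bead(80), opt)
  e101 <- scatter_equivalent_diameter(polystyrene_bead(101), opt)
  expect_gt(e101, e80)
  expect_gt(e80, 80)   # vesicles scatter less than polystyrene
  tiny <- particle_model(5, 1.35)
  expect_error(scatter_equivalent_diameter(tiny, opt, interval = c(100, 300)),
               "not representable")
})

test_that("slope-free variant reproduces a constructed slope", {
  intens <- 10^(1.8 * log10(bead_sigma) + 0.7)
  cal <- fit_scatter_calibration(make_beads(intens), opt, slope_free = TRUE,
                                 grid = grid_coarse)
  expect_equal(unname(coef(cal)[["slope"]]), 1.8, tolerance = 1e-9)
  expect_equal(unname(coef(cal)[["log_offset"]]), 0.7, tolerance = 1e-9)
})

test_that("calibrations survive a serialization round trip", {
  cal <- fit_scatter_calibration(make_beads(10^2.5 * bead_sigma), opt,
                                 grid = grid_coarse)
  path <- tempfile(fileext = ".yaml")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_s3_class(back, "scatter_calibration")
  expect_equal(back$log_offset, cal$log_offset, tolerance = 1e-12)
  sig <- effective_scattering_cross_section(ev_default_model(140), opt)$sigma_effective
  expect_equal(intensity_to_diameter(10^2.5 * sig, back)$diameter,
               intensity_to_diameter(10^2.5 * sig, cal)$diameter,
               tolerance = 1e-9)
})
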