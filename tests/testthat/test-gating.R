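test_that("control percentile threshold follows the quantile definition", {
  zero <- event_table(data.frame(calcein = rep(0, 100)))
  expect_equal(calcein_threshold_from_control(zero), 0)
  set.seed(501)
  ctrl <- event_table(data.frame(calcein = rnorm(1e5, 100, 10)))
  thr <- calcein_threshold_from_control(ctrl)
  expect_equal(thr, 100 + qnorm(0.999) * 10, tolerance = 0.5 / 131)
  # applying a control-derived threshold back to the control leaves ~0.1%
  frac <- mean(ctrl$calcein > thr)
  expect_lt(abs(frac - 0.001), 5e-4)
  expect_error(calcein_threshold_from_control(
    event_table(data.frame(calcein = numeric(0)))), "empty")
})

toy_cascade_table <- function() {
  # six events engineered so exactly one fails each scatter-mode gate and
  # one survives everything
  event_table(data.frame(
    VSSC_H = c(100, 100, 100, 100, 100, 100),
    VSSC_A = c(100, 100, 400, 100, 100, 100),   # event 3 fails singlet
    calcein = c(500, 500, 500, 10, 500, 500)),  # event 4 fails calcein
    acquired_volume = 20, dilution_factor = 100)
}

test_that("a constructed truth table attrits one event per gate", {
  ev <- toy_cascade_table()
  sizes <- c(500, 150, 150, 150, 150, 150)      # event 1 fails size
  gates <- gate_set(max_diameter = 300, calcein_threshold = 100)
  res <- apply_cascade(ev, gates, sizes = sizes[1:6])
  expect_equal(unname(res$counts), c(5L, 4L, 3L))
  expect_equal(res$final_count, 3L)
  expect_true(all(diff(res$counts) <= 0))
  expect_equal(res$concentration, concentration(3, 20, 100))
})

test_that("imaging-mode cascade applies spot-count and focus gates", {
  ev <- event_table(data.frame(
    scatter_intensity = c(10, 900, 10, 10, 10),
    brightfield_spot_count = c(0, 0, 2, 0, 0),
    calcein = c(500, 500, 500, 5, 500),
    gradient_rms = c(60, 60, 60, 60, 10)),
    acquired_volume = 2)
  gates <- gate_set(calcein_threshold = 100, size_proxy_max = 500,
                    focus_min_gradient_rms = 50)
  res <- apply_cascade(ev, gates, mode = "imaging")
  expect_equal(unname(res$counts), c(4L, 3L, 2L, 1L))
  # enumeration ignores the focus gate; cargo analysis uses it
  expect_equal(res$final_count, 2L)
  expect_equal(res$focused_count, 1L)
})

test_that("empty tables and neutral gates behave as limits", {
  empty <- event_table(data.frame(VSSC_H = numeric(0), VSSC_A = numeric(0),
                                  calcein = numeric(0)),
                       acquired_volume = 20)
  res <- apply_cascade(empty, gate_set(calcein_threshold = 10))
  expect_equal(res$final_count, 0L)
  expect_equal(res$concentration, 0)
  ev <- toy_cascade_table()
  wide <- gate_set(max_diameter = Inf, singlet_band = c(0, Inf),
                   calcein_threshold = 100)
  res2 <- apply_cascade(ev, wide)
  expect_equal(res2$final_count, sum(ev$calcein > 100))
})

test_that("gate masks are idempotent and permutation-invariant", {
  set.seed(502)
  samp <- generate_ev_sample(population_spec(count = 2000),
                             instrument_profile("nanoscale"), seed = 503)
  gates <- gate_set(calcein_threshold = 100)
  res1 <- apply_cascade(samp, gates)
  # applying the cascade to the already-gated subset changes nothing
  sub <- event_table(as.data.frame(samp)[res1$masks$calcein, ],
                     acquired_volume = 2)
  res2 <- apply_cascade(sub, gates)
  expect_equal(res2$final_count, res1$final_count)
  perm <- sample(nrow(samp))
  shuffled <- event_table(as.data.frame(samp)[perm, ], acquired_volume = 2)
  res3 <- apply_cascade(shuffled, gates)
  expect_equal(res3$final_count, res1$final_count)
  expect_equal(unname(res3$counts), unname(res1$counts))
})

test_that("concentration arithmetic matches the acquisition settings", {
  expect_equal(concentration(500, 20, 100), 2.5e6)
  expect_equal(concentration(0, 20, 100), 0)
  expect_error(concentration(10, 0), "positive")
  # 2 minutes at 10 uL/min is the default conventional acquisition volume
  inst <- instrument_profile("conventional")
  expect_equal(inst$flow_rate * 2, inst$acquired_volume)
})

test_that("detergent lysis control reduces calcein counts", {
  ev <- toy_cascade_table()
  gates <- gate_set(calcein_threshold = 100)
  stained <- apply_cascade(ev, gates)
  none <- event_table(data.frame(VSSC_H = 100, VSSC_A = 100, calcein = 5),
                      acquired_volume = 20)
  lysed <- apply_cascade(none, gates)
  chk <- detergent_control_check(stained, lysed)
  expect_equal(chk$reduction, 1)
  expect_true(chk$pass)
  same <- detergent_control_check(stained, stained)
  expect_equal(same$reduction, 0)
  expect_false(same$pass)
  undef <- detergent_control_check(lysed, lysed)
  expect_false(undef$defined)
})

test_that("synthetic lysis of 95% of esterase-positive vesicles is measured", {
  inst <- instrument_profile("nanoscale")
  stained <- generate_ev_sample(
    population_spec(count = 10000, esterase_positive_fraction = 0.8),
    inst, seed = 504)
  lysed <- generate_ev_sample(
    population_spec(count = 10000, esterase_positive_fraction = 0.8 * 0.05),
    inst, seed = 505)
  thr <- calcein_threshold_from_control(
    generate_buffer_control(20000, inst, seed = 506))
  gates <- gate_set(calcein_threshold = thr)
  chk <- detergent_control_check(apply_cascade(stained, gates),
                                 apply_cascade(lysed, gates))
  expect_equal(chk$reduction, 0.95, tolerance = 0.02)
  expect_true(chk$pass)
})

test_that("dilution linearity calls a Poisson halving series linear", {
  exact <- data.frame(dilution_factor = 2^(0:4),
                      count = 32000 / 2^(0:4))
  res <- dilution_linearity(exact)
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$verdict, "linear")
  pois <- generate_dilution_series(base_count = 50000, seed = 507)
  resp <- dilution_linearity(pois)
  expect_lt(abs(resp$slope - 1), 0.05)
  expect_equal(resp$verdict, "linear")
})

test_that("constant counts across dilutions are flagged as possible swarm", {
  flat <- data.frame(dilution_factor = 2^(0:4), count = rep(5000, 5))
  res <- dilution_linearity(flat)
  expect_equal(res$slope, 0, tolerance = 1e-12)
  expect_equal(res$verdict, "non-linear (possible swarm)")
  withzero <- data.frame(dilution_factor = c(1, 2, 4, 8),
                         count = c(100, 50, 25, 0))
  expect_warning(dilution_linearity(withzero), "zero-count")
  expect_error(dilution_linearity(data.frame(dilution_factor = c(1, 2),
                                             count = c(10, 5))), "at least 3")
})

test_that("background correction recovers the true esterase fraction", {
  inst <- instrument_profile("nanoscale")
  f <- 0.8
  n <- 20000
  samp <- generate_ev_sample(
    population_spec(count = n, esterase_positive_fraction = f), inst,
    seed = 508)
  ctrl <- generate_buffer_control(n_events(samp), inst, seed = 509)
  thr <- calcein_threshold_from_control(ctrl)
  pos <- sum(samp$calcein > thr)
  bg_rate <- mean(ctrl$calcein > thr)
  corrected <- (pos - bg_rate * n_events(samp)) / n_events(samp)
  expect_true(within_binomial_ci(corrected, f, n_events(samp)))
})
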