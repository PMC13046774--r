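markers <- c("CD9", "CD63", "CD81")

make_single <- function(primary, spill_into = NULL, spill_frac = 0,
                        n = 5000, af = 50, noise_cv = 0, seed = 1) {
  set.seed(seed)
  sig <- 5000 * if (noise_cv > 0) rlnorm(n, 0, sqrt(log(1 + noise_cv^2))) else rep(1, n)
  df <- data.frame(CD9 = rep(af, n), CD63 = rep(af, n), CD81 = rep(af, n))
  df[[primary]] <- af + sig
  if (!is.null(spill_into)) df[[spill_into]] <- af + spill_frac * sig
  event_table(df)
}

unstained <- event_table(data.frame(CD9 = rep(50, 1000), CD63 = rep(50, 1000),
                                    CD81 = rep(50, 1000)))

test_that("clean single stains give an identity spillover matrix", {
  singles <- lapply(markers, make_single)
  names(singles) <- markers
  S <- estimate_spillover(singles, unstained)
  expect_equal(unclass(S)[seq_len(9)], as.vector(diag(3)))
  expect_error(estimate_spillover(list(CD9 = unstained), unstained),
               "no primary-channel signal")
})

test_that("generated spillover fractions are recovered from medians", {
  singles <- list(CD9 = make_single("CD9", "CD63", 0.10),
                  CD63 = make_single("CD63"),
                  CD81 = make_single("CD81"))
  S <- estimate_spillover(singles, unstained)
  expect_equal(S["CD9", "CD63"], 0.10, tolerance = 1e-9)
  # noisy singles: entries within 0.01 of truth
  noisy <- list(CD9 = make_single("CD9", "CD63", 0.10, noise_cv = 0.05, seed = 11),
                CD63 = make_single("CD63", "CD81", 0.07, noise_cv = 0.05, seed = 12),
                CD81 = make_single("CD81", noise_cv = 0.05, seed = 13))
  Sn <- estimate_spillover(noisy, unstained)
  expect_lt(abs(Sn["CD9", "CD63"] - 0.10), 0.01)
  expect_lt(abs(Sn["CD63", "CD81"] - 0.07), 0.01)
  expect_lt(max(abs(Sn - diag(3) -
                      matrix(c(0, 0.10, 0, 0, 0, 0.07, 0, 0, 0), 3, 3,
                             byrow = TRUE))), 0.01)
})

test_that("compensation exactly unmixes data generated through the matrix", {
  S <- default_spillover()
  set.seed(21)
  truth <- matrix(rexp(300 * 3, 1 / 1000), ncol = 3,
                  dimnames = list(NULL, markers))
  raw <- truth %*% S
  ev <- event_table(as.data.frame(raw))
  comp <- compensate(ev, S)
  expect_equal(as.matrix(as.data.frame(comp)[markers]), truth,
               tolerance = 1e-9, ignore_attr = TRUE)
  # identity matrix leaves data untouched; round trip is exact
  ident <- structure(diag(3), dimnames = list(markers, markers))
  expect_equal(as.data.frame(compensate(ev, ident)), as.data.frame(ev))
  back <- event_table(as.data.frame(
    as.matrix(as.data.frame(comp)[markers]) %*% S))
  expect_equal(as.data.frame(compensate(back, S))[markers],
               as.data.frame(comp)[markers], tolerance = 1e-9,
               ignore_attr = TRUE)
  singular <- matrix(1, 3, 3, dimnames = list(markers, markers))
  expect_error(compensate(ev, singular), "singular")
  expect_error(compensate(event_table(data.frame(CD9 = 1)), S), "absent")
})

test_that("isotype thresholds match the control quantiles per marker", {
  zero <- event_table(data.frame(CD9 = rep(0, 100)))
  expect_equal(unname(isotype_thresholds(list(CD9 = zero))), 0)
  set.seed(31)
  iso <- lapply(markers, function(mk) {
    df <- data.frame(x = rnorm(1e5, 50, 5))
    names(df) <- mk
    event_table(df)
  })
  names(iso) <- markers
  thr <- isotype_thresholds(iso)
  expect_equal(unname(thr), rep(50 + qnorm(0.999) * 5, 3), tolerance = 0.01)
  # threshold applied to its own control leaves ~0.1% positives
  frac <- mean(iso$CD9$CD9 > thr[["CD9"]])
  expect_lt(abs(frac - 0.001), 5e-4)
  expect_error(isotype_thresholds(list(CD9 = NULL)), "missing isotype")
})

test_that("combination counts partition the calcein-positive events", {
  thr <- c(CD9 = 100, CD63 = 100, CD81 = 100)
  ev <- event_table(data.frame(CD9 = c(500, 500, 10, 500),
                               CD63 = c(500, 10, 10, 500),
                               CD81 = c(500, 10, 10, 10)))
  cc <- combination_counts(ev, thr, rep(TRUE, 4))
  expect_equal(sum(cc$count), 4)
  expect_equal(cc$count[cc$combination == "CD9+CD63+CD81+"], 1)
  expect_equal(cc$count[cc$combination == "CD9+CD63-CD81-"], 1)
  expect_equal(cc$count[cc$combination == "triple-negative"], 1)
  all_pos <- combination_counts(ev, thr, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(all_pos$count), 1)
  expect_equal(all_pos$count[all_pos$combination == "CD9+CD63+CD81+"], 1)
  none <- combination_counts(ev, thr, rep(FALSE, 4))
  expect_equal(sum(none$count), 0)
})

test_that("generated combination probabilities are recovered after compensation", {
  probs <- c("CD9" = 0.3, "CD63+CD81" = 0.2, "CD9+CD63+CD81" = 0.1,
             "none" = 0.4)
  inst <- instrument_profile("nanoscale")
  n <- 20000
  samp <- generate_ev_sample(
    population_spec(count = n, esterase_positive_fraction = 1,
                    combination_probs = probs), inst, seed = 41)
  comp <- compensate(samp, inst$spillover)
  ctrl <- generate_buffer_control(20000, inst, seed = 42)
  thr_cal <- calcein_threshold_from_control(ctrl)
  thr <- isotype_thresholds(list(CD9 = ctrl, CD63 = ctrl, CD81 = ctrl))
  cc <- combination_counts(comp, thr, comp$calcein > thr_cal)
  got <- function(lab) cc$fraction[cc$combination == lab]
  ncc <- attr(cc, "total")
  expect_true(within_binomial_ci(got("CD9+CD63-CD81-"), 0.3, ncc))
  expect_true(within_binomial_ci(got("CD9-CD63+CD81+"), 0.2, ncc))
  expect_true(within_binomial_ci(got("CD9+CD63+CD81+"), 0.1, ncc))
  expect_true(within_binomial_ci(got("triple-negative"), 0.4, ncc))
  expect_equal(sum(cc$count), attr(cc, "total"))
})

test_that("counting is invariant to detector ordering", {
  thr <- c(CD9 = 100, CD63 = 100, CD81 = 100)
  set.seed(51)
  df <- data.frame(CD9 = runif(500, 0, 200), CD63 = runif(500, 0, 200),
                   CD81 = runif(500, 0, 200))
  cc1 <- combination_counts(event_table(df), thr, rep(TRUE, 500))
  cc2 <- combination_counts(event_table(df[c(3, 1, 2)]),
                            thr[c("CD63", "CD9", "CD81")][c("CD9", "CD63", "CD81")],
                            rep(TRUE, 500))
  expect_equal(sort(cc1$count), sort(cc2$count))
  m1 <- cc1$count[cc1$combination == "CD9+CD63+CD81+"]
  m2 <- cc2$count[cc2$combination == "CD9+CD63+CD81+"]
  expect_equal(m1, m2)
})

test_that("replicate confidence intervals behave like t intervals", {
  same <- replicate_ci(rep(42, 5))
  expect_equal(same$mean, 42)
  expect_equal(same$lower, 42)
  expect_equal(same$upper, 42)
  expect_error(replicate_ci(7), "fewer than 2")
  # coverage: ~95% of 1000 resimulated n=15 intervals cover the truth
  set.seed(61)
  cover <- mean(replicate(1000, {
    ci <- replicate_ci(rnorm(15, 100, 20))
    ci$lower <= 100 && 100 <= ci$upper
  }))
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("replicate summary aggregates per combination", {
  thr <- c(CD9 = 100, CD63 = 100, CD81 = 100)
  reps <- lapply(1:3, function(i) {
    set.seed(70 + i)
    df <- data.frame(CD9 = runif(300, 0, 200), CD63 = runif(300, 0, 200),
                     CD81 = runif(300, 0, 200))
    combination_counts(event_table(df), thr, rep(TRUE, 300))
  })
  summ <- combination_summary(reps)
  expect_equal(nrow(summ), 8)
  expect_true(all(summ$lower <= summ$mean_count & summ$mean_count <= summ$upper))
})

test_that("a pan-fluorophore panel never detects fewer events than a mixed panel", {
  inst <- instrument_profile("nanoscale")
  samp <- generate_ev_sample(
    population_spec(count = 10000, esterase_positive_fraction = 1),
    inst, seed = 81)
  # LoD-limited detection: threshold equivalent to 12 antibodies at 50/copy
  res <- compare_panel_sensitivity(samp, brightness_per_copy = 50,
                                   detection_threshold = 600)
  expect_gte(res$pan, res$mixed)
  expect_gt(res$n_positive, 0)
  # and strictly greater when single-marker copies straddle the threshold
  res2 <- compare_panel_sensitivity(samp, detection_threshold = 1400)
  expect_gt(res2$pan, res2$mixed)
})
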