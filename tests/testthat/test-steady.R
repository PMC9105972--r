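test_that("closed-form rate laws evaluate exactly", {
  expect_equal(v_ss_competitive(1e-7, 1e-5, 1e-5, 0, 1e-6), 5e-8)
  expect_equal(v_ss_competitive(1e-7, 1e-5, 1e-5, 1e-6, 1e-6),
               1e-7 / 3, tolerance = 1e-12)
  # competitive limit: saturating substrate overcomes any I
  expect_rel_equal(v_ss_competitive(1e-7, 1e-5, 1e3, 50e-6, 1e-6), 1e-7,
                   1e-6)
  expect_equal(v_meas_preincubated(1e-7, 1e-5, 1e-5, 0, 1e-6), 5e-8)
  expect_equal(v_meas_preincubated(1e-7, 1e-5, 1e-5, 1e-6, 1e-6), 2.5e-8)
  # v_meas/v_ss at S = Km, I = Ki: (1/2 * 1/2) / (1/3)
  expect_equal(v_meas_preincubated(1e-7, 1e-5, 1e-5, 1e-6, 1e-6) /
               v_ss_competitive(1e-7, 1e-5, 1e-5, 1e-6, 1e-6), 0.75)
})

test_that("rapid-equilibrium partition fractions are exact and sum to one", {
  expect_equal(equilibrium_fractions(1e-5, 1e-5, 1e-6, 1e-6),
               c(fE = 1, fES = 1, fEI = 1) / 3)
  expect_equal(equilibrium_fractions(0, 1e-5, 1e-6, 1e-6),
               c(fE = 0.5, fES = 0, fEI = 0.5))
  expect_equal(equilibrium_fractions(0, 1e-5, 0, 1e-6),
               c(fE = 1, fES = 0, fEI = 0))
  set.seed(11)
  for (i in 1:20) {
    f <- equilibrium_fractions(runif(1, 0, 1e-4), 1e-5,
                               runif(1, 0, 1e-5), 1e-6)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(f >= 0))
  }
  expect_error(equilibrium_fractions(1, -1, 1, 1), "positive")
})

test_that("residence time and dissociation fraction follow first-order law", {
  expect_rel_equal(residence_time(1.57e-2), 63.69, 1e-3)
  expect_equal(fraction_dissociated(0, 1), 0)
  expect_equal(fraction_dissociated(3 * residence_time(0.5), 0.5),
               1 - exp(-3), tolerance = 1e-12)  # 95.02% at 3 tau
  # 3.5 tau gives ~97%, not 95
  expect_equal(fraction_dissociated(3.5, 1), 1 - exp(-3.5))
  expect_error(residence_time(0), "positive")
  expect_error(fraction_dissociated(-1, 1), "non-negative")
})

test_that("initial-velocity extraction matches its two definitions", {
  tt <- seq(0, 30, 0.5)
  lin <- data.frame(time_s = tt, signal = 3e-9 * tt)
  expect_equal(initial_velocity(lin, 10, 10, "window"), 3e-9)
  expect_equal(initial_velocity(lin, 10, 10, "chord"), 3e-9)
  # window mode on a saturating exponential equals an independent OLS fit
  a <- 1e-5; b <- 1e-2
  expc <- data.frame(time_s = tt, signal = a * (1 - exp(-b * tt)))
  sel <- tt >= 10 & tt <= 20
  oracle <- unname(coef(lm(y ~ x, data.frame(x = tt[sel],
                                             y = expc$signal[sel])))[2])
  expect_equal(initial_velocity(expc, 10, 10, "window"), oracle,
               tolerance = 1e-12)
  # chord mode: first reading after the dead time over elapsed time
  expect_equal(initial_velocity(expc, 10, 10, "chord"),
               a * (1 - exp(-b * 10)) / 10, tolerance = 1e-12)
  expect_error(initial_velocity(lin[1:40, ], 25, 10, "window"),
               "fewer than 3")
})

test_that("simulated fast-unbinder velocities agree with the closed form", {
  fd <- preincubation_design(1e2, s0 = 1e-5, i0 = 1e-6)
  curves <- generate_curves(fd$design, fd$mechanism, fd$rates)
  v <- velocities(curves)$v
  d <- derived_constants(fd$rates, e0 = fd$design$e0)
  expect_rel_equal(v, v_ss_competitive(d$Vmax, d$Km, 1e-5, 1e-6, d$Ki),
                   0.02)
})

test_that("double-reciprocal regression is exact on exact data", {
  Vmax <- 1e-7; Km <- 1e-5
  ds <- closed_form_dataset(v_ss_competitive, i0 = 0)
  for (w in c("relative_variance", "unweighted")) {
    lb <- lineweaver_burk(ds, w)
    expect_equal(lb$slope, Km / Vmax, tolerance = 1e-9)
    expect_equal(lb$intercept, 1 / Vmax, tolerance = 1e-9)
  }
  expect_warning(
    lineweaver_burk(data.frame(s0_M = c(1, 2, 5) * 1e-6, i0_M = 0,
                               v = c(0, 1e-8, 2e-8))),
    "excluded")
})

test_that("replots recover the generating constants from closed-form data", {
  # true competitive data: common 1/v-axis intercept, Kic = Ki, no Kiu
  ds_ss <- closed_form_dataset(v_ss_competitive)
  lb <- lineweaver_burk(ds_ss)
  expect_lt(diff(range(lb$intercept)) / mean(lb$intercept), 1e-3)
  expect_rel_equal(dixon_kic(lb), 1e-6, 1e-3)
  expect_equal(cornish_bowden_kiu(lb), Inf)
  # slow-dissociation limit: looks purely noncompetitive at the true Ki
  ds_meas <- closed_form_dataset(v_meas_preincubated)
  lb2 <- lineweaver_burk(ds_meas)
  expect_rel_equal(dixon_kic(lb2), 1e-6, 1e-3)
  expect_rel_equal(cornish_bowden_kiu(lb2), 1e-6, 1e-3)
  # intercepts scale as (1 + I/Ki): common intersection on the 1/S axis
  scaled <- lb2$intercept / (1 + lb2$i0_M / 1e-6)
  expect_lt(diff(range(scaled)) / mean(scaled), 1e-6)
  expect_error(dixon_kic(lb2[1:2, ]), "3 inhibitor levels")
})

test_that("mechanism classification follows the ratio thresholds", {
  expect_identical(classify_inhibition(1e-6, Inf), "competitive")
  expect_identical(classify_inhibition(1e-6, 1.05e-6), "noncompetitive")
  expect_identical(classify_inhibition(1e-6, 8e-6), "mixed")
  expect_identical(classify_inhibition(1e-6, 2e-5), "competitive")
  expect_identical(classify_inhibition(8e-6, 1e-6 * 0.05), "uncompetitive")
  expect_identical(classify_inhibition(Inf, Inf), "none")
  expect_error(classify_inhibition(-1, 1), "positive")
})

test_that("measured velocities are bracketed by the two limiting rate laws", {
  # intermediate k_off: v_meas <= v(chord) <= v_ss
  fd <- preincubation_design(3e-3, s0 = c(10, 50) * 1e-6, i0 = c(1, 5) * 1e-6)
  curves <- generate_curves(fd$design, fd$mechanism, fd$rates)
  vd <- velocities(curves)
  d <- derived_constants(fd$rates, e0 = fd$design$e0)
  lo <- v_meas_preincubated(d$Vmax, d$Km, vd$s0_M, vd$i0_M, d$Ki)
  hi <- v_ss_competitive(d$Vmax, d$Km, vd$s0_M, vd$i0_M, d$Ki)
  expect_true(all(vd$v >= lo * 0.99 & vd$v <= hi * 1.01))
})

test_that("inhibition_fit couples the replots and prints a readable summary", {
  ds <- closed_form_dataset(v_ss_competitive)
  fit <- fit_inhibition(ds)
  expect_s3_class(fit, "inhibition_fit")
  expect_identical(fit$classification, "competitive")
  expect_output(print(fit), "Dixon")
  path <- tempfile(fileext = ".json")
  write_inhibition(fit, path)
  doc <- jsonlite::read_json(path)
  expect_false(doc$K_iu_detected)  # absent component flagged, not a sentinel
  expect_null(doc$K_iu_M)
  expect_true(doc$K_ic_detected)
  unlink(path)
})
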