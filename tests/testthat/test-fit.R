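# Round-trip fits here use a reduced two-addition series (helper) so the
# suite stays fast; the full published-scale round trips run in
# test-acceptance.R.

truth4 <- tcache_rates()[c("k1", "k2", "k3", "k4")]

test_that("starting at the generating truth gives a zero-residual fit", {
  des <- small_series_design()
  curves <- generate_curves(des, build_scheme("slyke_cullen_product"), truth4)
  fit <- fit_stage1(curves, start = truth4[c("k1", "k2", "k4")])
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-24)
  expect_equal(coef(fit), truth4[c("k1", "k2", "k4")], tolerance = 1e-6)
})

test_that("stage-1 round trip recovers hydrolysis and product constants", {
  des <- small_series_design()
  curves <- generate_curves(des, build_scheme("slyke_cullen_product"), truth4)
  fit <- fit_stage1(curves, start = c(k1 = truth4[["k1"]] * 3,
                                      k2 = truth4[["k2"]] / 3,
                                      k4 = truth4[["k4"]] * 3))
  expect_true(fit$converged)
  expect_rel_equal(coef(fit)[["k1"]], truth4[["k1"]], 0.005)
  expect_rel_equal(coef(fit)[["k2"]], truth4[["k2"]], 0.005)
  expect_rel_equal(coef(fit)[["k4"]], truth4[["k4"]], 0.005)
  # derived constants recomputed from estimates
  d <- derived.progress_fit(fit)
  expect_identical(d$Ki_P, coef(fit)[["k4"]] / 2e8)
})

test_that("only the product Ki ratio matters when binding is near equilibrium", {
  des <- small_series_design()
  curves <- generate_curves(des, build_scheme("slyke_cullen_product"), truth4)
  fit_a <- fit_stage1(curves, start = c(k1 = truth4[["k1"]] * 2,
                                        k2 = truth4[["k2"]] / 2,
                                        k4 = truth4[["k4"]] * 2), k3 = 2e8)
  fit_b <- fit_stage1(curves, start = c(k1 = truth4[["k1"]] * 2,
                                        k2 = truth4[["k2"]] / 2,
                                        k4 = truth4[["k4"]] * 2 * 5), k3 = 1e9)
  KiP_a <- coef(fit_a)[["k4"]] / 2e8
  KiP_b <- coef(fit_b)[["k4"]] / 1e9
  expect_rel_equal(KiP_b, KiP_a, 0.002)
})

test_that("fitting in absorbance or concentration units is equivalent", {
  des <- small_series_design()
  curves <- generate_curves(des, build_scheme("slyke_cullen_product"), truth4)
  start <- c(k1 = truth4[["k1"]] * 2, k2 = truth4[["k2"]] / 2,
             k4 = truth4[["k4"]] * 2)
  fit_c <- fit_stage1(curves, start = start)
  fit_a <- fit_stage1(to_absorbance(curves, ellman_params()), start = start)
  expect_equal(coef(fit_a), coef(fit_c), tolerance = 1e-6)
})

test_that("global fitting is deterministic", {
  des <- small_series_design()
  curves <- generate_curves(des, build_scheme("slyke_cullen_product"), truth4)
  start <- c(k1 = truth4[["k1"]] * 2, k2 = truth4[["k2"]] / 2,
             k4 = truth4[["k4"]] * 2)
  f1 <- fit_stage1(curves, start = start)
  f2 <- fit_stage1(curves, start = start)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rss, f2$rss)
})

test_that("an uninhibited dataset leaves the inhibitor rates unidentifiable", {
  des <- gal_design("gal_fit_series")
  des$i0 <- 0
  des$duration_s <- 200
  curves <- generate_curves(des, build_scheme("slyke_cullen_product_inhibitor"),
                            tcache_rates())
  expect_warning(
    expect_warning(
      fit <- fit_stage2(curves, truth4, start = c(k5 = 1e6, k6 = 0.1)),
      "no inhibited curves"),
    "identifiable|ill-conditioned")
  expect_false(fit$identifiable)
})

test_that("omitting the product-inhibition step leaves systematic residuals", {
  des <- small_series_design()
  curves <- generate_curves(des, build_scheme("slyke_cullen_product"), truth4)
  full <- fit_stage1(curves, start = c(k1 = truth4[["k1"]] * 2,
                                       k2 = truth4[["k2"]] / 2,
                                       k4 = truth4[["k4"]] * 2))
  # reduced model: plain van Slyke-Cullen, no E+P binding
  bare <- mechanism("no_product_inhibition", c("E", "S", "EA", "P", "A"),
                    list(kin_step(c(E = 1, S = 1), c(EA = 1, P = 1), "k1"),
                         kin_step(c(EA = 1), c(E = 1, A = 1), "k2")))
  sig <- curves[curves$replicate == 1L, ]
  exp1 <- kin_experiment(sig$time_s, sig$signal, init = c(E = des$e0),
                         phases = rep(list(list(
                           duration = des$addition_interval_s,
                           additions = c(S = des$s0))), des$n_additions))
  red <- fit_progress(list(exp1), bare,
                      start = c(k1 = truth4[["k1"]], k2 = truth4[["k2"]]),
                      free = c("k1", "k2"))
  expect_gte(red$per_curve_rms[1], 5 * max(full$per_curve_rms[1], 1e-12))
})

test_that("profile of the residual norm is minimal and convex at the optimum", {
  des <- small_series_design()
  curves <- generate_curves(des, build_scheme("slyke_cullen_product"), truth4)
  fit <- fit_stage1(curves, start = c(k1 = truth4[["k1"]] * 2,
                                      k2 = truth4[["k2"]] / 2,
                                      k4 = truth4[["k4"]] * 2))
  k2_hat <- coef(fit)[["k2"]]
  prof <- profile_uncertainty(fit, "k2", k2_hat * c(0.9, 1, 1.1))
  expect_true(all(prof$converged))
  expect_lt(prof$rss[2], prof$rss[1])
  expect_lt(prof$rss[2], prof$rss[3])
  expect_equal(prof$rss[2], fit$rss, tolerance = 1e-6)
})

test_that("progress_fit methods behave like a standard fitted model", {
  des <- small_series_design()
  curves <- generate_curves(des, build_scheme("slyke_cullen_product"), truth4)
  fit <- fit_stage1(curves, start = truth4[c("k1", "k2", "k4")])
  expect_named(coef(fit), c("k1", "k2", "k4"))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_length(fitted(fit), fit$nobs)
  expect_equal(length(residuals(fit)), fit$nobs)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(deviance(fit), fit$rss)
  pr <- predict(fit, times = list(c(0, 100, 200)))
  expect_equal(nrow(pr[[1]]), 3L)
  expect_output(print(fit), "Converged")
  expect_output(print(summary(fit)), "condition number")
  sims <- simulate(fit, nsim = 2, seed = 1, cv = 0.01)
  expect_length(sims, 2L)
  expect_false(identical(sims[[1]][[1]]$signal, sims[[2]][[1]]$signal))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
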