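test_that("mass-action derivatives match hand evaluation", {
  empty <- mechanism("empty", c("A", "B"), list())
  expect_equal(mass_action_derivatives(empty, c(k = 1), c(A = 1)),
               c(A = 0, B = 0))

  m <- mechanism("bind", c("E", "I", "EI"),
                 list(kin_step(c(E = 1, I = 1), c(EI = 1), "k")))
  d <- mass_action_derivatives(m, c(k = 1e6), c(E = 1e-8, I = 1e-8))
  expect_equal(d[["EI"]], 1e-10)
  expect_equal(d[["E"]], -1e-10)

  vs <- build_scheme("slyke_cullen_product")
  r <- tcache_rates()[c("k1", "k2", "k3", "k4")]
  st1 <- c(E = 1e-10, S = 1e-5, EA = 2e-11)
  st2 <- c(E = 1e-10, S = 5e-5, EA = 2e-11)  # only S differs
  d1 <- mass_action_derivatives(vs, r, st1)
  d2 <- mass_action_derivatives(vs, r, st2)
  expect_equal(d1[["A"]], r[["k2"]] * 2e-11)
  expect_equal(d1[["A"]], d2[["A"]])  # acetate release independent of S

  expect_error(mass_action_derivatives(m, c(wrong = 1), c(E = 1)), "missing")
  expect_error(mass_action_derivatives(m, c(k = 1), c(E = -1)), "negative")
})

test_that("integration reproduces the pseudo-first-order binding relaxation", {
  mech <- binding_mech()
  kon <- 1e5; koff <- 1e-2; e0 <- 1e-9; i0 <- 1e-5  # i0 >> e0
  tr <- integrate_mechanism(mech, c(kon = kon, koff = koff),
                            c(E = e0, I = i0), seq(0, 5, by = 0.1),
                            atol = 1e-16)
  kobs <- kon * i0 + koff
  Kd <- koff / kon
  closed <- e0 * (i0 / (i0 + Kd)) * (1 - exp(-kobs * tr$time_s))
  expect_lt(max(abs(tr$EI[-1] / closed[-1] - 1)), 1e-4)
})

test_that("no enzyme means no product; uninhibited start runs at ~Vmax", {
  fd <- preincubation_design(1e2)
  tr0 <- integrate_mechanism(fd$mechanism, fd$rates, c(S = 2e-4),
                             seq(0, 10, 1))
  expect_true(all(tr0$P == 0))
  tr <- integrate_mechanism(fd$mechanism, fd$rates,
                            c(E = 1e-10, S = 2e-4), c(0, 0.05, 0.1),
                            atol = 1e-16)
  v0 <- (tr$P[3] - tr$P[2]) / 0.05  # after the ms-scale E-S burst
  expect_rel_equal(v0, 1e-7, 0.05)  # Vmax = kcat * e0
})

test_that("detailed balance holds for an isolated reversible step", {
  mech <- binding_mech()
  kon <- 1e6; koff <- 1
  tr <- integrate_mechanism(mech, c(kon = kon, koff = koff),
                            c(E = 2e-6, I = 3e-6), c(0, 50), atol = 1e-18)
  fin <- tr[nrow(tr), ]
  expect_rel_equal(fin$EI / (fin$E * fin$I), kon / koff, 1e-6)
})

test_that("halving tolerances leaves the solution unchanged to 1e-4", {
  fd <- preincubation_design(3e-2)
  init <- c(E = 1e-10, S = 1e-5, I = 1e-6, EI = 0)
  tt <- seq(0, 20, 0.5)
  a <- integrate_mechanism(fd$mechanism, fd$rates, init, tt,
                           rtol = 1e-8, atol = 1e-16)
  b <- integrate_mechanism(fd$mechanism, fd$rates, init, tt,
                           rtol = 5e-9, atol = 5e-17)
  for (sp in c("P", "ES", "EI")) {
    scale <- max(abs(a[[sp]]))
    expect_lt(max(abs(a[[sp]] - b[[sp]])) / scale, 1e-4)
  }
})

test_that("exact binding equilibrium handles depletion correctly", {
  expect_equal(equilibrium_bound(1e-9, 0, 1e-6),
               c(E_free = 1e-9, EI = 0, I_free = 0))
  # free-ligand regime: e0 << i0 = Kd gives half the enzyme bound
  eq <- equilibrium_bound(100e-12, 1e-6, 1e-6)
  expect_rel_equal(eq[["EI"]], 0.5 * 100e-12, 1e-4)
  # full depletion-aware quadratic
  eq2 <- equilibrium_bound(1, 1, 1)
  expect_equal(eq2[["EI"]], (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_error(equilibrium_bound(-1, 1, 1), "non-negative")
})

test_that("protocols preserve state continuity and honour additions", {
  mech <- binding_mech()
  rates <- c(kon = 1e5, koff = 1e-2)
  # one phase with no additions is plain integration
  tt <- seq(0, 10, 1)
  p1 <- run_protocol(mech, rates, c(E = 1e-9, I = 1e-6),
                     list(list(duration = 10, times = tt)), atol = 1e-16)
  d1 <- integrate_mechanism(mech, rates, c(E = 1e-9, I = 1e-6), tt,
                            atol = 1e-16)
  expect_equal(p1$EI, d1$EI, tolerance = 1e-10)

  expect_error(run_protocol(mech, rates, c(E = 1e-9),
                            list(list(duration = 1, additions = c(X = 1)))),
               "unknown species")
  expect_error(run_protocol(mech, rates, c(E = 1e-9),
                            list(list(duration = -1))), "duration")
})

test_that("long pre-incubation reaches the analytic binding equilibrium", {
  fd <- preincubation_design(1e-2)   # kon = 1e4, koff = 1e-2, Ki = 1 uM
  e0 <- 100e-12; i0 <- 1e-6
  ph <- list(list(duration = 1e6))
  # analytic shortcut path
  fast <- run_protocol(fd$mechanism, fd$rates, c(E = e0, I = i0), ph,
                       shortcut = TRUE)
  # brute-force integration path
  slow <- run_protocol(fd$mechanism, fd$rates, c(E = e0, I = i0), ph,
                       shortcut = FALSE, atol = 1e-18)
  eq <- equilibrium_bound(e0, i0, 1e-6)
  expect_rel_equal(fast$EI[nrow(fast)], eq[["EI"]], 1e-9)
  expect_rel_equal(slow$EI[nrow(slow)], eq[["EI"]], 1e-6)
})

test_that("sequential additions conserve the substrate moiety", {
  mech <- build_scheme("slyke_cullen_product")
  rates <- tcache_rates()[c("k1", "k2", "k3", "k4")]
  phases <- rep(list(list(duration = 500, additions = c(S = 35e-6),
                          times = seq(0, 500, 10))), 5)
  tr <- run_protocol(mech, rates, c(E = 200e-12), phases)
  fin <- tr[nrow(tr), ]
  # choline moiety: S + P + EP equals the 5 x 35 uM added
  expect_rel_equal(fin$S + fin$P + fin$EP, 175e-6, 1e-6)
  # essentially all of it converted to detected product by completion
  expect_gt(fin$P, 170e-6)
  # enzyme conservation along the whole protocol
  etot <- tr$E + tr$EA + tr$EP
  expect_lt(max(abs(etot - 200e-12)) / 200e-12, 1e-6)
})
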