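# Closed-form oracles and small fixtures shared across tests.

# exact velocity datasets from the steady-state rate laws (no simulation)
closed_form_dataset <- function(rate_fn, Vmax = 1e-7, Km = 1e-5, Ki = 1e-6,
                                s0 = c(2, 5, 10, 20, 50, 100, 150, 200) * 1e-6,
                                i0 = c(0, 0.5, 1, 2, 5, 10, 20, 50) * 1e-6) {
  g <- expand.grid(s0_M = s0, i0_M = i0)
  g$v <- rate_fn(Vmax, Km, g$s0_M, g$i0_M, Ki)
  g$replicate <- 1L
  g
}

# minimal reversible-binding mechanism used by several integration tests
binding_mech <- function() {
  mechanism("binding", c("E", "I", "EI"),
            list(kin_step(c(E = 1, I = 1), c(EI = 1), "kon"),
                 kin_step(c(EI = 1), c(E = 1, I = 1), "koff")))
}

# reduced sequential-addition design: same chemistry as the full
# product-inhibition series but 2 additions and coarser sampling, for fast
# round-trip tests
small_series_design <- function() {
  assay_design(e0 = 200e-12, s0 = 35e-6, i0 = 0,
               order = "enzyme_initiated", dead_time_s = 10,
               duration_s = 800, sample_dt_s = 2,
               n_additions = 2L, addition_interval_s = 400)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual / expected - 1) < rel_tol),
              label = paste0(deparse(substitute(actual)), " within ",
                             rel_tol, " of ", deparse(substitute(expected)),
                             " (got ",
                             paste(signif(actual, 6), collapse = ", "), ")"))
}
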