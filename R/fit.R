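# Pre-steady-state global fitting of reaction progress curves: simultaneous
# nonlinear least squares on mechanism rate constants (and, optionally,
# initial concentrations) by repeated ODE integration.

#' A single progress-curve experiment for global fitting
#'
#' Couples one measured (or simulated) trace to the protocol that produced
#' it: initial concentrations and, for sequential-addition experiments, the
#' phase structure.
#'
#' @param time_s sample times (s), non-decreasing, >= 0.
#' @param signal detected signal at \code{time_s} (product concentration in
#'   M, or absorbance when \code{scale} is the extinction factor).
#' @param init named initial concentrations (M) at t = 0 (before any phase-1
#'   addition when \code{phases} is given).
#' @param phases optional protocol phases as in \code{\link{run_protocol}}
#'   (without \code{times}; the model is sampled at \code{time_s} on the
#'   cumulative clock).  \code{NULL} means a single uninterrupted run.
#' @param scale factor mapping model product concentration to the signal
#'   scale (1 for concentration, epsilon*path for absorbance).
#' @param signal_species detected species, default \code{"P"}.
#' @param label optional curve label.
#' @return object of class \code{"kin_experiment"}.
#' @export
kin_experiment <- function(time_s, signal, init, phases = NULL, scale = 1,
                           signal_species = "P", label = NULL) {
  if (length(time_s) != length(signal))
    stop("'time_s' and 'signal' must have equal length")
  if (is.unsorted(time_s) || any(time_s < 0))
    stop("'time_s' must be non-decreasing and non-negative")
  structure(list(time_s = as.numeric(time_s), signal = as.numeric(signal),
                 init = init, phases = phases, scale = scale,
                 signal_species = signal_species,
                 label = if (is.null(label)) "" else label),
            class = "kin_experiment")
}

# model signal for one experiment given mechanism/rates (linear
# interpolation from the integration grid onto the data times)
eval_experiment <- function(exp, mech, rates, rtol, atol) {
  if (is.null(exp$phases)) {
    tt <- sort(unique(c(0, exp$time_s)))
    traj <- integrate_mechanism(mech, rates, exp$init, tt,
                                rtol = rtol, atol = atol)
    mod <- stats::approx(traj$time_s, traj[[exp$signal_species]],
                         xout = exp$time_s, rule = 2)$y
  } else {
    t0 <- 0
    phases <- lapply(exp$phases, function(ph) {
      inside <- exp$time_s[exp$time_s >= t0 - 1e-9 &
                           exp$time_s <= t0 + ph$duration + 1e-9] - t0
      ph$times <- sort(unique(c(0, pmin(pmax(inside, 0), ph$duration),
                                ph$duration)))
      t0 <<- t0 + ph$duration
      ph
    })
    traj <- run_protocol(mech, rates, exp$init, phases,
                         rtol = rtol, atol = atol)
    traj <- traj[!duplicated(traj$time_s), , drop = FALSE]
    mod <- stats::approx(traj$time_s, traj[[exp$signal_species]],
                         xout = exp$time_s, rule = 2)$y
  }
  mod * exp$scale
}

#' Global fit of mechanism parameters to progress curves
#'
#' Minimizes the sum over curves and samples of (model - data)^2 on the
#' detected-signal scale, unweighted, by trust-region Levenberg-Marquardt
#' least squares with every free parameter optimized in log10 space (rate
#' constants span ten decades).  Initial concentrations can be co-fitted:
#' per-curve species (e.g. the nominal substrate load of each cuvette) and
#' species shared across all curves (e.g. the enzyme stock), both bounded to
#' +/-20% of nominal by default.
#'
#' Standard errors come from the linearized Jacobian at the optimum; the
#' Jacobian condition number flags structurally unidentifiable parameter
#' combinations (see \code{\link{profile_uncertainty}} for the honest
#' alternative).
#'
#' @param experiments list of \code{\link{kin_experiment}} objects.
#' @param mechanism a \code{\link{mechanism}}.
#' @param start full named vector of rate constants (starting guesses for
#'   the free ones, fixed values for the rest).
#' @param free labels of the rate constants to optimize.
#' @param lower,upper optional named bounds (natural scale) on free rates.
#' @param free_init_per_curve species whose initial concentration is fitted
#'   independently per curve.
#' @param free_init_shared species whose initial concentration is fitted
#'   once, shared across curves.
#' @param init_bounds_frac relative bounds on fitted concentrations.
#' @param rtol,atol integration tolerances; \code{atol} defaults to
#'   1e-6 x the smallest non-zero initial enzyme-scale concentration,
#'   capped at 1e-12 M.
#' @param control \code{minpack.lm::nls.lm.control} list; defaults enforce
#'   ftol 1e-10 and ptol 1e-8.
#' @return object of class \code{"progress_fit"}.
#' @export
fit_progress <- function(experiments, mechanism, start, free,
                         lower = NULL, upper = NULL,
                         free_init_per_curve = character(0),
                         free_init_shared = character(0),
                         init_bounds_frac = 0.2,
                         rtol = 1e-8, atol = NULL,
                         control = list()) {
  stopifnot(is.list(experiments), length(experiments) >= 1L,
            all(vapply(experiments, inherits, TRUE, "kin_experiment")),
            inherits(mechanism, "mechanism"))
  start <- rate_set(start, mechanism)
  labels <- vapply(mechanism$steps, `[[`, "", "rate")
  if (!all(free %in% labels))
    stop("free parameter(s) not in the mechanism: ",
         paste(setdiff(free, labels), collapse = ", "))
  if (any(free_init_shared %in% free_init_per_curve))
    stop("a species cannot be both shared and per-curve")
  if (is.null(atol)) {
    e_like <- unlist(lapply(experiments, function(e)
      e$init[e$init > 0]))
    atol <- min(1e-12, 1e-6 * min(e_like))
  }

  # parameter layout: free rates, shared inits, per-curve inits (log10)
  p_names <- free
  p0 <- log10(unname(start[free]))
  lo <- rep(-30, length(free)); hi <- rep(30, length(free))
  if (!is.null(lower)) lo[match(names(lower), free)] <- log10(lower)
  if (!is.null(upper)) hi[match(names(upper), free)] <- log10(upper)
  for (sp in free_init_shared) {
    v <- experiments[[1]]$init[[sp]]
    if (is.null(v) || v <= 0)
      stop("shared init species '", sp, "' must start positive")
    p_names <- c(p_names, sp)
    p0 <- c(p0, log10(v))
    lo <- c(lo, log10(v * (1 - init_bounds_frac)))
    hi <- c(hi, log10(v * (1 + init_bounds_frac)))
  }
  for (ci in seq_along(experiments)) for (sp in free_init_per_curve) {
    v <- experiments[[ci]]$init[[sp]]
    if (is.null(v) || v <= 0)
      stop("per-curve init species '", sp, "' must start positive (curve ",
           ci, ")")
    p_names <- c(p_names, paste0(sp, ".", ci))
    p0 <- c(p0, log10(v))
    lo <- c(lo, log10(v * (1 - init_bounds_frac)))
    hi <- c(hi, log10(v * (1 + init_bounds_frac)))
  }
  names(p0) <- p_names

  obs <- unlist(lapply(experiments, `[[`, "signal"))
  resid_fn <- function(p) {
    names(p) <- p_names
    k <- unclass(start)
    k[free] <- 10^p[seq_along(free)]
    mod <- unlist(lapply(seq_along(experiments), function(ci) {
      exp <- experiments[[ci]]
      for (sp in free_init_shared) exp$init[[sp]] <- 10^p[[sp]]
      for (sp in free_init_per_curve)
        exp$init[[sp]] <- 10^p[[paste0(sp, ".", ci)]]
      eval_experiment(exp, mechanism, k, rtol, atol)
    }))
    mod - obs
  }

  ctrl <- utils::modifyList(list(ftol = 1e-10, ptol = 1e-8, maxiter = 200),
                            control)
  res <- minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lo, upper = hi,
                            control = do.call(minpack.lm::nls.lm.control,
                                              ctrl))
  p_hat <- res$par
  rss <- res$deviance
  n <- length(obs); np <- length(p_hat)
  sigma2 <- if (n > np) rss / (n - np) else 0
  # covariance of log10 parameters from J'J; delta method to natural scale
  h <- res$hessian
  ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
  cond_J <- if (min(ev) <= 0) Inf else sqrt(max(ev) / min(ev))
  cov_log <- tryCatch(solve(h) * sigma2,
                      error = function(e) matrix(NA_real_, np, np))
  est_nat <- 10^p_hat
  dnat <- est_nat * log(10)
  se_nat <- sqrt(pmax(diag(cov_log), 0)) * dnat
  vcov_nat <- cov_log * tcrossprod(dnat)
  dimnames(vcov_nat) <- list(p_names, p_names)

  converged <- res$info %in% 1:4
  at_bound <- p_hat <= lo + 1e-10 | p_hat >= hi - 1e-10
  if (any(at_bound))
    warning("parameter(s) at bound: ",
            paste(p_names[at_bound], collapse = ", "))
  identifiable <- is.finite(cond_J) && cond_J <= 1e8
  if (!identifiable)
    warning("Jacobian is ill-conditioned (condition number ",
            format(cond_J, digits = 3),
            "); some parameter combinations are not identifiable ",
            "and estimates are provisional")

  rates_hat <- unclass(start)
  rates_hat[free] <- est_nat[seq_along(free)]
  fitted_list <- lapply(seq_along(experiments), function(ci) {
    exp <- experiments[[ci]]
    for (sp in free_init_shared) exp$init[[sp]] <- 10^p_hat[[sp]]
    for (sp in free_init_per_curve)
      exp$init[[sp]] <- 10^p_hat[[paste0(sp, ".", ci)]]
    data.frame(time_s = exp$time_s, signal = exp$signal,
               fitted = eval_experiment(exp, mechanism, rates_hat,
                                        rtol, atol))
  })
  per_curve_rms <- vapply(fitted_list, function(d)
    sqrt(mean((d$signal - d$fitted)^2)), 0)

  structure(list(
    estimates = stats::setNames(est_nat, p_names),
    se = stats::setNames(se_nat, p_names),
    vcov = vcov_nat,
    rates = rates_hat, free = free,
    free_init_per_curve = free_init_per_curve,
    free_init_shared = free_init_shared,
    rss = rss, sigma = sqrt(sigma2), nobs = n,
    per_curve_rms = per_curve_rms,
    niter = res$niter, info = res$info, message = res$message,
    converged = converged, cond_J = cond_J, identifiable = identifiable,
    at_bound = stats::setNames(at_bound, p_names),
    experiments = experiments, mechanism = mechanism,
    fitted_curves = fitted_list,
    rtol = rtol, atol = atol,
    call = match.call()), class = "progress_fit")
}

#' Derived constants of a fitted model
#'
#' Composite quantities recomputed from the current estimates (never stored
#' independently): K_m, k_cat, k_cat/K_m, product and inhibitor K_i, and the
#' residence time tau = 1/k_off.
#'
#' @param object a \code{"progress_fit"}.
#' @param e0 optional enzyme total for Vmax.
#' @return named list, see \code{\link{derived_constants}}.
#' @export
derived.progress_fit <- function(object, e0 = NA_real_) {
  derived_constants(object$rates, e0)
}

#' @export
coef.progress_fit <- function(object, ...) object$estimates

#' @export
vcov.progress_fit <- function(object, ...) object$vcov

#' @export
fitted.progress_fit <- function(object, ...)
  unlist(lapply(object$fitted_curves, `[[`, "fitted"))

#' @export
residuals.progress_fit <- function(object, ...)
  unlist(lapply(object$fitted_curves, function(d) d$signal - d$fitted))

#' @export
deviance.progress_fit <- function(object, ...) object$rss

#' Model predictions on new time grids
#'
#' @param object a \code{"progress_fit"}.
#' @param times optional list of time vectors (one per experiment); default
#'   the data times.
#' @param ... unused.
#' @return list of data.frames \code{(time_s, fitted)}.
#' @export
predict.progress_fit <- function(object, times = NULL, ...) {
  lapply(seq_along(object$experiments), function(ci) {
    exp <- object$experiments[[ci]]
    if (!is.null(times)) exp$time_s <- times[[ci]]
    data.frame(time_s = exp$time_s,
               fitted = eval_experiment(exp, object$mechanism, object$rates,
                                        object$rtol, object$atol))
  })
}

#' @export
print.progress_fit <- function(x, digits = 4, ...) {
  cat("Global progress-curve fit (", length(x$experiments), " curve",
      if (length(x$experiments) > 1) "s", ", ", x$nobs, " points)\n",
      sep = "")
  cat(if (x$converged) "Converged" else
      paste0("NOT converged (", x$message, "); estimates provisional"),
      " in ", x$niter, " iterations; RSS = ",
      format(x$rss, digits = digits), "\n", sep = "")
  est <- cbind(estimate = x$estimates, se = x$se)
  print(signif(est, digits))
  d <- derived.progress_fit(x)
  if (length(d)) {
    cat("Derived:\n")
    for (nm in names(d))
      cat(sprintf("  %-8s %s\n", nm, format(d[[nm]], digits = digits)))
  }
  invisible(x)
}

#' @export
summary.progress_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.progress_fit")
}

#' @export
print.summary.progress_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  f <- x$fit
  cat("Per-curve RMS:", paste(signif(f$per_curve_rms, 3), collapse = ", "),
      "\n")
  cat("Jacobian condition number:", format(f$cond_J, digits = 3),
      if (!f$identifiable) " (ill-conditioned)", "\n")
  if (any(f$at_bound))
    cat("At bound:", paste(names(f$at_bound)[f$at_bound], collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
plot.progress_fit <- function(x, ...) {
  nexp <- length(x$fitted_curves)
  mf <- grDevices::n2mfrow(nexp)
  op <- graphics::par(mfrow = mf, mar = c(4, 4, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (ci in seq_len(nexp)) {
    d <- x$fitted_curves[[ci]]
    graphics::plot(d$time_s, d$signal, pch = 16, cex = 0.3, col = "grey40",
                   xlab = "time (s)", ylab = "signal",
                   main = x$experiments[[ci]]$label, ...)
    graphics::lines(d$time_s, d$fitted, col = "red", lwd = 1.5)
  }
  invisible(x)
}

#' Simulate noisy datasets from a fitted model
#'
#' @param object a \code{"progress_fit"}.
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param cv relative noise level applied to the fitted signal.
#' @param ... unused.
#' @return list of lists of data.frames \code{(time_s, signal)}.
#' @export
simulate.progress_fit <- function(object, nsim = 1, seed = NULL, cv = 0.01,
                                  ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    lapply(object$fitted_curves, function(d)
      data.frame(time_s = d$time_s,
                 signal = d$fitted * (1 + stats::rnorm(nrow(d), sd = cv)))))
}

#' Stage 1: hydrolysis and product-inhibition parameters from a
#' sequential-addition series
#'
#' Fits the van Slyke--Cullen + product-inhibition scheme to the continuous
#' multi-addition trace (shared cuvette state - the accumulating
#' thiocholine-TNB - is the point of the design): frees k1 (= kcat/Km),
#' k2 (= kcat) and the product off-rate k4, with the product association
#' rate k3 fixed at the diffusion limit so that only the ratio K_i,P = k4/k3
#' is identified.
#'
#' @param curves tidy curve data.frame from
#'   \code{\link{generate_curves}}(\code{gal_design("product_series")}), or
#'   any single continuous trace with the design attached.
#' @param design the generating \code{\link{assay_design}}; defaults to the
#'   attached attribute.
#' @param start named starting guesses for \code{c(k1, k2, k4)}.
#' @param k3 fixed product association rate (1/(M s)).
#' @param ... passed to \code{\link{fit_progress}}.
#' @return a \code{"progress_fit"}.
#' @export
fit_stage1 <- function(curves, design = attr(curves, "design"),
                       start = c(k1 = 1e8, k2 = 1000, k4 = 1000),
                       k3 = 2e8, ...) {
  if (is.null(design)) stop("'design' is required (none attached to curves)")
  if (any(curves$detection == "absorbance"))
    curves <- to_concentration(curves)
  curves <- curves[curves$replicate == min(curves$replicate), , drop = FALSE]
  mech <- build_scheme("slyke_cullen_product")
  phases <- rep(list(list(duration = design$addition_interval_s,
                          additions = c(S = design$s0[1]))),
                design$n_additions)
  exp <- kin_experiment(curves$time_s, curves$signal,
                        init = c(E = design$e0), phases = phases,
                        label = "product series")
  fit_progress(list(exp), mech,
               start = c(start, k3 = k3), free = names(start), ...)
}

#' Stage 2: inhibitor on/off rates from enzyme-initiated inhibited curves
#'
#' With the hydrolysis and product parameters constrained to their stage-1
#' values, fits the inhibitor microscopic rate constants k5 (k_on) and
#' k6 (k_off) - and optionally the per-curve substrate and shared enzyme
#' concentrations - to the full inhibited progress curves.  The
#' pre-steady-state onset of inhibition is what identifies k5 and k6
#' separately; K_i = k6/k5 and tau = 1/k6 follow.
#'
#' @param curves tidy curve data.frame from
#'   \code{\link{generate_curves}}(\code{gal_design("gal_fit_series")}).
#' @param stage1 a stage-1 \code{"progress_fit"}, or a named vector
#'   containing k1..k4.
#' @param design the generating design; defaults to the attached attribute.
#' @param start starting guesses for \code{c(k5, k6)}.
#' @param fit_s0 fit each curve's substrate load (+/-20%).
#' @param fit_e0 fit a shared enzyme concentration (+/-20%).
#' @param upper optional upper bounds; a k5 bound at the diffusion limit is
#'   applied by default (warned about if hit).
#' @param ... passed to \code{\link{fit_progress}}.
#' @return a \code{"progress_fit"}.
#' @export
fit_stage2 <- function(curves, stage1, design = attr(curves, "design"),
                       start = c(k5 = 1e6, k6 = 0.1),
                       fit_s0 = FALSE, fit_e0 = FALSE,
                       upper = c(k5 = 1e9), ...) {
  if (is.null(design)) stop("'design' is required (none attached to curves)")
  if (any(curves$detection == "absorbance"))
    curves <- to_concentration(curves)
  fixed <- if (inherits(stage1, "progress_fit")) stage1$rates else stage1
  need <- c("k1", "k2", "k3", "k4")
  if (!all(need %in% names(fixed)))
    stop("stage-1 result must provide ", paste(need, collapse = ", "))
  curves <- curves[curves$replicate == min(curves$replicate), , drop = FALSE]
  mech <- build_scheme("slyke_cullen_product_inhibitor")
  conds <- unique(curves[, c("s0_M", "i0_M")])
  if (max(conds$i0_M) == 0)
    warning("no inhibited curves: k5 and k6 are unidentifiable from an ",
            "uninhibited dataset")
  exps <- lapply(seq_len(nrow(conds)), function(ci) {
    d <- curves[curves$s0_M == conds$s0_M[ci] &
                curves$i0_M == conds$i0_M[ci], ]
    init <- c(E = design$e0, S = conds$s0_M[ci])
    if (conds$i0_M[ci] > 0) init <- c(init, I = conds$i0_M[ci])
    kin_experiment(d$time_s, d$signal, init = init,
                   label = sprintf("i0 = %.3g nM", conds$i0_M[ci] * 1e9))
  })
  fit_progress(exps, mech,
               start = c(fixed[need], start), free = names(start),
               upper = upper,
               free_init_per_curve = if (fit_s0) "S" else character(0),
               free_init_shared = if (fit_e0) "E" else character(0),
               ...)
}

#' Residual-norm profile of one parameter
#'
#' Re-optimizes all other free parameters at each grid value of the chosen
#' parameter and returns the profile of the residual norm - a more honest
#' uncertainty assessment than the linearized standard errors when the
#' problem is poorly conditioned.
#'
#' @param fit a converged \code{"progress_fit"}.
#' @param parameter a free rate-constant label.
#' @param grid values (natural scale) at which to profile.
#' @return data.frame \code{(value, rss, converged)}.
#' @export
profile_uncertainty <- function(fit, parameter, grid) {
  stopifnot(inherits(fit, "progress_fit"))
  if (!fit$converged) stop("profile requires a converged fit")
  if (!(parameter %in% fit$free))
    stop("'", parameter, "' is not a free parameter of this fit")
  other <- setdiff(fit$free, parameter)
  rows <- lapply(grid, function(val) {
    start <- fit$rates
    start[parameter] <- val
    res <- tryCatch({
      if (length(other)) {
        f <- fit_progress(fit$experiments, fit$mechanism, start,
                          free = other,
                          free_init_per_curve = fit$free_init_per_curve,
                          free_init_shared = fit$free_init_shared,
                          rtol = fit$rtol, atol = fit$atol)
        c(f$rss, f$converged)
      } else {
        r <- unlist(lapply(fit$experiments, function(exp)
          eval_experiment(exp, fit$mechanism, start, fit$rtol, fit$atol) -
            exp$signal))
        c(sum(r^2), TRUE)
      }
    }, error = function(e) c(NA_real_, FALSE))
    data.frame(value = val, rss = res[1], converged = as.logical(res[2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
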