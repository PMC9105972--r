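# Conventional steady-state analysis: closed-form rate laws, initial
# velocities, weighted double-reciprocal regression, Dixon and
# Cornish-Bowden replots, and the k_off scan that exposes how long residence
# times make a competitive inhibitor look mixed or noncompetitive.

#' Closed-form competitive steady-state rate
#'
#' v = Vmax * S / (S + Km * (1 + I/Ki)): the true steady-state initial rate
#' for a rapidly equilibrating competitive inhibitor.
#'
#' @param Vmax maximal velocity (M/s).
#' @param Km Michaelis constant (M).
#' @param S substrate concentration (M).
#' @param I inhibitor concentration (M).
#' @param Ki competitive inhibition constant (M).
#' @return rate (M/s); vectorized over S and I.
#' @export
v_ss_competitive <- function(Vmax, Km, S, I, Ki) {
  stopifnot(Km > 0, Ki > 0)
  Vmax * S / (S + Km * (1 + I / Ki))
}

#' Measured initial rate after pre-incubation with a slow-dissociating
#' inhibitor
#'
#' If the EI complex does not dissociate on the measurement timescale, only
#' the fraction 1/(1 + I/Ki) of the enzyme is available when substrate is
#' added, so the measured rate is
#' v = Vmax/(1 + I/Ki) * S/(S + Km) - formally identical to pure
#' noncompetitive inhibition (Kiu = Kic).  (The limiting maximal velocity is
#' Vimax = Vmax/(1 + I/Ki).)
#'
#' @inheritParams v_ss_competitive
#' @return rate (M/s).
#' @export
v_meas_preincubated <- function(Vmax, Km, S, I, Ki) {
  stopifnot(Km > 0, Ki > 0)
  Vmax / (1 + I / Ki) * S / (S + Km)
}

#' Rapid-equilibrium enzyme partition
#'
#' Fractions of total enzyme in the free, substrate-bound and
#' inhibitor-bound forms under the rapid-equilibrium and free-ligand
#' approximations: fE = 1/(1 + S/Km + I/Ki), fES = (S/Km) fE,
#' fEI = (I/Ki) fE.  At S = Km and I = Ki each form holds one third of the
#' enzyme; before substrate addition (S = 0, I = Ki) half of it is EI.
#'
#' @inheritParams v_ss_competitive
#' @return named vector \code{c(fE, fES, fEI)} summing to 1.
#' @export
equilibrium_fractions <- function(S, Km, I, Ki) {
  if (Km <= 0 || Ki <= 0) stop("'Km' and 'Ki' must be positive")
  fE <- 1 / (1 + S / Km + I / Ki)
  c(fE = fE, fES = (S / Km) * fE, fEI = (I / Ki) * fE)
}

#' Residence time and first-order dissociation
#'
#' tau = 1/k_off is the mean lifetime of the EI complex.  With rebinding
#' neglected, the fraction of bound inhibitor dissociated by time t is
#' 1 - exp(-k_off t); 95% dissociation therefore takes ln(20) ~ 3.0 tau
#' (3.5 tau corresponds to ~97%).
#'
#' @param k_off dissociation rate constant (1/s), positive.
#' @return residence time in seconds.
#' @export
residence_time <- function(k_off) {
  if (any(k_off <= 0)) stop("'k_off' must be positive")
  1 / k_off
}

#' @rdname residence_time
#' @param t time since reaction start (s), non-negative.
#' @return \code{fraction_dissociated}: fraction in [0, 1).
#' @export
fraction_dissociated <- function(t, k_off) {
  if (any(k_off <= 0)) stop("'k_off' must be positive")
  if (any(t < 0)) stop("'t' must be non-negative")
  1 - exp(-k_off * t)
}

#' Initial velocity from a progress curve
#'
#' Two operational definitions of the "initial" velocity an experimenter
#' extracts when detection starts only after the instrument dead time:
#' \describe{
#'   \item{\code{"chord"} (default)}{the straight line from the reaction
#'     start (t = 0, where the blank fixes the signal) to the first reading
#'     at t1 = max(dead_time, window): v = (signal(t1) - signal(0)) / t1.
#'     This is the dashed "slope of the first seconds of reaction" line of a
#'     standard assay trace, and the definition under which a 10 s dead
#'     time hides - or reveals - slow EI dissociation.}
#'   \item{\code{"window"}}{ordinary least-squares slope of signal versus
#'     time over [dead_time, dead_time + window] (needs >= 3 samples); an
#'     instantaneous-rate estimate that ignores the unobserved burst.}
#' }
#'
#' @param curve data.frame with \code{time_s} and \code{signal} columns, in
#'   concentration units.
#' @param dead_time_s dead time (s).
#' @param window_s window length (s).
#' @param mode \code{"chord"} or \code{"window"}.
#' @return slope (M/s).
#' @export
initial_velocity <- function(curve, dead_time_s = 10, window_s = 10,
                             mode = c("chord", "window")) {
  mode <- match.arg(mode)
  tt <- curve$time_s
  if (is.unsorted(tt)) stop("curve times must be non-decreasing")
  if (mode == "chord") {
    t1 <- max(dead_time_s, window_s)
    i1 <- which(tt >= t1 - 1e-9)[1]
    if (is.na(i1)) stop("no sample at or after t = ", t1, " s")
    s0 <- if (any(tt <= 1e-9)) curve$signal[which(tt <= 1e-9)[1]] else 0
    return(unname((curve$signal[i1] - s0) / tt[i1]))
  }
  sel <- tt >= dead_time_s & tt <= dead_time_s + window_s + 1e-9
  if (sum(sel) < 3L)
    stop("fewer than 3 samples inside the velocity window [",
         dead_time_s, ", ", dead_time_s + window_s, "] s")
  x <- tt[sel]; y <- curve$signal[sel]
  unname(stats::cov(x, y) / stats::var(x))
}

#' Initial-velocity dataset from generated curves
#'
#' Applies \code{\link{initial_velocity}} per (s0, i0, replicate) condition;
#' absorbance curves are converted to concentration first.
#'
#' @param curves curve data.frame from \code{\link{generate_curves}} or
#'   \code{\link{read_curves}}.
#' @param dead_time_s,window_s,mode velocity extraction settings (see
#'   \code{\link{initial_velocity}}); the dead time defaults to the attached
#'   design's when present.
#' @return data.frame \code{(s0_M, i0_M, replicate, v)}.
#' @export
velocities <- function(curves, dead_time_s = NULL, window_s = 10,
                       mode = c("chord", "window")) {
  mode <- match.arg(mode)
  des <- attr(curves, "design")
  if (is.null(dead_time_s))
    dead_time_s <- if (!is.null(des)) des$dead_time_s else 10
  if (any(curves$detection == "absorbance"))
    curves <- to_concentration(curves)
  sp <- split(curves, list(curves$s0_M, curves$i0_M, curves$replicate),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    s0_M = d$s0_M[1], i0_M = d$i0_M[1], replicate = d$replicate[1],
    v = initial_velocity(d, dead_time_s, window_s, mode))))
  out <- out[order(out$i0_M, out$s0_M, out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Weighted Lineweaver-Burk regression per inhibitor level
#'
#' Fits 1/v = slope * (1/S) + intercept for each inhibitor concentration.
#' The \code{"relative_variance"} weighting assumes var(v) = (c v)^2
#' (constant percentage error), which propagates to var(1/v) ~ (c/v)^2 and
#' hence to weights proportional to v^2 in reciprocal space.
#'
#' @param dataset velocity data.frame \code{(s0_M, i0_M, v)} (replicates are
#'   used as individual records).
#' @param weighting \code{"relative_variance"} or \code{"unweighted"}.
#' @return data.frame \code{(i0_M, slope, intercept, se_slope,
#'   se_intercept, n)}; zero/negative velocities are dropped with a warning.
#' @export
lineweaver_burk <- function(dataset,
                            weighting = c("relative_variance", "unweighted")) {
  weighting <- match.arg(weighting)
  bad <- dataset$v <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with v <= 0 excluded from the reciprocal fit")
    dataset <- dataset[!bad, , drop = FALSE]
  }
  res <- lapply(split(dataset, dataset$i0_M), function(d) {
    if (length(unique(d$s0_M)) < 2L)
      stop("need >= 2 distinct substrate concentrations per inhibitor level")
    w <- if (weighting == "relative_variance") d$v^2 else NULL
    fit <- stats::lm(I(1 / v) ~ I(1 / s0_M), data = d, weights = w)
    cf <- stats::coef(fit)
    # exact synthetic data produce zero-residual fits; the perfect-fit
    # warning from summary.lm is expected there and carries no information
    se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
    data.frame(i0_M = d$i0_M[1], slope = unname(cf[2]),
               intercept = unname(cf[1]), se_slope = unname(se[2]),
               se_intercept = unname(se[1]), n = nrow(d))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$i0_M), ]
  rownames(out) <- NULL
  out
}

# straight-line replot of y(I) vs I; returns -x intercept, or Inf when the
# replot slope is non-positive or negligible relative to intercept/I_max
replot_intersect <- function(i0, y, rel_tol = 1e-3) {
  if (length(i0) < 3L)
    stop("need >= 3 inhibitor levels (including 0) for a replot")
  fit <- stats::lm(y ~ i0)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (b <= 0 || b < rel_tol * a / max(i0)) return(Inf)
  a / b
}

#' Dixon and Cornish-Bowden replots
#'
#' \code{dixon_kic} re-plots Lineweaver-Burk slopes against [I]; the negated
#' x-axis intersection estimates the competitive inhibition constant K_ic.
#' \code{cornish_bowden_kiu} does the same with the apparent 1/Vmax
#' (the LB intercepts), estimating the uncompetitive constant K_iu.  A
#' non-positive or negligible replot slope (relative slope below
#' \code{rel_tol} of intercept/I_max) means no detectable component and
#' returns \code{Inf}.  Replot lines are unweighted.
#'
#' @param lb_results output of \code{\link{lineweaver_burk}} covering at
#'   least 3 inhibitor levels including 0.
#' @param rel_tol relative-slope threshold below which the component is
#'   reported as absent.
#' @return the inhibition constant (M), possibly \code{Inf}.
#' @export
dixon_kic <- function(lb_results, rel_tol = 1e-3) {
  replot_intersect(lb_results$i0_M, lb_results$slope, rel_tol)
}

#' @rdname dixon_kic
#' @export
cornish_bowden_kiu <- function(lb_results, rel_tol = 1e-3) {
  replot_intersect(lb_results$i0_M, lb_results$intercept, rel_tol)
}

#' Classify an inhibition mechanism from its apparent constants
#'
#' Labels the mechanism by the K_iu/K_ic ratio: competitive when
#' K_iu/K_ic >= \code{comp}, noncompetitive when K_iu/K_ic <= \code{noncomp},
#' uncompetitive when K_ic/K_iu >= \code{comp}, otherwise mixed; "none" when
#' neither component is detectable.  Thresholds are labels only - they never
#' enter any numeric fit.
#'
#' @param K_ic,K_iu apparent inhibition constants (M), \code{Inf} allowed.
#' @param comp,noncomp classification thresholds (defaults 10 and 1.25).
#' @return one of \code{"competitive"}, \code{"mixed"},
#'   \code{"noncompetitive"}, \code{"uncompetitive"}, \code{"none"}.
#' @export
classify_inhibition <- function(K_ic, K_iu, comp = 10, noncomp = 1.25) {
  if (any(c(K_ic, K_iu) <= 0)) stop("inhibition constants must be positive")
  if (is.infinite(K_ic) && is.infinite(K_iu)) return("none")
  ratio <- K_iu / K_ic
  if (is.infinite(K_iu) || ratio >= comp) return("competitive")
  if (is.infinite(K_ic) || 1 / ratio >= comp) return("uncompetitive")
  if (ratio <= noncomp && ratio >= 1 / noncomp) return("noncompetitive")
  "mixed"
}

#' Steady-state inhibition analysis of a velocity dataset
#'
#' The conventional pipeline: weighted Lineweaver-Burk regression per
#' inhibitor level, Dixon replot for K_ic, Cornish-Bowden replot for K_iu,
#' and mechanism classification.
#'
#' @param dataset velocity data.frame \code{(s0_M, i0_M, v)}.
#' @param weighting passed to \code{\link{lineweaver_burk}}.
#' @param rel_tol passed to the replots.
#' @param comp,noncomp classification thresholds.
#' @return object of class \code{"inhibition_fit"}: list with \code{lb}
#'   (per-level lines), \code{K_ic}, \code{K_iu}, \code{classification}.
#' @export
fit_inhibition <- function(dataset, weighting = "relative_variance",
                           rel_tol = 1e-3, comp = 10, noncomp = 1.25) {
  lb <- lineweaver_burk(dataset, weighting)
  K_ic <- dixon_kic(lb, rel_tol)
  K_iu <- cornish_bowden_kiu(lb, rel_tol)
  structure(list(lb = lb, K_ic = K_ic, K_iu = K_iu,
                 classification = classify_inhibition(K_ic, K_iu,
                                                      comp, noncomp)),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat("Steady-state inhibition analysis\n")
  fmt <- function(k) if (is.infinite(k)) "not detectable"
         else sprintf("%.4g M", k)
  cat("  K_ic (Dixon replot):          ", fmt(x$K_ic), "\n")
  cat("  K_iu (Cornish-Bowden replot): ", fmt(x$K_iu), "\n")
  cat("  classification:               ", x$classification, "\n")
  cat("  inhibitor levels:             ", nrow(x$lb), "\n")
  invisible(x)
}

#' Export an inhibition analysis as JSON
#'
#' Infinite constants are reported as an absent component (empty value plus
#' a boolean flag), never as a numeric sentinel.
#'
#' @param x an \code{"inhibition_fit"}.
#' @param path output JSON file.
#' @export
write_inhibition <- function(x, path) {
  stopifnot(inherits(x, "inhibition_fit"))
  doc <- list(
    K_ic_M = if (is.finite(x$K_ic)) x$K_ic else NULL,
    K_ic_detected = is.finite(x$K_ic),
    K_iu_M = if (is.finite(x$K_iu)) x$K_iu else NULL,
    K_iu_detected = is.finite(x$K_iu),
    classification = x$classification,
    lineweaver_burk = x$lb)
  doc <- Filter(Negate(is.null), doc)   # absent component -> absent key
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Approach of a pre-incubated slow-unbinder system to its steady-state rate
#'
#' Simulates the substrate-initiated ES time course after extensive E-I
#' pre-incubation for a slow-dissociating inhibitor and for a matched
#' fast-dissociating reference of identical K_i, and reports the first time
#' the slow system's ES occupancy (equivalently, its instantaneous rate
#' k_cat.[ES]) comes within \code{threshold} of the reference trajectory.
#' Upon substrate addition the EI equilibrium is displaced by mass action;
#' the slow system recovers activity at a rate bounded by k_off, so this
#' time grows with the residence time.
#'
#' @param k_off slow-unbinder dissociation rate (1/s).
#' @param k_off_ref fast reference dissociation rate (1/s), same K_i.
#' @param s0,i0 substrate and inhibitor concentrations (M).
#' @param threshold relative closeness criterion.
#' @param duration_s,dt_s simulated reaction window and sampling step.
#' @return list with \code{time} (s, \code{NA} if not reached),
#'   \code{threshold}, and the two sampled ES trajectories.
#' @export
approach_to_steady_state <- function(k_off = 1e-2, k_off_ref = 1e3,
                                     s0 = 200e-6, i0 = 1e-6,
                                     threshold = 0.03,
                                     duration_s = 600, dt_s = 0.5) {
  sim <- function(k) {
    fd <- preincubation_design(k)
    phases <- list(
      list(duration = fd$design$preincubation_s),
      list(duration = duration_s, additions = c(S = s0),
           times = seq(0, duration_s, by = dt_s)))
    tr <- run_protocol(fd$mechanism, fd$rates, c(E = fd$design$e0, I = i0),
                       phases, atol = 1e-6 * fd$design$e0)
    tr <- tr[tr$phase == 2, , drop = FALSE]
    tr$time_s <- tr$time_s - min(tr$time_s)
    tr
  }
  slow <- sim(k_off)
  ref <- sim(k_off_ref)
  rel <- abs(slow$ES - ref$ES) / ref$ES
  hit <- which(rel <= threshold)[1]
  list(time = if (is.na(hit)) NA_real_ else slow$time_s[hit],
       threshold = threshold,
       slow = slow[, c("time_s", "ES")], ref = ref[, c("time_s", "ES")])
}

#' Dissociation-rate scan of the pre-incubation artifact
#'
#' For each k_off: build the pre-incubated synthetic design
#' (\code{\link{preincubation_design}}, K_i fixed at 1 uM), generate noiseless
#' curves, extract windowed initial velocities, run the Lineweaver-Burk /
#' Dixon / Cornish-Bowden analysis, and record the apparent constants.  The
#' scan reproduces the emergence of a spurious uncompetitive component as
#' the residence time grows: fast unbinders classify competitive, slow
#' unbinders purely noncompetitive (at the true K_i), with an apparent
#' mixed-type band in between.
#'
#' @param k_off_grid dissociation rates to scan (1/s), inside (1e-5, 1e3).
#' @param s0,i0 optional overrides of the design concentration grids; the
#'   default substrate grid is the 2--200 uM list used for the scan figure.
#' @param dead_time_s,window_s,mode velocity extraction (see
#'   \code{\link{initial_velocity}}).
#' @param weighting passed to \code{\link{lineweaver_burk}}.
#' @return data.frame \code{(k_off, K_ic_app, K_iu_app, ratio,
#'   classification)}.
#' @export
koff_scan <- function(k_off_grid,
                      s0 = c(2, 5, 10, 20, 50, 100, 150, 200) * 1e-6,
                      i0 = c(0, 0.5, 1, 2, 5, 10, 20, 50) * 1e-6,
                      dead_time_s = 10, window_s = 10,
                      mode = c("chord", "window"),
                      weighting = "relative_variance") {
  mode <- match.arg(mode)
  rows <- lapply(k_off_grid, function(k_off) {
    fd <- preincubation_design(k_off, s0 = s0, i0 = i0)
    curves <- generate_curves(fd$design, fd$mechanism, fd$rates)
    vd <- velocities(curves, dead_time_s, window_s, mode)
    fit <- fit_inhibition(vd, weighting)
    data.frame(k_off = k_off, K_ic_app = fit$K_ic, K_iu_app = fit$K_iu,
               ratio = fit$K_iu / fit$K_ic,
               classification = fit$classification)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
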