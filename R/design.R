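# Synthetic assay designs and progress-curve generation.

#' Assay design
#'
#' Describes an initial-velocity or progress-curve experiment: reagent
#' concentrations, order of addition, pre-incubation, instrument dead time,
#' sampling and detection mode.  All concentrations in molar, times in
#' seconds.
#'
#' @param e0 total enzyme (M).
#' @param s0 substrate concentrations (M), one curve set per value.
#' @param i0 inhibitor concentrations (M); include 0 for the uninhibited
#'   reference.
#' @param p0 initial product concentration (M).
#' @param order \code{"substrate_initiated"} (enzyme + inhibitor
#'   pre-incubated, substrate added at t = 0) or \code{"enzyme_initiated"}
#'   (all reagents mixed at t = 0, no E-I pre-equilibration).
#' @param preincubation_s E-I pre-incubation time (s); only meaningful for
#'   substrate-initiated assays.
#' @param dead_time_s instrument dead time (s) between reaction start and
#'   first usable datum (hides fast relaxations from initial-velocity
#'   analysis).
#' @param duration_s monitored reaction time (s); must exceed the dead time.
#' @param sample_dt_s sampling interval (s).
#' @param replicates number of replicate curves per condition.
#' @param detection \code{"concentration"} (M of detected product) or
#'   \code{"absorbance"} (A412 via \code{\link{ellman_params}}).
#' @param n_additions number of sequential substrate additions (each of
#'   \code{s0}, spaced \code{addition_interval_s} apart) measured as one
#'   continuous trace in the same cuvette; default 1.
#' @param addition_interval_s time between sequential additions (s);
#'   defaults to \code{duration_s / n_additions}.
#' @return object of class \code{"assay_design"}.
#' @export
assay_design <- function(e0, s0, i0 = 0, p0 = 0,
                         order = c("substrate_initiated", "enzyme_initiated"),
                         preincubation_s = 0, dead_time_s = 10,
                         duration_s, sample_dt_s = 1, replicates = 1L,
                         detection = c("concentration", "absorbance"),
                         n_additions = 1L, addition_interval_s = NULL) {
  order <- match.arg(order)
  detection <- match.arg(detection)
  conc <- c(e0, s0, i0, p0)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative")
  if (!is.finite(duration_s) || duration_s <= dead_time_s)
    stop("'duration_s' must exceed 'dead_time_s'")
  if (replicates < 1L) stop("'replicates' must be >= 1")
  if (n_additions < 1L) stop("'n_additions' must be >= 1")
  if (is.null(addition_interval_s)) addition_interval_s <-
      duration_s / n_additions
  structure(list(e0 = e0, s0 = s0, i0 = i0, p0 = p0, order = order,
                 preincubation_s = preincubation_s,
                 dead_time_s = dead_time_s, duration_s = duration_s,
                 sample_dt_s = sample_dt_s,
                 replicates = as.integer(replicates), detection = detection,
                 n_additions = as.integer(n_additions),
                 addition_interval_s = addition_interval_s),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Assay design (", x$order, ")\n", sep = "")
  cat(sprintf("  e0 = %g M; s0 = %s M; i0 = %s M\n", x$e0,
              paste(signif(x$s0, 3), collapse = ", "),
              paste(signif(x$i0, 3), collapse = ", ")))
  cat(sprintf("  pre-incubation %g s, dead time %g s, duration %g s, dt %g s\n",
              x$preincubation_s, x$dead_time_s, x$duration_s, x$sample_dt_s))
  cat(sprintf("  replicates %d, detection %s", x$replicates, x$detection))
  if (x$n_additions > 1L)
    cat(sprintf(", %d sequential additions every %g s",
                x$n_additions, x$addition_interval_s))
  cat("\n")
  invisible(x)
}

#' Ellman detection parameters
#'
#' Thiocholine reacts stoichiometrically with DTNB to give the 412 nm
#' thiocholine-TNB chromophore; absorbance A = epsilon * path * [P].
#'
#' @param epsilon molar extinction coefficient (1/(M cm)); default 13600.
#' @param path_cm optical path length (cm).
#' @export
ellman_params <- function(epsilon = 13600, path_cm = 1) {
  if (epsilon <= 0 || path_cm <= 0)
    stop("'epsilon' and 'path_cm' must be positive")
  structure(list(epsilon = epsilon, path_cm = path_cm),
            class = "ellman_params")
}

#' Measurement noise model
#'
#' Gaussian noise applied to generated signals: an additive component with
#' standard deviation \code{sd_abs} (absorbance units) and a relative
#' component with coefficient of variation \code{cv}.  Identical seeds give
#' identical datasets; per-curve child seeds are derived by a stable hash of
#' (s0, i0, replicate) so the result does not depend on generation order.
#'
#' @param sd_abs additive sd in absorbance units (converted through the
#'   extinction coefficient when the detection mode is concentration).
#' @param cv relative sd (dimensionless).
#' @param seed integer master seed.
#' @export
noise_model <- function(sd_abs = 0, cv = 0, seed = 1L) {
  if (sd_abs < 0 || cv < 0) stop("'sd_abs' and 'cv' must be >= 0")
  structure(list(sd_abs = sd_abs, cv = cv, seed = as.integer(seed)),
            class = "noise_model")
}

# stable string hash -> integer in [0, 2^31-2]; insertion-order independent
child_seed <- function(master, s0, i0, replicate) {
  key <- sprintf("%.9e|%.9e|%d", s0, i0, as.integer(replicate))
  h <- 0
  for (b in as.integer(charToRaw(key))) h <- (h * 131 + b) %% 2147483629
  as.integer((master %% 2147483629 + h) %% 2147483629)
}

#' Simulated pre-incubation initial-velocity experiment design
#'
#' The synthetic study of a hypothetical Michaelis--Menten enzyme
#' (K_m ~ 10 uM, k_cat = 1000 1/s) inhibited by a competitive inhibitor of
#' K_i = 1 uM whose dissociation rate is scanned: ES association/dissociation
#' constants are 1e8 1/(M s) and 1 1/s, k_on = k_off / 1e-6 M so that
#' K_i stays fixed while the residence time varies.  Enzyme and inhibitor are
#' pre-incubated for 1e6 s, the reaction is started with substrate, and
#' detection begins after a 10 s dead time.
#'
#' @param k_off inhibitor dissociation rate constant (1/s), in [1e-5, 1e3].
#' @param s0 substrate grid (M); default the 9-level 1--200 uM list.
#' @param i0 inhibitor grid (M), including the uninhibited 0.
#' @return list with \code{mechanism}, \code{rates} and \code{design}.
#' @export
preincubation_design <- function(
    k_off,
    s0 = c(1, 2, 5, 10, 20, 50, 100, 150, 200) * 1e-6,
    i0 = c(0, 0.5, 1, 2, 5, 10, 20, 50) * 1e-6) {
  if (!is.finite(k_off) || k_off < 1e-5 || k_off > 1e3)
    stop("'k_off' must lie in [1e-5, 1e3] 1/s")
  mech <- build_scheme("competitive_mm")
  rates <- rate_set(c(ks_on = 1e8, ks_off = 1, kcat = 1000,
                      kon = k_off / 1e-6, koff = k_off), mech)
  design <- assay_design(e0 = 100e-12, s0 = s0, i0 = i0,
                         order = "substrate_initiated",
                         preincubation_s = 1e6, dead_time_s = 10,
                         duration_s = 20, sample_dt_s = 0.5)
  list(mechanism = mech, rates = rates, design = design)
}

#' Published TcAChE / galantamine rate-constant set
#'
#' Rate constants for the van Slyke--Cullen + product-inhibition + inhibitor
#' scheme (\code{build_scheme("slyke_cullen_product_inhibitor")}) at the
#' values reported for Torpedo californica acetylcholinesterase inhibited by
#' galantamine: k1 = kcat/Km, k2 = kcat, k3 fixed at the diffusion limit with
#' k4 = k3 * Ki_P, k5 = k_on and k6 = k5 * Ki.
#'
#' @param kcat_Km apparent bimolecular constant k1 (1/(M s)).
#' @param kcat catalytic constant k2 (1/s).
#' @param k3 product association rate (1/(M s)), diffusion-limited.
#' @param Ki_P competitive inhibition constant of thiocholine-TNB (M).
#' @param k_on inhibitor association rate k5 (1/(M s)).
#' @param Ki inhibitor dissociation constant k6/k5 (M).
#' @return named \code{\link{rate_set}} with k1..k6.
#' @export
tcache_rates <- function(kcat_Km = 3.73e8, kcat = 2965, k3 = 2e8,
                         Ki_P = 21.54e-6, k_on = 1.9e6, Ki = 8.45e-9) {
  rate_set(c(k1 = kcat_Km, k2 = kcat, k3 = k3, k4 = k3 * Ki_P,
             k5 = k_on, k6 = k_on * Ki),
           build_scheme("slyke_cullen_product_inhibitor"))
}

#' Galantamine Ellman-assay designs
#'
#' The four experiment layouts of the TcAChE/galantamine study:
#' \describe{
#'   \item{\code{enzyme_initiated}}{200 pM enzyme added last; ATCh
#'     10--200 uM; GAL 0/50/100/200/400 nM; 60 s monitored, velocities from
#'     the first 10 s.}
#'   \item{\code{substrate_initiated}}{50 pM enzyme pre-incubated 20 min
#'     with GAL 0/5/10/20/30 nM; same substrate grid.}
#'   \item{\code{product_series}}{five consecutive 35 uM ATCh additions in
#'     the same cuvette (200 pM enzyme), accumulating 0 to ~140 uM
#'     thiocholine-TNB; one continuous trace for the product-inhibition /
#'     Michaelian-parameter fit.}
#'   \item{\code{gal_fit_series}}{200 pM enzyme, 50 uM ATCh, GAL
#'     0/15/30/60/120/180 nM, enzyme-initiated, monitored up to 33 min; the
#'     global-fit dataset.}
#' }
#'
#' @param variant one of the four names above.
#' @return an \code{\link{assay_design}}.
#' @export
gal_design <- function(variant = c("enzyme_initiated", "substrate_initiated",
                                   "product_series", "gal_fit_series")) {
  variant <- match.arg(variant)
  s_grid <- c(10, 20, 50, 100, 200) * 1e-6
  switch(variant,
    enzyme_initiated = assay_design(
      e0 = 200e-12, s0 = s_grid, i0 = c(0, 50, 100, 200, 400) * 1e-9,
      order = "enzyme_initiated", dead_time_s = 0,
      duration_s = 60, sample_dt_s = 0.5),
    substrate_initiated = assay_design(
      e0 = 50e-12, s0 = s_grid, i0 = c(0, 5, 10, 20, 30) * 1e-9,
      order = "substrate_initiated", preincubation_s = 1200,
      dead_time_s = 0, duration_s = 60, sample_dt_s = 0.5),
    product_series = assay_design(
      e0 = 200e-12, s0 = 35e-6, i0 = 0,
      order = "enzyme_initiated", dead_time_s = 10,
      duration_s = 2500, sample_dt_s = 1,
      n_additions = 5L, addition_interval_s = 500),
    gal_fit_series = assay_design(
      e0 = 200e-12, s0 = 50e-6, i0 = c(0, 15, 30, 60, 120, 180) * 1e-9,
      order = "enzyme_initiated", dead_time_s = 0,
      duration_s = 1980, sample_dt_s = 1))
}

#' Generate simulated progress curves for a design
#'
#' Runs the multi-phase protocol implied by the design for every
#' (s0, i0, replicate) condition and samples the detected product:
#' substrate-initiated conditions pre-equilibrate E + I for
#' \code{preincubation_s} then add substrate at t = 0; enzyme-initiated
#' conditions start with all species present and zero complexes (mixing is
#' instantaneous).  Detection conversion and Gaussian noise are applied per
#' replicate; generation is deterministic under a fixed master seed and
#' independent of condition order.
#'
#' @param design an \code{\link{assay_design}}.
#' @param mechanism a \code{\link{mechanism}} whose species include E, S, P,
#'   and I/EI when inhibitor concentrations are non-zero.
#' @param rates named rate vector for the mechanism.
#' @param noise a \code{\link{noise_model}}.
#' @param ellman an \code{\link{ellman_params}} (used when
#'   \code{design$detection == "absorbance"} or \code{sd_abs > 0}).
#' @param rtol relative integration tolerance.
#' @param atol absolute tolerance; default shrinks to \code{1e-6 * e0} below
#'   1e-12 M so that sub-nanomolar enzyme species keep at least four
#'   significant digits.
#' @param signal_species detected species label; default \code{"P"}.
#' @return data.frame with columns \code{time_s}, \code{signal},
#'   \code{s0_M}, \code{i0_M}, \code{replicate}, \code{detection}; the
#'   Ellman parameters and design are attached as attributes.
#' @export
generate_curves <- function(design, mechanism, rates,
                            noise = noise_model(),
                            ellman = ellman_params(),
                            rtol = 1e-8, atol = NULL,
                            signal_species = "P") {
  stopifnot(inherits(design, "assay_design"), inherits(mechanism, "mechanism"))
  rates <- rate_set(rates, mechanism)
  if (is.null(atol)) atol <- min(1e-12, 1e-6 * max(design$e0, 1e-12))
  if (!(signal_species %in% mechanism$species))
    stop("signal species '", signal_species, "' not in the mechanism")
  grid <- expand.grid(s0 = design$s0, i0 = design$i0,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    s0 <- grid$s0[g]; i0 <- grid$i0[g]
    if (i0 > 0 && !("I" %in% mechanism$species))
      stop("design has non-zero inhibitor but the mechanism lacks species I",
           " (condition ", g, ")")
    traj <- tryCatch(
      simulate_condition(design, mechanism, rates, s0, i0, rtol, atol),
      error = function(e) stop("solver failure at condition ", g,
                               " (s0 = ", s0, ", i0 = ", i0, "): ",
                               conditionMessage(e)))
    base <- traj[[signal_species]]
    tt <- traj$time_s
    for (r in seq_len(design$replicates)) {
      sig <- base
      if (design$detection == "absorbance")
        sig <- sig * ellman$epsilon * ellman$path_cm
      sd_add <- if (design$detection == "absorbance") noise$sd_abs
                else noise$sd_abs / (ellman$epsilon * ellman$path_cm)
      if (noise$cv > 0 || sd_add > 0) {
        seed_r <- child_seed(noise$seed, s0, i0, r)
        sig <- withr_seed(seed_r, function()
          sig + stats::rnorm(length(sig),
                             sd = sqrt((noise$cv * abs(sig))^2 + sd_add^2)))
      }
      out[[g]] <- rbind(out[[g]], data.frame(
        time_s = tt, signal = sig, s0_M = s0, i0_M = i0,
        replicate = r, detection = design$detection))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "ellman") <- ellman
  attr(res, "design") <- design
  res
}

# evaluate fn() under a temporary RNG state
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# One (s0, i0) condition -> sampled reaction trajectory (time from reaction
# start).  Handles pre-incubation, order of addition and sequential
# substrate additions.
simulate_condition <- function(design, mechanism, rates, s0, i0, rtol, atol) {
  dt <- design$sample_dt_s
  if (design$n_additions > 1L) {
    tgrid <- seq(0, design$addition_interval_s, by = dt)
    phases <- rep(list(list(duration = design$addition_interval_s,
                            additions = c(S = s0), times = tgrid)),
                  design$n_additions)
    init <- c(E = design$e0)
    if (i0 > 0) init <- c(init, I = i0)
    if (design$p0 > 0) init <- c(init, P = design$p0)
    traj <- run_protocol(mechanism, rates, init, phases,
                         rtol = rtol, atol = atol)
    return(traj[!duplicated(traj$time_s), , drop = FALSE])
  }
  tgrid <- seq(0, design$duration_s, by = dt)
  if (design$order == "substrate_initiated") {
    phases <- list()
    if (design$preincubation_s > 0)
      phases <- list(list(duration = design$preincubation_s))
    add <- c(S = s0)
    if (design$p0 > 0) add <- c(add, P = design$p0)
    phases <- c(phases, list(list(duration = design$duration_s,
                                  additions = add, times = tgrid)))
    init <- c(E = design$e0)
    if (i0 > 0) init <- c(init, I = i0)
    traj <- run_protocol(mechanism, rates, init, phases,
                         rtol = rtol, atol = atol)
    traj <- traj[traj$phase == length(phases), , drop = FALSE]
    traj$time_s <- traj$time_s - min(traj$time_s)
    traj
  } else {
    init <- c(E = design$e0, S = s0)
    if (i0 > 0) init <- c(init, I = i0)
    if (design$p0 > 0) init <- c(init, P = design$p0)
    integrate_mechanism(mechanism, rates, init, tgrid,
                        rtol = rtol, atol = atol)
  }
}

#' Convert curves between concentration and absorbance
#'
#' A = epsilon * path * [P]; the round trip is an identity to machine
#' precision.
#'
#' @param curves data.frame from \code{\link{generate_curves}} (or any frame
#'   with \code{signal} and \code{detection} columns).
#' @param ellman an \code{\link{ellman_params}}; defaults to the attribute
#'   attached by \code{\link{generate_curves}}.
#' @return the converted curves.
#' @export
to_absorbance <- function(curves, ellman = attr(curves, "ellman")) {
  convert_detection(curves, ellman, "concentration", "absorbance")
}

#' @rdname to_absorbance
#' @export
to_concentration <- function(curves, ellman = attr(curves, "ellman")) {
  convert_detection(curves, ellman, "absorbance", "concentration")
}

convert_detection <- function(curves, ellman, from, to) {
  if (is.null(ellman)) ellman <- ellman_params()
  stopifnot(inherits(ellman, "ellman_params"))
  if (!all(curves$detection == from))
    stop("curves are not in ", from, " units")
  f <- ellman$epsilon * ellman$path_cm
  curves$signal <- if (to == "absorbance") curves$signal * f
                   else curves$signal / f
  curves$detection <- to
  attr(curves, "ellman") <- ellman
  curves
}

#' Write / read progress curves as tidy CSV
#'
#' Columns: \code{time_s, signal, s0_M, i0_M, replicate, detection}.
#'
#' @param curves curve data.frame.
#' @param path CSV file path.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(curves[, c("time_s", "signal", "s0_M", "i0_M",
                              "replicate", "detection")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
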