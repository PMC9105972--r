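# Mass-action ODE generation and integration.
#
# Internal units are molar and seconds throughout; I/O conversions (e.g.
# absorbance) are explicit and live in the assay layer.

#' Mass-action derivatives
#'
#' Exact mass-action law: d[X]/dt = sum over steps of nu_X * k * prod of
#' reactant concentrations (with their stoichiometric exponents).
#'
#' @param mech a \code{\link{mechanism}}.
#' @param rates named rate vector resolving every step label.
#' @param state named concentration vector (M); missing species default to 0.
#' @param neg_tol concentrations below \code{-neg_tol} are rejected.
#' @return named numeric vector of d[X]/dt (M/s) for every species.
#' @export
mass_action_derivatives <- function(mech, rates, state, neg_tol = 1e-11) {
  rates <- rate_set(rates, mech)
  y <- full_state(mech, state)
  if (any(!is.finite(y))) stop("non-finite concentration in 'state'")
  if (any(y < -neg_tol))
    stop("negative concentration beyond tolerance: ",
         paste(names(y)[y < -neg_tol], collapse = ", "))
  sm <- stoich_matrix(mech)
  k <- vapply(mech$steps, function(s) unname(rates[[s$rate]]), 0)
  v <- step_rates(pmax(y, 0), k, sm$R)
  stats::setNames(as.vector(sm$N %*% v), mech$species)
}

full_state <- function(mech, state) {
  y <- stats::setNames(numeric(length(mech$species)), mech$species)
  if (length(state)) {
    unknown <- setdiff(names(state), mech$species)
    if (length(unknown))
      stop("unknown species in state: ", paste(unknown, collapse = ", "))
    y[names(state)] <- state
  }
  y
}

step_rates <- function(y, k, R) {
  v <- k
  for (i in which(rowSums(R) > 0)) v <- v * y[i]^R[i, ]
  v
}

# d(step rate)/dy, used as analytic ODE Jacobian for the stiff solver
step_rate_jacobian <- function(y, k, R, N) {
  nr <- length(k); ns <- length(y)
  dv <- matrix(0, nr, ns)
  for (j in seq_len(nr)) {
    ri <- which(R[, j] > 0)
    for (i in ri) {
      term <- k[j] * R[i, j] * if (R[i, j] > 1) y[i]^(R[i, j] - 1) else 1
      for (m in setdiff(ri, i)) term <- term * y[m]^R[m, j]
      dv[j, i] <- term
    }
  }
  N %*% dv
}

#' Integrate a mechanism over a time grid
#'
#' Solves the mass-action ODE system with a stiff-capable integrator
#' (\code{deSolve}'s \code{lsoda}, with an analytic Jacobian).  The built-in
#' schemes mix rate constants spanning many orders of magnitude
#' (1e-4 .. 1e8), so an implicit method is the default.
#'
#' Values that dip into \code{[-10*atol, 0)} are clamped to zero; more
#' negative values raise an error (they indicate tolerance failure).
#'
#' @param mech a \code{\link{mechanism}}.
#' @param rates named rate vector.
#' @param init named initial concentrations (M); missing species are 0.
#' @param times strictly increasing sample times (s), \code{times[1] >= 0}.
#' @param rtol,atol relative / absolute (M) integration tolerances.
#' @param method a \code{deSolve} method name.
#' @return data.frame with column \code{time_s} followed by one column per
#'   species (M).
#' @export
integrate_mechanism <- function(mech, rates, init, times,
                                rtol = 1e-8, atol = 1e-12, method = "lsoda") {
  stopifnot(inherits(mech, "mechanism"))
  rates <- rate_set(rates, mech)
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE) ||
      times[1] < 0)
    stop("'times' must be finite, strictly increasing and start at >= 0")
  y0 <- full_state(mech, init)
  if (any(!is.finite(y0))) stop("non-finite initial concentrations")
  if (any(y0 < 0)) stop("negative initial concentrations")
  sm <- stoich_matrix(mech)
  k <- vapply(mech$steps, function(s) unname(rates[[s$rate]]), 0)
  derivs <- function(t, y, p) list(as.vector(sm$N %*% step_rates(y, k, sm$R)))
  jac <- function(t, y, p) step_rate_jacobian(y, k, sm$R, sm$N)
  # deSolve needs >= 2 output times; pad a lone requested time with t=0
  pad <- length(times) == 1L
  tt <- if (pad) unique(c(0, times)) else times
  sol <- deSolve::ode(y = y0, times = tt, func = derivs, parms = NULL,
                      method = method, rtol = rtol, atol = atol,
                      jacfunc = jac, jactype = "fullusr")
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE solver failure (istate = ", attr(sol, "istate")[1L],
         "); the system may be stiffer than the tolerances allow - ",
         "try a smaller rtol/atol or method = 'bdf'")
  out <- as.data.frame(sol)
  names(out)[1] <- "time_s"
  if (pad) out <- out[out$time_s %in% times, , drop = FALSE]
  for (sp in mech$species) {
    v <- out[[sp]]
    bad <- v < -10 * atol
    if (any(bad))
      stop("species ", sp, " went negative beyond 10*atol (min ",
           format(min(v)), "); tighten tolerances")
    out[[sp]] <- pmax(v, 0)
  }
  rownames(out) <- NULL
  out
}

#' Exact binding equilibrium for A + B <-> AB
#'
#' Depletion-aware (quadratic) solution of the two-component binding
#' equilibrium; no free-ligand approximation.
#'
#' @param e0 total enzyme (M).
#' @param i0 total ligand/inhibitor (M).
#' @param Kd dissociation constant (M).
#' @return named vector \code{c(E_free, EI, I_free)}.
#' @export
equilibrium_bound <- function(e0, i0, Kd) {
  if (any(c(e0, i0, Kd) < 0) || any(!is.finite(c(e0, i0, Kd))))
    stop("'e0', 'i0' and 'Kd' must be finite and non-negative")
  b <- e0 + i0 + Kd
  EI <- (b - sqrt(b * b - 4 * e0 * i0)) / 2
  EI <- min(EI, e0, i0)             # guard rounding at extreme ratios
  c(E_free = e0 - EI, EI = EI, I_free = i0 - EI)
}

#' Run a multi-phase assay protocol
#'
#' Integrates a mechanism across consecutive phases; each phase first adds
#' stated concentration increments to named species (order of addition,
#' sequential substrate additions), then integrates for its duration.  State
#' is continuous across phase boundaries except for the additions.
#'
#' Long pre-incubation phases in which the only active chemistry is a single
#' reversible bimolecular binding step (e.g. E + I <-> EI before substrate
#' addition) are resolved analytically via \code{\link{equilibrium_bound}}
#' when the relaxation time 1/(k_on*c + k_off) is shorter than
#' duration/20 (c = the larger free-partner total), avoiding pointless
#' integration of an equilibrated flat system.
#'
#' @param mech a \code{\link{mechanism}}.
#' @param rates named rate vector.
#' @param init named initial concentrations (M).
#' @param phases list; each element a list with \code{duration} (s),
#'   optional \code{additions} (named non-negative increments, M) and
#'   optional \code{times} (sample times within the phase, default
#'   \code{c(0, duration)}).
#' @param rtol,atol integration tolerances (see
#'   \code{\link{integrate_mechanism}}).
#' @param shortcut logical; allow the analytic pre-incubation shortcut.
#' @return data.frame \code{time_s} (cumulative), \code{phase}, one column
#'   per species.
#' @export
run_protocol <- function(mech, rates, init, phases,
                         rtol = 1e-8, atol = 1e-12, shortcut = TRUE) {
  stopifnot(inherits(mech, "mechanism"), is.list(phases), length(phases) >= 1L)
  rates <- rate_set(rates, mech)
  state <- full_state(mech, init)
  t0 <- 0
  out <- vector("list", length(phases))
  for (p in seq_along(phases)) {
    ph <- phases[[p]]
    if (is.null(ph$duration) || !is.finite(ph$duration) || ph$duration < 0)
      stop("phase ", p, ": 'duration' must be a non-negative number")
    add <- ph$additions
    if (!is.null(add) && length(add)) {
      unknown <- setdiff(names(add), mech$species)
      if (length(unknown))
        stop("phase ", p, ": addition of unknown species: ",
             paste(unknown, collapse = ", "))
      if (any(add < 0)) stop("phase ", p, ": additions must be non-negative")
      state[names(add)] <- state[names(add)] + add
    }
    times <- if (!is.null(ph$times)) ph$times else c(0, ph$duration)
    if (max(times) > ph$duration + 1e-9)
      stop("phase ", p, ": sample times exceed phase duration")
    eq <- if (shortcut && length(times) <= 2L)
      preincubation_equilibrium(mech, rates, state, ph$duration) else NULL
    if (!is.null(eq)) {
      m <- rbind(state, eq)[rep(1:2, length.out = max(2L, length(times))), ,
                            drop = FALSE]
      traj <- cbind(data.frame(time_s = range(times)),
                    as.data.frame(m, row.names = NULL))
      names(traj)[-1] <- mech$species
      state <- eq
    } else {
      traj <- integrate_mechanism(mech, rates, state, sort(unique(c(0, times))),
                                  rtol = rtol, atol = atol)
      state <- stats::setNames(as.numeric(traj[nrow(traj),
                                               mech$species]), mech$species)
      traj <- traj[traj$time_s %in% times, , drop = FALSE]
    }
    traj$time_s <- traj$time_s + t0
    traj$phase <- p
    t0 <- t0 + ph$duration
    out[[p]] <- traj[, c("time_s", "phase", mech$species)]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# If the only reachable chemistry from the current state is one reversible
# bimolecular association A + B <-> AB and the system relaxes much faster
# than the phase duration, return the analytic equilibrium state, else NULL.
preincubation_equilibrium <- function(mech, rates, state, duration) {
  if (duration <= 0) return(NULL)
  active <- names(state)[state > 0]
  # closure of potentially active steps over producible species
  repeat {
    idx <- which(vapply(mech$steps, function(s)
      all(names(s$reactants) %in% active), TRUE))
    prod_sp <- unique(unlist(lapply(mech$steps[idx],
                                    function(s) names(s$products))))
    if (all(prod_sp %in% active)) break
    active <- union(active, prod_sp)
  }
  if (length(idx) != 2L) return(NULL)
  s1 <- mech$steps[[idx[1]]]; s2 <- mech$steps[[idx[2]]]
  if (sum(s1$reactants) == 2L && sum(s2$reactants) == 1L) {
    fwd <- s1; rev <- s2
  } else if (sum(s2$reactants) == 2L && sum(s1$reactants) == 1L) {
    fwd <- s2; rev <- s1
  } else return(NULL)
  ab <- names(rev$reactants)
  if (length(names(fwd$reactants)) != 2L || length(ab) != 1L) return(NULL)
  if (!setequal(names(fwd$products), ab) ||
      !setequal(names(rev$products), names(fwd$reactants))) return(NULL)
  kon <- unname(rates[[fwd$rate]]); koff <- unname(rates[[rev$rate]])
  a <- names(fwd$reactants)[1]; b <- names(fwd$reactants)[2]
  tot_a <- state[a] + state[ab]; tot_b <- state[b] + state[ab]
  relax <- 1 / (kon * max(tot_a, tot_b) + koff)
  if (relax >= duration / 20) return(NULL)
  eq <- equilibrium_bound(tot_a, tot_b, koff / kon)
  new <- state
  new[a] <- tot_a - eq[["EI"]]
  new[b] <- tot_b - eq[["EI"]]
  new[ab] <- eq[["EI"]]
  new
}

#' Conservation drift along a trajectory
#'
#' Maximum relative drift of each conserved moiety (rows of
#' \code{\link{conserved_moieties}}) along an integrated trajectory;
#' a correctness diagnostic for the integrator.
#'
#' @param mech a \code{\link{mechanism}}.
#' @param traj trajectory data.frame from \code{\link{integrate_mechanism}}
#'   or \code{\link{run_protocol}} (single phase).
#' @return numeric vector of relative drifts, one per conserved moiety.
#' @export
conservation_drift <- function(mech, traj) {
  basis <- conserved_moieties(mech)
  if (ncol(basis) == 0L) return(numeric(0))
  Y <- as.matrix(traj[, mech$species, drop = FALSE])
  apply(basis, 2, function(cvec) {
    tot <- Y %*% cvec
    scale <- max(abs(tot[1]), max(abs(Y) %*% abs(cvec)) * 1e-6)
    if (scale == 0) 0 else max(abs(tot - tot[1])) / scale
  })
}
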