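#' Elementary mass-action step
#'
#' A single elementary reaction with integer stoichiometry and a named rate
#' constant.  Reaction order must equal the total reactant stoichiometry
#' (only first- and second-order steps arise in the built-in schemes).
#'
#' @param reactants named integer vector, species -> stoichiometry.
#'   Use an empty vector for a source step.
#' @param products named integer vector, species -> stoichiometry.
#' @param rate single character, label of the rate constant driving the step.
#' @return an object of class \code{"kin_step"}.
#' @export
kin_step <- function(reactants, products, rate) {
  reactants <- as_stoich(reactants, "reactants")
  products <- as_stoich(products, "products")
  if (!is.character(rate) || length(rate) != 1L || !nzchar(rate))
    stop("'rate' must be a single non-empty rate-constant label")
  structure(
    list(reactants = reactants, products = products,
         rate = rate, order = sum(reactants)),
    class = "kin_step")
}

as_stoich <- function(x, what) {
  if (length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("'", what, "' must be a named vector (species -> stoichiometry)")
  if (any(x != round(x)) || any(x <= 0))
    stop("'", what, "' stoichiometries must be positive integers")
  stats::setNames(as.integer(x), names(x))
}

#' Enzyme mechanism as a mass-action reaction network
#'
#' @param name mechanism name.
#' @param species character vector of species labels (e.g. E, S, ES, P, I, EI).
#' @param steps list of \code{\link{kin_step}} objects.  Every species a step
#'   references must appear in \code{species}; rate labels must be unique
#'   (one label per reaction direction).
#' @return an object of class \code{"mechanism"}.
#' @seealso \code{\link{build_scheme}} for the built-in schemes.
#' @export
mechanism <- function(name, species, steps) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.character(species) || anyDuplicated(species))
    stop("'species' must be a character vector without duplicates")
  if (!is.list(steps) || !all(vapply(steps, inherits, TRUE, "kin_step")))
    stop("'steps' must be a list of kin_step objects")
  used <- unique(unlist(lapply(steps, function(s)
    c(names(s$reactants), names(s$products)))))
  missing <- setdiff(used, species)
  if (length(missing))
    stop("step(s) reference species not in the species list: ",
         paste(missing, collapse = ", "))
  labels <- vapply(steps, `[[`, "", "rate")
  if (anyDuplicated(labels))
    stop("rate labels must be unique per reaction direction; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  structure(list(name = name, species = species, steps = steps),
            class = "mechanism")
}

#' @export
print.mechanism <- function(x, ...) {
  cat("Mechanism:", x$name, "\n")
  cat("Species:  ", paste(x$species, collapse = ", "), "\n")
  cat("Steps:\n")
  for (s in x$steps) {
    side <- function(v) if (length(v) == 0L) "0" else
      paste(ifelse(v > 1L, paste0(v, " "), ""), names(v),
            sep = "", collapse = " + ")
    cat(sprintf("  %s -> %s   [%s]\n",
                side(s$reactants), side(s$products), s$rate))
  }
  invisible(x)
}

#' Built-in inhibition schemes
#'
#' Constructs one of four canonical mechanisms:
#' \describe{
#'   \item{\code{competitive_mm}}{E+S <-> ES -> E+P plus E+I <-> EI; the
#'     generic Michaelis--Menten scheme with a competitive inhibitor.}
#'   \item{\code{mixed_mm}}{as above plus ES+I <-> ESI (mixed-type).}
#'   \item{\code{slyke_cullen_product}}{the two-step irreversible
#'     (van Slyke--Cullen) hydrolysis E+S -> EA+P (k1), EA -> E+A (k2),
#'     with competitive product inhibition E+P <-> EP (k3/k4).  For the
#'     Ellman AChE assay P is thiocholine-TNB (detected and inhibitory),
#'     EA the acyl-enzyme and A acetate.}
#'   \item{\code{slyke_cullen_product_inhibitor}}{as above plus a one-step
#'     competitive inhibitor E+I <-> EI (k5/k6).}
#' }
#'
#' Rate labels: the Michaelis--Menten schemes use \code{ks_on}, \code{ks_off},
#' \code{kcat}, \code{kon}, \code{koff} (and \code{kon_u}/\code{koff_u} for
#' the uncompetitive step of \code{mixed_mm}); the van Slyke--Cullen schemes
#' use \code{k1}..\code{k6}.
#'
#' @param name one of \code{"competitive_mm"}, \code{"mixed_mm"},
#'   \code{"slyke_cullen_product"}, \code{"slyke_cullen_product_inhibitor"}.
#' @return a \code{\link{mechanism}}.
#' @export
build_scheme <- function(name) {
  valid <- c("competitive_mm", "mixed_mm",
             "slyke_cullen_product", "slyke_cullen_product_inhibitor")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown scheme name; valid names are: ",
         paste(valid, collapse = ", "))
  switch(name,
    competitive_mm = mechanism(
      name, c("E", "S", "ES", "P", "I", "EI"),
      list(kin_step(c(E = 1, S = 1), c(ES = 1), "ks_on"),
           kin_step(c(ES = 1), c(E = 1, S = 1), "ks_off"),
           kin_step(c(ES = 1), c(E = 1, P = 1), "kcat"),
           kin_step(c(E = 1, I = 1), c(EI = 1), "kon"),
           kin_step(c(EI = 1), c(E = 1, I = 1), "koff"))),
    mixed_mm = mechanism(
      name, c("E", "S", "ES", "P", "I", "EI", "ESI"),
      list(kin_step(c(E = 1, S = 1), c(ES = 1), "ks_on"),
           kin_step(c(ES = 1), c(E = 1, S = 1), "ks_off"),
           kin_step(c(ES = 1), c(E = 1, P = 1), "kcat"),
           kin_step(c(E = 1, I = 1), c(EI = 1), "kon"),
           kin_step(c(EI = 1), c(E = 1, I = 1), "koff"),
           kin_step(c(ES = 1, I = 1), c(ESI = 1), "kon_u"),
           kin_step(c(ESI = 1), c(ES = 1, I = 1), "koff_u"))),
    slyke_cullen_product = mechanism(
      name, c("E", "S", "EA", "P", "A", "EP"),
      list(kin_step(c(E = 1, S = 1), c(EA = 1, P = 1), "k1"),
           kin_step(c(EA = 1), c(E = 1, A = 1), "k2"),
           kin_step(c(E = 1, P = 1), c(EP = 1), "k3"),
           kin_step(c(EP = 1), c(E = 1, P = 1), "k4"))),
    slyke_cullen_product_inhibitor = mechanism(
      name, c("E", "S", "EA", "P", "A", "EP", "I", "EI"),
      list(kin_step(c(E = 1, S = 1), c(EA = 1, P = 1), "k1"),
           kin_step(c(EA = 1), c(E = 1, A = 1), "k2"),
           kin_step(c(E = 1, P = 1), c(EP = 1), "k3"),
           kin_step(c(EP = 1), c(E = 1, P = 1), "k4"),
           kin_step(c(E = 1, I = 1), c(EI = 1), "k5"),
           kin_step(c(EI = 1), c(E = 1, I = 1), "k6"))))
}

#' Stoichiometric structure of a mechanism
#'
#' @param mech a \code{\link{mechanism}}.
#' @return list with \code{N} (species x steps net stoichiometric matrix) and
#'   \code{R} (species x steps reactant-exponent matrix).
#' @export
stoich_matrix <- function(mech) {
  stopifnot(inherits(mech, "mechanism"))
  ns <- length(mech$species); nr <- length(mech$steps)
  N <- matrix(0, ns, nr, dimnames = list(mech$species, NULL))
  R <- N
  for (j in seq_len(nr)) {
    st <- mech$steps[[j]]
    R[names(st$reactants), j] <- st$reactants
    N[names(st$reactants), j] <- N[names(st$reactants), j] - st$reactants
    N[names(st$products), j] <- N[names(st$products), j] + st$products
  }
  list(N = N, R = R)
}

#' Conserved moieties of a mechanism
#'
#' Basis of the left null space of the stoichiometric matrix: vectors c with
#' c'N = 0, i.e. linear combinations of concentrations conserved along every
#' trajectory (total enzyme, total substrate-derived material, total
#' inhibitor, ...).
#'
#' @param mech a \code{\link{mechanism}}.
#' @param tol singular-value threshold.
#' @return matrix (species x n_conserved), possibly zero columns.
#' @export
conserved_moieties <- function(mech, tol = 1e-10) {
  N <- stoich_matrix(mech)$N
  sv <- svd(N, nu = nrow(N))
  null_idx <- which(c(sv$d, rep(0, nrow(N) - length(sv$d))) < tol)
  basis <- sv$u[, null_idx, drop = FALSE]
  rownames(basis) <- mech$species
  basis
}

#' Validate a set of rate constants against a mechanism
#'
#' First-order constants are in 1/s, second-order constants in 1/(M s); all
#' values must be strictly positive and finite, and every step's label must
#' be present.
#'
#' @param rates named numeric vector, rate label -> value.
#' @param mech a \code{\link{mechanism}} (optional; label completeness is
#'   checked when given).
#' @return the validated (named numeric) rate set, invisibly classed as
#'   \code{"rate_set"}.
#' @export
rate_set <- function(rates, mech = NULL) {
  if (!is.numeric(rates) || is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("'rates' must be a named numeric vector")
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants must be strictly positive and finite")
  if (!is.null(mech)) {
    needed <- vapply(mech$steps, `[[`, "", "rate")
    missing <- setdiff(needed, names(rates))
    if (length(missing))
      stop("missing rate constant(s): ", paste(missing, collapse = ", "))
  }
  structure(rates, class = c("rate_set", "numeric"))
}

#' Derived kinetic constants
#'
#' Computes the composite constants a kineticist reads off a scheme:
#' K_m, K_i = k_off/k_on, V_max = k_cat * e0 and the residence time
#' tau = 1/k_off.  Works for the built-in schemes; labels are resolved as in
#' \code{\link{build_scheme}}.
#'
#' @param rates named rate vector (see \code{\link{rate_set}}).
#' @param e0 total enzyme (M), used for V_max; default \code{NA}.
#' @return named list with whichever of \code{Km}, \code{Ki}, \code{Ki_P},
#'   \code{Vmax}, \code{kcat}, \code{kcat_Km}, \code{tau} are resolvable.
#' @export
derived_constants <- function(rates, e0 = NA_real_) {
  out <- list()
  r <- as.list(rates)
  if (!is.null(r$ks_on) && !is.null(r$ks_off) && !is.null(r$kcat)) {
    out$Km <- (r$ks_off + r$kcat) / r$ks_on
    out$kcat <- r$kcat
    out$kcat_Km <- r$kcat / out$Km
  }
  if (!is.null(r$k1) && !is.null(r$k2)) {
    out$Km <- r$k2 / r$k1          # van Slyke-Cullen: v = k1 k2 e0 S/(k1 S + k2)
    out$kcat <- r$k2
    out$kcat_Km <- r$k1
  }
  if (!is.null(r$k3) && !is.null(r$k4)) out$Ki_P <- r$k4 / r$k3
  kon <- if (!is.null(r$k5)) r$k5 else r$kon
  koff <- if (!is.null(r$k6)) r$k6 else r$koff
  if (!is.null(kon) && !is.null(koff)) {
    out$Ki <- koff / kon
    out$tau <- 1 / koff
  }
  if (!is.null(out$kcat) && is.finite(e0)) out$Vmax <- out$kcat * e0
  out
}

#' Write / read a mechanism and rates as YAML or JSON
#'
#' The document has keys \code{name}, \code{species},
#' \code{steps[{reactants, products, rate}]} and optionally
#' \code{rates{label: value}}.
#'
#' @param mech a \code{\link{mechanism}}.
#' @param path output file; extension selects the format (.yaml/.yml or .json).
#' @param rates optional named rate vector stored alongside.
#' @return \code{path}, invisibly.
#' @export
write_mechanism <- function(mech, path, rates = NULL) {
  doc <- list(
    name = mech$name,
    species = as.list(mech$species),
    steps = lapply(mech$steps, function(s) list(
      reactants = as.list(s$reactants),
      products = as.list(s$products),
      rate = s$rate)))
  if (!is.null(rates)) doc$rates <- as.list(unclass(rate_set(rates)))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else stop("unrecognized extension (use .yaml/.yml or .json): ", path)
  invisible(path)
}

#' @rdname write_mechanism
#' @return \code{read_mechanism}: list with elements \code{mechanism} and
#'   \code{rates} (\code{NULL} when absent from the file).
#' @export
read_mechanism <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path)
  else stop("unrecognized extension (use .yaml/.yml or .json): ", path)
  steps <- lapply(doc$steps, function(s)
    kin_step(unlist(s$reactants), unlist(s$products), s$rate))
  mech <- mechanism(doc$name, unlist(doc$species), steps)
  rates <- if (!is.null(doc$rates)) rate_set(unlist(doc$rates), mech) else NULL
  list(mechanism = mech, rates = rates)
}
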