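# Configuration-driven runs chaining the simulation, steady-state and
# global-fitting layers; each run writes its outputs plus a manifest
# (config echo, package version, seed) into its own directory.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  config
}

validate_config <- function(config, allowed, required = character(0),
                            where = "config") {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop(where, ": unknown key(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop(where, ": missing required key(s): ",
         paste(missing, collapse = ", "))
  config
}

write_manifest <- function(out_dir, command, config, seed) {
  manifest <- list(
    command = command,
    package = "tdikin",
    version = as.character(utils::packageVersion("tdikin")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

prepare_out <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

#' Simulate progress curves from a configuration
#'
#' Config keys: \code{design} (\code{"preincubation"} with \code{k_off}, or a
#' \code{gal_design} variant name), \code{noise_cv}, \code{noise_sd_abs},
#' optional \code{mechanism_file} (YAML/JSON with mechanism + rates,
#' overriding the built-in ones).  Writes \code{curves.csv} and
#' \code{manifest.json}; repeated runs with the same seed are
#' byte-identical apart from the manifest timestamp.
#'
#' @param config list or YAML file path.
#' @param out_dir output directory (created).
#' @param seed master noise seed.
#' @return the curve data.frame, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = 1L) {
  config <- validate_config(read_config(config),
                            allowed = c("design", "k_off", "noise_cv",
                                        "noise_sd_abs", "mechanism_file"),
                            required = "design")
  prepare_out(out_dir)
  noise <- noise_model(sd_abs = config$noise_sd_abs %||% 0,
                       cv = config$noise_cv %||% 0, seed = seed)
  if (config$design == "preincubation") {
    if (is.null(config$k_off)) stop("preincubation design requires 'k_off'")
    fd <- preincubation_design(config$k_off)
    mech <- fd$mechanism; rates <- fd$rates; design <- fd$design
  } else {
    design <- gal_design(config$design)
    mech <- build_scheme("slyke_cullen_product_inhibitor")
    rates <- tcache_rates()
  }
  if (!is.null(config$mechanism_file)) {
    mr <- read_mechanism(config$mechanism_file)
    mech <- mr$mechanism
    if (!is.null(mr$rates)) rates <- mr$rates
  }
  curves <- generate_curves(design, mech, rates, noise = noise)
  write_curves(curves, file.path(out_dir, "curves.csv"))
  write_manifest(out_dir, "simulate", config, seed)
  invisible(curves)
}

#' Dissociation-rate scan from a configuration
#'
#' Config keys: \code{k_off_grid} (defaults to 25 log-spaced points spanning
#' the slow-to-fast unbinder range), \code{dead_time_s}, \code{window_s}.
#' Writes \code{scan.csv} (one row per k_off with the apparent constants,
#' their ratio and the classification) and \code{manifest.json}.
#'
#' @inheritParams run_simulate
#' @return the scan data.frame, invisibly.
#' @export
run_scan_koff <- function(config = list(), out_dir, seed = 1L) {
  config <- validate_config(read_config(config),
                            allowed = c("k_off_grid", "dead_time_s",
                                        "window_s"))
  prepare_out(out_dir)
  grid <- config$k_off_grid %||% 10^seq(-5, 3, length.out = 25)
  scan <- koff_scan(grid,
                    dead_time_s = config$dead_time_s %||% 10,
                    window_s = config$window_s %||% 10)
  utils::write.csv(scan, file.path(out_dir, "scan.csv"), row.names = FALSE)
  write_manifest(out_dir, "scan_koff", config, seed)
  invisible(scan)
}

#' Steady-state analysis of the galantamine emulation
#'
#' Generates (or reads) initial-velocity data for both initiation orders and
#' runs the Lineweaver-Burk / Dixon / Cornish-Bowden analysis on each.
#' Config keys: \code{curves_csv} (optional pre-generated tidy curves; when
#' absent both \code{gal_design} layouts are simulated), \code{noise_cv},
#' \code{window_s}.  Writes one JSON result per initiation order plus the
#' velocity tables.
#'
#' @inheritParams run_simulate
#' @return named list of \code{"inhibition_fit"} objects, invisibly.
#' @export
run_steady_state <- function(config = list(), out_dir, seed = 1L) {
  config <- validate_config(read_config(config),
                            allowed = c("curves_csv", "noise_cv", "window_s"))
  prepare_out(out_dir)
  window <- config$window_s %||% 10
  mech <- build_scheme("slyke_cullen_product_inhibitor")
  rates <- tcache_rates()
  out <- list()
  variants <- if (!is.null(config$curves_csv)) "curves"
              else c("enzyme_initiated", "substrate_initiated")
  for (variant in variants) {
    if (variant == "curves") {
      curves <- read_curves(config$curves_csv)
    } else {
      design <- gal_design(variant)
      curves <- generate_curves(design, mech, rates,
                                noise = noise_model(
                                  cv = config$noise_cv %||% 0, seed = seed))
    }
    vd <- velocities(curves, dead_time_s = 0, window_s = window)
    utils::write.csv(vd, file.path(out_dir,
                                   paste0("velocities_", variant, ".csv")),
                     row.names = FALSE)
    fit <- fit_inhibition(vd)
    write_inhibition(fit, file.path(out_dir,
                                    paste0("inhibition_", variant, ".json")))
    out[[variant]] <- fit
  }
  write_manifest(out_dir, "steady_state", config, seed)
  invisible(out)
}

#' Two-stage global fit from a configuration
#'
#' Stage 1 fits the hydrolysis / product-inhibition constants to a
#' sequential-addition series; stage 2 (optional) constrains them and fits
#' the inhibitor on/off rates to the inhibited series.  When no curve files
#' are supplied, noiseless series are generated from the published
#' parameter set and refitted from perturbed guesses (a round-trip
#' self-check).  Config keys: \code{stage1_csv}, \code{stage2_csv},
#' \code{stages} (1 or 2), \code{noise_cv}, \code{perturb} (guess
#' perturbation factor, default 3), \code{fit_s0}, \code{fit_e0}.
#' Writes \code{stage1.json} (and \code{stage2.json}) with estimates,
#' standard errors, derived constants and diagnostics, plus a flat
#' \code{summary.csv}.
#'
#' @inheritParams run_simulate
#' @return list with elements \code{stage1} and (optionally) \code{stage2},
#'   invisibly.
#' @export
run_globalfit <- function(config = list(), out_dir, seed = 1L) {
  config <- validate_config(read_config(config),
                            allowed = c("stage1_csv", "stage2_csv", "stages",
                                        "noise_cv", "perturb", "fit_s0",
                                        "fit_e0"))
  prepare_out(out_dir)
  stages <- config$stages %||% 2
  perturb <- config$perturb %||% 3
  truth <- tcache_rates()
  noise <- noise_model(cv = config$noise_cv %||% 0, seed = seed)

  if (!is.null(config$stage1_csv)) {
    c1 <- read_curves(config$stage1_csv)
    attr(c1, "design") <- gal_design("product_series")
  } else {
    c1 <- generate_curves(gal_design("product_series"),
                          build_scheme("slyke_cullen_product"),
                          truth[c("k1", "k2", "k3", "k4")], noise = noise)
  }
  s1 <- fit_stage1(c1, start = c(k1 = truth[["k1"]] * perturb,
                                 k2 = truth[["k2"]] / perturb,
                                 k4 = truth[["k4"]] * perturb))
  write_fit_json(s1, file.path(out_dir, "stage1.json"))
  out <- list(stage1 = s1)

  if (stages >= 2) {
    if (!is.null(config$stage2_csv)) {
      c2 <- read_curves(config$stage2_csv)
      attr(c2, "design") <- gal_design("gal_fit_series")
    } else {
      c2 <- generate_curves(gal_design("gal_fit_series"),
                            build_scheme("slyke_cullen_product_inhibitor"),
                            truth, noise = noise)
    }
    s2 <- fit_stage2(c2, s1,
                     start = c(k5 = truth[["k5"]] * perturb,
                               k6 = truth[["k6"]] / perturb),
                     fit_s0 = isTRUE(config$fit_s0),
                     fit_e0 = isTRUE(config$fit_e0))
    write_fit_json(s2, file.path(out_dir, "stage2.json"))
    out$stage2 <- s2
  } else if (!is.null(config$stage2_csv)) {
    stop("stage2_csv given but stages = 1; set stages: 2")
  }
  summ <- do.call(rbind, lapply(names(out), function(nm) {
    f <- out[[nm]]
    data.frame(stage = nm, parameter = names(f$estimates),
               estimate = unname(f$estimates), se = unname(f$se))
  }))
  utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "globalfit", config, seed)
  invisible(out)
}

write_fit_json <- function(fit, path) {
  d <- derived.progress_fit(fit)
  doc <- list(
    estimates = as.list(fit$estimates),
    se = as.list(fit$se),
    derived = d,
    rss = fit$rss,
    per_curve_rms = fit$per_curve_rms,
    iterations = fit$niter,
    converged = fit$converged,
    identifiable = fit$identifiable,
    condition_number = if (is.finite(fit$cond_J)) fit$cond_J else NULL)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
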