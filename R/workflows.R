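# Reproducible run workflows binding system, method, field and property
# protocol together; these back the command-line interface.

#' Solve the ground state for any supported method
#'
#' @param ints An `integral_set`.
#' @param method `"ccsd"`, `"cc2"`, `"cc2b"` or `"omp2"`.
#' @param ... Passed to the underlying solver.
#' @return A `ground_state_result`.
#' @export
ground_state <- function(ints, method, ...) {
  method <- tolower(method)
  if (!method %in% c("ccsd", "cc2", "cc2b", "omp2")) {
    stop("unknown method '", method, "'; valid methods: ccsd, cc2, cc2b, omp2")
  }
  if (method == "omp2") solve_omp2_ground_state(ints, ...)
  else solve_cc_ground_state(ints, method, ...)
}

#' Run configuration
#'
#' Flat key-value configuration with sections, read from a JSON document or
#' given as a list.  Exactly one system source must be set: `system$fixture`
#' (arguments of [make_fixture()] or `name = "minimal"`) or `system$file`
#' (a named-array integral container).
#'
#' @param config A list or a path to a JSON config file.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  src <- c(fixture = !is.null(config$system$fixture),
           file = !is.null(config$system$file))
  if (sum(src) != 1L) stop("config needs exactly one system source ",
                           "(system$fixture or system$file)")
  if (is.null(config$method)) stop("config$method is required")
  config$method <- tolower(config$method)
  if (!config$method %in% c("ccsd", "cc2", "cc2b", "omp2")) {
    stop("invalid method '", config$method,
         "'; valid methods: ccsd, cc2, cc2b, omp2")
  }
  structure(config, class = c("run_config", "list"))
}

.config_system <- function(config) {
  if (!is.null(config$system$fixture)) {
    do.call(integral_provider, c(list(source = "fixture"),
                                 config$system$fixture))
  } else {
    integral_provider("file", path = config$system$file)
  }
}

.config_integrator <- function(config) {
  ig <- config$integrator
  integrator_spec(stages = ig$stages %||% 3L, dt = ig$dt %||% 0.01,
                  tol = ig$tol %||% 1e-10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_provenance <- function(config, path) {
  meta <- list(config = unclass(config),
               package = "rtcc",
               version = as.character(utils::packageVersion("rtcc")))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run a delta-kick absorption-spectrum workflow
#'
#' Solves the ground state, applies the impulse, propagates, and writes the
#' trajectory, spectrum and peak CSVs plus a provenance JSON into the output
#' directory.  Deterministic for a fixed configuration.
#'
#' @param config A [run_config()] (or list / JSON path).  Relevant keys:
#'   `system`, `method`, `integrator` (`stages`, `dt`, `tol`), `field`
#'   (`strength`, `polarization`), `protocol` (`n_steps`, `gamma`,
#'   `record_every`).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `trajectory`, `spectrum`, `peaks` and the
#'   artifact paths.
#' @export
run_spectrum <- function(config, out_dir = ".") {
  config <- run_config(config)
  ints <- .config_system(config)
  spec <- .config_integrator(config)
  pr <- config$protocol %||% list()
  fld <- config$field %||% list()
  kick <- field_spec("delta_kick",
                     strength = fld$strength %||% 1e-3,
                     polarization = unlist(fld$polarization %||% c(0, 0, 1)))
  gs <- ground_state(ints, config$method)
  mu0 <- state_observables(gs$state, ints)$dipole
  n_steps <- pr$n_steps %||% 2000L
  traj <- propagate(gs$state, ints, kick, spec,
                    t_final = n_steps * spec$dt,
                    record_every = pr$record_every %||% 1L)
  sp <- absorption_spectrum(traj, mu0, kick, gamma = pr$gamma %||% 0.00921)
  pk <- detect_peaks(sp, min_height_fraction = pr$min_height_fraction %||% 0.02)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("trajectory.csv", "spectrum.csv",
                                "peaks.csv", "provenance.json"))
  write_trajectory_csv(traj, paths[1])
  write_spectrum_csv(sp, paths[2])
  utils::write.csv(pk, paths[3], row.names = FALSE)
  .write_provenance(config, paths[4])
  invisible(list(trajectory = traj, spectrum = sp, peaks = pk,
                 ground_state = gs, paths = paths))
}

#' Run a ramped-cosine response workflow
#'
#' Orchestrates the field-strength family (0, +/-E, +/-2E) of ramped-cosine
#' propagations along one axis, extracts the polarizability and first
#' hyperpolarizabilities via [response_from_signals()], and writes a
#' ResponseResult JSON.  The +/-2E members are required by the four-point
#' stencil; requesting hyperpolarizabilities without them is a configuration
#' error caught before any propagation.
#'
#' @param config A [run_config()].  Relevant keys: `system`, `method`,
#'   `integrator`, `field` (`omega`, `strength`, `axis`), `protocol`
#'   (`cycles_total`, `cycles_ramp`, `component`).
#' @param out_dir Output directory.
#' @return Invisibly, the `response_result` plus artifact paths.
#' @export
run_response <- function(config, out_dir = ".") {
  config <- run_config(config)
  ints <- .config_system(config)
  spec <- .config_integrator(config)
  fld <- config$field %||% list()
  pr <- config$protocol %||% list()
  omega <- fld$omega %||% stop("field$omega is required for response runs")
  E <- fld$strength %||% 5e-4
  axis <- fld$axis %||% 3L
  comp <- pr$component %||% axis
  cyc_ramp <- pr$cycles_ramp %||% 1
  cyc_total <- pr$cycles_total %||% (cyc_ramp + 3)
  pol <- c(0, 0, 0); pol[axis] <- 1
  gs <- ground_state(ints, config$method)
  t_final <- cyc_total * 2 * pi / omega
  one <- function(s) {
    fldspec <- field_spec("ramped_cosine", strength = abs(s),
                          polarization = sign(s) * pol, omega = omega,
                          ramp_cycles = cyc_ramp)
    tr <- propagate(gs$state, ints, fldspec, spec, t_final = t_final)
    tr[[c("mu_x", "mu_y", "mu_z")[comp]]]
  }
  signals <- list(p1 = one(E), m1 = one(-E), p2 = one(2 * E), m2 = one(-2 * E))
  # the field-free member of the family is the unperturbed ground state,
  # which is stationary: its dipole signal is the constant permanent dipole
  mu0 <- state_observables(gs$state, ints)$dipole[comp]
  signals$zero <- rep(mu0, length(signals$p1))
  times <- seq(0, by = spec$dt, length.out = length(signals$zero))
  rr <- response_from_signals(signals, times, omega, E,
                              discard_cycles = cyc_ramp)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("response.json", "provenance.json"))
  jsonlite::write_json(list(method = config$method, omega = omega,
                            axis = axis, component = comp,
                            alpha = rr$alpha, beta_or = rr$beta_or,
                            beta_shg = rr$beta_shg,
                            residual_mu1 = rr$residual_mu1,
                            residual_mu2 = rr$residual_mu2,
                            strengths = rr$strengths),
                       paths[1], auto_unbox = TRUE, digits = NA)
  .write_provenance(config, paths[2])
  invisible(c(rr, list(paths = paths)))
}
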