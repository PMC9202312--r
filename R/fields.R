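#' External electric-field protocol
#'
#' Describes the semiclassical electric field applied to the system: `none`,
#' a `delta_kick` (a box of height `strength / dt_kick` over one integrator
#' step, so the impulse area equals `strength`; used for broadband
#' absorption spectra), or a `ramped_cosine` (a monochromatic field switched
#' on with a linear envelope lasting `ramp_cycles` optical cycles; used for
#' polarizability and hyperpolarizability extraction).  All quantities in
#' atomic units.
#'
#' @param kind `"none"`, `"delta_kick"` or `"ramped_cosine"`.
#' @param strength Peak field strength (delta kick: impulse area) in a.u.
#' @param polarization Real unit 3-vector.
#' @param omega Carrier angular frequency (ramped cosine only).
#' @param ramp_cycles Ramp duration in optical cycles (default one cycle).
#' @param dt_kick Width of the discretized delta kick (set to the integrator
#'   step by the propagation driver if left `NULL`).
#' @return Object of class `field_spec`.
#' @export
field_spec <- function(kind = c("none", "delta_kick", "ramped_cosine"),
                       strength = 0, polarization = c(0, 0, 1),
                       omega = NULL, ramp_cycles = 1, dt_kick = NULL) {
  kind <- match.arg(kind)
  if (strength < 0) stop("field strength must be non-negative")
  nrm <- sqrt(sum(polarization^2))
  if (kind != "none") {
    if (abs(nrm - 1) > 1e-8) stop("polarization must be a unit vector")
    if (kind == "ramped_cosine" && (is.null(omega) || omega <= 0))
      stop("ramped_cosine needs a positive carrier frequency")
  }
  structure(list(kind = kind, strength = strength,
                 polarization = polarization, omega = omega,
                 ramp_cycles = ramp_cycles, dt_kick = dt_kick),
            class = "field_spec")
}

#' Electric-field value at a time
#'
#' Delta kick: `strength / dt_kick` times the polarization on
#' `0 <= t < dt_kick`, zero elsewhere (time integral = `strength`).
#' Ramped cosine: `strength * (t / T_ramp) * cos(omega t)` during the ramp
#' and `strength * cos(omega t)` afterwards.
#'
#' @param spec A `field_spec`.
#' @param t Time (a.u.), scalar or vector.
#' @return 3 x length(t) matrix of field components (a.u.).
#' @export
field_value <- function(spec, t) {
  stopifnot(inherits(spec, "field_spec"))
  amp <- switch(spec$kind,
    none = rep(0, length(t)),
    delta_kick = {
      if (is.null(spec$dt_kick)) stop("delta_kick needs dt_kick set")
      ifelse(t >= 0 & t < spec$dt_kick, spec$strength / spec$dt_kick, 0)
    },
    ramped_cosine = {
      T_ramp <- spec$ramp_cycles * 2 * pi / spec$omega
      env <- pmin(pmax(t, 0) / T_ramp, 1)
      spec$strength * env * cos(spec$omega * t)
    },
    stop("unknown field kind"))
  outer(spec$polarization, amp)
}

#' Length-gauge interaction matrix
#'
#' \eqn{-\sum_i E_i(t)\,\mu_i} in the orbital basis of the integral set;
#' Hermitian whenever the dipole matrices are.
#'
#' @param spec A `field_spec`.
#' @param t Time (a.u., scalar).
#' @param ints An `integral_set` providing the dipole matrices.
#' @return Complex L x L matrix.
#' @export
interaction_matrix <- function(spec, t, ints) {
  E <- field_value(spec, t)[, 1]
  L <- ints$n_orbitals
  V <- matrix(0 + 0i, L, L)
  for (k in 1:3) {
    if (E[k] != 0) V <- V - E[k] * ints$dipole[[k]]
  }
  V
}
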