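# Extraction of optical properties from induced-dipole signals.

#' @noRd
HARTREE_EV <- 27.211386
SPEED_OF_LIGHT_AU <- 137.035999

#' Linear absorption spectrum from a delta-kick trajectory
#'
#' Forms the induced dipole \eqn{\mu^{ind}_{ij}(t) = \mu_{ij}(t) - \mu^0_i}
#' for a kick along direction j, damps it with \eqn{e^{-\gamma t}} (yielding
#' Lorentzian lines of half-width \eqn{\gamma}), Fourier transforms it, and
#' normalizes by the impulse area to obtain the polarizability column
#' \eqn{\alpha_{ij}(\omega)}.  The spectral function is
#' \eqn{S(\omega) = \frac{4\pi\omega}{3c}\,\mathrm{Im}\,\alpha_{jj}(\omega)}
#' (the trace contribution available from a single kick direction).
#'
#' @param traj A `trajectory` from a `delta_kick` propagation.
#' @param mu0 Permanent dipole moment (length-3, a.u.): the dipole of the
#'   unkicked ground state.
#' @param kick The [field_spec()] used (for the impulse area and direction).
#' @param gamma Damping parameter in a.u. (default 0.00921, i.e. 0.251 eV).
#' @return Object of class `spectrum_result`: data.frame with `omega_au`,
#'   `omega_ev`, `S`, and `alpha_im_x/y/z`; `gamma` and the grid resolution
#'   as attributes.
#' @export
absorption_spectrum <- function(traj, mu0, kick, gamma = 0.00921) {
  if (is.null(attr(traj, "field")) && !inherits(kick, "field_spec"))
    stop("kick field specification required")
  if (kick$kind != "delta_kick")
    stop("absorption spectra require a delta-kick trajectory")
  if (gamma <= 0) stop("damping parameter must be positive")
  tgrid <- traj$t
  dt <- tgrid[2] - tgrid[1]
  n <- length(tgrid)
  damp <- exp(-gamma * tgrid)
  area <- kick$strength
  ft <- function(x) {
    # sum_k x(t_k) exp(+i omega t_k) dt  via the inverse FFT convention
    stats::fft(x, inverse = TRUE) * dt
  }
  alpha <- sapply(c("mu_x", "mu_y", "mu_z"), function(cn) {
    ind <- (traj[[cn]] - mu0[match(cn, c("mu_x", "mu_y", "mu_z"))]) * damp
    ft(ind) / area
  })
  domega <- 2 * pi / (n * dt)
  nkeep <- floor(n / 2)
  omega <- (seq_len(nkeep) - 1) * domega
  alpha <- alpha[seq_len(nkeep), , drop = FALSE]
  jdir <- which.max(abs(kick$polarization))
  S <- 4 * pi * omega / (3 * SPEED_OF_LIGHT_AU) * Im(alpha[, jdir])
  out <- data.frame(omega_au = omega, omega_ev = omega * HARTREE_EV, S = S,
                    alpha_im_x = Im(alpha[, 1]), alpha_im_y = Im(alpha[, 2]),
                    alpha_im_z = Im(alpha[, 3]))
  attr(out, "gamma") <- gamma
  attr(out, "resolution_au") <- domega
  attr(out, "kick") <- kick
  class(out) <- c("spectrum_result", "data.frame")
  out
}

#' Automated peak detection on a spectrum
#'
#' Local maxima of the spectral function above a height threshold.  The
#' reported positions are grid points: close-lying resonances within the
#' Lorentzian width merge into a single line (possibly with shoulders) and
#' are reported once, reflecting the finite spectral resolution.
#'
#' @param spec A `spectrum_result` (or data.frame with `omega_ev` and `S`).
#' @param min_height_fraction Peaks below this fraction of the global
#'   maximum are ignored.
#' @return Data frame with `omega_ev`, `omega_au`, `height`.
#' @export
detect_peaks <- function(spec, min_height_fraction = 0.02) {
  S <- spec$S
  n <- length(S)
  if (n < 3L) return(data.frame(omega_ev = numeric(0), omega_au = numeric(0),
                                height = numeric(0)))
  thr <- min_height_fraction * max(S)
  is_peak <- c(FALSE, S[2:(n - 1)] > S[1:(n - 2)] & S[2:(n - 1)] >= S[3:n],
               FALSE) & S > thr
  idx <- which(is_peak)
  data.frame(omega_ev = spec$omega_ev[idx], omega_au = spec$omega_au[idx],
             height = S[idx])
}

#' Polarizability and first hyperpolarizability from field-strength families
#'
#' Implements the finite-difference plus curve-fit protocol: the first- and
#' second-order dipole response functions are formed from trajectories at
#' field strengths \eqn{\pm E, \pm 2E} (plus the field-free signal) by the
#' four-point central-difference stencils
#' \deqn{\mu^{(1)} = [8(\mu_{+E}-\mu_{-E}) - (\mu_{+2E}-\mu_{-2E})]/(12E)}
#' \deqn{\mu^{(2)} = [16(\mu_{+E}+\mu_{-E}) - (\mu_{+2E}+\mu_{-2E}) -
#'   30\mu_0]/(12E^2)}
#' and fitted, after discarding the ramp cycle, by linear least squares to
#' \eqn{\mu^{(1)}(t) = \alpha\cos\omega t} and \eqn{\mu^{(2)}(t) =
#' \tfrac12[\beta^{OR} + \beta^{SHG}\cos 2\omega t]}, the forms of the
#' adiabatic dipole expansion
#' \eqn{\mu = \mu^0 + \alpha E\cos\omega t + \tfrac{E^2}{4}(\beta^{OR} +
#' \beta^{SHG}\cos 2\omega t) + O(E^3)}.
#'
#' @param signals Named list with components `zero`, `p1`, `m1`, `p2`, `m2`:
#'   dipole signals (numeric vectors) at field strengths 0, +E, -E, +2E, -2E
#'   on a common time grid.
#' @param times Time grid (a.u.).
#' @param omega Carrier frequency (a.u.).
#' @param strength Base field strength E (a.u.).
#' @param discard_cycles Optical cycles dropped from the start of the fit
#'   window (the ramp; default 1).
#' @return Object of class `response_result`: list with `alpha`, `beta_or`,
#'   `beta_shg`, fit residuals, and the protocol parameters.
#' @export
response_from_signals <- function(signals, times, omega, strength,
                                  discard_cycles = 1) {
  need <- c("zero", "p1", "m1", "p2", "m2")
  if (!all(need %in% names(signals))) {
    stop("signals must contain ", paste(need, collapse = ", "),
         " (the +/-E and +/-2E stencil needs all five)")
  }
  len <- vapply(signals[need], length, integer(1))
  if (length(unique(c(len, length(times)))) != 1L)
    stop("signals must share one time grid")
  E <- strength
  mu1 <- (8 * (signals$p1 - signals$m1) - (signals$p2 - signals$m2)) / (12 * E)
  mu2 <- (16 * (signals$p1 + signals$m1) - (signals$p2 + signals$m2) -
            30 * signals$zero) / (12 * E^2)
  T_cycle <- 2 * pi / omega
  win <- times >= discard_cycles * T_cycle - 1e-12
  if (sum(win) < 8L) stop("fit window too short after discarding the ramp")
  tw <- times[win]
  # first order: single cosine
  b1 <- cos(omega * tw)
  alpha <- sum(b1 * mu1[win]) / sum(b1 * b1)
  res1 <- sqrt(mean((mu1[win] - alpha * b1)^2))
  # second order: constant + double-frequency cosine
  B <- cbind(0.5, 0.5 * cos(2 * omega * tw))
  qrB <- qr(B)
  if (qrB$rank < 2L) stop("rank-deficient second-order fit basis")
  cf <- qr.coef(qrB, mu2[win])
  res2 <- sqrt(mean((mu2[win] - drop(B %*% cf))^2))
  structure(list(omega = omega, alpha = alpha, beta_or = cf[[1]],
                 beta_shg = cf[[2]], residual_mu1 = res1, residual_mu2 = res2,
                 strengths = c(E, 2 * E), discard_cycles = discard_cycles),
            class = "response_result")
}

#' Isotropic polarizability
#'
#' \eqn{\alpha_{iso} = (\alpha_{xx} + \alpha_{yy} + \alpha_{zz})/3}.
#'
#' @param alpha_diagonals Numeric length-3 vector of the diagonal tensor
#'   components at a common frequency.
#' @return Scalar mean.
#' @export
isotropic_polarizability <- function(alpha_diagonals) {
  if (length(alpha_diagonals) != 3L || any(!is.finite(alpha_diagonals)))
    stop("need the three finite diagonal components")
  mean(alpha_diagonals)
}

#' Static polarizability from finite-field ground states
#'
#' Independent static-limit reference: the second derivative of the
#' field-dependent ground-state energy, \eqn{\alpha_{jj} = -\partial^2
#' E_0(\epsilon)/\partial\epsilon^2}, from a five-point stencil of
#' ground-state solves with \eqn{h \to h - \epsilon\,\mu_j}.
#'
#' @param ints An `integral_set`.
#' @param method `"omp2"` or one of the CC models.
#' @param axis 1, 2 or 3 (x, y, z).
#' @param eps Field-strength step (a.u.).
#' @param ... Passed to the ground-state solver.
#' @return Static polarizability component (a.u.).
#' @export
finite_field_polarizability <- function(ints, method = "omp2", axis = 3,
                                        eps = 1e-3, ...) {
  mu <- ints$dipole[[axis]]
  en <- function(s) {
    hf <- ints$h - s * mu
    if (method == "omp2") {
      solve_omp2_ground_state(ints, h = hf, ...)$energy
    } else {
      ints2 <- ints
      ints2$h <- hf
      solve_cc_ground_state(ints2, method, ...)$energy
    }
  }
  e <- vapply(c(-2, -1, 0, 1, 2) * eps, en, numeric(1))
  -(-e[1] + 16 * e[2] - 30 * e[3] + 16 * e[4] - e[5]) / (12 * eps^2)
}

#' Write a spectrum (and peaks) to CSV
#'
#' @param spec A `spectrum_result`.
#' @param path Output CSV path.
#' @param peaks_path Optional peaks CSV path.
#' @param ... Passed to [detect_peaks()].
#' @export
write_spectrum_csv <- function(spec, path, peaks_path = NULL, ...) {
  hdr <- sprintf("# gamma=%g resolution_au=%g", attr(spec, "gamma"),
                 attr(spec, "resolution_au"))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(spec), con, row.names = FALSE)
  close(con)
  if (!is.null(peaks_path)) {
    utils::write.csv(detect_peaks(spec, ...), peaks_path, row.names = FALSE)
  }
  invisible(path)
}
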