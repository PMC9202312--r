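# Spectra, peak detection, and response-function extraction.

make_signal_traj <- function(mu, dt) {
  n <- length(mu)
  d <- data.frame(t = (seq_len(n) - 1) * dt, mu_x = 0, mu_y = 0, mu_z = mu)
  class(d) <- c("trajectory", "data.frame")
  d
}

test_that("the spectrum of a damped sinusoid matches the closed form", {
  w0 <- 0.5; n <- 20000; dt <- 0.05; g <- 0.00921
  tg <- (0:(n - 1)) * dt
  traj <- make_signal_traj(1e-3 * sin(w0 * tg), dt)
  kick <- field_spec("delta_kick", strength = 1e-3,
                     polarization = c(0, 0, 1), dt_kick = dt)
  sp <- absorption_spectrum(traj, c(0, 0, 0), kick, gamma = g)
  pk <- detect_peaks(sp, 0.1)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$omega_au - w0), attr(sp, "resolution_au"))
  # finite-time Fourier integral of sin(w0 t) e^{-g t}, evaluated exactly
  anl <- function(w) {
    Tend <- n * dt
    f <- function(a) (exp((1i * a - g) * Tend) - 1) / (1i * a - g)
    (f(w + w0) - f(w - w0)) / (2i)
  }
  sel <- sp$omega_au > 0.4 & sp$omega_au < 0.6
  err <- max(abs(sp$alpha_im_z[sel] - Im(sapply(sp$omega_au[sel], anl))))
  expect_lt(err, 1e-6 * max(abs(sp$alpha_im_z[sel])))
})

test_that("damping broadens lines without moving them", {
  w0 <- 0.5; n <- 8000; dt <- 0.05
  tg <- (0:(n - 1)) * dt
  traj <- make_signal_traj(1e-3 * sin(w0 * tg), dt)
  kick <- field_spec("delta_kick", strength = 1e-3,
                     polarization = c(0, 0, 1), dt_kick = dt)
  s1 <- absorption_spectrum(traj, c(0, 0, 0), kick, gamma = 0.00921)
  s2 <- absorption_spectrum(traj, c(0, 0, 0), kick, gamma = 2 * 0.00921)
  p1 <- detect_peaks(s1, 0.1); p2 <- detect_peaks(s2, 0.1)
  expect_equal(p1$omega_au, p2$omega_au)
  fwhm <- function(s) {
    half <- max(s$S) / 2
    sum(s$S > half) * attr(s, "resolution_au")
  }
  expect_gt(fwhm(s2), fwhm(s1))
  # zero induced dipole gives a null spectrum
  s0 <- absorption_spectrum(make_signal_traj(rep(0.37, n), dt),
                            c(0, 0, 0.37), kick)
  expect_equal(max(abs(s0$S)), 0)
})

test_that("close-lying lines merge while separated lines resolve", {
  n <- 8000; dt <- 0.05; g <- 0.00921
  tg <- (0:(n - 1)) * dt
  kick <- field_spec("delta_kick", strength = 1e-3,
                     polarization = c(0, 0, 1), dt_kick = dt)
  two <- function(sep) {
    traj <- make_signal_traj(1e-3 * (sin(0.5 * tg) + sin((0.5 + sep) * tg)),
                             dt)
    detect_peaks(absorption_spectrum(traj, c(0, 0, 0), kick, gamma = g), 0.05)
  }
  far <- two(10 * 2 * g)
  expect_equal(nrow(far), 2L)
  expect_lt(abs(far$omega_au[1] - 0.5), 2 * pi / (n * dt))
  expect_equal(nrow(two(0.5 * 2 * g)), 1L)
})

test_that("model-matched response signals are recovered exactly", {
  omega <- 0.2; E <- 1e-3
  tt <- seq(0, 6 * 2 * pi / omega, by = 0.1)
  model <- function(s) {
    0.4 + 3.5 * s * cos(omega * tt) +
      s^2 / 4 * (1.0 + 2.0 * cos(2 * omega * tt))
  }
  sig <- list(zero = model(0), p1 = model(E), m1 = model(-E),
              p2 = model(2 * E), m2 = model(-2 * E))
  rr <- response_from_signals(sig, tt, omega, E)
  expect_lt(abs(rr$alpha - 3.5), 1e-10)
  expect_lt(abs(rr$beta_or - 1.0), 1e-9)
  expect_lt(abs(rr$beta_shg - 2.0), 1e-9)
  # signals linear in the field leave no second-order response
  lin <- function(s) 0.1 + 2.2 * s * cos(omega * tt)
  sigl <- list(zero = lin(0), p1 = lin(E), m1 = lin(-E),
               p2 = lin(2 * E), m2 = lin(-2 * E))
  rrl <- response_from_signals(sigl, tt, omega, E)
  expect_lt(abs(rrl$beta_or), 1e-10)
  expect_lt(abs(rrl$beta_shg), 1e-10)
  expect_lt(abs(rrl$alpha - 2.2), 1e-10)
  # the +/-2E members are required by the stencil
  expect_error(response_from_signals(sigl[c("zero", "p1", "m1")], tt,
                                     omega, E), "p2")
})

test_that("cubic contamination cancels from the four-point first derivative", {
  omega <- 0.2; E <- 1e-3
  tt <- seq(0, 4 * 2 * pi / omega, by = 0.1)
  cub <- function(s) 2.2 * s * cos(omega * tt) + 5 * s^3 * cos(omega * tt)^3
  sig <- list(zero = cub(0), p1 = cub(E), m1 = cub(-E),
              p2 = cub(2 * E), m2 = cub(-2 * E))
  rr <- response_from_signals(sig, tt, omega, E)
  # five-strength polynomial oracle for the first derivative at zero field
  strengths <- c(-2, -1, 0, 1, 2) * E
  k <- length(tt) %/% 2
  vals <- vapply(strengths, function(s) cub(s)[k], numeric(1))
  c1 <- coef(lm(vals ~ poly(strengths, 3, raw = TRUE)))[2]
  mu1_k <- (8 * (sig$p1[k] - sig$m1[k]) - (sig$p2[k] - sig$m2[k])) / (12 * E)
  expect_equal(mu1_k, unname(c1), tolerance = 1e-9)
  # the E^3 term cancels exactly from the stencil, so alpha is clean
  expect_lt(abs(rr$alpha - 2.2), 1e-10)
})

test_that("the isotropic polarizability is the diagonal mean", {
  expect_equal(isotropic_polarizability(c(2, 2, 2)), 2)
  expect_equal(isotropic_polarizability(c(1, 2, 3)), 2)
  expect_error(isotropic_polarizability(c(1, 2)), "three")
  expect_error(isotropic_polarizability(c(1, 2, NA)), "three")
})
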