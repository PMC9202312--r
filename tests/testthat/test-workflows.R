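# Run workflows and configuration handling.

test_that("the spectrum workflow writes deterministic artifacts", {
  cfg <- list(system = list(fixture = list(seed = 11, n_occ = 2, n_virt = 2,
                                           coupling_scale = 0.2)),
              method = "ccsd",
              integrator = list(stages = 3, dt = 0.05),
              field = list(strength = 1e-3, polarization = c(0, 0, 1)),
              protocol = list(n_steps = 200))
  d1 <- file.path(tempdir(), "spec-run-1")
  d2 <- file.path(tempdir(), "spec-run-2")
  r1 <- run_spectrum(cfg, d1)
  r2 <- run_spectrum(cfg, d2)
  for (f in c("trajectory.csv", "spectrum.csv", "peaks.csv",
              "provenance.json")) {
    expect_true(file.exists(file.path(d1, f)))
  }
  expect_identical(readLines(file.path(d1, "trajectory.csv")),
                   readLines(file.path(d2, "trajectory.csv")))
  expect_identical(readLines(file.path(d1, "spectrum.csv")),
                   readLines(file.path(d2, "spectrum.csv")))
  # provenance embeds the resolved configuration and version
  prov <- jsonlite::read_json(file.path(d1, "provenance.json"),
                              simplifyVector = TRUE)
  expect_equal(prov$config$method, "ccsd")
  expect_true(nzchar(prov$version))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("invalid configurations fail before any computation", {
  cfg <- list(system = list(fixture = list(seed = 1, n_occ = 2, n_virt = 2)),
              method = "ccsdt")
  expect_error(run_config(cfg), "ccsd, cc2, cc2b, omp2")
  expect_error(run_config(list(method = "ccsd", system = list())),
               "system source")
  expect_error(ground_state(fix2e(), "mp3"), "valid methods")
})

test_that("spectrum peaks of a kicked model match its exact excitations", {
  # the delta kick excites every dipole-allowed transition: peak positions
  # from the simulated spectrum must match the dense spectral gaps
  cfg <- list(system = list(fixture = list(seed = 11, n_occ = 2, n_virt = 2,
                                           coupling_scale = 0.2)),
              method = "ccsd",
              integrator = list(stages = 3, dt = 0.05),
              field = list(strength = 1e-3, polarization = c(0, 0, 1)),
              protocol = list(n_steps = 2000, gamma = 0.03))
  out <- run_spectrum(cfg, file.path(tempdir(), "spec-run-3"))
  pk <- out$peaks
  dense <- dense_hamiltonian(fix2e())
  ev <- sort(Re(eigen(dense$H, symmetric = TRUE)$values))
  gaps <- (ev - ev[1])[-1]
  res <- attr(out$spectrum, "resolution_au")
  for (w in pk$omega_au) {
    expect_lt(min(abs(gaps - w)), res)
  }
  unlink(file.path(tempdir(), "spec-run-3"), recursive = TRUE)
})

test_that("the response workflow produces a well-formed result", {
  cfg <- list(system = list(fixture = list(seed = 21, n_occ = 2, n_virt = 2,
                                           coupling_scale = 0.2,
                                           one_body_scale = 0.5)),
              method = "omp2",
              integrator = list(stages = 3, dt = 0.4),
              field = list(omega = 0.2, strength = 5e-4, axis = 3),
              protocol = list(cycles_total = 2, cycles_ramp = 1))
  d <- file.path(tempdir(), "resp-run")
  rr <- run_response(cfg, d)
  expect_true(is.finite(rr$alpha))
  js <- jsonlite::read_json(file.path(d, "response.json"),
                            simplifyVector = TRUE)
  expect_equal(js$method, "omp2")
  expect_equal(js$alpha, rr$alpha, tolerance = 1e-12)
  expect_true(all(c("beta_or", "beta_shg", "residual_mu1") %in% names(js)))
  unlink(d, recursive = TRUE)
})
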