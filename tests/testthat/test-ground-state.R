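# Stationary-state solvers.

test_that("first-order doubles reduce to the closed form for diagonal Fock", {
  i0 <- make_fixture(seed = 2, n_occ = 2, n_virt = 2, coupling_scale = 0)
  expect_equal(max(Mod(mp2_amplitudes(i0))), 0)
  ints <- fix2e()
  t2 <- mp2_amplitudes(ints)
  # antisymmetry in both pairs
  expect_close(t2 + aperm(t2, c(2, 1, 3, 4)), 0 * t2, 1e-12)
  expect_close(t2 + aperm(t2, c(1, 2, 4, 3)), 0 * t2, 1e-12)
  # elementwise loop oracle with the diagonal denominator on a fixture whose
  # Fock matrix is made exactly diagonal
  intsd <- ints
  f <- build_fock(ints)
  intsd$h <- ints$h - (f - diag(diag(f)))   # cancel off-diagonal Fock
  fd <- build_fock(intsd)
  expect_lt(max(Mod(fd - diag(diag(fd)))), 1e-12)
  t2d <- mp2_amplitudes(intsd)
  eps <- Re(diag(fd))
  vir <- 3:4
  for (a in 1:2) for (b in 1:2) for (i in 1:2) for (j in 1:2) {
    den <- eps[i] + eps[j] - eps[vir[a]] - eps[vir[b]]
    expect_equal(t2d[a, b, i, j], intsd$v[vir[a], vir[b], i, j] / den,
                 tolerance = 1e-9)
  }
})

test_that("CCSD ground state equals full diagonalization for two electrons", {
  ints <- fix2e()
  gs <- gs_of("ccsd")
  efci <- min(Re(eigen(dense2e()$H, symmetric = TRUE)$values))
  expect_equal(gs$energy, efci, tolerance = 1e-9)
  expect_lt(tail(gs$residual_history, 1), 1e-10)
})

test_that("CC2 is a distinct approximation to CCSD", {
  gs_ccsd <- gs_of("ccsd")
  gs_cc2 <- gs_of("cc2")
  gs_cc2b <- gs_of("cc2b")
  efci <- min(Re(eigen(dense2e()$H, symmetric = TRUE)$values))
  expect_gt(abs(gs_cc2$energy - efci), 1e-6)
  expect_gt(abs(gs_cc2$energy - gs_ccsd$energy), 1e-6)
  expect_gt(abs(gs_cc2b$energy - gs_cc2$energy), 1e-8)
})

test_that("mean-field fixtures have no correlation", {
  i0 <- make_fixture(seed = 5, n_occ = 2, n_virt = 2, coupling_scale = 0)
  g0 <- solve_cc_ground_state(i0, "ccsd")
  expect_equal(max(Mod(g0$state$t2)), 0)
  expect_equal(g0$energy, Re(reference_energy(i0)), tolerance = 1e-12)
  o0 <- solve_omp2_ground_state(i0)
  expect_close(o0$state$U, diag(1 + 0i, 4), 1e-10)
  expect_equal(o0$energy, Re(reference_energy(i0)), tolerance = 1e-12)
})

test_that("DIIS and plain fixed-point iterations find the same state", {
  ints <- fix2e()
  a <- solve_cc_ground_state(ints, "ccsd", diis = TRUE)
  b <- solve_cc_ground_state(ints, "ccsd", diis = FALSE, max_iter = 2000L)
  expect_equal(a$energy, b$energy, tolerance = 1e-9)
})

test_that("OMP2 lies below plain MP2 and is rotation invariant", {
  ints <- fix5()
  gs <- gs_of("omp2", ints, key = "5")
  t2 <- mp2_amplitudes(ints)
  occ <- 1:2; vir <- 3:5
  emp2 <- Re(reference_energy(ints)) +
    Re(0.25 * sum(ints$v[occ, occ, vir, vir] * aperm(t2, c(3, 4, 1, 2))))
  expect_lte(gs$energy, emp2 + 1e-12)
  # initial occupied-occupied unitary mixing leaves the energy unchanged
  K <- matrix(0, 5, 5); K[1, 2] <- 0.37; K[2, 1] <- -0.37
  r <- transform_integrals(ints, orbital_transform("unitary-kappa", K, 2, 5))
  rot <- integral_set(2, r$h, r$u, r$dipole, r$e_nuc)
  gs2 <- solve_omp2_ground_state(rot)
  expect_equal(gs$energy, gs2$energy, tolerance = 1e-9)
})

test_that("OMP2 solution is a stationary point of the Lagrangian", {
  ints <- fix2e()
  gs <- gs_of("omp2")
  st <- gs$state
  # directional derivatives of the Hamilton function along random doubles
  # and orbital directions, lambda held at its stationary value
  frame <- rtcc:::.method_frame(st, ints)
  terms <- hamilton_terms("omp2")
  l2 <- aperm(Conj(st$t2), c(3, 4, 1, 2))
  hval <- function(t2, hmat, vmat) {
    Re(rtcc:::table_value(terms, list(h = hmat, v = vmat, t2 = t2, l2 = l2),
                          2, 4))
  }
  set.seed(3)
  d <- array(rnorm(16), c(2, 2, 2, 2))
  d <- d - aperm(d, c(2, 1, 3, 4)) - aperm(d, c(1, 2, 4, 3)) +
    aperm(d, c(2, 1, 4, 3))
  h <- 1e-5
  fd_t2 <- (hval(st$t2 + h * d, frame$tensors$h, frame$tensors$v) -
              hval(st$t2 - h * d, frame$tensors$h, frame$tensors$v)) / (2 * h)
  expect_lt(abs(fd_t2), 1e-6)
  # orbital direction: unitary kappa rotation of the integrals
  K <- matrix(0, 4, 4)
  K[3, 1] <- 0.7; K[4, 2] <- -0.3
  K <- K - t(K)
  rot <- function(s) {
    Em <- rtcc:::mat_exp(-s * K); Ep <- rtcc:::mat_exp(s * K)
    hval(st$t2, Em %*% frame$tensors$h %*% Ep,
         rtcc:::transform_two_body(frame$tensors$v, Em, Ep))
  }
  fd_k <- (rot(h) - rot(-h)) / (2 * h)
  expect_lt(abs(fd_k), 1e-6)
})
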