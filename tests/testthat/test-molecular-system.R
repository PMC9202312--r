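# Integral containers, symmetries, transforms and fixtures.

test_that("anti-symmetrization reproduces the elementwise definition", {
  # direct arithmetic on a hand-set element pair
  L <- 4
  u <- array(0, rep(L, 4))
  u[1, 2, 1, 2] <- 0.5; u[2, 1, 2, 1] <- 0.5   # particle-exchange partners
  u[1, 2, 2, 1] <- 0.2; u[2, 1, 1, 2] <- 0.2
  v <- antisymmetrize_two_body(u)
  expect_equal(v[1, 2, 1, 2], 0.5 - 0.2)
  # forced antisymmetry for random symmetric input, against a loop oracle
  set.seed(4)
  u <- array(rnorm(L^4), rep(L, 4))
  u <- (u + aperm(u, c(2, 1, 4, 3))) / 2
  v <- antisymmetrize_two_body(u)
  vo <- array(0, rep(L, 4))
  for (p in 1:L) for (q in 1:L) for (r in 1:L) for (s in 1:L) {
    vo[p, q, r, s] <- u[p, q, r, s] - u[p, q, s, r]
  }
  expect_close(v, vo, 1e-14)
  expect_close(v + aperm(v, c(1, 2, 4, 3)), 0 * v, 1e-14)
  expect_error(antisymmetrize_two_body(array(0, c(2, 2, 2, 3))), "rank-4")
})

test_that("Fock matrix matches the explicit double-loop sum", {
  ints <- fix5()
  f <- build_fock(ints)
  L <- ints$n_orbitals
  fo <- ints$h
  for (p in 1:L) for (q in 1:L) for (i in 1:2) {
    fo[p, q] <- fo[p, q] + ints$v[p, i, q, i]
  }
  expect_close(f, fo, 1e-13)
  expect_close(f, Conj(t(f)), 1e-12)          # Hermiticity preserved
  # v = 0 limit
  i0 <- make_fixture(seed = 2, n_occ = 2, n_virt = 2, coupling_scale = 0)
  expect_close(build_fock(i0), i0$h, 1e-14)
})

test_that("fixtures are deterministic and satisfy the validator", {
  a <- make_fixture(seed = 1, n_occ = 2, n_virt = 3)
  b <- make_fixture(seed = 1, n_occ = 2, n_virt = 3)
  expect_identical(a, b)
  expect_silent(validate_integral_set(a))
  c <- make_fixture(seed = 2, n_occ = 2, n_virt = 3)
  expect_gt(max(Mod(a$h - c$h)), 0)
})

test_that("integral transforms compose and invert correctly", {
  ints <- fix5()
  L <- ints$n_orbitals
  # zero shift is the identity
  xf0 <- orbital_transform("t1", matrix(0, 3, 2), 2, L)
  expect_close(transform_integrals(ints, xf0)$h, ints$h, 1e-14)
  # kappa then -kappa recovers the input
  set.seed(9)
  K <- matrix(rnorm(L^2, sd = 0.2), L, L)
  K <- K - t(K)
  xf <- orbital_transform("unitary-kappa", K, 2, L)
  xfi <- orbital_transform("unitary-kappa", -K, 2, L)
  back <- transform_integrals(transform_integrals(ints, xf), xfi)
  expect_close(back$h, ints$h, 1e-12)
  expect_close(back$v, ints$v, 1e-12)
  # unitary kappa preserves Hermiticity
  fwd <- transform_integrals(ints, xf)
  expect_close(fwd$h, Conj(t(fwd$h)), 1e-12)
  # t1 dressing equals the dense matrix-exponential similarity transform
  t1 <- matrix(rnorm(6, sd = 0.3), 3, 2)
  xft <- orbital_transform("t1", t1, 2, L)
  M <- xft$generator
  Em <- rtcc:::mat_exp(-M); Ep <- rtcc:::mat_exp(M)
  expect_close(transform_integrals(ints, xft)$h, Em %*% ints$h %*% Ep, 1e-12)
})

test_that("reference energy is invariant under occupied-occupied mixing", {
  ints <- fix5()
  K <- matrix(0, 5, 5); K[1, 2] <- 0.4; K[2, 1] <- -0.4
  xf <- orbital_transform("unitary-kappa", K, 2, 5)
  r <- transform_integrals(ints, xf)
  rot <- integral_set(2, r$h, r$u, r$dipole, r$e_nuc)
  expect_equal(Re(reference_energy(ints)), Re(reference_energy(rot)),
               tolerance = 1e-12)
})

test_that("spin-orbital expansion reproduces restricted quantities", {
  # two electrons in one spatial level: E_ref = 2 h11
  h <- matrix(-1, 1, 1)
  u <- array(0, rep(1, 4))
  so <- spatial_to_spinorbital(h, u, n_electrons = 2)
  expect_equal(Re(reference_energy(so)), -2)
  expect_equal(so$n_orbitals, 2L)
  # spin blocking: alpha-beta one-body blocks vanish
  expect_equal(so$h[1, 2], 0 + 0i)
  # dipole trace over the reference = 2 x spatial occupied trace
  hs <- matrix(c(-1, 0.1, 0.1, 0.3), 2, 2)
  us <- array(0, rep(2, 4))
  dz <- matrix(c(0.2, 0.5, 0.5, -0.1), 2, 2)
  so2 <- spatial_to_spinorbital(hs, us, 2, dipole_spatial = list(dz, dz, dz))
  expect_equal(Re(sum(diag(so2$dipole[[3]])[1:2])), 2 * dz[1, 1])
  expect_error(spatial_to_spinorbital(hs, us, 3), "even")
})

test_that("minimal molecular fixture agrees with its dense reference", {
  ints <- minimal_molecular_fixture()
  dense <- dense_hamiltonian(ints)
  # reference (mean-field) energy equals the dense diagonal element of the
  # reference determinant
  expect_equal(Re(reference_energy(ints)), Re(dense$H[1, 1]),
               tolerance = 1e-10)
  # CCSD equals full diagonalization for two electrons
  gs <- solve_cc_ground_state(ints, "ccsd")
  efci <- min(Re(eigen(dense$H, symmetric = TRUE)$values))
  expect_equal(gs$energy, efci, tolerance = 1e-9)
})

test_that("integral sets survive the JSON container round trip", {
  ints <- fix2e()
  path <- tempfile(fileext = ".json")
  write_integral_set(ints, path)
  back <- read_integral_set(path)
  expect_close(back$h, ints$h, 1e-14)
  expect_close(back$u, ints$u, 1e-14)
  expect_equal(back$n_electrons, ints$n_electrons)
  expect_equal(back$e_nuc, ints$e_nuc)
  unlink(path)
})

test_that("XYZ geometry files parse with and without header lines", {
  p <- tempfile(fileext = ".xyz")
  writeLines(c("2", "water fragment", "O 0.0 0.0 0.117", "H 0.0 0.757 -0.47"),
             p)
  g <- read_xyz(p)
  expect_equal(g$element, c("O", "H"))
  expect_equal(g$z, c(0.117, -0.47))
  writeLines(c("He 0 0 0"), p)
  expect_equal(nrow(read_xyz(p)), 1L)
  unlink(p)
})
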