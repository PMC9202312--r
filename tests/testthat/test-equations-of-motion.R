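# Equations of motion, densities and expectation values.

test_that("CCSD residuals and conjugate residuals match the dense bracket", {
  ints <- fix5()
  st <- random_state("ccsd", 2, 5, seed = 7)
  der <- eom_derivative(st, ints)
  db <- dense_bivariational(dense_hamiltonian(ints), 2,
                            t1 = st$t1, t2 = st$t2, l1 = st$l1, l2 = st$l2)
  expect_close(der$hamilton, db$hamilton + ints$e_nuc * 0, 1e-12)
  expect_close(1i * der$dt1, db$omega1, 1e-12)
  expect_close(1i * der$dt2, db$omega2, 1e-12)
  expect_close(-1i * der$dl1, db$lres1, 1e-12)
  expect_close(-1i * der$dl2, db$lres2, 1e-12)
})

test_that("every method is stationary at its own field-free ground state", {
  ints <- fix2e()
  for (m in c("ccsd", "cc2", "cc2b")) {
    der <- eom_derivative(gs_of(m)$state, ints)
    expect_lt(max(Mod(der$dt1)), 1e-9)
    expect_lt(max(Mod(der$dt2)), 1e-9)
    expect_lt(max(Mod(der$dl1)), 1e-9)
    expect_lt(max(Mod(der$dl2)), 1e-9)
  }
  der <- eom_derivative(gs_of("omp2")$state, ints)
  expect_lt(max(Mod(der$dt2)), 1e-9)
  expect_lt(max(Mod(der$dU)), 1e-9)
})

test_that("derivatives are affine in the external field", {
  ints <- fix2e()
  st <- gs_of("ccsd")$state
  V <- -0.02 * ints$dipole[[3]]
  d0 <- eom_derivative(st, ints)
  d1 <- eom_derivative(st, ints, V)
  d2 <- eom_derivative(st, ints, 2 * V)
  expect_close((d2$dt2 - d0$dt2) - 2 * (d1$dt2 - d0$dt2), 0 * d0$dt2, 1e-12)
  expect_close((d2$dl1 - d0$dl1) - 2 * (d1$dl1 - d0$dl1), 0 * d0$dl1, 1e-12)
})

test_that("the CC2 variants coincide exactly when the singles vanish", {
  ints <- fix5()
  st2 <- random_state("cc2", 2, 5, seed = 5)
  st2$t1 <- 0 * st2$t1
  stb <- st2; stb$method <- "cc2b"
  da <- eom_derivative(st2, ints)
  db <- eom_derivative(stb, ints)
  expect_close(da$dt2, db$dt2, 1e-12)
  expect_close(da$dt1, db$dt1, 1e-12)
  # and differ once singles dress the Fock operator
  st2 <- random_state("cc2", 2, 5, seed = 6)
  stb <- st2; stb$method <- "cc2b"
  expect_gt(max(Mod(eom_derivative(st2, ints)$dt2 -
                      eom_derivative(stb, ints)$dt2)), 1e-10)
})

test_that("CC2 doubles derivative equals the numerical Lagrangian gradient", {
  ints <- fix5()
  st <- random_state("cc2", 2, 5, seed = 8)
  der <- eom_derivative(st, ints)
  # i * dt2 is the gradient of the Hamilton function w.r.t. lambda-2; check
  # elementwise against central differences of the scalar functional
  hof <- function(s) eom_derivative(s, ints)$hamilton
  h <- 1e-6
  for (idx in list(c(1, 2, 1, 2), c(2, 3, 2, 1))) {
    sp <- st; sm <- st
    # perturb the antisymmetric quadruple consistently
    bump <- function(l2, eps) {
      l2[idx[3], idx[4], idx[1], idx[2]] <- l2[idx[3], idx[4], idx[1], idx[2]] + eps
      l2[idx[4], idx[3], idx[1], idx[2]] <- l2[idx[4], idx[3], idx[1], idx[2]] - eps
      l2[idx[3], idx[4], idx[2], idx[1]] <- l2[idx[3], idx[4], idx[2], idx[1]] - eps
      l2[idx[4], idx[3], idx[2], idx[1]] <- l2[idx[4], idx[3], idx[2], idx[1]] + eps
      l2
    }
    sp$l2 <- bump(st$l2, h); sm$l2 <- bump(st$l2, -h)
    fd <- (hof(sp) - hof(sm)) / (2 * h)
    expect_close(fd, 1i * der$dt2[idx[1], idx[2], idx[3], idx[4]], 1e-6)
  }
})

test_that("density matrices satisfy their structural identities", {
  ints <- fix2e()
  # vanishing amplitudes: reference density
  st0 <- cluster_state("omp2", 2, 4)
  dp0 <- density_pair(st0)
  expect_close(dp0$gamma, diag(c(1, 1, 0, 0) + 0i), 1e-14)
  # random orbital-adaptive state: Hermitian densities, particle number
  st <- random_state("omp2", 2, 4, seed = 4)
  dp <- density_pair(st)
  expect_close(dp$gamma, Conj(t(dp$gamma)), 1e-12)
  expect_close(dp$Gamma, Conj(aperm(dp$Gamma, c(3, 4, 1, 2))), 1e-12)
  expect_equal(Re(sum(diag(dp$gamma))), 2, tolerance = 1e-12)
  # expectation of the identity one-body operator is the electron count
  expect_equal(Re(expectation_value(st, one_body = diag(1 + 0i, 4))), 2,
               tolerance = 1e-12)
  # energy via the density trace contract equals the method's Hamilton
  # function (the functional is linear in the integrals, so the gamma/Gamma
  # contraction reconstructs it exactly)
  terms_e <- Re(expectation_value(st, one_body = ints$h, two_body = ints$v))
  hval <- Re(eom_derivative(st, ints)$hamilton)
  expect_equal(terms_e + ints$e_nuc, hval, tolerance = 1e-10)
  # for the untruncated parametrization (CCSD) the same contract equals the
  # dense bivariational bracket
  stc <- random_state("ccsd", 2, 4, seed = 4)
  db <- dense_bivariational(dense_hamiltonian(ints), 2, t1 = stc$t1,
                            t2 = stc$t2, l1 = stc$l1, l2 = stc$l2)
  fr <- rtcc:::.method_frame(stc, ints)
  ec <- expectation_value(stc, one_body = fr$tensors$h,
                          two_body = fr$tensors$v)
  expect_close(ec + ints$e_nuc, db$hamilton, 1e-10)
})

test_that("reference-state dipole is the occupied diagonal sum", {
  ints <- fix2e()
  st0 <- cluster_state("ccsd", 2, 4)
  obs <- state_observables(st0, ints)
  expect_equal(obs$dipole[3], Re(sum(diag(ints$dipole[[3]])[1:2])),
               tolerance = 1e-12)
})

test_that("the orbital-rotation solve satisfies its linear system", {
  ints <- fix2e()
  st <- random_state("omp2", 2, 4, seed = 9)
  der <- eom_derivative(st, ints)
  dp <- density_pair(st)
  # residual of gamma_vv^T K - K gamma_oo^T = -i G_ov^T
  frame <- rtcc:::.method_frame(st, ints)
  plan <- rtcc:::compile_hamiltonian("omp2", 2, 4)
  ev <- rtcc:::eval_compiled(plan, frame$tensors, c("h", "v"))
  G <- rtcc:::dressing_gradient(ev$grad$h, ev$grad$v,
                                frame$tensors$h, frame$tensors$v)
  K <- der$kappa_dot
  lhs <- t(dp$gamma[3:4, 3:4]) %*% K - K %*% t(dp$gamma[1:2, 1:2])
  rhs <- -1i * t(G[1:2, 3:4])
  expect_close(lhs, rhs, 1e-10)
})

test_that("orbital-adaptive dynamics reduce to the exact mean-field limit", {
  i0 <- make_fixture(seed = 5, n_occ = 2, n_virt = 2, coupling_scale = 0)
  g0 <- solve_omp2_ground_state(i0)
  kick <- field_spec("delta_kick", strength = 1e-2, polarization = c(0, 0, 1))
  sp <- integrator_spec(stages = 3, dt = 0.05)
  tr <- propagate(g0$state, i0, kick, sp, t_final = 5)
  kick$dt_kick <- sp$dt
  fc <- fci_propagate(dense_hamiltonian(i0), kick, tr$t)
  expect_lt(max(abs(tr$mu_z - fc$mu_z)), 1e-10)
})
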