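# Shared fixtures and lazily-cached expensive objects (ground states, dense
# Hamiltonians).  Everything is generated in code; nothing is read from disk.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# interacting two-electron model (CCSD exact; dense oracle cheap)
fix2e <- function() memo("fix2e", make_fixture(seed = 11, n_occ = 2,
                                               n_virt = 2,
                                               coupling_scale = 0.2))

# slightly larger interacting model
fix5 <- function() memo("fix5", make_fixture(seed = 3, n_occ = 2, n_virt = 3,
                                             coupling_scale = 0.3))

# soft model for slow-field (response) protocols
fix_soft <- function() memo("fix_soft",
                            make_fixture(seed = 21, n_occ = 2, n_virt = 2,
                                         coupling_scale = 0.2,
                                         one_body_scale = 0.5))

dense2e <- function() memo("dense2e", dense_hamiltonian(fix2e()))

gs_of <- function(method, ints = fix2e(), key = "2e") {
  memo(paste0("gs_", method, "_", key), ground_state(ints, method))
}

# random antisymmetrized complex amplitudes for property-style tests
random_state <- function(method, nocc, norb, seed = 1, sd = 0.1) {
  set.seed(seed)
  nv <- norb - nocc
  rc <- function(n) complex(real = rnorm(n, sd = sd),
                            imaginary = rnorm(n, sd = sd))
  anti4 <- function(a) a - aperm(a, c(2, 1, 3, 4)) - aperm(a, c(1, 2, 4, 3)) +
    aperm(a, c(2, 1, 4, 3))
  t2 <- anti4(array(rc(nv^2 * nocc^2), c(nv, nv, nocc, nocc)))
  if (method == "omp2") {
    cluster_state(method, nocc, norb, t2 = t2)
  } else {
    l2 <- anti4(array(rc(nocc^2 * nv^2), c(nocc, nocc, nv, nv)))
    cluster_state(method, nocc, norb,
                  t1 = matrix(rc(nv * nocc), nv, nocc),
                  l1 = matrix(rc(nocc * nv), nocc, nv),
                  t2 = t2, l2 = l2)
  }
}

expect_close <- function(a, b, tol) {
  expect_lt(max(Mod(a - b)), tol)
}
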