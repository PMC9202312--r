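#' Time-dependent cluster state
#'
#' Container for the dynamical parameters of a method: the phase
#' amplitude `t0` (carried but excluded from every observable), cluster
#' amplitudes `t1`/`t2`, conjugate amplitudes `l1`/`l2`, and for the
#' orbital-adaptive method the accumulated orbital-coefficient matrix `U`
#' (current orbitals expressed in the reference basis; the instantaneous
#' orbital-rotation generator kappa is always absorbed, so the state never
#' stores a finite kappa).  `l0` is fixed to 1 by intermediate normalization
#' and never evolves.
#'
#' @param method `"ccsd"`, `"cc2"`, `"cc2b"` or `"omp2"`.
#' @param nocc,norb Occupied and total spin-orbital counts.
#' @param t1,t2,l1,l2,U Optional initial values (zeros / identity otherwise).
#' @param t0 Initial phase amplitude.
#' @return Object of class `cluster_state`.
#' @export
cluster_state <- function(method, nocc, norb, t1 = NULL, t2 = NULL,
                          l1 = NULL, l2 = NULL, U = NULL, t0 = 0 + 0i) {
  method <- tolower(method)
  nv <- norb - nocc
  zero2 <- function(d1, d2) matrix(0 + 0i, d1, d2)
  zero4 <- function(d) array(0 + 0i, d)
  st <- list(method = method, nocc = nocc, norb = norb, t0 = as.complex(t0),
             l0 = 1 + 0i)
  if (method %in% c("ccsd", "cc2", "cc2b")) {
    st$t1 <- if (is.null(t1)) zero2(nv, nocc) else t1
    st$l1 <- if (is.null(l1)) zero2(nocc, nv) else l1
  }
  st$t2 <- if (is.null(t2)) zero4(c(nv, nv, nocc, nocc)) else t2
  if (method == "omp2") {
    st$U <- if (is.null(U)) diag(1 + 0i, norb) else U
  } else {
    st$l2 <- if (is.null(l2)) zero4(c(nocc, nocc, nv, nv)) else l2
  }
  structure(st, class = "cluster_state")
}

# effective lambda-2 (slaved to t2 for the orbital-adaptive method, Eq. of
# motion equivalence under unitary rotations)
.state_l2 <- function(state) {
  if (state$method == "omp2") {
    aperm(Conj(state$t2), c(3, 4, 1, 2))
  } else {
    state$l2
  }
}

# Assemble the primitive tensors of the Hamilton-function table for the
# current state: T1-dressed integrals for the conventional methods,
# kappa-absorbed (current-basis) integrals for the orbital-adaptive one.
# `field_matrix` is the one-body interaction -E(t).mu in the REFERENCE basis.
.method_frame <- function(state, ints, field_matrix = NULL) {
  L <- state$norb
  nocc <- state$nocc
  h_tot <- ints$h
  if (!is.null(field_matrix)) h_tot <- h_tot + field_matrix
  if (state$method == "omp2") {
    U <- state$U
    Ud <- Conj(t(U))
    h <- Ud %*% h_tot %*% U
    v <- transform_two_body(ints$v, Ud, U)
    dip <- function() lapply(ints$dipole, function(m) Ud %*% m %*% U)
    tensors <- list(h = h, v = v, t2 = state$t2, l2 = .state_l2(state))
  } else {
    M <- matrix(0 + 0i, L, L)
    M[(nocc + 1):L, seq_len(nocc)] <- state$t1
    Em <- diag(1 + 0i, L) - M
    Ep <- diag(1 + 0i, L) + M
    h <- Em %*% h_tot %*% Ep
    v <- transform_two_body(ints$v, Em, Ep)
    dip <- function() lapply(ints$dipole, function(m) Em %*% m %*% Ep)
    tensors <- list(h = h, v = v, t2 = state$t2, l1 = state$l1,
                    l2 = .state_l2(state))
    if (state$method == "cc2") {
      # bare Fock operator (plus field), untransformed
      tensors$fb <- build_fock(ints, h = h_tot)
    }
  }
  list(tensors = tensors, dipole_fun = dip, h_tot = h_tot)
}

#' Equations of motion: time derivative of a cluster state
#'
#' Evaluates the bivariational equations of motion for the state's method:
#' the amplitude derivatives \eqn{i\dot\tau_\mu = \partial H/\partial
#' \lambda_\mu}, the conjugate-amplitude derivatives \eqn{i\dot\lambda_\mu =
#' -\partial H/\partial\tau^\mu}, the (ignorable) phase derivative, and for
#' the orbital-adaptive method the orbital equation of motion obtained by
#' solving the density-weighted linear system for the rotation generator.
#'
#' @param state A `cluster_state`.
#' @param ints An `integral_set`.
#' @param field_matrix Optional L x L interaction matrix \eqn{-E(t)\cdot\mu}
#'   in the reference orbital basis.
#' @return List with the derivatives of every dynamical field (`dt0`, `dt1`,
#'   `dt2`, `dl1`, `dl2`, `dU` as applicable) plus `hamilton` (complex value
#'   of the Hamilton function including nuclear repulsion).
#' @export
eom_derivative <- function(state, ints, field_matrix = NULL) {
  nocc <- state$nocc; L <- state$norb; nv <- L - nocc
  frame <- .method_frame(state, ints, field_matrix)
  plan <- compile_hamiltonian(state$method, nocc, L)
  grads <- c("l2", "t2", "h", "v")
  if (state$method %in% c("ccsd", "cc2", "cc2b")) grads <- c(grads, "l1")
  ev <- eval_compiled(plan, frame$tensors, grads)
  e_proj <- ev$energy_value + ints$e_nuc
  out <- list(hamilton = ev$value + ints$e_nuc, dt0 = -1i * e_proj)
  omega2 <- antisymmetrize_pairs(aperm(ev$grad$l2, c(3, 4, 1, 2)))
  out$dt2 <- -1i * omega2
  if (state$method == "omp2") {
    D1 <- ev$grad$h
    D2 <- ev$grad$v
    G <- dressing_gradient(D1, D2, frame$tensors$h, frame$tensors$v)
    occ <- seq_len(nocc); vir <- seq.int(nocc + 1L, L)
    g_oo <- D1[occ, occ, drop = FALSE]
    g_vv <- D1[vir, vir, drop = FALSE]
    # i (gamma_vv^T Kvo - Kvo gamma_oo^T) = G_ov^T  (solved for Kvo = dkappa)
    A <- .kron(diag(1 + 0i, nocc), t(g_vv)) - .kron(g_oo, diag(1 + 0i, nv))
    rhs <- -1i * t(G[occ, vir, drop = FALSE])
    x <- tryCatch(solve(A, as.vector(rhs)), error = function(e) NULL)
    if (is.null(x)) {
      sv <- svd(A)
      stop(sprintf(paste0("orbital rotation system is singular ",
                          "(smallest singular value %.3e): an occupied and a ",
                          "virtual density eigenvalue coincide"), min(sv$d)))
    }
    kvo <- matrix(x, nv, nocc)
    K <- matrix(0 + 0i, L, L)
    K[vir, occ] <- kvo
    K[occ, vir] <- -Conj(t(kvo))
    out$dU <- state$U %*% K
    out$kappa_dot <- kvo
  } else {
    out$dt1 <- -1i * t(ev$grad$l1)
    out$dl2 <- 1i * aperm(antisymmetrize_pairs(ev$grad$t2), c(3, 4, 1, 2))
    D1 <- ev$grad$h
    D2 <- ev$grad$v
    G <- dressing_gradient(D1, D2, frame$tensors$h, frame$tensors$v)
    occ <- seq_len(nocc); vir <- seq.int(nocc + 1L, L)
    out$dl1 <- 1i * t(G[vir, occ, drop = FALSE])
    out$densities <- list(D1 = D1, D2 = D2)
  }
  out
}

#' Effective one- and two-body density matrices
#'
#' Returns the density pair of the bivariational expectation-value
#' functional: \eqn{\gamma = \partial H/\partial h} and the anti-symmetrized
#' two-body density \eqn{\Gamma} (normalized so that a two-body expectation
#' value is \eqn{\tfrac14\sum \Gamma^{pq}_{rs}\,\omega^{pq}_{rs}}), in the
#' basis in which the state's amplitudes are defined (T1-dressed frame for
#' the conventional methods, current orbital basis for the orbital-adaptive
#' one).
#'
#' @param state A `cluster_state`.
#' @return List with `gamma` (L x L) and `Gamma` (rank-4), class
#'   `density_pair`.
#' @export
density_pair <- function(state) {
  nocc <- state$nocc; L <- state$norb
  tensors <- list(h = matrix(0 + 0i, L, L), v = array(0 + 0i, rep(L, 4)),
                  t2 = state$t2, l2 = .state_l2(state))
  if (!is.null(state$t1)) tensors$l1 <- state$l1
  if (state$method == "cc2") tensors$fb <- matrix(0 + 0i, L, L)
  plan <- compile_hamiltonian(state$method, nocc, L)
  ev <- eval_compiled(plan, tensors, c("h", "v"))
  D1 <- ev$grad$h
  D2 <- ev$grad$v
  Gam <- D2 - aperm(D2, c(2, 1, 3, 4)) - aperm(D2, c(1, 2, 4, 3)) +
    aperm(D2, c(2, 1, 4, 3))
  structure(list(gamma = D1, Gamma = Gam), class = "density_pair")
}

#' Bivariational expectation value of an operator
#'
#' \eqn{\langle\Omega\rangle = \sum_{pq}\gamma^p_q\,\omega^p_q +
#' \tfrac14\sum \Gamma^{pq}_{rs}\,\omega^{pq}_{rs}} with the effective
#' densities of the state.  One- and two-body operator integrals must be
#' supplied in the same frame conventions as the state (they are dressed /
#' rotated internally when `frame_of` is given).
#'
#' @param state A `cluster_state`.
#' @param one_body Optional L x L one-body integrals (reference basis).
#' @param two_body Optional rank-4 anti-symmetrized two-body integrals.
#' @param frame_of Optional `integral_set` used to build the state's frame
#'   (needed to dress the operator); when `NULL` the operator is assumed to
#'   already be expressed in the state's frame.
#' @return Complex scalar.
#' @export
expectation_value <- function(state, one_body = NULL, two_body = NULL,
                              frame_of = NULL) {
  dp <- density_pair(state)
  val <- 0 + 0i
  if (!is.null(one_body)) {
    ob <- one_body
    if (!is.null(frame_of)) ob <- .operator_in_frame(state, ob)
    val <- val + sum(dp$gamma * ob)
    if (state$method == "cc2") {
      # the bare-Fock commutator block carries its own one-body dependence
      nocc <- state$nocc; L <- state$norb
      tensors <- list(h = matrix(0 + 0i, L, L), v = array(0 + 0i, rep(L, 4)),
                      t2 = state$t2, l1 = state$l1, l2 = state$l2,
                      fb = matrix(0 + 0i, L, L))
      Dfb <- table_grad(hamilton_terms("cc2"), tensors, "fb", nocc, L)
      val <- val + sum(Dfb * one_body)
    }
  }
  if (!is.null(two_body)) {
    tb <- two_body
    val <- val + 0.25 * sum(dp$Gamma * tb)
  }
  val
}

# dress / rotate a one-body operator into the state's frame
.operator_in_frame <- function(state, op) {
  L <- state$norb; nocc <- state$nocc
  if (state$method == "omp2") {
    Conj(t(state$U)) %*% op %*% state$U
  } else {
    M <- matrix(0 + 0i, L, L)
    M[(nocc + 1):L, seq_len(nocc)] <- state$t1
    (diag(1 + 0i, L) - M) %*% op %*% (diag(1 + 0i, L) + M)
  }
}

#' Observables of a state
#'
#' Computes the dipole expectation values (real parts of the bivariational
#' functional) and the energy (real and imaginary part of the Hamilton
#' function) for recording along a trajectory.
#'
#' @param state A `cluster_state`.
#' @param ints An `integral_set`.
#' @param field_matrix Optional interaction matrix at the current time
#'   (enters the energy only through the Hamilton function).
#' @return List with `dipole` (length-3 real), `energy` (complex).
#' @export
state_observables <- function(state, ints, field_matrix = NULL) {
  frame <- .method_frame(state, ints, field_matrix)
  plan <- compile_hamiltonian(state$method, state$nocc, state$norb)
  ev <- eval_compiled(plan, frame$tensors,
                      grads = c("h", if (state$method == "cc2") "fb"))
  dip <- frame$dipole_fun()
  mu <- vapply(seq_len(3), function(k) {
    m <- sum(ev$grad$h * dip[[k]])
    if (state$method == "cc2") {
      m <- m + sum(ev$grad$fb * ints$dipole[[k]])
    }
    Re(m)
  }, numeric(1))
  list(dipole = mu, energy = ev$value + ints$e_nuc)
}
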