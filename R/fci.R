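# Dense determinant-space reference routines.
#
# These build the electronic Hamiltonian, excitation operators and exact
# (full configuration interaction) propagation directly in the basis of
# Slater determinants of the N-electron sector.  They are independent of the
# tensor-contraction equation-of-motion code and serve as cross-validation
# oracles on small model systems (the construction is exponential in the
# orbital count and is intended for L <= 10 or so).

#' Determinant basis of the N-electron sector
#'
#' @param n_orbitals Number of spin orbitals L.
#' @param n_electrons Number of electrons N.
#' @return Integer matrix, one column per determinant, rows = occupied
#'   orbital indices (ascending).  The first column is the reference
#'   determinant (orbitals 1..N).
#' @export
slater_basis <- function(n_orbitals, n_electrons) {
  cols <- utils::combn(n_orbitals, n_electrons)
  # put the reference determinant first
  ref <- which(apply(cols, 2, function(x) all(x == seq_len(n_electrons))))
  cols[, c(ref, setdiff(seq_len(ncol(cols)), ref)), drop = FALSE]
}

# Apply a_q to an occupation vector; returns list(occ=..., sign=...) or NULL.
.annihilate <- function(occ, q) {
  pos <- match(q, occ)
  if (is.na(pos)) return(NULL)
  list(occ = occ[-pos], sign = (-1)^(pos - 1))
}

# Apply a_p^dagger.
.create <- function(occ, p) {
  if (p %in% occ) return(NULL)
  nbelow <- sum(occ < p)
  list(occ = sort(c(occ, p)), sign = (-1)^nbelow)
}

#' One-body replacement operators in the determinant basis
#'
#' Builds dense matrices of \eqn{E_{pq} = a_p^\dagger a_q} for all p, q over
#' the N-electron determinant basis.
#'
#' @param basis Matrix from [slater_basis()].
#' @param n_orbitals L.
#' @return A list `E` with `E[[p]][[q]]` the D x D matrix, plus the key map.
#' @export
replacement_operators <- function(basis, n_orbitals) {
  D <- ncol(basis)
  key <- apply(basis, 2, paste, collapse = ",")
  lookup <- stats::setNames(seq_len(D), key)
  E <- vector("list", n_orbitals)
  for (p in seq_len(n_orbitals)) {
    E[[p]] <- vector("list", n_orbitals)
    for (q in seq_len(n_orbitals)) {
      m <- matrix(0, D, D)
      for (d in seq_len(D)) {
        occ <- basis[, d]
        s1 <- .annihilate(occ, q)
        if (is.null(s1)) next
        s2 <- .create(s1$occ, p)
        if (is.null(s2)) next
        tgt <- lookup[[paste(s2$occ, collapse = ",")]]
        m[tgt, d] <- m[tgt, d] + s1$sign * s2$sign
      }
      E[[p]][[q]] <- m
    }
  }
  E
}

#' Dense Hamiltonian (and one-body operator) matrices
#'
#' Assembles \eqn{H = \sum h^p_q E_{pq} + \tfrac14 \sum v^{pq}_{rs}
#' (E_{pr} E_{qs} - \delta_{qr} E_{ps})} over the determinant basis, plus the
#' three dipole matrices.  The nuclear repulsion is added to the diagonal.
#'
#' @param ints An `integral_set`.
#' @return List with `H`, `dipole` (list of 3), `basis`, `E` (replacement
#'   operators), `D` (dimension).
#' @export
dense_hamiltonian <- function(ints) {
  L <- ints$n_orbitals
  basis <- slater_basis(L, ints$n_electrons)
  E <- replacement_operators(basis, L)
  D <- ncol(basis)
  one_body <- function(mat) {
    M <- matrix(0 + 0i, D, D)
    for (p in seq_len(L)) for (q in seq_len(L)) {
      if (mat[p, q] != 0) M <- M + mat[p, q] * E[[p]][[q]]
    }
    M
  }
  H <- one_body(ints$h)
  v <- ints$v
  for (p in seq_len(L)) for (r in seq_len(L)) {
    # M_pr = sum_{qs} v[p,q,r,s] E_qs
    Mpr <- matrix(0 + 0i, D, D)
    any_nz <- FALSE
    for (q in seq_len(L)) for (s in seq_len(L)) {
      if (v[p, q, r, s] != 0) {
        Mpr <- Mpr + v[p, q, r, s] * E[[q]][[s]]
        any_nz <- TRUE
      }
    }
    if (!any_nz) next
    H <- H + 0.25 * (E[[p]][[r]] %*% Mpr)
    # the -delta_qr E_ps correction: q == r
    for (s in seq_len(L)) {
      if (v[p, r, r, s] != 0) H <- H - 0.25 * v[p, r, r, s] * E[[p]][[s]]
    }
  }
  H <- H + diag(ints$e_nuc + 0i, D)
  list(H = H, dipole = lapply(ints$dipole, one_body),
       basis = basis, E = E, D = D)
}

#' Exact wave-function propagation in the determinant basis
#'
#' Propagates \eqn{i\dot\psi = H(t)\psi} exactly through intervals on which
#' the Hamiltonian is piecewise constant (the delta-kick protocol), using
#' eigendecomposition of each interval Hamiltonian, and records the dipole
#' expectation values.
#'
#' @param dense Output of [dense_hamiltonian()] (carries the dense dipole
#'   matrices used for the kick coupling and the recorded expectations).
#' @param field A [field_spec()]; only `none` and `delta_kick` protocols are
#'   piecewise constant and supported here.
#' @param times Vector of record times (uniform grid starting at 0); for a
#'   delta kick the first interval `[0, dt_kick)` carries the kick
#'   Hamiltonian.
#' @param psi0 Initial state vector (defaults to the ground state of H).
#' @return Data frame with columns `t`, `mu_x`, `mu_y`, `mu_z`, `energy_re`.
#' @export
fci_propagate <- function(dense, field, times, psi0 = NULL) {
  H0 <- dense$H
  if (is.null(psi0)) {
    eg <- eigen(H0, symmetric = TRUE)
    psi0 <- eg$vectors[, dense$D]
  }
  psi0 <- psi0 / sqrt(sum(Mod(psi0)^2))
  dt <- times[2] - times[1]
  prop_const <- function(H, tau) {
    eg <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
    V <- eg$vectors
    function(psi) drop(V %*% (exp(-1i * eg$values * tau) *
                                drop(Conj(t(V)) %*% psi)))
  }
  psi <- psi0
  out <- matrix(0, length(times), 5)
  mu_mats <- dense$dipole
  record <- function(k, tme, psi) {
    nrm <- sum(Mod(psi)^2)
    out[k, 1] <<- tme
    for (c3 in 1:3) {
      out[k, 1 + c3] <<- Re(sum(Conj(psi) * (mu_mats[[c3]] %*% psi))) / nrm
    }
    out[k, 5] <<- Re(sum(Conj(psi) * (H0 %*% psi))) / nrm
  }
  if (field$kind == "delta_kick") {
    wk <- if (is.null(field$dt_kick)) dt else field$dt_kick
    if (wk > dt + 1e-12) stop("kick width exceeds the record-grid spacing")
    Ef <- field$strength / wk
    Hk <- H0
    for (c3 in 1:3) Hk <- Hk - Ef * field$polarization[c3] * mu_mats[[c3]]
    step_kick <- prop_const(Hk, wk)
    step_rest <- prop_const(H0, dt - wk)
    step_free <- prop_const(H0, dt)
    record(1, times[1], psi)
    psi <- step_rest(step_kick(psi))
    for (k in 2:length(times)) {
      record(k, times[k], psi)
      if (k < length(times)) psi <- step_free(psi)
    }
  } else if (field$kind == "none") {
    step_free <- prop_const(H0, dt)
    for (k in seq_along(times)) {
      record(k, times[k], psi)
      if (k < length(times)) psi <- step_free(psi)
    }
  } else {
    stop("fci_propagate supports only piecewise-constant protocols")
  }
  d <- as.data.frame(out)
  names(d) <- c("t", "mu_x", "mu_y", "mu_z", "energy_re")
  d
}

# --- dense bivariational brackets (oracles for the CC equations) -----------

# Build the determinant-space matrix of the cluster operator
# T = sum_mu t_mu X_mu (singles t1[a,i], doubles t2[a,b,i,j]).
cluster_operator_matrix <- function(dense, nocc, t1 = NULL, t2 = NULL) {
  E <- dense$E
  D <- dense$D
  L <- length(E)
  Tm <- matrix(0 + 0i, D, D)
  vir <- seq.int(nocc + 1L, L)
  if (!is.null(t1)) {
    for (a in seq_along(vir)) for (i in seq_len(nocc)) {
      if (t1[a, i] != 0) Tm <- Tm + t1[a, i] * E[[vir[a]]][[i]]
    }
  }
  if (!is.null(t2)) {
    for (a in seq_along(vir)) for (b in seq_along(vir)) {
      for (i in seq_len(nocc)) for (j in seq_len(nocc)) {
        if (t2[a, b, i, j] != 0) {
          # X_mu = a_a^+ a_b^+ a_j a_i = E_ai E_bj - delta for b==i impossible
          Tm <- Tm + 0.25 * t2[a, b, i, j] *
            (E[[vir[a]]][[i]] %*% E[[vir[b]]][[j]])
        }
      }
    }
  }
  Tm
}

# exp(T) for an excitation operator (nilpotent in the N-electron sector).
exp_nilpotent <- function(Tm, nmax) {
  D <- nrow(Tm)
  R <- diag(1 + 0i, D)
  P <- diag(1 + 0i, D)
  for (k in seq_len(nmax)) {
    P <- P %*% Tm / k
    if (max(Mod(P)) == 0) break
    R <- R + P
  }
  R
}

#' Dense bivariational Hamilton function and residuals
#'
#' Computes, in the determinant basis, the Hamilton function
#' \eqn{\langle\Phi|(1+\Lambda) e^{-T} H e^{T}|\Phi\rangle}, the amplitude
#' residuals \eqn{\Omega_\mu = \langle\Phi_\mu|e^{-T} H e^{T}|\Phi\rangle}
#' and the conjugate-amplitude residuals
#' \eqn{L_\mu = \langle\Phi|(1+\Lambda)[e^{-T}He^{T}, X_\mu]|\Phi\rangle},
#' for arbitrary complex amplitudes.  Used as the independent oracle for the
#' tensor-contraction equations of motion.
#'
#' @param dense Output of [dense_hamiltonian()] (possibly with a field added
#'   to `H` by the caller).
#' @param H Determinant-basis Hamiltonian to use (defaults to `dense$H`).
#' @param nocc Occupied count.
#' @param t1,t2,l1,l2 Cluster amplitudes; `l1[i,a]`, `l2[i,j,a,b]`.
#' @return List with `energy` (projection on the reference), `hamilton`
#'   (bivariational Hamilton function), `omega1`, `omega2`, `lres1`, `lres2`.
#' @export
dense_bivariational <- function(dense, nocc, t1 = NULL, t2 = NULL,
                                l1 = NULL, l2 = NULL, H = NULL) {
  if (is.null(H)) H <- dense$H
  E <- dense$E
  D <- dense$D
  L <- length(E)
  N <- nocc
  vir <- seq.int(nocc + 1L, L)
  nv <- length(vir)
  Tm <- cluster_operator_matrix(dense, nocc, t1, t2)
  eT <- exp_nilpotent(Tm, N + 1L)
  emT <- exp_nilpotent(-Tm, N + 1L)
  Hbar <- emT %*% H %*% eT
  # bra <Phi|(1+Lambda): Lambda = sum l_mu X_mu^dagger
  Lm <- matrix(0 + 0i, D, D)
  if (!is.null(l1)) {
    for (i in seq_len(N)) for (a in seq_len(nv)) {
      if (l1[i, a] != 0) Lm <- Lm + l1[i, a] * t(E[[vir[a]]][[i]])
    }
  }
  if (!is.null(l2)) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      for (a in seq_len(nv)) for (b in seq_len(nv)) {
        if (l2[i, j, a, b] != 0) {
          Lm <- Lm + 0.25 * l2[i, j, a, b] *
            t(E[[vir[a]]][[i]] %*% E[[vir[b]]][[j]])
        }
      }
    }
  }
  e0 <- numeric(D); e0[1] <- 1
  bra <- drop(crossprod(e0, diag(1 + 0i, D) + Lm))  # row vector
  ket <- Hbar[, 1]                                  # Hbar |Phi0>
  energy <- ket[1]
  hamilton <- sum(bra * ket)
# residuals: projections of Hbar|Phi0> on the biorthonormal excited
  # determinants (X_mu|Phi0> is a signed unit vector in this basis)
  omega1 <- matrix(0 + 0i, nv, N)
  for (a in seq_len(nv)) for (i in seq_len(N)) {
    proj <- E[[vir[a]]][[i]][, 1]   # X_mu |Phi0>
    omega1[a, i] <- sum(proj * ket)
  }
  omega2 <- array(0 + 0i, c(nv, nv, N, N))
  for (a in seq_len(nv)) for (b in seq_len(nv)) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      proj <- (E[[vir[a]]][[i]] %*% E[[vir[b]]][[j]])[, 1]
      omega2[a, b, i, j] <- sum(proj * ket)
    }
  }
  # lambda residuals: <Phi|(1+Lambda)[Hbar, X_mu]|Phi0>
  lres1 <- matrix(0 + 0i, N, nv)
  for (i in seq_len(N)) for (a in seq_len(nv)) {
    X <- E[[vir[a]]][[i]]
    comm <- Hbar %*% X - X %*% Hbar
    lres1[i, a] <- sum(bra * comm[, 1])
  }
  lres2 <- array(0 + 0i, c(N, N, nv, nv))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    for (a in seq_len(nv)) for (b in seq_len(nv)) {
      X <- E[[vir[a]]][[i]] %*% E[[vir[b]]][[j]]
      comm <- Hbar %*% X - X %*% Hbar
      lres2[i, j, a, b] <- sum(bra * comm[, 1])
    }
  }
  list(energy = energy, hamilton = hamilton,
       omega1 = omega1, omega2 = omega2, lres1 = lres1, lres2 = lres2)
}
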