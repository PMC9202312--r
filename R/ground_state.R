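# Ground-state solvers: DIIS-accelerated amplitude iteration for the CC
# family and amplitude + diagonal-Hessian orbital iteration for OMP2.

# Simple DIIS accelerator over packed complex vectors.
.diis_new <- function(size = 8L) {
  env <- new.env(parent = emptyenv())
  env$size <- size
  env$amps <- list()
  env$resid <- list()
  env
}

.diis_push <- function(d, amp, res) {
  d$amps[[length(d$amps) + 1L]] <- amp
  d$resid[[length(d$resid) + 1L]] <- res
  if (length(d$amps) > d$size) {
    d$amps <- d$amps[-1L]
    d$resid <- d$resid[-1L]
  }
}

.diis_extrapolate <- function(d) {
  n <- length(d$amps)
  if (n < 2L) return(d$amps[[n]])
  B <- matrix(0 + 0i, n + 1L, n + 1L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    B[i, j] <- sum(Conj(d$resid[[i]]) * d$resid[[j]])
  }
  B[n + 1L, seq_len(n)] <- -1
  B[seq_len(n), n + 1L] <- -1
  rhs <- c(rep(0 + 0i, n), -1)
  coef <- tryCatch(solve(B, rhs)[seq_len(n)],
                   error = function(e) NULL)
  if (is.null(coef)) return(d$amps[[n]])
  out <- 0
  for (i in seq_len(n)) out <- out + coef[i] * d$amps[[i]]
  out
}

# orbital-energy denominators from the (possibly non-diagonal) Fock matrix
.denoms <- function(f, nocc, norb) {
  eps <- Re(diag(f))
  occ <- seq_len(nocc); vir <- seq.int(nocc + 1L, norb)
  d1 <- outer(eps[occ], eps[vir], `-`)          # [i, a] = eps_i - eps_a
  d2 <- array(0, c(norb - nocc, norb - nocc, nocc, nocc))
  for (a in seq_along(vir)) for (b in seq_along(vir)) {
    d2[a, b, , ] <- outer(eps[occ], eps[occ], `+`) -
      eps[vir[a]] - eps[vir[b]]
  }
  list(d1 = t(d1), d2 = d2)                     # d1 as [a, i]
}

#' First-order (MP2-type) doubles amplitudes
#'
#' Solves the first-order doubles equation
#' \eqn{0 = v^{ab}_{ij} + P(ab)\sum_c f_{bc} t^{ac}_{ij} - P(ij)\sum_k
#' f_{kj} t^{ab}_{ik}} for a general (non-diagonal) Fock matrix by
#' denominator-preconditioned fixed-point iteration with DIIS; for a
#' diagonal Fock this reduces to the closed form
#' \eqn{t^{ab}_{ij} = v^{ab}_{ij} / (f_{ii}+f_{jj}-f_{aa}-f_{bb})}.
#'
#' @param ints An `integral_set`.
#' @param h Optional replacement one-body matrix (e.g. with a static field).
#' @param tol Residual-norm convergence threshold.
#' @param max_iter Iteration cap.
#' @return Rank-4 doubles amplitude tensor `t2[a,b,i,j]`, antisymmetric in
#'   both index pairs.
#' @export
mp2_amplitudes <- function(ints, h = NULL, tol = 1e-10, max_iter = 200L) {
  nocc <- ints$n_electrons; L <- ints$n_orbitals
  f <- build_fock(ints, h = h)
  dn <- .denoms(f, nocc, L)
  if (any(abs(dn$d2) < 1e-8))
    stop("vanishing occupied-virtual gap: first-order amplitudes diverge")
  occ <- seq_len(nocc); vir <- seq.int(nocc + 1L, L)
  vvoo <- ints$v[vir, vir, occ, occ, drop = FALSE]
  t2 <- vvoo / dn$d2
  resid_fun <- function(t2) {
    r <- vvoo
    fvv <- f[vir, vir, drop = FALSE]; foo <- f[occ, occ, drop = FALSE]
    # + P(ab) sum_c f[b,c] t[a,c,i,j]
    tc <- .pair_contract(t2, c("a", "c", "i", "j"), fvv, c("b", "c"), "c")
    x <- aperm(tc$arr, match(c("a", "b", "i", "j"), tc$letters))
    r <- r + x - aperm(x, c(2, 1, 3, 4))
    # - P(ij) sum_k f[k,j] t[a,b,i,k]
    tk <- .pair_contract(t2, c("a", "b", "i", "k"), foo, c("k", "j"), "k")
    y <- aperm(tk$arr, match(c("a", "b", "i", "j"), tk$letters))
    r <- r - y + aperm(y, c(1, 2, 4, 3))
    r
  }
  d <- .diis_new()
  for (it in seq_len(max_iter)) {
    r <- resid_fun(t2)
    if (sqrt(sum(Mod(r)^2)) < tol) return(t2)
    t2 <- t2 + r / dn$d2
    .diis_push(d, as.vector(t2), as.vector(r))
    t2 <- array(.diis_extrapolate(d), dim = dim(t2))
  }
  stop("first-order doubles equation did not converge in ", max_iter,
       " iterations")
}

#' Ground state of the coupled-cluster family
#'
#' Solves the stationary amplitude equations (the zero-field equations of
#' motion) for CCSD, CC2 or CC2-b with denominator-preconditioned DIIS
#' iterations, then the conjugate (lambda) equations the same way.  The
#' energy is the real part of the Hamilton function at the solution.
#'
#' @param ints An `integral_set`.
#' @param model `"ccsd"`, `"cc2"` or `"cc2b"`.
#' @param tol Residual-norm threshold (applied to amplitude and lambda
#'   residuals separately).
#' @param max_iter Iteration cap per equation set.
#' @param diis Logical; turn DIIS extrapolation off for plain fixed-point
#'   iteration.
#' @return List of class `ground_state_result`: converged `state`
#'   (a [cluster_state()]), `energy`, `residual_history`, `iterations`.
#' @export
solve_cc_ground_state <- function(ints, model = c("ccsd", "cc2", "cc2b"),
                                  tol = 1e-10, max_iter = 500L, diis = TRUE) {
  model <- match.arg(model)
  nocc <- ints$n_electrons; L <- ints$n_orbitals
  f <- build_fock(ints)
  dn <- .denoms(f, nocc, L)
  state <- cluster_state(model, nocc, L, t2 = mp2_amplitudes(ints))
  hist <- numeric(0)
  d <- .diis_new()
  pack <- function(s) c(as.vector(s$t1), as.vector(s$t2))
  unpack <- function(s, x) {
    n1 <- length(s$t1)
    s$t1 <- matrix(x[seq_len(n1)], nrow(s$t1), ncol(s$t1))
    s$t2 <- array(x[-seq_len(n1)], dim = dim(s$t2))
    s
  }
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    der <- eom_derivative(state, ints)
    om1 <- 1i * der$dt1            # amplitude residuals Omega_mu
    om2 <- 1i * der$dt2
    rn <- sqrt(sum(Mod(om1)^2) + sum(Mod(om2)^2))
    hist <- c(hist, rn)
    if (rn < tol) { conv <- TRUE; break }
    state$t1 <- state$t1 + om1 / dn$d1
    state$t2 <- state$t2 + om2 / dn$d2
    if (diis) {
      .diis_push(d, pack(state), c(as.vector(om1), as.vector(om2)))
      state <- unpack(state, .diis_extrapolate(d))
    }
  }
  if (!conv) {
    stop("amplitude equations did not converge; residual history: ",
         paste(signif(utils::tail(hist, 5), 3), collapse = ", "))
  }
  n_amp_iter <- it
  # lambda equations, initialized from the conjugate amplitudes
  state$l1 <- Conj(t(state$t1))
  state$l2 <- aperm(Conj(state$t2), c(3, 4, 1, 2))
  d <- .diis_new()
  packl <- function(s) c(as.vector(s$l1), as.vector(s$l2))
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    der <- eom_derivative(state, ints)
    lr1 <- -1i * der$dl1           # lambda residuals dH/dtau
    lr2 <- -1i * der$dl2
    rn <- sqrt(sum(Mod(lr1)^2) + sum(Mod(lr2)^2))
    hist <- c(hist, rn)
    if (rn < tol) { conv <- TRUE; break }
    state$l1 <- state$l1 + lr1 / t(dn$d1)
    state$l2 <- state$l2 + lr2 / aperm(dn$d2, c(3, 4, 1, 2))
    if (diis) {
      .diis_push(d, packl(state), c(as.vector(lr1), as.vector(lr2)))
      x <- .diis_extrapolate(d)
      n1 <- length(state$l1)
      state$l1 <- matrix(x[seq_len(n1)], nocc, L - nocc)
      state$l2 <- array(x[-seq_len(n1)], dim = dim(state$l2))
    }
  }
  if (!conv) {
    stop("lambda equations did not converge; residual history: ",
         paste(signif(utils::tail(hist, 5), 3), collapse = ", "))
  }
  energy <- Re(eom_derivative(state, ints)$hamilton)
  structure(list(method = model, state = state, energy = energy,
                 residual_history = hist,
                 iterations = n_amp_iter + it), class = "ground_state_result")
}

#' Orbital-optimized MP2 ground state
#'
#' Alternates first-order doubles solves with orbital-rotation updates using
#' the diagonal approximation of the orbital Hessian (gradient divided by
#' twice the occupied-virtual Fock gap, with a minimum-denominator level
#' shift), absorbing each rotation into the accumulated orbital coefficient
#' matrix.  At convergence both the doubles residual and the orbital
#' gradient vanish, the conjugate doubles equal the complex conjugate of the
#' doubles, and the effective densities are Hermitian.
#'
#' @param ints An `integral_set`.
#' @param h Optional replacement one-body matrix (static-field studies).
#' @param tol Residual-norm threshold on the combined amplitude/orbital
#'   gradient.
#' @param max_iter Iteration cap.
#' @param level_shift Minimum denominator magnitude for the diagonal-Hessian
#'   update.
#' @return List of class `ground_state_result` with the converged `state`
#'   (holding the absorbed orbital rotation in `U`), `energy`,
#'   `residual_history`, `iterations`.
#' @export
solve_omp2_ground_state <- function(ints, h = NULL, tol = 1e-10,
                                    max_iter = 500L, level_shift = 1e-3) {
  nocc <- ints$n_electrons; L <- ints$n_orbitals; nv <- L - nocc
  occ <- seq_len(nocc); vir <- seq.int(nocc + 1L, L)
  ints_eff <- ints
  if (!is.null(h)) { ints_eff$h <- as_complex_matrix(h) }
  state <- cluster_state("omp2", nocc, L)
  hist <- numeric(0)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    # current-basis integrals and Fock
    frame <- .method_frame(state, ints_eff)
    hc <- frame$tensors$h; vc <- frame$tensors$v
    fc <- hc
    for (k in occ) fc <- fc + vc[, k, , k]
    # doubles solve (first-order equation in the current basis)
    state$t2 <- mp2_amplitudes_from(hc, vc, nocc, tol = max(tol, 1e-12))
    # orbital gradient of the real energy via the dressing chain rule
    G <- .omp2_orbital_gradient(state, ints_eff)
    w <- G[vir, occ, drop = FALSE] - Conj(t(G[occ, vir, drop = FALSE]))
    grad_norm <- sqrt(sum(Mod(w)^2))
    hist <- c(hist, grad_norm)
    if (grad_norm < tol) { conv <- TRUE; break }
    # diagonal-Hessian step on the unitary generator, level-shifted
    denom <- 2 * outer(Re(diag(fc))[vir], Re(diag(fc))[occ], `-`)
    small <- abs(denom) < level_shift
    if (any(small)) {
      denom[small] <- sign(denom[small] + (denom[small] == 0)) * level_shift
      warning("small orbital-Hessian denominator: level shift applied")
    }
    step <- -w / denom
    K <- matrix(0 + 0i, L, L)
    K[vir, occ] <- step
    K[occ, vir] <- -Conj(t(step))
    state$U <- state$U %*% mat_exp(K)
  }
  if (!conv) {
    stop("OMP2 iteration did not converge; gradient history: ",
         paste(signif(utils::tail(hist, 5), 3), collapse = ", "))
  }
  der <- eom_derivative(state, ints_eff)
  energy <- Re(der$hamilton)
  structure(list(method = "omp2", state = state, energy = energy,
                 residual_history = hist, iterations = it),
            class = "ground_state_result")
}

# first-order doubles from explicit current-basis integrals
mp2_amplitudes_from <- function(h, v, nocc, tol = 1e-10, max_iter = 200L) {
  L <- nrow(h)
  fake <- structure(list(n_electrons = nocc, n_orbitals = L, h = h,
                         v = v, occ_mask = seq_len(L) <= nocc, e_nuc = 0,
                         dipole = replicate(3, matrix(0 + 0i, L, L),
                                            simplify = FALSE)),
                    class = "integral_set")
  mp2_amplitudes(fake, tol = tol, max_iter = max_iter)
}

# Hamilton-function gradient with respect to the orbital-rotation generator
# at kappa = 0 (current basis), with lambda slaved to the amplitudes.
.omp2_orbital_gradient <- function(state, ints) {
  frame <- .method_frame(state, ints)
  plan <- compile_hamiltonian("omp2", state$nocc, state$norb)
  ev <- eval_compiled(plan, frame$tensors, c("h", "v"))
  dressing_gradient(ev$grad$h, ev$grad$v, frame$tensors$h, frame$tensors$v)
}
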