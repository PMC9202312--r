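#' Orbital transform specification
#'
#' Describes a similarity transformation of the integrals by an exponential
#' one-body operator: `t1` (singles cluster dressing, virtual-occupied block
#' only, nilpotent), `kappa` (general occupied-virtual rotation, possibly
#' non-unitary) or `unitary-kappa` (anti-Hermitian generator).
#'
#' @param kind One of `"t1"`, `"kappa"`, `"unitary-kappa"`.
#' @param shift For `"t1"`: the virtual x occupied amplitude block (or a full
#'   L x L matrix whose only nonzero block is virtual-occupied).  For the
#'   kappa kinds: the full L x L generator matrix.
#' @param n_occ Number of occupied orbitals (needed to place a block).
#' @param n_orbitals Total orbital count.
#' @return An object of class `orbital_transform` holding the full generator.
#' @export
orbital_transform <- function(kind = c("t1", "kappa", "unitary-kappa"),
                              shift, n_occ, n_orbitals) {
  kind <- match.arg(kind)
  L <- n_orbitals
  M <- matrix(0 + 0i, L, L)
  shift <- as_complex_matrix(shift)
  if (all(dim(shift) == c(L, L))) {
    M <- shift
  } else if (kind == "t1") {
    M[(n_occ + 1):L, seq_len(n_occ)] <- shift
  } else {
    stop("kappa transforms need a full L x L generator")
  }
  occ <- seq_len(n_occ); vir <- setdiff(seq_len(L), occ)
  if (kind == "t1") {
    if (max(Mod(M[occ, , drop = FALSE])) > 0 ||
        max(Mod(M[vir, vir, drop = FALSE])) > 0)
      stop("t1 transform: only the virtual-occupied block may be nonzero")
  }
  if (kind == "unitary-kappa" &&
      max(Mod(M + Conj(t(M)))) > 1e-12)
    stop("unitary-kappa transform needs an anti-Hermitian generator")
  structure(list(kind = kind, generator = M, n_occ = n_occ,
                 n_orbitals = L), class = "orbital_transform")
}

# Dense matrix exponential by scaling and squaring of the Taylor series;
# adequate for the small generator matrices used here.
mat_exp <- function(M, order = 16L) {
  L <- nrow(M)
  nrm <- max(rowSums(Mod(M)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps))) + 1L)
  A <- M / 2^s
  R <- diag(1 + 0i, L)
  P <- diag(1 + 0i, L)
  for (k in seq_len(order)) {
    P <- P %*% A / k
    R <- R + P
  }
  for (k in seq_len(s)) R <- R %*% R
  R
}

# Transform a rank-4 tensor under the one-body similarity transform: upper
# (creation) indices contract with Em = exp(-X) from the left, lower
# (annihilation) indices with Ep = exp(X) from the right.
# fast Kronecker product for small dense matrices
.kron <- function(A, B) {
  m <- nrow(A); n <- nrow(B); p <- ncol(A); q <- ncol(B)
  A[rep(seq_len(m), each = n), rep(seq_len(p), each = q), drop = FALSE] *
    B[rep(seq_len(n), m), rep(seq_len(q), p), drop = FALSE]
}

transform_two_body <- function(v, Em, Ep) {
  L <- dim(v)[1]
  # pair the (p,q) and (r,s) axes and transform with Kronecker factors:
  # v'[pq, rs] = (Em (x) Em)[pq, p'q'] v[p'q', r's'] (Ep (x) Ep)[r's', rs]
  dim(v) <- c(L * L, L * L)
  v <- .kron(Em, Em) %*% v %*% .kron(Ep, Ep)
  dim(v) <- rep(L, 4)
  v
}

#' Similarity-transform an integral set
#'
#' Applies the exponential similarity transformation
#' \eqn{\tilde h = e^{-X} h e^{X}} (and the analogous four-index transform on
#' the two-body tensor and the dipole matrices) for the generator stored in
#' an [orbital_transform()].  For the `t1` kind this reproduces the standard
#' T1-dressing of the integrals; for `unitary-kappa` the transformed one-body
#' matrix remains Hermitian; for a general `kappa` Hermiticity is not
#' guaranteed and the validator is therefore bypassed.
#'
#' @param ints An `integral_set`.
#' @param xf An `orbital_transform`.
#' @return A list with the same fields as an `integral_set` (class kept),
#'   containing the transformed `h`, `u`, `v` and `dipole`.
#' @export
transform_integrals <- function(ints, xf) {
  stopifnot(inherits(xf, "orbital_transform"))
  M <- xf$generator
  if (xf$kind == "t1") {
    Em <- diag(1 + 0i, nrow(M)) - M   # exp(-M), M nilpotent of order 2
    Ep <- diag(1 + 0i, nrow(M)) + M
  } else {
    Em <- mat_exp(-M)
    Ep <- mat_exp(M)
  }
  h2 <- Em %*% ints$h %*% Ep
  u2 <- transform_two_body(ints$u, Em, Ep)
  dip2 <- lapply(ints$dipole, function(m) Em %*% m %*% Ep)
  if (any(!is.finite(Mod(h2)))) stop("transform produced non-finite elements")
  out <- ints
  out$h <- h2
  out$u <- u2
  out$v <- antisymmetrize_two_body(u2)
  out$dipole <- dip2
  out
}
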