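# Hamilton-function tables.
#
# Every dynamical method in the package is defined by a single scalar: the
# bivariational Hamilton function H(t, lambda) = <Phi|(1+Lambda) e^-T H(t)
# e^T|Phi>, written as a table of tensor contractions over T1-dressed (or
# kappa-transformed) integrals.  All working quantities are generic
# derivatives of this scalar:
#
#   amplitude EOM    :  i d(tau_mu)/dt   =  dH/d(lambda_mu)
#   conjugate EOM    :  i d(lambda_mu)/dt = -dH/d(tau^mu)
#   densities        :  gamma = dH/dh,  Gamma ~ dH/dv
#   orbital/singles  :  chain rule of the exponential dressing (commutator
#                       form), evaluated from gamma and Gamma
#
# so each equation term appears exactly once, in the index-string table
# below.  Primitive tensor names: h (one-body, field included, dressed where
# applicable), v (anti-symmetrized two-body, dressed where applicable),
# fb (bare Fock plus field; plain CC2 only), t2, l1, l2.

.table_cache <- new.env(parent = emptyenv())

# energy terms shared by all methods (reference + doubles correlation)
.energy_terms <- function() {
  list(.term(1.0, c("h", "ii")),
       .term(0.5, c("v", "ijij")),
       .term(0.25, c("v", "ijab"), c("t2", "abij")))
}

# singles projection terms (CCSD and CC2, in dressed integrals)
.singles_terms <- function() {
  list(.term(1.0, c("l1", "ia"), c("h", "ai")),
       .term(1.0, c("l1", "ia"), c("v", "akik")),
       .term(1.0, c("l1", "ia"), c("t2", "acik"), c("h", "kc")),
       .term(1.0, c("l1", "ia"), c("t2", "acik"), c("v", "klcl")),
       .term(0.5, c("l1", "ia"), c("v", "akcd"), c("t2", "cdik")),
       .term(-0.5, c("l1", "ia"), c("v", "klic"), c("t2", "ackl")))
}

# doubles projection, full CCSD (dressed CCD form)
.ccsd_doubles_terms <- function() {
  list(.term(0.25, c("l2", "ijab"), c("v", "abij")),
       .term(0.5, c("l2", "ijab"), c("t2", "acij"), c("h", "bc")),
       .term(0.5, c("l2", "ijab"), c("t2", "acij"), c("v", "bkck")),
       .term(-0.25, c("l2", "ijab"), c("t2", "acij"), c("v", "klcd"), c("t2", "bdkl")),
       .term(-0.5, c("l2", "ijab"), c("t2", "abik"), c("h", "kj")),
       .term(-0.5, c("l2", "ijab"), c("t2", "abik"), c("v", "kljl")),
       .term(-0.25, c("l2", "ijab"), c("t2", "abik"), c("v", "klcd"), c("t2", "cdjl")),
       .term(0.125, c("l2", "ijab"), c("v", "klij"), c("t2", "abkl")),
       .term(0.125, c("l2", "ijab"), c("v", "abcd"), c("t2", "cdij")),
       .term(0.0625, c("l2", "ijab"), c("v", "klcd"), c("t2", "cdij"), c("t2", "abkl")),
       .term(1.0, c("l2", "ijab"), c("v", "kbcj"), c("t2", "acik")),
       .term(0.5, c("l2", "ijab"), c("v", "klcd"), c("t2", "acik"), c("t2", "bdjl")))
}

# doubles projection, CC2 family: driver + one-body (Fock) commutator only.
# `fock` selects the operator in the commutator: "bare" (plain CC2, the
# untransformed Fock plus field, primitive `fb`) or "dressed" (CC2-b and
# OMP2: the Fock matrix of the dressed/current-basis integrals).
.cc2_doubles_terms <- function(fock = c("bare", "dressed")) {
  fock <- match.arg(fock)
  base <- list(.term(0.25, c("l2", "ijab"), c("v", "abij")))
  if (fock == "bare") {
    c(base,
      list(.term(0.5, c("l2", "ijab"), c("t2", "acij"), c("fb", "bc")),
           .term(-0.5, c("l2", "ijab"), c("t2", "abik"), c("fb", "kj"))))
  } else {
    c(base,
      list(.term(0.5, c("l2", "ijab"), c("t2", "acij"), c("h", "bc")),
           .term(0.5, c("l2", "ijab"), c("t2", "acij"), c("v", "bkck")),
           .term(-0.5, c("l2", "ijab"), c("t2", "abik"), c("h", "kj")),
           .term(-0.5, c("l2", "ijab"), c("t2", "abik"), c("v", "kljl"))))
  }
}

#' Hamilton-function contraction table for a method
#'
#' @param method One of `"ccsd"`, `"cc2"`, `"cc2b"`, `"omp2"`.
#' @return List of contraction terms defining the scalar Hamilton function.
#' @export
hamilton_terms <- function(method) {
  method <- tolower(method)
  if (!is.null(.table_cache[[method]])) return(.table_cache[[method]])
  terms <- switch(method,
    ccsd = c(.energy_terms(), .singles_terms(), .ccsd_doubles_terms()),
    cc2  = c(.energy_terms(), .singles_terms(), .cc2_doubles_terms("bare")),
    cc2b = c(.energy_terms(), .singles_terms(), .cc2_doubles_terms("dressed")),
    omp2 = c(.energy_terms(), .cc2_doubles_terms("dressed")),
    stop("unknown method: ", method,
         " (valid: ccsd, cc2, cc2b, omp2)"))
  .table_cache[[method]] <- terms
  terms
}

# terms that carry no lambda factor: their sum is the projected energy
# (the lambda-0 derivative of the Hamilton function)
.energy_only <- function(terms) {
  Filter(function(tm) {
    !any(vapply(tm$factors, function(f) f$name %in% c("l1", "l2"), logical(1)))
  }, terms)
}

#' Evaluate a Hamilton-function table and its gradients
#'
#' @param terms Table from [hamilton_terms()].
#' @param tensors Named list of primitive tensors (`h`, `v`, and for the
#'   methods that use them `fb`, `t1`, `t2`, `l1`, `l2`).
#' @param nocc,norb Occupied and total orbital counts.
#' @param grads Character vector of tensor names to differentiate against.
#' @return List with `value` (complex scalar) and `grad` (named list).
#' @export
eval_hamilton <- function(terms, tensors, nocc, norb, grads = character()) {
  val <- table_value(terms, tensors, nocc, norb)
  g <- lapply(grads, function(w) table_grad(terms, tensors, w, nocc, norb))
  names(g) <- grads
  list(value = val, grad = g)
}

# Gradient of the Hamilton function with respect to an exponential one-body
# transformation of the integrals (T1-dressing or orbital rotation), by the
# chain rule: dH/dX[x,y] at X = 0 given the densities D1 = dH/dh,
# D2 = dH/dv evaluated at the transformed integrals h, v.
dressing_gradient <- function(D1, D2, h, v) {
  L <- nrow(h)
  G <- t(h) %*% D1 - D1 %*% t(h)
  m <- function(a) { dim(a) <- c(L, L^3); a }
  # upper indices (axes 1, 2): -dX acts from the left
  G <- G - m(D2) %*% t(m(v))
  D2a <- aperm(D2, c(2, 1, 3, 4)); va <- aperm(v, c(2, 1, 3, 4))
  G <- G - m(D2a) %*% t(m(va))
  # lower indices (axes 3, 4): +dX acts from the right
  D2c <- aperm(D2, c(3, 1, 2, 4)); vc <- aperm(v, c(3, 1, 2, 4))
  G <- G + m(vc) %*% t(m(D2c))
  D2d <- aperm(D2, c(4, 1, 2, 3)); vd <- aperm(v, c(4, 1, 2, 3))
  G <- G + m(vd) %*% t(m(D2d))
  G
}

# Antisymmetrization projector P(12)P(34) for rank-4 amplitude gradients.
antisymmetrize_pairs <- function(A) {
  A - aperm(A, c(2, 1, 3, 4)) - aperm(A, c(1, 2, 4, 3)) + aperm(A, c(2, 1, 4, 3))
}
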