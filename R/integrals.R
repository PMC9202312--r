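#' Second-quantized Hamiltonian data in an orthonormal spin-orbital basis
#'
#' An `integral_set` collects every matrix element needed to define the
#' electronic Hamiltonian and the dipole operator in a fixed orthonormal
#' orbital basis, in Hartree atomic units.  Orbitals are ordered with the
#' occupied orbitals of the reference determinant first, and tensors are
#' stored with upper (creation) indices as leading axes, so the two-body
#' element \eqn{u^{pq}_{rs}} lives at `u[p, q, r, s]`.
#'
#' @param n_electrons Number of electrons in the reference determinant.
#' @param h Complex one-body matrix (L x L), Hermitian.
#' @param u Complex two-body tensor (L x L x L x L) with particle-exchange
#'   symmetry `u[p,q,r,s] == u[q,p,s,r]`.
#' @param dipole List of three real/complex L x L matrices (Cartesian
#'   components of the electric dipole operator).
#' @param e_nuc Nuclear-repulsion energy (Hartree).
#'
#' @return An object of class `integral_set` with fields `n_electrons`,
#'   `n_orbitals`, `h`, `u`, `v` (anti-symmetrized two-body elements),
#'   `dipole`, `e_nuc` and `occ_mask`.
#' @export
integral_set <- function(n_electrons, h, u, dipole = NULL, e_nuc = 0) {
  h <- as_complex_matrix(h)
  L <- nrow(h)
  if (is.null(dipole)) {
    dipole <- replicate(3, matrix(0 + 0i, L, L), simplify = FALSE)
  }
  dipole <- lapply(dipole, as_complex_matrix)
  u <- array(as.complex(u), dim = dim(u))
  obj <- structure(list(
    n_electrons = as.integer(n_electrons),
    n_orbitals = L,
    h = h,
    u = u,
    v = antisymmetrize_two_body(u),
    dipole = dipole,
    e_nuc = as.numeric(e_nuc),
    occ_mask = seq_len(L) <= n_electrons
  ), class = "integral_set")
  validate_integral_set(obj)
  obj
}

as_complex_matrix <- function(m) {
  m <- as.matrix(m)
  matrix(as.complex(m), nrow(m), ncol(m))
}

#' Validate the structural invariants of an integral set
#'
#' Checks Hermiticity of the one-body part, particle-exchange symmetry of the
#' two-body part, antisymmetry of the anti-symmetrized elements, shapes, and
#' the occupied-first orbital ordering.  Every test fixture goes through this
#' single validator.
#'
#' @param ints An `integral_set`.
#' @param tol Numerical tolerance for the symmetry checks.
#' @return `ints`, invisibly; stops with a message on violation.
#' @export
validate_integral_set <- function(ints, tol = 1e-10) {
  L <- ints$n_orbitals
  stopifnot(inherits(ints, "integral_set"))
  if (!identical(dim(ints$h), c(L, L)))
    stop("one-body matrix has wrong shape")
  if (!identical(dim(ints$u), c(L, L, L, L)))
    stop("two-body tensor has wrong shape")
  if (ints$n_electrons < 0L || ints$n_electrons > L)
    stop("electron count outside orbital range")
  if (max(Mod(ints$h - Conj(t(ints$h)))) > tol)
    stop("one-body matrix is not Hermitian")
  if (max(Mod(ints$u - aperm(ints$u, c(2, 1, 4, 3)))) > tol)
    stop("two-body tensor lacks particle-exchange symmetry")
  v <- ints$v
  if (max(Mod(v + aperm(v, c(1, 2, 4, 3)))) > tol ||
      max(Mod(v + aperm(v, c(2, 1, 3, 4)))) > tol)
    stop("anti-symmetrized elements violate antisymmetry")
  for (mu in ints$dipole) {
    if (!identical(dim(mu), c(L, L))) stop("dipole matrix has wrong shape")
    if (max(Mod(mu - Conj(t(mu)))) > tol) stop("dipole matrix is not Hermitian")
  }
  if (!identical(ints$occ_mask, seq_len(L) <= ints$n_electrons))
    stop("orbitals must be ordered occupied-first")
  invisible(ints)
}

#' Anti-symmetrize two-body matrix elements
#'
#' Forms \eqn{v^{pq}_{rs} = u^{pq}_{rs} - u^{pq}_{sr}}, the anti-symmetrized
#' two-electron elements used throughout the spin-orbital equations.
#'
#' @param u Rank-4 tensor with particle-exchange symmetry.
#' @return Rank-4 tensor `v`, antisymmetric under exchange of either the two
#'   upper or the two lower indices.
#' @export
antisymmetrize_two_body <- function(u) {
  d <- dim(u)
  if (length(d) != 4L || length(unique(d)) != 1L)
    stop("u must be a rank-4 tensor with equal extents")
  u - aperm(u, c(1, 2, 4, 3))
}

#' Fock matrix of the reference determinant
#'
#' \eqn{f^p_q = h^p_q + \sum_i v^{pi}_{qi}} with the sum over the occupied
#' orbitals of the reference determinant.  No canonicity (diagonal Fock) is
#' assumed anywhere in the package.
#'
#' @param ints An `integral_set`, or a list with fields `h`, `v`, `occ_mask`.
#' @param h Optional replacement one-body matrix (e.g. including a field).
#' @return Complex L x L Fock matrix.
#' @export
build_fock <- function(ints, h = NULL) {
  if (is.null(h)) h <- ints$h
  occ <- which(ints$occ_mask)
  f <- h
  if (length(occ) > 0) {
    vsl <- ints$v[, occ, , occ, drop = FALSE]
    L <- ints$n_orbitals
    no <- length(occ)
    # sum_k v[p, k, q, k]
    m <- aperm(vsl, c(1, 3, 2, 4))
    dim(m) <- c(L * L, no * no)
    f <- f + matrix(m[, (seq_len(no) - 1L) * no + seq_len(no), drop = FALSE] %*%
                      rep(1, no), L, L)
  }
  f
}

#' Reference-determinant energy
#'
#' \eqn{E_{ref} = \sum_i h_{ii} + \tfrac12 \sum_{ij} v^{ij}_{ij} + E_{nuc}}.
#'
#' @param ints An `integral_set`.
#' @param h Optional replacement one-body matrix.
#' @return Complex scalar (real for Hermitian inputs).
#' @export
reference_energy <- function(ints, h = NULL) {
  if (is.null(h)) h <- ints$h
  occ <- which(ints$occ_mask)
  e <- sum(diag(h)[occ])
  for (i in occ) for (j in occ) e <- e + 0.5 * ints$v[i, j, i, j]
  e + ints$e_nuc
}

#' Random Hermitian model system with correct tensor symmetries
#'
#' Builds a deterministic synthetic `integral_set`: a random real symmetric
#' one-body matrix with a guaranteed gap between occupied and virtual levels,
#' a random two-body tensor with full particle-exchange and Hermitian
#' symmetry scaled by `coupling_scale`, and random symmetric dipole matrices.
#' Used as the test and demonstration system for all dynamical methods; with
#' `n_occ = 2` spin orbitals the model holds two electrons, for which coupled
#' cluster with singles and doubles is exact.
#'
#' @param seed Integer seed; the fixture is bit-reproducible per seed.
#' @param n_occ,n_virt Number of occupied / virtual spin orbitals.
#' @param coupling_scale Overall scale of the two-body elements; `0` gives an
#'   exactly mean-field model.
#' @param gap Minimum separation between occupied and virtual one-body levels.
#' @param one_body_scale Overall scale of the one-body spectrum; values below
#'   one give a softer model whose dynamics admit larger integration steps.
#' @return An `integral_set`.
#' @export
make_fixture <- function(seed, n_occ, n_virt, coupling_scale = 0.1, gap = 1,
                         one_body_scale = 1) {
  stopifnot(n_occ >= 1, n_virt >= 1)
  L <- n_occ + n_virt
  rs <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    # one-body: well-separated diagonal plus small symmetric off-diagonal
    eps <- c(sort(stats::runif(n_occ, -2, -1 - gap / 2)),
             sort(stats::runif(n_virt, -1 + gap / 2, 1)))
    h <- diag(eps)
    # non-canonical one-body noise, tied to the coupling so that the
    # coupling_scale = 0 limit is an exactly canonical mean-field model
    off <- matrix(stats::rnorm(L * L, sd = 0.05), L, L)
    h <- one_body_scale * (h + min(1, coupling_scale) * (off + t(off)) / 2)
    u <- array(stats::rnorm(L^4, sd = 1), rep(L, 4))
    u <- (u + aperm(u, c(2, 1, 4, 3))) / 2          # particle exchange
    u <- (u + aperm(u, c(3, 4, 1, 2))) / 2          # Hermiticity (real)
    u <- coupling_scale * u
    dip <- lapply(1:3, function(k) {
      m <- matrix(stats::rnorm(L * L, sd = 0.5), L, L)
      (m + t(m)) / 2
    })
    list(h = h, u = u, dip = dip)
  })
  integral_set(n_electrons = n_occ, h = rs$h, u = rs$u,
               dipole = rs$dip, e_nuc = 0.5)
}

#' Expand spatial-orbital integrals to spin orbitals
#'
#' Takes spatial one- and two-body integrals (chemists' input already in
#' physicists' index order `u[p,q,r,s] =` \eqn{\langle pq | rs\rangle}) for a
#' closed-shell system and expands them to the spin-orbital basis used by the
#' dynamical equations.  Spin orbitals are ordered occupied-first with alpha
#' and beta interleaved within each spatial orbital, and elements vanish
#' unless spin labels match pairwise.
#'
#' @param h_spatial Spatial one-body matrix (K x K).
#' @param u_spatial Spatial two-body tensor (K x K x K x K), physicists'
#'   notation.
#' @param n_electrons Even electron count.
#' @param dipole_spatial Optional list of three K x K dipole matrices.
#' @param e_nuc Nuclear-repulsion energy.
#' @return An `integral_set` with `2 K` spin orbitals.
#' @export
spatial_to_spinorbital <- function(h_spatial, u_spatial, n_electrons,
                                   dipole_spatial = NULL, e_nuc = 0) {
  if (n_electrons %% 2L != 0L)
    stop("closed-shell expansion needs an even electron count")
  K <- nrow(h_spatial)
  L <- 2L * K
  spat <- rep(seq_len(K), each = 2L)   # spatial index of each spin orbital
  spin <- rep(c(1L, 2L), K)            # 1 = alpha, 2 = beta
  h <- matrix(0 + 0i, L, L)
  for (p in seq_len(L)) for (q in seq_len(L)) {
    if (spin[p] == spin[q]) h[p, q] <- h_spatial[spat[p], spat[q]]
  }
  u <- array(0 + 0i, rep(L, 4))
  for (p in seq_len(L)) for (q in seq_len(L)) for (r in seq_len(L)) for (s in seq_len(L)) {
    if (spin[p] == spin[r] && spin[q] == spin[s]) {
      u[p, q, r, s] <- u_spatial[spat[p], spat[q], spat[r], spat[s]]
    }
  }
  dip <- NULL
  if (!is.null(dipole_spatial)) {
    dip <- lapply(dipole_spatial, function(ms) {
      m <- matrix(0 + 0i, L, L)
      for (p in seq_len(L)) for (q in seq_len(L)) {
        if (spin[p] == spin[q]) m[p, q] <- ms[spat[p], spat[q]]
      }
      m
    })
  }
  integral_set(n_electrons = n_electrons, h = h, u = u,
               dipole = dip, e_nuc = e_nuc)
}

#' Minimal two-electron molecular fixture
#'
#' A synthetic minimal-basis two-electron diatomic in its canonical molecular
#' orbital basis (two spatial orbitals, parameters typical of H2 near its
#' equilibrium bond length).  All quantities are in Hartree atomic units.
#' This is a stand-in constructed for testing; it is not produced by an
#' integral program.
#'
#' @return An `integral_set` with four spin orbitals and two electrons.
#' @export
minimal_molecular_fixture <- function() {
  # spatial MO integrals of a minimal-basis two-electron diatomic
  h <- matrix(c(-1.2528, 0, 0, -0.4756), 2, 2)
  # chemists' (pq|rs) values
  J11 <- 0.6746; J12 <- 0.6636; J22 <- 0.6975; K12 <- 0.1813
  u <- array(0, rep(2, 4))  # physicists' <pq|rs> = (pr|qs)
  chem <- function(p, r, q, s) {
    key <- paste(sort(c(paste(sort(c(p, r)), collapse = ""),
                        paste(sort(c(q, s)), collapse = ""))), collapse = "|")
    switch(key,
           "11|11" = J11, "11|22" = J12, "22|22" = J22,
           "11|12" = 0, "12|22" = 0, "12|12" = K12)
  }
  for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    u[p, q, r, s] <- chem(p, r, q, s)
  }
  # dipole along the bond axis (z): symmetric off-diagonal coupling
  dz <- matrix(c(0.0, 0.9, 0.9, 0.0), 2, 2)
  zero <- matrix(0, 2, 2)
  spatial_to_spinorbital(h, u, n_electrons = 2,
                         dipole_spatial = list(zero, zero, dz),
                         e_nuc = 0.7143)
}

# --- file-based provider ----------------------------------------------------

#' Write an integral set to a named-array JSON container
#'
#' Serializes all arrays (h, u, dipole_x/y/z split into real and imaginary
#' parts) and scalars (e_nuc, n_electrons) to a JSON document, the package's
#' portable integral-exchange format.
#'
#' @param ints An `integral_set`.
#' @param path Output file path.
#' @export
write_integral_set <- function(ints, path) {
  enc <- function(a) list(dim = dim(a), re = as.vector(Re(a)),
                          im = as.vector(Im(a)))
  doc <- list(n_electrons = ints$n_electrons,
              e_nuc = ints$e_nuc,
              h = enc(ints$h),
              u = enc(ints$u),
              dipole_x = enc(ints$dipole[[1]]),
              dipole_y = enc(ints$dipole[[2]]),
              dipole_z = enc(ints$dipole[[3]]))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an integral set from a named-array JSON container
#'
#' @param path File written by [write_integral_set()].
#' @return An `integral_set`.
#' @export
read_integral_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(x) array(complex(real = x$re, imaginary = x$im), dim = x$dim)
  integral_set(n_electrons = doc$n_electrons,
               h = dec(doc$h), u = dec(doc$u),
               dipole = list(dec(doc$dipole_x), dec(doc$dipole_y),
                             dec(doc$dipole_z)),
               e_nuc = doc$e_nuc)
}

#' Read an XYZ-style geometry file
#'
#' Parses the plain-text format: an optional atom-count line, an optional
#' comment line, then one `element x y z` line per atom (coordinates in
#' Angstrom).  The geometry itself is only metadata for external integral
#' providers; the package does not evaluate Gaussian integrals.
#'
#' @param path Path to the geometry file.
#' @return A data.frame with columns `element`, `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  is_atom <- vapply(toks, function(t) {
    length(t) == 4L && !is.na(suppressWarnings(as.numeric(t[2])))
  }, logical(1))
  atoms <- toks[is_atom]
  if (length(atoms) == 0L) stop("no atom lines found in ", path)
  data.frame(element = vapply(atoms, `[[`, "", 1L),
             x = vapply(atoms, function(t) as.numeric(t[2]), 0),
             y = vapply(atoms, function(t) as.numeric(t[3]), 0),
             z = vapply(atoms, function(t) as.numeric(t[4]), 0))
}

#' Resolve an integral provider
#'
#' The package consumes integrals through a provider interface: a function
#' returning an `integral_set`.  Two providers are bundled: `"file"` (the
#' named-array JSON container) and `"fixture"` (synthetic model systems).
#' An adapter to an external integral program can be registered by passing a
#' function.
#'
#' @param source Either a function, `"file"`, or `"fixture"`.
#' @param ... For `"file"`: `path`.  For `"fixture"`: arguments of
#'   [make_fixture()], or `name = "minimal"` for the bundled two-electron
#'   molecular fixture.
#' @return An `integral_set`.
#' @export
integral_provider <- function(source, ...) {
  if (is.function(source)) return(source(...))
  args <- list(...)
  switch(source,
         file = read_integral_set(args$path),
         fixture = {
           if (identical(args$name, "minimal")) minimal_molecular_fixture()
           else do.call(make_fixture, args)
         },
         stop("unknown integral source: ", source))
}
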