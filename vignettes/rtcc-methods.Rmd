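---
title: "Real-time coupled-cluster dynamics in rtcc: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time coupled-cluster dynamics in rtcc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcc)
```

## The physical problem

When a molecule is exposed to a time-dependent electric field, its electrons
respond on attosecond-to-femtosecond time scales.  Real-time electronic
structure methods follow this response explicitly: the correlated wave
function is propagated under the time-dependent Hamiltonian, and optical
observables are read off the induced electric dipole moment.  A single
broadband impulse yields the whole linear absorption spectrum; slow
monochromatic driving at a frequency below the first resonance yields
frequency-dependent polarizabilities $\alpha(\omega)$ and, at second order in
the field, the first hyperpolarizabilities $\beta(0;\omega,-\omega)$
(optical rectification) and $\beta(-2\omega;\omega,\omega)$ (second-harmonic
generation).

`rtcc` implements four wave-function models of this response in a
spin-orbital formulation:

* **TDCCSD** — time-dependent coupled cluster with singles and doubles;
* **TDCC2** — its second-order approximation, in which the doubles are
  driven by the bare Fock operator and the singles act through
  $T_1$-transformed integrals;
* **TDCC2-b** — the variant in which the fully $T_1$-transformed Fock
  matrix replaces the bare one in the doubles equation;
* **TDOMP2** — orbital-adaptive second-order Møller–Plesset dynamics, in
  which singles are replaced by a unitary exponential orbital rotation
  $e^{\hat\kappa}$ carried by all orbitals, and the doubles enter at first
  order.

All methods are *bivariational*: the bra and the ket are parametrized
independently, $|\Psi\rangle = e^{\hat T}|\Phi_0\rangle$ and
$\langle\tilde\Psi| = \langle\Phi_0|(1+\hat\Lambda)e^{-\hat T}$, and all
equations of motion follow from making the action stationary in all
parameters.

## One scalar generates every working equation

The package is built around a single organizing idea.  For each method the
*Hamilton function*

$$ \mathcal H(\tau,\lambda;t)
   \;=\; \langle\Phi_0|(1+\hat\Lambda)\,e^{-\hat T} \hat H(t)\, e^{\hat T}
   |\Phi_0\rangle $$

(truncated according to the method's perturbation rules) is written once as
a table of tensor contractions over primitive tensors — the one-body
integrals $h$ (field included), the anti-symmetrized two-body integrals
$v$, the amplitudes $t_2$ (and $t_1$ where applicable, absorbed into
dressed integrals) and the conjugate amplitudes $\lambda$.  Every working
quantity is then a *generic derivative* of that table:

* amplitude equations of motion:
  $i\dot\tau_\mu = \partial\mathcal H/\partial\lambda_\mu$;
* conjugate equations:
  $i\dot\lambda_\mu = -\partial\mathcal H/\partial\tau^\mu$;
* one- and two-body densities:
  $\gamma = \partial\mathcal H/\partial h$,
  $\Gamma \propto \partial\mathcal H/\partial v$, so that any expectation
  value is a trace contract and the dipole is
  $\mu(t) = \mathrm{Re}\sum_{pq}\gamma^p_q\,\tilde\mu^p_q$;
* singles and orbital-rotation equations: because *all* $t_1$ and $\kappa$
  dependence enters through the exponential one-body transformation of the
  integrals, the chain rule reduces their gradients to commutator-type
  contractions of $\gamma$ and $\Gamma$ with the transformed $h$ and $v$
  (`dressing_gradient()`).

This eliminates the traditional duplication in which the amplitude
equations, the lambda equations and the density matrices are coded (and
debugged) separately: each term of each method exists exactly once, in the
index-string table returned by `hamilton_terms()`.  The doubles projection
of the CCSD table is the standard spin-orbital CCD-form residual over
$T_1$-dressed integrals; the CC2 family keeps only the two-body driver and
a one-body (Fock) commutator in the doubles block; the TDOMP2 table is the
same MP2-level functional evaluated in the instantaneous orbital basis.

For TDOMP2 the orbital equation of motion is the linear system

$$ i\left(\gamma_{vv}^{T}\dot\kappa - \dot\kappa\,\gamma_{oo}^{T}\right)
   = -i\,\partial\mathcal H/\partial\kappa_{ov}\big._{\kappa=0}, $$

whose matrix is singular exactly when an eigenvalue of the occupied density
block meets one of the virtual block; the solver reports the smallest
singular value and aborts if that happens (it has not, in any run
performed while developing the package).  The rotation is absorbed into an
accumulated orbital-coefficient matrix $U$ at every step, so the state
never carries a finite $\kappa$ and the equations are always evaluated at
$\kappa = 0$.  Because the conjugate doubles of the unitary theory satisfy
$\lambda_2 = t_2^*$ at all times, only $t_2$ is propagated and $\lambda_2$
is slaved; the density pair is then Hermitian by construction, which the
tests verify along kicked trajectories rather than assume.

The phase amplitude $\tau_0$ is integrated but excluded from every
observable, and $\lambda_0 = 1$ is fixed by intermediate normalization and
never evolved.

## Validation strategy: dense determinant-space oracles

All equations are cross-checked against an independent implementation that
knows nothing about tensor contractions: `dense_hamiltonian()` builds
$\hat H$ and all excitation operators as explicit matrices over the Slater
determinant basis of the $N$-electron sector, and `dense_bivariational()`
evaluates the Hamilton function, the amplitude residuals
$\langle\Phi_\mu|e^{-T}\hat He^{T}|\Phi_0\rangle$ and the conjugate
residuals $\langle\Phi_0|(1+\Lambda)[e^{-T}\hat He^{T},X_\mu]|\Phi_0\rangle$
by brute-force matrix algebra.  On random complex amplitudes the compiled
tensor path agrees with the dense bracket to machine precision, which fixes
every coefficient of every term in the tables.

Two exactness limits provide end-to-end dynamical oracles:

* CCSD is exact for two electrons, so a TDCCSD dipole trajectory on a
  two-electron model must reproduce dense full-CI propagation
  (`fci_propagate()`, eigendecomposition-exact for piecewise-constant
  fields).  The test suite holds this to about $10^{-11}$ over 50 a.u.
* With the two-body coupling switched off, the orbital-adaptive method
  reduces to exact mean-field dynamics of a single determinant, which again
  must match dense propagation; this pins down every sign and factor of the
  orbital equation of motion.

A note on one deliberately weaker check: for the MP2-truncated functional,
the density trace contract reproduces the method's *own* Hamilton function
exactly (the functional is linear in the integrals), but not the
untruncated dense bracket, from which it differs by the neglected
$\Lambda\!\cdot\![\hat U, T_2]$ term at third order.  The tests therefore
assert trace-contract/functional consistency for TDOMP2 and reserve the
dense-bracket identity for the untruncated CCSD parametrization.

## Synthetic model systems

Real-molecule work requires molecular-orbital integrals from an external
integral program, supplied through the named-array JSON container
(`read_integral_set()`); the package deliberately does not evaluate
Gaussian integrals.  All bundled tests run instead on synthetic model
systems from `make_fixture()`: random Hermitian one-body matrices with a
guaranteed occupied–virtual gap, random two-body tensors with the full
particle-exchange and Hermitian symmetries scaled by `coupling_scale`, and
random symmetric dipole matrices.  Key generator choices:

* `gap = 1` a.u. between occupied and virtual levels keeps every method's
  denominators well conditioned and the transparent region wide, so a
  driving frequency of 0.01–0.2 a.u. sits far below the first resonance —
  the same regime the response protocols assume for molecules.
* `coupling_scale = 0.2`–`0.3` gives correlation energies of a few
  hundredths of a Hartree on a 4–5 spin-orbital model, comparable in
  relative size to valence correlation in small molecules.
* The non-canonical one-body noise is tied to the coupling so that the
  `coupling_scale = 0` limit is an exactly canonical mean-field model with
  the reference determinant as exact eigenstate.
* `one_body_scale` rescales the whole one-body spectrum: soft models
  (0.5) admit larger integration steps for the long slow-field
  polarizability runs; stiff models (6) push discretization errors of the
  integrator far above round-off so its convergence order is measurable.

What these fixtures do *not* emulate: spin symmetry of closed-shell
molecules (the models are spinless fermions; the closed-shell expansion
path is exercised separately by `spatial_to_spinorbital()` and a minimal
two-electron diatomic fixture), realistic spectral densities with Rydberg
or continuum character, and size scaling.  Passing tests therefore
establish the correctness of the equations and protocols, not basis-set or
method quality for real molecules.

## Numerical choices

* **Integrator.** The $s$-stage Gauss–Legendre collocation scheme
  ($s\in\{1,2,3\}$, order $2s$), default $s=3$ and $\Delta t = 0.01$ a.u.
  It is symplectic and preserves quadratic invariants, which shows up
  directly as machine-precision conservation of the real energy and of
  orbital unitarity in field-free propagation.  Stage equations are solved
  by fixed-point iteration to a residual norm of $10^{-10}$ (default),
  seeded by the previous step's converged stage derivatives and
  Anderson-accelerated (depth 3); both refinements change the iteration
  count, not the converged collocation solution, which is gated by the
  same residual test.  The delta kick is realized as a box of height
  $E_{\max}/\Delta t$ over exactly one step, so the impulse area is
  $E_{\max}$ independent of the step; spectra are normalized by that area,
  making the height convention immaterial.
* **Ground states.** CC amplitude and lambda equations use
  denominator-preconditioned fixed-point iteration with DIIS (subspace 8,
  error vectors = residuals); the orbital-optimized ground state uses the
  diagonal orbital-Hessian update with denominators $2(f_{aa}-f_{ii})$ and
  a $10^{-3}$ level shift, re-solving the first-order doubles in each
  orbital iteration.  Initial guesses: first-order doubles, zero singles,
  $\lambda = t^*$.  Convergence thresholds default to $10^{-10}$ residual
  norm.
* **Spectra.** The damped induced dipole is Fourier transformed with the
  plain FFT grid $\Delta\omega = 2\pi/(N\Delta t)$ — no zero padding, so
  the stated resolution is honest.  The damping $\gamma = 0.00921$ a.u.
  (0.251 eV) produces Lorentzian lines of half-width $\gamma$; peak
  detection reports grid-point maxima, so resonances closer than roughly a
  line width merge, possibly leaving shoulders.
* **Response fits.** The field family $0,\pm E,\pm 2E$ enters the
  four-point stencils
  $\mu^{(1)} = [8(\mu_{+E}-\mu_{-E}) - (\mu_{+2E}-\mu_{-2E})]/(12E)$ and
  $\mu^{(2)} = [16(\mu_{+E}+\mu_{-E}) - (\mu_{+2E}+\mu_{-2E}) -
  30\mu_0]/(12E^2)$, which annihilate the cubic field response exactly.
  The fits are linear least squares against $\alpha\cos\omega t$ and
  $\tfrac12[\beta^{OR} + \beta^{SHG}\cos 2\omega t]$ — the forms implied by
  the adiabatic expansion $\mu = \mu^0 + \alpha E\cos\omega t +
  \tfrac{E^2}{4}(\beta^{OR} + \beta^{SHG}\cos 2\omega t) + O(E^3)$ — after
  discarding the one-cycle linear ramp; no nonlinear optimization and no
  starting guesses are involved.  The zero-field member of the family is
  the unperturbed ground state, which is stationary, so its dipole signal
  is the constant permanent dipole and is not propagated.
  Default strengths $E = 5\times10^{-4}$ a.u. (so the family spans
  $10^{-3}$); the linear-regime tests verify that halving the kick
  strength rescales the induced dipole to within $10^{-3}$ relative.
* **Problem sizes in the shipped studies.** The validation studies run on
  4–5 spin-orbital models: 50 a.u. of TDCCSD propagation at
  $\Delta t = 0.05$ for the exactness study, 1000 field-free steps at
  $\Delta t = 0.01$ for conservation, step sets
  $\{0.02, 0.01, 0.005\}$ against a $0.0025$ reference for the order
  study (with the stage tolerance tightened to $10^{-13}$ so the
  collocation error is what is measured), and a one-cycle ramp plus
  half-cycle fit window at $\omega = 0.01$, $\Delta t = 0.4$ on a soft
  fixture for the static-limit comparison with finite-field ground-state
  curvature.  These sizes were chosen so each effect under study sits
  orders of magnitude above its numerical noise floor.

## Design decisions that were genuinely open

* The doubles commutator of plain TDCC2 uses the *bare Fock plus field*
  operator: the field is part of the zeroth-order Hamiltonian, and a
  one-body operator cannot drive doubles through the dressed two-body
  block, so omitting it there would decouple the doubles from the field
  entirely.  TDCC2-b replaces this operator by the Fock matrix of the
  fully dressed integrals.
* CC2 expectation values include the bare-Fock block's own derivative
  (`fb` gradient) alongside the dressed one-body density, i.e. the full
  variational derivative of the CC2 functional with respect to a one-body
  perturbation; this keeps Hellmann–Feynman consistency within the model.
* Orbital dynamics store accumulated coefficients $U$ rather than
  accumulated $\kappa$; composition of rotations is then matrix
  multiplication and the equations are always evaluated at $\kappa = 0$.
  Unitarity of $U$ is preserved by the integrator's quadratic-invariant
  conservation and asserted in tests rather than re-imposed.
* The non-unitary (biorthogonal) variant of the orbital-adaptive method,
  which propagates $\lambda_2$ and both $\kappa$ blocks independently, is
  not implemented; the unitary theory covers every use case exercised
  here, and the derivative machinery (independent `l2` gradients, general
  `kappa` transforms) was written so the extension is additive.

## Known limitations

* Everything is dense and in-memory; the intended regime is small models
  and small molecular basis sets supplied through the integral container.
  No point-group symmetry, no frozen core, no spatial-spin factorization
  fast path.
* The delta-kick spectrum inherits the usual finite-simulation resolution
  $2\pi/T$; excitation energies are reported as grid maxima, not fitted
  line centers.
* Hyperpolarizability extraction assumes the transparent region; close to
  a pole the second-order signal is no longer a two-term cosine and the
  fit residuals (always reported) grow accordingly.
* The fixed-point stage solve limits the step through
  $\Delta t\,\lVert J\rVert \lesssim 1$; stiff Hamiltonians need smaller
  steps not for accuracy but for the iteration to contract.

## A worked micro-example

```{r example, eval = FALSE}
ints <- make_fixture(seed = 11, n_occ = 2, n_virt = 2, coupling_scale = 0.2)
gs <- ground_state(ints, "ccsd")
kick <- field_spec("delta_kick", strength = 1e-3, polarization = c(0, 0, 1))
traj <- propagate(gs$state, ints, kick, integrator_spec(3, dt = 0.05),
                  t_final = 100)
mu0 <- state_observables(gs$state, ints)$dipole
spec <- absorption_spectrum(traj, mu0, kick, gamma = 0.03)
detect_peaks(spec, 0.05)
```

The chunk is not evaluated during vignette building (a few minutes of
propagation); the README shows the same pipeline with the numbers it
actually printed.
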