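Package: rtcc
Title: Real-Time Time-Dependent Coupled-Cluster Electron Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Real-time propagation of time-dependent coupled-cluster wave
    functions (TDCCSD, TDCC2, TDCC2-b) and orbital-adaptive second-order
    Moller-Plesset dynamics (TDOMP2) in a spin-orbital formulation, driven by
    semiclassical electric fields in the length gauge.  Includes DIIS ground
    state solvers, an implicit symplectic Gauss-Legendre integrator, delta-kick
    absorption spectra, and frequency-dependent polarizabilities and first
    hyperpolarizabilities extracted from induced-dipole signals by finite
    differences in the field strength and linear least-squares fits.  Dense
    determinant-space (full configuration interaction) reference routines are
    provided for cross-validation on small model systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
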