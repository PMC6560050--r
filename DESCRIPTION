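Package: redoxbench
Title: Complete-Basis-Set Reference Energies and Density-Functional
    Benchmarks for Iron Redox Couples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing CCSD(T)/CBS reference values of the
    electronic component of the Fe(III)/Fe(II) reduction energy in
    amino-acid-mimicking iron coordination complexes, and for scoring
    density-functional predictions against those references.  Implements
    two complete-basis-set extrapolation schemes (a two-point power-law
    form for Hartree-Fock and correlation components, and a three-point
    exponential Hartree-Fock fit combined with the X^-3 correlation
    formula), composite CCSD(T)/CBS assembly from MP2/CBS plus a
    double-zeta coupled-cluster correction, unit-checked energy
    arithmetic, spin-state diagnostics, benchmark statistics (MSE, MUE,
    MaxE, volt-based accuracy groups, rankings), and a synthetic energy
    generator with known basis-set convergence so the whole pipeline is
    testable without an electronic-structure engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
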