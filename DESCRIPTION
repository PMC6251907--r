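Package: chordaemr
Title: Chordae Rupture Biomechanics and Mitral Regurgitation Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis of mitral valve chordae rupture and its
    hemodynamic consequences. Implements a fiber-reinforced anisotropic
    hyperelastic (modified Holzapfel-Gasser-Ogden) constitutive model for
    mitral leaflet tissue and an Ogden law for chordae tendineae; an
    idealized chordae-network generator with a tension-only nonlinear truss
    equilibrium solver and rupture-scenario analysis; quantification of
    mitral regurgitation from transvalvular flow waveforms (closing and
    leakage volume split, regurgitant fraction, severity grading);
    pressure-volume loop energetics (stroke work, forward stroke work,
    pressure-volume area, ventricular efficiency); and a synthetic waveform
    generator that emulates left-heart flow and pressure records with a
    controllable regurgitation severity for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
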