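Package: nanodef
Title: Monte Carlo Simulation of Nanoparticle Dose Enhancement under Cs-137 Irradiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, three-stage Monte Carlo pipeline for computing the
    dose-enhancement factor (DEF) around a nanometric platinum nanoparticle in
    a cell-culture geometry irradiated by a 137Cs gamma source. Stage one
    transports 662 keV photons through the culture medium and records the
    particle field entering the cell layer as a phase-space file; stage two
    drives that phase space onto a 3.2 nm platinum (or water control) sphere
    with forced-interaction variance reduction and records the escaping
    secondary electrons; stage three transports those electrons in liquid
    water and scores energy deposits in concentric 10 nm shells, from which
    DEF profiles with batch uncertainties are formed, with and without an
    electronic-equilibrium beam construction. Ships compact vendored photon
    cross-section, electron stopping-power and atomic-relaxation tables for
    liquid water and platinum, with Klein-Nishina Compton sampling, a
    simplified photoelectric and Auger-cascade model, and condensed-history
    CSDA electron transport.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
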