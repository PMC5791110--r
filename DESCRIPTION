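Package: hydrosieve
Title: In-Silico Design of Crosslinked PVA Hydrogel Pesticide Absorbents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational design of crosslinked poly(vinyl
    alcohol) (PVA) hydrogels as absorbents for the organophosphorus
    pesticide dimethoate. Implements rigid-body Monte-Carlo screening of
    nanopore/pesticide complexes with supermolecular interaction energies,
    an algorithmic construction of ester-crosslinked polymer networks in
    periodic boxes, trajectory observables (solvent-accessible surface
    area, radius of gyration, water-shell occupancy, pesticide capture and
    hydrogen-bond counts), a two-level factorial design regression for
    absorption kinetics, and seed-deterministic synthetic-data generators
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
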