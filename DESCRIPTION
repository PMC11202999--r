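Package: ctbind
Title: Spectroscopic and Computational Characterization of Ligand-DNA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for determining how a small molecule binds
    double-stranded DNA from solution measurements. Implements inner-filter
    correction of fluorescence titrations, Stern-Volmer quenching analysis
    with static/dynamic mechanism classification, double-logarithm binding
    constant and site-number fits, van't Hoff thermodynamics with
    driving-force classification, DNA melting-temperature extraction from
    hyperchromicity curves, cube-root relative-viscosity profiling, and an
    evidence-voting classifier that aggregates all assays into a binding-mode
    verdict (intercalation, groove, or electrostatic). Also provides
    standalone trajectory observables (RMSD, RMSF, radius of gyration,
    Shrake-Rupley solvent-accessible surface area) for multi-frame coordinate
    sets, and seedable synthetic-data generators with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
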