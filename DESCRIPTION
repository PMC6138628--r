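Package: pepmem
Title: Quantitative Analysis of Peptide-Membrane Interaction Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for the biophysical characterization of
    membranotropic peptides against model lipid membranes: Laurdan
    generalized polarization (membrane fluidity), FRET lipid-mixing and
    inner-monolayer fusion assays with ANTS/DPX leakage normalization,
    tryptophan-fluorescence binding isotherms and surface partition
    coefficients (Kp), acrylamide Stern-Volmer quenching constants (Ksv),
    circular-dichroism helix content and monomer/oligomer classification,
    and inside/outside-vessel integrated-density quantification of
    fluorescence micrographs with calibration-curve inversion. Includes
    seeded synthetic-data generators for every assay so the full pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, minpack.lm, EBImage
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
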