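Package: phylopep
Title: Phylopeptidomics: Relative Biomass of Organisms from Shared-Peptide
    Metaproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates relative biomass contributions of organisms in a
    microbial community from shotgun metaproteomics identifications.
    Counts taxon-to-spectrum matches (TSMs) from validated peptide-spectrum
    matches, rolls them up the NCBI-style taxonomy, computes pan-domain
    phylogenetic distances (patristic from newick trees, or percent-identity
    from concatenated marker-gene supervectors with conservation masking),
    and deconvolves the observed TSM-versus-distance profile into
    per-organism abundances by bounded nonlinear least-squares fitting of
    bi-exponential phylopeptidomic signatures. Includes estimator
    comparisons, biomass arithmetic for mock-community standards, and a
    synthetic-community simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
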