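Package: tcemscan
Title: T Cell Exposed Motif Frequency and Neoepitope Down-Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores missense tumor mutations for immune visibility by
    combining three patient-specific signals: the frequency, in reference
    proteomes, of the pentamer motif a bound peptide exposes to the T cell
    receptor (the T cell exposed motif, TCEM); predicted peptide-MHC binding
    from a bagged regression ensemble over principal-component amino acid
    descriptors; and whether the preferred binding registers place the mutant
    residue in a T-cell-exposed or an anchor (groove-facing) position.
    Provides pentamer frequency tables over the complete 20^5 key space,
    zero-inflated Poisson and sinh-arcsinh (SHASH) standardization fits,
    4-parameter logistic and Weibull growth curve fits, HLA genotype bitmap
    coding with Shannon diversity, per-case down-selection cascades, and
    synthetic generators for proteomes, mutation sets, genotypes, and binding
    training data so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
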