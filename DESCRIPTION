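Package: carnlib
Title: Diagnostic Fragment-Ion Mining and Delta-Mass Library Curation for
    Acylcarnitine MS/MS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mining tandem mass spectrometry repositories for
    acylcarnitines: evaluation of diagnostic product-ion queries (m/z
    60.0808, 85.0284, 144.1019), redundancy-reducing spectral clustering,
    modified-cosine molecular networking with purging of contaminated
    subnetworks, curation of a delta-mass spectral library with CAR
    lipid nomenclature and bounded elemental-formula decomposition,
    cosine and reverse-cosine library searching, repository-level
    statistics (rarefaction, presence matrices, composition frequencies),
    and downstream feature-table analyses including blank subtraction,
    relative abundance normalisation and synchronized time-course group
    detection. A synthetic-repository generator with known ground truth
    makes every stage testable without repository downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    jsonlite
Config/testthat/edition: 3
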