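Package: spatmir
Title: Spatial Integration of miRNA-mRNA Expression Across Tumour Resection Margins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Paired moderated-t differential expression, sparse partial
    least squares (sPLS) miRNA-mRNA integration against a validated target
    catalog, spatial Pearson correlation along a normal-tissue-to-tumour
    biopsy axis, and leave-one-patient-out stability selection, yielding a
    reciprocal/non-reciprocal miRNA-mRNA interaction signature for oral
    squamous cell carcinoma resection margins. Includes a synthetic-data
    generator that emulates the three-site (NBI, WL, T) paired study design
    with planted regulatory interactions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
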