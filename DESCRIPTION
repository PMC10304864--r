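Package: phagevo
Title: Analysis of Phage Experimental Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing experimental evolution of bacteriophages:
    strand-aware annotation of mutations against an annotated reference genome,
    classification of amino-acid property changes (charge, polarity, volume),
    statistics for parallel molecular evolution across replicate populations,
    estimation of phage adsorption rates from paired titers, quantification of
    plaque sizes from plate photographs, and summaries of phage and host
    population dynamics. Includes generators for synthetic genomes, mutation
    tables, assay counts, plate images and dynamics series with known ground
    truth, suitable for validating every step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    EBImage,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    png
Config/testthat/edition: 3
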