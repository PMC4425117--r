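Package: enzymome
Title: Comparative Enzyme Profiling of Artificial Metagenomes from
    GenBank Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds artificial metagenomes from annotated GenBank genome
    records, assigns missing Enzyme Commission (EC) numbers de novo by
    matching coding-sequence product names against the ExPASy ENZYME
    flat-file nomenclature, and compares the enzyme complements of two
    microbiome groups. Reports the enzymes shared between the groups and
    unique to each (gene copies counted), per-genome annotation-coverage
    statistics before and after de novo annotation, and a binary
    reliability flag distinguishing unique or pre-existing annotations
    from ambiguous multi-match assignments. Includes a synthetic fixture
    generator producing GenBank files and miniature ENZYME flat files
    with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
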