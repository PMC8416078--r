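Package: herbshot
Title: Shotgun Metabarcoding of Mixed Herbal Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies the biological ingredients of mixed herbal products
    (prescribed herbs, adulterants, weeds, fungi) from untargeted shotgun
    sequencing reads. Reads from three DNA barcode regions (ITS2, matK, rbcL)
    are enriched with a marker-labelled k-mer screen, assembled with a
    de Bruijn graph over a ladder of k-mer sizes, reduced to the barcode
    region proper by primer trimming (matK, rbcL) or conserved-flank profile
    annotation (ITS2), cleaned of chimeric splices, clustered into
    exact-haplotype OTUs, verified by read-mapping depth and coverage, and
    assigned taxonomy by identity-ranked reference search with
    lowest-common-ancestor placement. A bundled simulator generates
    dosage-weighted mock-formulation shotgun data with off-target background,
    contaminant taxa, sequencing errors and chimeric artifacts, so the whole
    pipeline can be exercised end to end with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
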