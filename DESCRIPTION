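Package: isosip
Title: Detection and Quantification of Isoprene-Degrading Bacteria from
    Metagenomes and DNA Stable-Isotope Probing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and quantify isoprene-degrading bacteria in
    shotgun metagenomes and DNA stable-isotope probing (DNA-SIP)
    experiments. Implements a six-frame translated homology search
    (Smith-Waterman local alignment with Karlin-Altschul E-values) for
    functional marker proteins such as IsoA, the alpha-subunit of isoprene
    monooxygenase; a recA-normalized estimate of the percentage of bacteria
    carrying the marker; heavy/light gradient-fraction identification and
    fold-enrichment calling for DNA-SIP incubations; screening of annotated
    contigs and metagenome-assembled genomes for isoprene-degradation gene
    clusters (isoABCDEFGHIJ and accessory genes); and fragment-based
    average nucleotide identity. A synthetic-community module generates
    genomes with planted marker genes, shotgun reads, and isopycnic
    gradient profiles so the whole pipeline can be exercised and validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
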