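Package: psoramap
Title: Genetic Linkage Mapping, Macrosynteny and Ks Divergence Dating for
    Psoraleoid Legumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds F2 genetic linkage maps from genotyping-by-sequencing
    SNP and presence/absence (PAV) marker calls: parental phasing,
    outlier-individual screening, recombination-fraction estimation by
    maximum likelihood, iterative linkage grouping, redundant-marker
    binning, seriation-based skeleton ordering with jackknife stability
    testing, and Kosambi map distances.  Aligns a genetic map to
    chromosome-level reference genomes by filtering translated-BLAST
    tabular hits (top-hit selection with a whole-genome-duplication mode,
    isolated-match window filtering) and produces concatenated-coordinate
    dotplots.  Estimates lineage divergence times from synonymous
    substitution (Ks) distributions: Nei-Gojobori (1986) Ka/Ks with
    Jukes-Cantor correction, kernel-density Ks peak detection, Ks-peak
    distance matrices over whole-genome-duplication replicate leaves,
    neighbor-joining topology inference, ultrametric non-negative
    least-squares branch fitting, and calibration of node ages against the
    papilionoid whole-genome duplication.  Includes simulators for every
    input (F2 populations, marker-to-genome matches under chromosome
    rearrangement, Ks samples, codon pairs) with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
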