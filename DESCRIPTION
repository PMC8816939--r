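Package: ctfrag
Title: Cell-Free DNA Fragmentomics and In-Silico ctDNA Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates plasma cell-free DNA fragments with size, signed
    distance of their start and end sites to the nearest nucleosome dyad,
    and a per-base nucleotide bias score learned as the first principal
    component separating healthy from tumor bootstrap-replicate end-motif
    position weight matrices. Quantifies circulating tumor DNA enrichment
    of any fragment selection through a bootstrap down-sampling procedure
    that estimates tumor fraction from shallow-coverage binned counts
    against a selection-matched panel of normals, and through aggregated
    mutant allele fraction at a designated point-mutation locus. A
    synthetic-cohort generator provides reference genomes, nucleosome
    tracks and healthy/tumor fragment pools with the statistical structure
    the analysis assumes, so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
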