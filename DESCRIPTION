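Package: genocurate
Title: Automated Metadata Curation for Local Bacterial Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-checks a locally downloaded collection of complete
    bacterial genome assemblies against NCBI-style bacteria and archaea
    genome-report tables. Nine flag categories mark inconsistencies between
    the genome report, the genome folder name, and the FASTA sequence file
    headers: accession presence in the report, BioProject/UID association,
    filename-vs-header accession consistency, genus and species agreement,
    archaeal contamination, non-reference RefSeq accessions, plasmid-only
    folders, and draft or partial sequence descriptions. Report statements
    are rendered for every raised flag, and non-destructive file management
    (directory listings, descriptive renaming, selective copy-out) preserves
    an unaltered master copy of the collection. A seeded fixture generator
    produces synthetic genome trees and matched reports with injected,
    ground-truth-labelled errors for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
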