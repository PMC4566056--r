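# genocurate

Automated metadata curation for local collections of complete bacterial
genomes.

## The problem

Downloading "all complete bacterial genomes" from a public ftp site gives
you thousands of per-genome folders (`Genus_species[_strain]_uid<digits>`)
of FASTA (`.fna`) files named by RefSeq accession — and a surprising number
of metadata errors: archaeal genomes filed under bacteria, folders whose
BioProject UID belongs to a different strain, files dropped into the wrong
genome's folder, draft or plasmid-only assemblies in a "complete" set,
discontinued accessions, and genome names that disagree between the folder,
the genome report, and the sequence file itself. Any of these can silently
corrupt downstream comparative-genomics, phylogenetics, or forensics work.

`genocurate` cross-checks every downloaded sequence file against the NCBI
bacteria and archaea genome-report tables and raises a flag wherever the
three name/identifier sources disagree. It never modifies the downloaded
tree: curation reads, reports, and (on request) copies — the master
collection stays byte-identical.

## The nine flag categories

For each sequence file (or folder, for the plasmid-only check), a flag is
`TRUE` when a problem is detected:

| category | raised when |
|---|---|
| `accession_in_report` | the header accession is in neither report |
| `bioproject_uid_match` | the folder UID is unknown, resolves to another genus, or the file's accession belongs to a different BioProject |
| `original_accession_consistency` | file name and header carry different accessions |
| `genus_match` | report, folder, and file disagree at genus rank |
| `species_match` | likewise at species rank (strain never compared) |
| `archaea` | the accession is listed in the archaea report |
| `refseq_reference_accession` | the accession is not an `NC_` reference assembly |
| `chromosome_data_present` | the folder holds only plasmid files |
| `draft_or_partial` | the description matches a draft keyword ("draft", "partial sequence", "provisional sequence", "nearly complete genome", "sequencing in progress", "non-contiguous finished genome") |

Name comparison is in a normalized form (lowercase, punctuation stripped,
`Candidatus` and placeholder epithets like `sp.` skipped), and one report
statement is rendered per raised flag.

## Worked example

There is no deposited genome collection to ship, so the package generates
one: a seeded fixture with injected, ground-truth-labelled errors for every
flag category (this is also how the package validates itself).

```r
library(genocurate)

fx <- generate_fixture(file.path(tempdir(), "demo"), n_clean = 5, seed = 42)
bacteria <- parse_genome_report(fx$bacteria_report, "bacteria")
archaea  <- parse_genome_report(fx$archaea_report, "archaea")
scan     <- scan_genomes(fx$genomes_root)
result   <- curate(scan, bacteria, archaea)
result
#> <curation_result: 31 folders, 57 files, 56 flags raised>
#> # A tibble: 9 × 3
#>   category                       files_flagged genomes_flagged
#>   <chr>                                  <dbl>           <dbl>
#> 1 accession_in_report                        1               1
#> 2 bioproject_uid_match                      21               5
#> 3 original_accession_consistency             1               1
#> 4 genus_match                               11               2
#> 5 species_match                             11               2
#> 6 archaea                                    1               1
#> 7 refseq_reference_accession                 2               1
#> 8 chromosome_data_present                    2               1
#> 9 draft_or_partial                           6               6
```

The 21 `bioproject_uid_match` files are the fixture's misfiled files: 17
foreign files planted in one *Vibrio parahaemolyticus* folder, one file in
each of three *Synechocystis* substrain folders carrying another
substrain's UID, and the renamed-genome conflict. `tidy(result)` gives the
per-file flag table, `glance(result)` one-row totals, and
`autoplot(result)` a bar chart of the summary. Clean genomes can then be
copied out for downstream use without touching the master tree:

```r
clean <- setdiff(unique(scan$folder),
                 unique(tidy(result)$folder[rowSums(tidy(result)[, flag_categories()]) > 0]))
manifest <- copy_genomes(scan, clean, file.path(tempdir(), "clean_set"))
```

A command-line interface wraps the same functions
(`exec/genocurate curate|select|fixture|print-dir`); `curate` exits 0 when
the collection is clean, 3 when flags were raised, 1 on operational error.

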