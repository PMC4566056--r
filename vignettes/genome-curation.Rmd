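---
title: "Curating a local bacterial genome collection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a local bacterial genome collection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genocurate)
```

## The curation model

A downloaded collection of complete bacterial genomes carries three
independent statements of each genome's identity: the genome-report row
(organism name, BioProject UID, status, RefSeq accession lists), the folder
name (`Genus_species[_strain]_uid<digits>`), and the first line of each
`.fna` file (accession, version, free-text description). Because these are
maintained by different processes and updated at different times, they
drift apart: genomes get renamed, files get misfiled, accessions get
discontinued, statuses get downgraded. The curation engine treats each
pairwise or three-way disagreement as a flag; it never attempts to decide
which source is right, and it never modifies the collection. Correction is
the curator's job; detection is the tool's.

Nine categories cover the error classes observed in real collections (see
`flag_categories()` and the README table). Flag polarity is uniform:
`TRUE` always means a problem, so a clean collection is an all-`FALSE`
table. Eight categories are per-file; only the plasmid-only check is
per-folder (and is carried onto each of the folder's file rows, so row-level
and statement-level counts stay consistent: one statement per raised flag).

A deliberate consequence of the model is that errors *inside* a genome
report are invisible: if the report itself mislists an accession, every
check that consults the report inherits the mistake. Two such cases are
pinned as expected misses in the test suite: a genome listed in both the
bacteria and archaea reports whose accessions appear only in the bacteria
report is not flagged as archaeal (the archaea rule is accession-based, by
design — name-based matching would false-positive on every dual listing),
and a misspelled draft keyword ("drat genome") escapes the keyword scan.

## Name comparison

Genus and species are extracted from all three sources by one shared rule
(`extract_genus_species()`): skip a leading `Candidatus` and any
quoted/bracketed token, take the first remaining token as genus, and accept
the next token as the species epithet only if it is purely alphabetic,
lowercase-initial, and not a placeholder (`sp.`, `genomosp.`). Strain
designations are never compared — strain naming is too inconsistent across
sources for mechanical comparison to be informative. Values are compared in
a normalized form (lowercase, punctuation stripped); strict byte equality
would additionally flag rows that differ only in punctuation or case, which
real reports do, so normalization trades a few true inconsistencies for far
fewer noise flags. With fewer than two sources carrying a value at a rank,
that rank's flag stays clear and the detail records the insufficiency
rather than guessing.

## Resolving a folder to its report record

The report is indexed three ways (accession, UID, normalized name), all as
multimaps — duplicate organism names and even duplicate BioProject IDs
occur in real reports and are *not* errors. A folder is resolved to its
candidate record(s) by UID first, then by normalized name; when several
candidates exist, any one candidate consistent with the other sources
clears a flag (details still list all candidates). The numeric UID is the
join key throughout; the `PRJNA...` BioProject accession is carried as
detail only, since the folder naming convention embeds the UID, not the
accession.

Resolution (for the UID and name checks) consults the bacteria report
first and then the archaea report. This is a deliberate choice: an
archaeal genome misfiled under the bacteria tree but correctly listed in
the archaea report is exactly one error — archaeal contamination — and
should raise exactly the archaea flag, not a spurious UID failure against
the bacteria report.

The UID check itself is two-part. Folder-level: the folder's UID must
exist in the report and resolve to a record agreeing at genus rank.
File-level: when a file's accession is itself listed in the report, at
least one of its records must carry the folder's UID. The file-level part
is what catches a file from another strain of the *same species* dropped
into the wrong folder — names agree, versionless accessions are
self-consistent, and only the accession→BioProject association betrays the
misplacement.

## The fixture generator

Real collections cannot be shipped or re-downloaded reproducibly, so the
package generates its own study material: `generate_fixture()` writes a
genome tree plus matched bacteria/archaea reports with injected errors,
each labelled with exactly the flags the engine should raise. Sequence
payloads are three lines of 60 seeded-random bases — curation reads only
the header, so content is arbitrary but reproducible; the same seed gives
a byte-identical fixture.

Scenario compositions mirror observed error cases at fixed magnitudes: the
misfiled folder holds its two correct chromosome files plus 17 foreign
files (7 from one other same-species strain — 2 chromosomes, 5 plasmids —
9 single-chromosome strains of a second genus, 1 of a third); the
substrain set has six folders of which three carry another substrain's UID
in a cyclic permutation while keeping their own files (a simultaneous swap
of UID *and* files would be self-consistent and undetectable by
cross-referencing, which is also why such errors are pernicious in real
data); the duplicate-name scenario carries three duplicated names, one
pair sharing a BioProject ID. Clean genomes draw from a pool of real
genus names with synthesized species epithets and strains, 1–2 chromosomes
and 0–2 plasmids each (about 1.9 files per genome, matching the shape of
a real download).

What the fixtures do *not* emulate: real sequence content, report columns
beyond the parsed subset, genuine taxonomic spelling variation (only the
pinned "drat" case), multi-level directory nesting, or transfer/unpacking
artifacts. Passing the truth-label tests therefore demonstrates the
engine's logic is exact on the modelled error taxonomy, not that the
taxonomy exhausts what a live download can contain.

## Numerical and procedural choices

* Accession comparison is always versionless: file names carry no version,
  so `NC_016802.1` and `NC_016802` are the same record.
* Report parsing locates columns by header name, case-insensitively, and
  ignores unknown columns; `-` or empty accession cells mean "none
  listed"; unrecognized statuses map to `other` with a warning rather than
  an error; rows with unparseable UIDs are kept with the UID absent. All
  of this keeps decade-spanning report snapshots parseable.
* The draft vocabulary is the closed six-phrase set above, matched
  case-insensitively as substrings, and is overridable
  (`draft_vocabulary()`, `--draft-vocab`).
* "plasmid" is matched as a whole word, so tokens merely containing it do
  not reclassify a file.
* Scanning reads one line per file (O(1) in sequence length), treats only
  immediate subdirectories as genomes, ignores non-`.fna` files, and
  orders output bytewise so results are deterministic.
* Renamed copies truncate their stem to 120 characters and suffix `_2`,
  `_3`, ... on collision; renaming applies only to copies, never the
  master tree.

## Problem sizes used in validation

The test suite validates the engine against the generator's truth labels
on 200 randomized fixtures (all scenarios, seeds 1–200, two clean genomes
each) and runs one scale pass of 2,600 clean genomes (~4,900 files,
generated and curated in about a minute on one core). These sizes were
chosen to match the scale of a full real-world download while keeping the
default test run fast; the engine's cost is linear in file count with
constant-time index lookups.

## Known limitations

Keyword and accession rules inherit the blind spots documented above
(misspelled draft markers; report-internal errors). Genus/species
extraction assumes binomial-style leading tokens and will return genus
only for unconventional names. The engine flags; it does not rank severity
or auto-correct.
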