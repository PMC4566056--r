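# checksum of an entire directory tree: file contents + relative paths,
# so any write, rename, or delete under the tree changes the value
tree_checksum <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, all.files = TRUE,
                           full.names = TRUE, no.. = TRUE))
  sums <- tools::md5sum(files)
  rel <- substring(files, nchar(root) + 2L)
  paste(rel, unname(sums), collapse = ";")
}

# generate a fixture in a fresh temp dir, returning the fixture object
local_fixture <- function(..., env = parent.frame()) {
  root <- withr::local_tempdir(.local_envir = env)
  generate_fixture(file.path(root, "fx"), ...)
}

# parse both reports and curate a fixture in one go
curate_fixture <- function(fx) {
  bac <- parse_genome_report(fx$bacteria_report, "bacteria")
  arc <- parse_genome_report(fx$archaea_report, "archaea")
  curate(scan_genomes(fx$genomes_root), bac, arc)
}

# the sorted set of raised categories per file, as a comma string
# matching the truth-label encoding
raised_by_file <- function(result) {
  fl <- tidy(result)
  cats <- flag_categories()
  m <- as.matrix(fl[, cats])
  vapply(seq_len(nrow(fl)), function(i) {
    paste(sort(cats[m[i, ]]), collapse = ",")
  }, "")
}

# compare a curation result against a fixture's truth labels; returns a
# character vector of human-readable mismatch descriptions (empty = exact)
truth_mismatches <- function(fx, result) {
  fl <- tidy(result)
  got <- raised_by_file(result)
  key <- paste(fl$folder, fl$file)

  out <- character(0)
  tr_f <- fx$truth[fx$truth$entity_type == "file", ]
  m <- match(paste(tr_f$folder, tr_f$file), key)
  for (i in seq_len(nrow(tr_f))) {
    if (is.na(m[i])) {
      out <- c(out, paste("file not scanned:", tr_f$path[i]))
    } else if (got[m[i]] != tr_f$expected_flags[i]) {
      out <- c(out, sprintf("%s: expected [%s] got [%s]", tr_f$path[i],
                            tr_f$expected_flags[i], got[m[i]]))
    }
  }
  cats <- flag_categories()
  fmat <- as.matrix(fl[, cats])
  tr_d <- fx$truth[fx$truth$entity_type == "folder", ]
  for (i in seq_len(nrow(tr_d))) {
    rows <- fl$folder == tr_d$folder[i]
    agg <- paste(sort(cats[colSums(fmat[rows, , drop = FALSE]) > 0]),
                 collapse = ",")
    if (agg != tr_d$expected_flags[i]) {
      out <- c(out, sprintf("folder %s: expected [%s] got [%s]",
                            tr_d$folder[i], tr_d$expected_flags[i], agg))
    }
  }
  out
}

# minimal report table text, built in code for parser tests
report_lines <- function(rows,
                         header = "#Organism/Name\tBioProject Accession\tBioProject ID\tStatus\tChromosomes/RefSeq\tPlasmids/RefSeq\tModify Date") {
  c(header, rows)
}

report_row <- function(name, uid, chr = "-", pls = "-",
                       status = "Complete Genome",
                       accession = paste0("PRJNA", uid),
                       date = "2014/03/05") {
  paste(name, accession, uid, status, chr, pls, date, sep = "\t")
}

write_fna <- function(path, header, n_seq = 2) {
  writeLines(c(header, strrep("ACGT", 15), strrep("TTGA", 15))[seq_len(n_seq + 1)],
             path)
}
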