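#' Names of the supported error-injection scenarios
#'
#' Each scenario injects one class of metadata error observed in real
#' downloaded genome collections, together with ground-truth labels of the
#' flags the curation engine is expected to raise (or, for the two pinned
#' false-negative scenarios, expected to miss):
#'
#' * `name_conflict` - report, folder, and file description disagree at
#'   genus and species rank (a renamed genome whose folder kept the old
#'   genus).
#' * `archaea_mixed` - an archaeal genome filed under the bacteria tree.
#' * `plasmid_only` - a folder whose files are all plasmids.
#' * `draft_keyword` - one genome per draft-vocabulary phrase.
#' * `draft_misspelled` - the pinned "drat genome" misspelling, an expected
#'   miss of keyword matching.
#' * `misplaced_files` - a folder with its two correct chromosome files
#'   plus 17 foreign files (7 from another strain of the same species,
#'   9 from another genus's strains, 1 from a third genus).
#' * `uid_swap` - six substrain folders, three of which carry another
#'   substrain's UID.
#' * `dual_report` - a genome named in both reports whose accessions are
#'   listed only in the bacteria report; an expected miss of the
#'   accession-based archaea flag.
#' * `accession_mismatch` - file name and header carry different
#'   accessions.
#' * `non_refseq` - header accessions with `AC_`/`NZ_` prefixes.
#' * `missing_from_report` - file accessions absent from both reports.
#' * `duplicate_names` - report rows sharing organism names (one pair also
#'   sharing a BioProject ID); not errors, and labelled clean.
#'
#' @return Character vector of scenario names.
#' @export
fixture_scenarios <- function() {
  c("name_conflict", "archaea_mixed", "plasmid_only", "draft_keyword",
    "draft_misspelled", "misplaced_files", "uid_swap", "dual_report",
    "accession_mismatch", "non_refseq", "missing_from_report",
    "duplicate_names")
}

#' Generate a synthetic genome collection with ground-truth error labels
#'
#' Writes a complete synthetic test bed under `root`: a `genomes/` tree of
#' per-genome folders with `.fna` files (FASTA header plus a few lines of
#' random sequence - curation never reads past the header), a bacteria and
#' an archaea genome-report table in the tab-separated report dialect, and
#' a truth-label table recording, for every file and folder, exactly which
#' flags the curation engine should raise. The same `seed` always produces
#' a byte-identical fixture.
#'
#' @param root Output directory; must not already contain files.
#' @param n_clean Number of clean (error-free) genomes to generate.
#' @param scenarios Which error scenarios to inject; any subset of
#'   [fixture_scenarios()].
#' @param seed Integer seed for the generator.
#' @param header_dialect FASTA header dialect for generated files:
#'   `"gi"` for `>gi|n|ref|ACC.V| description`, `"bare"` for
#'   `>ACC description`.
#' @return A list of class `genome_fixture` with paths (`root`,
#'   `genomes_root`, `bacteria_report`, `archaea_report`, `truth_path`)
#'   and the truth-label tibble (`truth`: `entity_type`, `path`, `folder`,
#'   `file`, `expected_flags`, `expected_miss`).
#' @export
generate_fixture <- function(root, n_clean = 20,
                             scenarios = fixture_scenarios(), seed = 1,
                             header_dialect = c("gi", "bare")) {
  header_dialect <- match.arg(header_dialect)
  unknown <- setdiff(scenarios, fixture_scenarios())
  if (length(unknown) > 0) {
    stop("unknown fixture scenario(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (dir.exists(root) && length(list.files(root, all.files = TRUE,
                                            no.. = TRUE)) > 0) {
    stop("fixture root must be empty or absent: ", root, call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  ctx <- new_fixture_ctx(n_clean)
  genomes <- list()
  extra_bac <- list()
  extra_arc <- list()

  for (sc in scenarios) {
    part <- switch(
      sc,
      name_conflict = sc_name_conflict(ctx),
      archaea_mixed = sc_archaea_mixed(ctx),
      plasmid_only = sc_plasmid_only(ctx),
      draft_keyword = sc_draft_keyword(ctx),
      draft_misspelled = sc_draft_misspelled(ctx),
      misplaced_files = sc_misplaced_files(ctx),
      uid_swap = sc_uid_swap(ctx),
      dual_report = sc_dual_report(ctx),
      accession_mismatch = sc_accession_mismatch(ctx),
      non_refseq = sc_non_refseq(ctx),
      missing_from_report = sc_missing_from_report(ctx),
      duplicate_names = sc_duplicate_names(ctx)
    )
    genomes <- c(genomes, part$genomes)
    extra_bac <- c(extra_bac, part$extra_bacteria %||% list())
    extra_arc <- c(extra_arc, part$extra_archaea %||% list())
  }
  genomes <- c(genomes, sc_clean(ctx, n_clean)$genomes)
  # report-only records: genomes listed on the reports but never downloaded
  for (k in seq_len(max(3L, ceiling(n_clean * 0.05)))) {
    nm <- mk_display_name(ctx)
    extra_bac <- c(extra_bac, list(mk_record(ctx, nm, take_uid(ctx),
                                             chr = take_acc(ctx), pls = character(0),
                                             domain = "bacteria")))
  }
  for (k in 1:3) {
    nm <- mk_display_name(ctx, archaeal = TRUE)
    extra_arc <- c(extra_arc, list(mk_record(ctx, nm, take_uid(ctx),
                                             chr = take_acc(ctx), pls = character(0),
                                             domain = "archaea")))
  }

  # ---- write the tree -------------------------------------------------
  genomes_root <- file.path(root, "genomes")
  dir.create(genomes_root, recursive = TRUE, showWarnings = FALSE)
  truth <- vector("list", length(genomes))
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    gdir <- file.path(genomes_root, g$folder)
    dir.create(gdir, showWarnings = FALSE)
    for (fi in seq_len(nrow(g$files))) {
      f <- g$files[fi, ]
      header <- fixture_header(f$accession, f$version, f$description,
                               header_dialect)
      writeLines(c(header, random_sequence_lines()),
                 file.path(gdir, f$filename))
    }
    folder_flags <- sort(unique(unlist(g$files$flags)))
    folder_miss <- sort(unique(unlist(g$files$miss)))
    truth[[gi]] <- dplyr::bind_rows(
      tibble::tibble(
        entity_type = "file",
        path = file.path("genomes", g$folder, g$files$filename),
        folder = g$folder, file = g$files$filename,
        expected_flags = vapply(g$files$flags, paste_flags, ""),
        expected_miss = vapply(g$files$miss, paste_flags, "")
      ),
      tibble::tibble(
        entity_type = "folder", path = file.path("genomes", g$folder),
        folder = g$folder, file = NA_character_,
        expected_flags = paste_flags(folder_flags),
        expected_miss = paste_flags(folder_miss)
      )
    )
  }
  truth <- dplyr::bind_rows(truth)

  bac_records <- c(unlist(lapply(genomes, function(g) g$records_bacteria),
                          recursive = FALSE), extra_bac)
  arc_records <- c(unlist(lapply(genomes, function(g) g$records_archaea),
                          recursive = FALSE), extra_arc)
  bac_path <- file.path(root, "bacteria_report.txt")
  arc_path <- file.path(root, "archaea_report.txt")
  write_record_list(bac_records, bac_path)
  write_record_list(arc_records, arc_path)

  truth_path <- file.path(root, "truth_labels.tsv")
  readr::write_tsv(truth, truth_path, na = "")

  structure(
    list(root = root, genomes_root = genomes_root,
         bacteria_report = bac_path, archaea_report = arc_path,
         truth_path = truth_path, truth = truth,
         n_genomes = length(genomes), n_files = sum(truth$entity_type == "file")),
    class = "genome_fixture"
  )
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat(sprintf("<genome_fixture: %d genomes, %d files at %s>\n",
              x$n_genomes, x$n_files, x$root))
  invisible(x)
}

paste_flags <- function(x) paste(sort(unique(x)), collapse = ",")

# ---- generator internals ---------------------------------------------

new_fixture_ctx <- function(n_clean) {
  n <- max(600L, as.integer(n_clean) * 3L + 200L)
  ctx <- new.env(parent = emptyenv())
  ctx$uid_pool <- sample(100000:999999, n)
  ctx$acc_pool <- sample(100000:999999, min(n * 3L, 899999L))
  ctx$uid_i <- 0L
  ctx$acc_i <- 0L
  ctx
}

take_uid <- function(ctx) {
  ctx$uid_i <- ctx$uid_i + 1L
  ctx$uid_pool[[ctx$uid_i]]
}

take_acc <- function(ctx, n = 1, prefix = "NC_") {
  idx <- ctx$acc_i + seq_len(n)
  ctx$acc_i <- ctx$acc_i + n
  sprintf("%s%06d", prefix, ctx$acc_pool[idx])
}

fixture_genera <- c(
  "Bacillus", "Escherichia", "Pseudomonas", "Streptococcus", "Clostridium",
  "Mycobacterium", "Lactobacillus", "Staphylococcus", "Salmonella",
  "Rhodococcus", "Burkholderia", "Acinetobacter", "Corynebacterium",
  "Xanthomonas", "Shewanella", "Desulfovibrio", "Geobacter", "Borrelia",
  "Helicobacter", "Neisseria", "Rickettsia", "Francisella", "Yersinia",
  "Brucella"
)

fixture_archaea_genera <- c(
  "Methanococcus", "Sulfolobus", "Halobacterium", "Pyrococcus",
  "Thermococcus", "Methanosarcina", "Archaeoglobus", "Nitrosopumilus"
)

rand_species <- function() {
  syl <- c("ba", "ce", "di", "fo", "ga", "lu", "mi", "no", "pe", "ra",
           "si", "tu", "ve", "xa", "ze", "co", "li", "ma")
  paste(sample(syl, 3, replace = TRUE), collapse = "")
}

rand_strain <- function() {
  kind <- sample(3, 1)
  if (kind == 1) {
    paste(sample(c("ATCC", "DSM", "NCTC", "CIP"), 1), sample(1000:99999, 1))
  } else if (kind == 2) {
    paste0("str. ", paste(sample(LETTERS, 2), collapse = ""),
           sample(10:999, 1))
  } else {
    paste0(sample(LETTERS, 1), sample(1:99, 1))
  }
}

mk_display_name <- function(ctx, archaeal = FALSE, with_strain = TRUE) {
  genus <- sample(if (archaeal) fixture_archaea_genera else fixture_genera, 1)
  nm <- paste(genus, rand_species())
  if (with_strain && stats::runif(1) < 0.7) nm <- paste(nm, rand_strain())
  nm
}

# organism display name -> folder name (tokens underscored, uid appended)
folder_from_name <- function(name, uid) {
  tok <- gsub("[^A-Za-z0-9._-]+", "_", name)
  tok <- gsub("_+", "_", tok)
  sprintf("%s_uid%d", tok, uid)
}

mk_record <- function(ctx, organism, uid, chr, pls, domain,
                      status = "complete") {
  gs <- extract_genus_species(strsplit(organism, "[[:space:]]+")[[1]])
  tibble::tibble(
    organism_name = organism,
    genus = gs$genus,
    species = gs$species,
    bioproject_accession = sprintf("PRJNA%d", uid),
    bioproject_uid = as.integer(uid),
    status = status,
    chromosome_accessions = list(chr),
    plasmid_accessions = list(pls),
    modify_date = as.Date("2014-03-05") - sample(0:400, 1),
    source_domain = domain
  )
}

mk_file <- function(accession, description, filename = NULL, version = 1L,
                    flags = character(0), miss = character(0)) {
  tibble::tibble(
    filename = filename %||% paste0(accession, ".fna"),
    accession = accession, version = as.integer(version),
    description = description,
    flags = list(flags), miss = list(miss)
  )
}

chrom_desc <- function(name, i = NA) {
  num <- if (is.na(i)) "" else paste0(" ", i)
  sprintf("%s chromosome%s, complete sequence", name, num)
}

plasmid_desc <- function(name, i = 1) {
  sprintf("%s plasmid p%s%d, complete sequence", name,
          paste(sample(LETTERS, 2), collapse = ""), i)
}

fixture_header <- function(accession, version, description, dialect) {
  if (dialect == "gi") {
    sprintf(">gi|%d|ref|%s.%d| %s", sample.int(500000000L, 1), accession,
            version, description)
  } else {
    sprintf(">%s %s", accession, description)
  }
}

random_sequence_lines <- function(n = 3, width = 60) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = "")
  }, "")
}

# one genome: folder + files + its own report record(s) + labels
mk_genome <- function(folder, files, records_bacteria = list(),
                      records_archaea = list()) {
  list(folder = folder, files = files,
       records_bacteria = records_bacteria, records_archaea = records_archaea)
}

write_record_list <- function(records, path) {
  recs <- if (length(records) == 0) {
    tibble::tibble(
      organism_name = character(), genus = character(), species = character(),
      bioproject_accession = character(), bioproject_uid = integer(),
      status = character(), chromosome_accessions = list(),
      plasmid_accessions = list(), modify_date = as.Date(character()),
      source_domain = character()
    )
  } else {
    dplyr::bind_rows(records)
  }
  if (nrow(recs) > 1) recs <- recs[sample.int(nrow(recs)), ]
  write_genome_report(new_genome_report(recs), path)
}

# ---- scenarios --------------------------------------------------------

sc_clean <- function(ctx, n) {
  genomes <- vector("list", n)
  for (k in seq_len(n)) {
    nm <- mk_display_name(ctx)
    uid <- take_uid(ctx)
    n_chr <- sample(1:2, 1, prob = c(0.85, 0.15))
    n_pls <- sample(0:2, 1, prob = c(0.45, 0.35, 0.2))
    chr <- take_acc(ctx, n_chr)
    pls <- if (n_pls > 0) take_acc(ctx, n_pls) else character(0)
    files <- dplyr::bind_rows(
      purrr::map(seq_len(n_chr), function(i) {
        mk_file(chr[i], chrom_desc(nm, if (n_chr > 1) i else NA))
      }),
      purrr::map(seq_len(n_pls), function(i) {
        mk_file(pls[i], plasmid_desc(nm, i))
      })
    )
    genomes[[k]] <- mk_genome(
      folder_from_name(nm, uid), files,
      records_bacteria = list(mk_record(ctx, nm, uid, chr, pls, "bacteria"))
    )
  }
  list(genomes = genomes)
}

# report, folder, and file all disagree: the genome was renamed but the
# folder kept the old genus and the file an intermediate name
sc_name_conflict <- function(ctx) {
  uid <- take_uid(ctx)
  acc <- take_acc(ctx)
  report_name <- "Candidatus Endolissoclinum faulkneri L2"
  folder <- sprintf("Thalassobaculum_L2_uid%d", uid)
  desc <- chrom_desc("Candidatus Endolissoclinum patella L2")
  files <- mk_file(acc, desc,
                   flags = c("genus_match", "species_match",
                             "bioproject_uid_match"))
  list(genomes = list(mk_genome(
    folder, files,
    records_bacteria = list(mk_record(ctx, report_name, uid, acc,
                                      character(0), "bacteria"))
  )))
}

sc_archaea_mixed <- function(ctx) {
  nm <- mk_display_name(ctx, archaeal = TRUE)
  uid <- take_uid(ctx)
  acc <- take_acc(ctx)
  files <- mk_file(acc, chrom_desc(nm), flags = "archaea")
  list(genomes = list(mk_genome(
    folder_from_name(nm, uid), files,
    records_archaea = list(mk_record(ctx, nm, uid, acc, character(0),
                                     "archaea"))
  )))
}

sc_plasmid_only <- function(ctx) {
  nm <- mk_display_name(ctx)
  uid <- take_uid(ctx)
  pls <- take_acc(ctx, 2)
  files <- dplyr::bind_rows(
    mk_file(pls[1], plasmid_desc(nm, 1), flags = "chromosome_data_present"),
    mk_file(pls[2], plasmid_desc(nm, 2), flags = "chromosome_data_present")
  )
  list(genomes = list(mk_genome(
    folder_from_name(nm, uid), files,
    records_bacteria = list(mk_record(ctx, nm, uid, character(0), pls,
                                      "bacteria"))
  )))
}

sc_draft_keyword <- function(ctx) {
  vocab <- draft_vocabulary()
  genomes <- vector("list", length(vocab))
  for (k in seq_along(vocab)) {
    nm <- mk_display_name(ctx)
    uid <- take_uid(ctx)
    acc <- take_acc(ctx)
    desc <- if (vocab[k] == "draft") {
      sprintf("%s draft genome", nm)
    } else {
      sprintf("%s chromosome, %s", nm, vocab[k])
    }
    genomes[[k]] <- mk_genome(
      folder_from_name(nm, uid),
      mk_file(acc, desc, flags = "draft_or_partial"),
      records_bacteria = list(mk_record(ctx, nm, uid, acc, character(0),
                                        "bacteria"))
    )
  }
  list(genomes = genomes)
}

# the pinned false negative: a misspelled draft keyword is not caught
sc_draft_misspelled <- function(ctx) {
  nm <- "Fibrella aestuarina BUZ 2"
  uid <- take_uid(ctx)
  acc <- take_acc(ctx)
  files <- mk_file(acc, sprintf("%s drat genome", nm),
                   miss = "draft_or_partial")
  list(genomes = list(mk_genome(
    folder_from_name(nm, uid), files,
    records_bacteria = list(mk_record(ctx, nm, uid, acc, character(0),
                                      "bacteria"))
  )))
}

# a folder holding its own two chromosomes plus 17 foreign files: 7 from
# another strain of the same species, 9 from single-chromosome strains of
# another genus, and 1 from a third genus
sc_misplaced_files <- function(ctx) {
  host_name <- "Vibrio parahaemolyticus O1:K33 str. CDC_K4557"
  host_uid <- take_uid(ctx)
  host_chr <- take_acc(ctx, 2)
  records <- list(mk_record(ctx, host_name, host_uid, host_chr,
                            character(0), "bacteria"))
  files <- list(
    mk_file(host_chr[1], chrom_desc(host_name, 1)),
    mk_file(host_chr[2], chrom_desc(host_name, 2))
  )

  other_vibrio <- "Vibrio parahaemolyticus BB22OP"
  ov_uid <- take_uid(ctx)
  ov_chr <- take_acc(ctx, 2)
  ov_pls <- take_acc(ctx, 5)
  records <- c(records, list(mk_record(ctx, other_vibrio, ov_uid, ov_chr,
                                       ov_pls, "bacteria")))
  for (i in 1:2) {
    files <- c(files, list(mk_file(ov_chr[i], chrom_desc(other_vibrio, i),
                                   flags = "bioproject_uid_match")))
  }
  for (i in 1:5) {
    files <- c(files, list(mk_file(ov_pls[i], plasmid_desc(other_vibrio, i),
                                   flags = "bioproject_uid_match")))
  }

  foreign_full <- c("genus_match", "species_match", "bioproject_uid_match")
  for (i in 1:9) {
    nm <- sprintf("Listeria monocytogenes %s", rand_strain())
    uid <- take_uid(ctx)
    acc <- take_acc(ctx)
    records <- c(records, list(mk_record(ctx, nm, uid, acc, character(0),
                                         "bacteria")))
    files <- c(files, list(mk_file(acc, chrom_desc(nm), flags = foreign_full)))
  }
  cj <- sprintf("Campylobacter jejuni %s", rand_strain())
  cj_uid <- take_uid(ctx)
  cj_acc <- take_acc(ctx)
  records <- c(records, list(mk_record(ctx, cj, cj_uid, cj_acc, character(0),
                                       "bacteria")))
  files <- c(files, list(mk_file(cj_acc, chrom_desc(cj), flags = foreign_full)))

  list(genomes = list(mk_genome(
    folder_from_name(host_name, host_uid), dplyr::bind_rows(files),
    records_bacteria = records
  )))
}

# six substrain folders; three carry another substrain's UID while their
# files stay correct, so only the accession->UID association betrays them
sc_uid_swap <- function(ctx) {
  subs <- c("GT-I", "PCC-N", "PCC-P", "GT-S", "PCC-M", "GT-L")
  uids <- vapply(subs, function(s) take_uid(ctx), 1L)
  accs <- take_acc(ctx, length(subs))
  # cyclic swap among the first three
  folder_uid <- uids
  folder_uid[1:3] <- uids[c(2, 3, 1)]
  genomes <- vector("list", length(subs))
  for (k in seq_along(subs)) {
    nm <- sprintf("Synechocystis sp. PCC 6803 substr. %s", subs[k])
    wrong <- k <= 3
    genomes[[k]] <- mk_genome(
      folder_from_name(nm, folder_uid[k]),
      mk_file(accs[k], chrom_desc(nm),
              flags = if (wrong) "bioproject_uid_match" else character(0)),
      records_bacteria = list(mk_record(ctx, nm, uids[k], accs[k],
                                        character(0), "bacteria"))
    )
  }
  list(genomes = genomes)
}

# named in both reports, accessions only in the bacteria report: the
# accession-based archaea flag cannot see it (pinned false negative)
sc_dual_report <- function(ctx) {
  nm <- "Thermoproteus tenax Kra 1"
  uid <- take_uid(ctx)
  acc <- take_acc(ctx)
  files <- mk_file(acc, chrom_desc(nm), miss = "archaea")
  list(genomes = list(mk_genome(
    folder_from_name(nm, uid), files,
    records_bacteria = list(mk_record(ctx, nm, uid, acc, character(0),
                                      "bacteria")),
    records_archaea = list(mk_record(ctx, nm, uid, character(0),
                                     character(0), "archaea"))
  )))
}

sc_accession_mismatch <- function(ctx) {
  nm <- mk_display_name(ctx)
  uid <- take_uid(ctx)
  acc <- take_acc(ctx)
  wrong_name <- take_acc(ctx)
  files <- mk_file(acc, chrom_desc(nm),
                   filename = paste0(wrong_name, ".fna"),
                   flags = "original_accession_consistency")
  list(genomes = list(mk_genome(
    folder_from_name(nm, uid), files,
    records_bacteria = list(mk_record(ctx, nm, uid, acc, character(0),
                                      "bacteria"))
  )))
}

sc_non_refseq <- function(ctx) {
  nm <- mk_display_name(ctx)
  uid <- take_uid(ctx)
  acc_ac <- take_acc(ctx, prefix = "AC_")
  acc_nz <- take_acc(ctx, prefix = "NZ_")
  files <- dplyr::bind_rows(
    mk_file(acc_ac, chrom_desc(nm, 1), flags = "refseq_reference_accession"),
    mk_file(acc_nz, chrom_desc(nm, 2), flags = "refseq_reference_accession")
  )
  list(genomes = list(mk_genome(
    folder_from_name(nm, uid), files,
    records_bacteria = list(mk_record(ctx, nm, uid, c(acc_ac, acc_nz),
                                      character(0), "bacteria"))
  )))
}

# the report still names the genome, but the downloaded file carries a
# superseded accession the report no longer lists
sc_missing_from_report <- function(ctx) {
  nm <- mk_display_name(ctx)
  uid <- take_uid(ctx)
  listed <- take_acc(ctx)
  downloaded <- take_acc(ctx)
  files <- mk_file(downloaded, chrom_desc(nm), flags = "accession_in_report")
  list(genomes = list(mk_genome(
    folder_from_name(nm, uid), files,
    records_bacteria = list(mk_record(ctx, nm, uid, listed, character(0),
                                      "bacteria"))
  )))
}

# duplicate organism names are correct data, not errors: two pairs with
# distinct BioProject IDs, one pair sharing its BioProject ID
sc_duplicate_names <- function(ctx) {
  genomes <- list()
  records <- list()
  for (pair in 1:2) {
    nm <- mk_display_name(ctx)
    for (j in 1:2) {
      uid <- take_uid(ctx)
      acc <- take_acc(ctx)
      records <- c(records, list(mk_record(ctx, nm, uid, acc, character(0),
                                           "bacteria")))
      genomes <- c(genomes, list(mk_genome(
        folder_from_name(nm, uid), mk_file(acc, chrom_desc(nm))
      )))
    }
  }
  nm <- mk_display_name(ctx)
  uid <- take_uid(ctx)
  acc1 <- take_acc(ctx)
  acc2 <- take_acc(ctx)
  records <- c(records,
               list(mk_record(ctx, nm, uid, acc1, character(0), "bacteria")),
               list(mk_record(ctx, nm, uid, acc2, character(0), "bacteria")))
  genomes <- c(genomes, list(mk_genome(
    folder_from_name(nm, uid), mk_file(acc1, chrom_desc(nm))
  )))
  genomes[[1]]$records_bacteria <- records
  list(genomes = genomes)
}
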