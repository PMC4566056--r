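test_that("genus/species extraction skips Candidatus and placeholders", {
  expect_equal(
    extract_genus_species(c("Candidatus", "Endolissoclinum", "faulkneri", "L2")),
    list(genus = "endolissoclinum", species = "faulkneri")
  )
  expect_equal(extract_genus_species(character(0)),
               list(genus = NA_character_, species = NA_character_))
  expect_equal(
    extract_genus_species(c("Synechocystis", "sp.", "PCC", "6803")),
    list(genus = "synechocystis", species = NA_character_)
  )
  # strain-like and capitalised tokens are never taken as species
  expect_true(is.na(extract_genus_species(c("Vibrio", "O1:K33"))$species))
  # comparison form strips case and punctuation
  expect_equal(extract_genus_species(c("'Bacillus'", "Subtilis"))$genus,
               "subtilis")  # quoted token skipped, next token is genus
})

test_that("name comparison needs two sources and tolerates duplicate records", {
  # the three-way conflict: report, folder, and file all disagree
  r <- check_name("endolissoclinum", "thalassobaculum", "endolissoclinum",
                  "faulkneri", NA, "patella")
  expect_true(r$genus_flag)
  expect_true(r$species_flag)

  # identity clears both
  r2 <- check_name("vibrio", "vibrio", "vibrio",
                   "parahaemolyticus", "parahaemolyticus", "parahaemolyticus")
  expect_false(r2$genus_flag)
  expect_false(r2$species_flag)

  # single source: clear, with an insufficient-data note
  r3 <- check_name("fibrella", NA, NA, "aestuarina", NA, NA)
  expect_false(r3$genus_flag)
  expect_match(r3$genus_detail, "insufficient")

  # two agreeing sources with no report record: clear
  r4 <- check_name(character(0), "fibrella", "fibrella",
                   character(0), "aestuarina", "aestuarina")
  expect_false(r4$genus_flag)
  expect_false(r4$species_flag)

  # duplicate report records: any one consistent candidate clears
  r5 <- check_name(c("alpha", "vibrio"), "vibrio", "vibrio",
                   c("beta", "parahaemolyticus"), "parahaemolyticus", NA)
  expect_false(r5$genus_flag)
  expect_false(r5$species_flag)
})

test_that("the archaea flag is accession-based, never name-based", {
  arc <- parse_genome_report(report_lines(c(
    report_row("Sulfolobus solfataricus P2", 101, chr = "NC_002754"),
    report_row("Thermoproteus tenax Kra 1", 102, chr = "-")
  )), "archaea")
  expect_true(check_archaea("NC_002754", arc))
  expect_true(check_archaea("NC_002754.2", arc))
  # named in the archaea report but accession listed elsewhere: not flagged
  expect_false(check_archaea("NC_014567", arc))
})

test_that("filename/header accession consistency is versionless", {
  expect_false(check_accession_consistency("NC_016802", "NC_016802")$flag)
  expect_false(check_accession_consistency("NC_016802", "NC_016802.1")$flag)
  r <- check_accession_consistency("NC_016802", "NC_004603")
  expect_true(r$flag)
  expect_match(r$detail, "NC_004603")
  r2 <- check_accession_consistency("NC_016802", NA, malformed_header = TRUE)
  expect_true(r2$flag)
  expect_match(r2$detail, "malformed")
})

test_that("UID check catches wrong folder UIDs and misfiled accessions", {
  rep <- parse_genome_report(report_lines(c(
    report_row("Vibrio parahaemolyticus host", 111, chr = "NC_000001,NC_000002"),
    report_row("Vibrio parahaemolyticus other", 222, chr = "NC_000003")
  )), "bacteria")

  # consistent folder and file
  expect_false(check_uid_bioproject(111, "vibrio", "NC_000001", rep)$flag)
  # folder UID absent from the report
  expect_true(check_uid_bioproject(999, "vibrio", "NC_000001", rep)$flag)
  # folder UID resolves to a different genus
  expect_true(check_uid_bioproject(111, "listeria", "NC_000001", rep)$flag)
  # same-species file misfiled: its accession belongs to another UID
  expect_true(check_uid_bioproject(111, "vibrio", "NC_000003", rep)$flag)
  # unlisted accession is not this check's business
  expect_false(check_uid_bioproject(111, "vibrio", "NC_999999", rep)$flag)
  # no UID suffix on the folder: cannot check, noted not raised
  r <- check_uid_bioproject(NA, "vibrio", "NC_000001", rep)
  expect_false(r$flag)
  expect_match(r$detail, "no UID")
})

test_that("accession presence, RefSeq prefix, plasmid-only, and draft checks", {
  bac <- parse_genome_report(report_lines(
    report_row("Some bacterium", 1, chr = "NC_000010")
  ), "bacteria")
  arc <- parse_genome_report(report_lines(
    report_row("Some archaeon", 2, chr = "NC_000020")
  ), "archaea")
  expect_false(check_accession_in_report("NC_000010", bac, arc))
  expect_false(check_accession_in_report("NC_000020", bac, arc))  # archaea-only
  expect_true(check_accession_in_report("NC_999999", bac, arc))

  expect_false(check_refseq_prefix("NC_016802"))
  expect_true(check_refseq_prefix("AC_000002"))
  expect_true(check_refseq_prefix("NZ_ABCD01000001"))
  expect_true(check_refseq_prefix(NA_character_))

  expect_false(check_chromosome_present(c("chromosome_or_genome", "plasmid")))
  expect_true(check_chromosome_present(c("plasmid", "plasmid")))

  expect_true(check_draft("draft"))
  expect_false(check_draft(character(0)))
})

test_that("a clean collection raises zero flags", {
  fx <- local_fixture(n_clean = 10, scenarios = character(0), seed = 5)
  res <- curate_fixture(fx)
  expect_equal(length(res$statements), 0)
  expect_equal(sum(as.matrix(tidy(res)[, flag_categories()])), 0)
  expect_equal(sum(res$summary$files_flagged), 0)
})

test_that("every injected error category is raised and statements match flags", {
  fx <- local_fixture(n_clean = 4, seed = 9)
  res <- curate_fixture(fx)
  fl <- as.matrix(tidy(res)[, flag_categories()])

  # all nine categories occur at least once across the scenario set
  expect_true(all(colSums(fl) > 0))
  # one statement per raised flag
  expect_equal(length(res$statements), sum(fl))
  # summary equals a brute-force recount of the rows
  expect_equal(res$summary$files_flagged, unname(colSums(fl)))
  genome_level <- rowsum(fl + 0L, tidy(res)$folder) > 0
  expect_equal(res$summary$genomes_flagged, unname(colSums(genome_level)))
})

test_that("curation is idempotent", {
  fx <- local_fixture(n_clean = 3, seed = 13)
  bac <- parse_genome_report(fx$bacteria_report, "bacteria")
  arc <- parse_genome_report(fx$archaea_report, "archaea")
  scan <- scan_genomes(fx$genomes_root)
  r1 <- curate(scan, bac, arc)
  r2 <- curate(scan, bac, arc)
  expect_equal(r1$flags, r2$flags)
  expect_equal(r1$statements, r2$statements)
  expect_equal(r1$summary, r2$summary)
})

test_that("duplicate report names are not errors: any consistent record clears", {
  fx <- local_fixture(n_clean = 0, scenarios = "duplicate_names", seed = 17)
  res <- curate_fixture(fx)
  expect_equal(length(res$statements), 0)
})

test_that("tidy, glance, and autoplot expose the result", {
  fx <- local_fixture(n_clean = 2, scenarios = "non_refseq", seed = 19)
  res <- curate_fixture(fx)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(flag_categories() %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_flags, 2)  # the AC_ and NZ_ files
  expect_equal(gl$n_statements, length(res$statements))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("curation outputs are written as flag table, summary, statements", {
  fx <- local_fixture(n_clean = 2, scenarios = "draft_keyword", seed = 23)
  res <- curate_fixture(fx)
  out <- withr::local_tempdir()
  paths <- write_curation(res, out)
  expect_true(all(file.exists(paths)))
  tab <- readr::read_tsv(paths[["flags"]], show_col_types = FALSE)
  expect_equal(nrow(tab), res$n_files)
  expect_true(all(flag_categories() %in% names(tab)))
  expect_true(all(unlist(tab[flag_categories()]) %in% 0:1))
  stmts <- readr::read_lines(paths[["statements"]])
  expect_equal(length(stmts), length(res$statements))
})
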