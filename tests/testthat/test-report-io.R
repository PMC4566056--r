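test_that("report rows parse into records with derived genus and species", {
  rep <- parse_genome_report(report_lines(c(
    report_row("Candidatus Endolissoclinum faulkneri L2", 183483,
               chr = "NC_023032.1", accession = "PRJNA182483"),
    report_row("Synechocystis sp. PCC 6803", 111111, chr = "NC_000911")
  )), "bacteria")
  r <- rep$records
  expect_equal(nrow(r), 2)
  expect_equal(r$bioproject_accession[1], "PRJNA182483")
  expect_equal(r$genus[1], "endolissoclinum")
  expect_equal(r$species[1], "faulkneri")
  expect_equal(r$chromosome_accessions[[1]], "NC_023032")  # version stripped
  expect_equal(r$genus[2], "synechocystis")
  expect_true(is.na(r$species[2]))  # "sp." is not an epithet
  expect_equal(r$source_domain, c("bacteria", "bacteria"))
})

test_that("column matching is header-name based and order-independent", {
  a <- parse_genome_report(report_lines(
    report_row("Escherichia coli K-12", 57779, chr = "NC_000913")
  ), "bacteria")
  b <- parse_genome_report(c(
    "#BioProject ID\tStatus\tChromosomes/RefSeq\tOrganism/Name\tExtraCol",
    "57779\tComplete Genome\tNC_000913\tEscherichia coli K-12\tignored"
  ), "bacteria")
  shared <- c("organism_name", "genus", "species", "bioproject_uid",
              "status", "chromosome_accessions")
  expect_equal(a$records[shared], b$records[shared])
})

test_that("missing required columns and empty input are hard errors", {
  expect_error(parse_genome_report(c("#Organism/Name\tStatus", "X y\tComplete Genome"),
                                   "bacteria"),
               "BioProject ID")
  expect_error(parse_genome_report(character(0), "bacteria"), "empty")
  expect_error(parse_genome_report("", "bacteria"), "empty")
})

test_that("header-only report yields zero records and empty indexes", {
  rep <- parse_genome_report(report_lines(character(0)), "archaea")
  expect_equal(nrow(rep$records), 0)
  expect_equal(length(ls(rep$by_accession)), 0)
  expect_equal(length(ls(rep$by_uid)), 0)
  expect_equal(length(ls(rep$by_name)), 0)
})

test_that("accession cells split on commas; '-' and empty mean none", {
  rep <- parse_genome_report(report_lines(c(
    report_row("Multi chrom", 1, chr = "NC_000001.2,NC_000002", pls = "NC_000003"),
    report_row("No accessions", 2, chr = "-", pls = "")
  )), "bacteria")
  expect_equal(rep$records$chromosome_accessions[[1]], c("NC_000001", "NC_000002"))
  expect_equal(rep$records$plasmid_accessions[[1]], "NC_000003")
  expect_equal(rep$records$chromosome_accessions[[2]], character(0))
  expect_equal(rep$records$plasmid_accessions[[2]], character(0))
  # record with no accessions is still reachable by uid and name
  expect_equal(nrow(lookup_by_uid(rep, 2)), 1)
  expect_equal(nrow(lookup_by_name(rep, "No accessions")), 1)
  expect_equal(length(ls(rep$by_accession)), 3)
})

test_that("accession lookup is versionless and silent on absence", {
  rep <- parse_genome_report(report_lines(
    report_row("Vibrio parahaemolyticus O1:K33 str. CDC_K4557", 230445,
               chr = "NC_016802,NC_016803")
  ), "bacteria")
  expect_equal(lookup_by_accession(rep, "NC_016802.1"),
               lookup_by_accession(rep, "NC_016802"))
  expect_equal(nrow(lookup_by_accession(rep, "NC_016802")), 1)
  expect_equal(nrow(lookup_by_accession(rep, "NC_999999")), 0)
})

test_that("unparseable UID and unknown status degrade with warnings", {
  expect_warning(
    rep <- parse_genome_report(report_lines(
      report_row("Broken uid", "notanumber", chr = "NC_000004")
    ), "bacteria"),
    "BioProject ID"
  )
  expect_true(is.na(rep$records$bioproject_uid[1]))
  expect_equal(nrow(lookup_by_accession(rep, "NC_000004")), 1)

  expect_warning(
    rep2 <- parse_genome_report(report_lines(
      report_row("Odd status", 5, status = "Mysterious")
    ), "bacteria"),
    "status"
  )
  expect_equal(rep2$records$status[1], "other")
})

test_that("duplicate organism names and BioProject IDs are multimapped", {
  # 50 rows; 3 names appear twice (so 47 distinct names)
  names50 <- c(sprintf("Genus unique%02d strain", 1:44),
               rep(c("Genus dupA one", "Genus dupB two", "Genus dupC three"),
                   each = 2))
  rows <- vapply(seq_along(names50), function(i) {
    report_row(names50[i], 1000 + i, chr = sprintf("NC_%06d", i))
  }, "")
  rep <- parse_genome_report(report_lines(rows), "bacteria")
  expect_equal(nrow(rep$records), 50)
  expect_equal(length(ls(rep$by_name)), 47)
  for (nm in c("Genus dupA one", "Genus dupB two", "Genus dupC three")) {
    expect_equal(nrow(lookup_by_name(rep, nm)), 2)
  }
  # duplicate BioProject IDs are also allowed
  dup_uid <- parse_genome_report(report_lines(c(
    report_row("Same uid one", 99, chr = "NC_111111"),
    report_row("Same uid two", 99, chr = "NC_222222")
  )), "bacteria")
  expect_equal(nrow(lookup_by_uid(dup_uid, 99)), 2)
})

test_that("a written report reparses to field-equal records", {
  fx <- local_fixture(n_clean = 6, seed = 11)
  rep <- parse_genome_report(fx$bacteria_report, "bacteria")
  path <- withr::local_tempfile(fileext = ".txt")
  write_genome_report(rep, path)
  rep2 <- parse_genome_report(path, "bacteria")
  expect_equal(rep$records, rep2$records)
})

test_that("index consistency: every record is reachable from each of its accessions", {
  fx <- local_fixture(n_clean = 8, seed = 3)
  rep <- parse_genome_report(fx$bacteria_report, "bacteria")
  r <- rep$records
  for (i in seq_len(nrow(r))) {
    for (acc in c(r$chromosome_accessions[[i]], r$plasmid_accessions[[i]])) {
      hits <- lookup_by_accession(rep, acc)
      expect_true(r$organism_name[[i]] %in% hits$organism_name)
    }
  }
})

test_that("parsing is independent of row order for index membership", {
  rows <- c(
    report_row("Alpha beta one", 1, chr = "NC_000010"),
    report_row("Gamma delta two", 2, chr = "NC_000020", pls = "NC_000021"),
    report_row("Epsilon zeta three", 3, chr = "NC_000030")
  )
  a <- parse_genome_report(report_lines(rows), "bacteria")
  b <- parse_genome_report(report_lines(rev(rows)), "bacteria")
  for (acc in c("NC_000010", "NC_000020", "NC_000021", "NC_000030")) {
    expect_equal(lookup_by_accession(a, acc)$organism_name,
                 lookup_by_accession(b, acc)$organism_name)
  }
})
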