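#' The nine curation flag categories
#'
#' Every flag marks a problem: `TRUE` means an inconsistency or error was
#' detected. Eight categories are evaluated per sequence file;
#' `chromosome_data_present` is evaluated per genome folder (raised when a
#' folder contains only plasmid files) and carried on each of the folder's
#' file rows.
#'
#' @return Character vector of the nine category names, in fixed output
#'   order.
#' @export
flag_categories <- function() {
  c("accession_in_report", "bioproject_uid_match",
    "original_accession_consistency", "genus_match", "species_match",
    "archaea", "refseq_reference_accession", "chromosome_data_present",
    "draft_or_partial")
}

#' Compare genus and species across report, folder, and file
#'
#' The three name sources for a sequence file - the resolved genome-report
#' record(s), the genome folder name, and the file's own description line -
#' are compared at genus and at species rank, in comparison form (lowercase,
#' punctuation stripped; strain designations excluded). A rank's flag is
#' raised only when at least two sources carry a value and they do not all
#' agree; with fewer than two sources the flag stays clear and the detail
#' notes the insufficient data. When duplicate report records are candidates,
#' any one candidate consistent with the other sources clears the flag.
#'
#' @param report_genus,report_species Character vectors of candidate record
#'   values (zero or more; duplicates allowed).
#' @param folder_genus,folder_species Single values from the folder name.
#' @param file_genus,file_species Single values from the file description.
#' @return A list with `genus_flag`, `species_flag` (logicals) and
#'   `genus_detail`, `species_detail` (strings or `NA`).
#' @export
check_name <- function(report_genus, folder_genus, file_genus,
                       report_species, folder_species, file_species) {
  rank <- function(report_vals, folder_val, file_val, label) {
    report_vals <- unique(report_vals[!is.na(report_vals)])
    have_report <- length(report_vals) > 0
    have_folder <- !is.na(folder_val)
    have_file <- !is.na(file_val)
    n_sources <- have_report + have_folder + have_file
    if (n_sources < 2) {
      return(list(flag = FALSE,
                  detail = sprintf("insufficient data to compare %s (%d source)",
                                   label, n_sources)))
    }
    others <- c(if (have_folder) folder_val, if (have_file) file_val)
    ok <- if (have_report) {
      any(vapply(report_vals, function(g) all(others == g), TRUE))
    } else {
      length(unique(others)) == 1
    }
    if (ok) return(list(flag = FALSE, detail = NA_character_))
    list(flag = TRUE, detail = sprintf(
      "%s mismatch: report=%s folder=%s file=%s", label,
      if (have_report) paste(report_vals, collapse = "|") else "?",
      if (have_folder) folder_val else "?",
      if (have_file) file_val else "?"
    ))
  }
  g <- rank(report_genus, folder_genus, file_genus, "genus")
  s <- rank(report_species, folder_species, file_species, "species")
  list(genus_flag = g$flag, genus_detail = g$detail,
       species_flag = s$flag, species_detail = s$detail)
}

#' Flag archaeal genomes by accession
#'
#' Raised when the file's header accession is listed in the archaea genome
#' report. The rule is accession-only by design: a genome merely *named* in
#' the archaea report, with its accessions listed only in the bacteria
#' report, is not flagged - a documented false negative inherited from the
#' report data itself.
#'
#' @param header_accession Versionless accession from the file header.
#' @param archaea_report The parsed archaea `genome_report`.
#' @return `TRUE` if the accession is indexed in the archaea report.
#' @export
check_archaea <- function(header_accession, archaea_report) {
  nrow(lookup_by_accession(archaea_report, header_accession)) > 0
}

#' Flag filename/header accession inconsistency
#'
#' Raised when the accession carried by the file's name differs from the
#' accession inside the file's header (versionless comparison), or when the
#' header could not be parsed at all.
#'
#' @param filename_accession Accession from the file name.
#' @param header_accession Accession from the header line (`NA` if
#'   malformed).
#' @param malformed_header `TRUE` when the first line was not a FASTA
#'   header.
#' @return A list with `flag` and `detail`.
#' @export
check_accession_consistency <- function(filename_accession, header_accession,
                                        malformed_header = FALSE) {
  if (isTRUE(malformed_header) || is.na(header_accession)) {
    return(list(flag = TRUE, detail = "malformed or missing FASTA header"))
  }
  if (strip_version(filename_accession) != strip_version(header_accession)) {
    return(list(flag = TRUE, detail = sprintf(
      "filename accession %s != header accession %s",
      filename_accession, header_accession)))
  }
  list(flag = FALSE, detail = NA_character_)
}

#' Flag BioProject/UID inconsistencies
#'
#' Two-part rule. Folder level: the UID in the folder name must resolve to
#' a report record, and at least one resolved record must agree with the
#' folder at genus rank - otherwise the folder's association is wrong.
#' File level: when the file's header accession is itself listed in the
#' report, at least one of its records must carry the folder's UID -
#' otherwise the file belongs to a different BioProject and was misfiled
#' (this is what catches a same-species file dropped into the wrong
#' folder). A folder without a UID suffix cannot be checked and stays
#' clear with a note.
#'
#' @param folder_uid Integer UID from the folder name (`NA` if absent).
#' @param folder_genus Folder genus in comparison form.
#' @param header_accession Versionless accession from the file header.
#' @param report A `genome_report` to resolve UIDs and accessions against
#'   (the bacteria report, or a combined bacteria+archaea view).
#' @return A list with `flag` and `detail`.
#' @export
check_uid_bioproject <- function(folder_uid, folder_genus, header_accession,
                                 report) {
  if (is.na(folder_uid)) {
    return(list(flag = FALSE, detail = "folder has no UID suffix; not checked"))
  }
  by_uid <- lookup_by_uid(report, folder_uid)
  if (nrow(by_uid) == 0) {
    return(list(flag = TRUE, detail = sprintf(
      "folder UID %d not found in genome report", folder_uid)))
  }
  if (!is.na(folder_genus)) {
    rec_genus <- by_uid$genus[!is.na(by_uid$genus)]
    if (length(rec_genus) > 0 && !any(rec_genus == folder_genus)) {
      return(list(flag = TRUE, detail = sprintf(
        "folder UID %d resolves to genus %s but folder genus is %s",
        folder_uid, paste(unique(rec_genus), collapse = "|"), folder_genus)))
    }
  }
  by_acc <- lookup_by_accession(report, header_accession)
  if (nrow(by_acc) > 0) {
    acc_uids <- by_acc$bioproject_uid[!is.na(by_acc$bioproject_uid)]
    if (length(acc_uids) > 0 && !any(acc_uids == folder_uid)) {
      return(list(flag = TRUE, detail = sprintf(
        "file accession %s belongs to BioProject UID %s, not folder UID %d",
        header_accession, paste(unique(acc_uids), collapse = "|"), folder_uid)))
    }
  }
  list(flag = FALSE, detail = NA_character_)
}

#' Flag accessions missing from both genome reports
#'
#' Raised when the header accession is listed in neither the bacteria nor
#' the archaea report - typically a discontinued or renamed accession.
#' An accession listed only in the archaea report is clear here (the
#' archaea flag covers that case).
#'
#' @param header_accession Versionless accession from the file header.
#' @param bacteria_report,archaea_report Parsed `genome_report`s.
#' @return `TRUE` when the accession appears in neither report.
#' @export
check_accession_in_report <- function(header_accession, bacteria_report,
                                      archaea_report) {
  nrow(lookup_by_accession(bacteria_report, header_accession)) == 0 &&
    nrow(lookup_by_accession(archaea_report, header_accession)) == 0
}

#' Flag non-reference RefSeq accessions
#'
#' RefSeq reference-assembly chromosome records carry the `NC_` prefix;
#' any other prefix (`AC_`, `NZ_`, ...) marks a file that is not a
#' reference assembly.
#'
#' @param header_accession Versionless accession (`NA` counts as raised).
#' @return `TRUE` unless the accession begins with `NC_`.
#' @export
check_refseq_prefix <- function(header_accession) {
  is.na(header_accession) || !startsWith(header_accession, "NC_")
}

#' Flag genome folders with only plasmid files
#'
#' A genome-level flag: raised when every sequence file in the folder is a
#' plasmid, i.e. chromosome or whole-genome data are absent.
#'
#' @param molecule_classes Character vector of `molecule_class` values for
#'   all files in one folder.
#' @return `TRUE` when all files are plasmids.
#' @export
check_chromosome_present <- function(molecule_classes) {
  length(molecule_classes) > 0 && all(molecule_classes == "plasmid")
}

#' Flag potential draft or partial sequences
#'
#' Raised when the description matched any phrase of the draft keyword
#' vocabulary. Keyword matching is literal: misspellings outside the
#' vocabulary are not caught.
#'
#' @param draft_hits Character vector of matched phrases for one file.
#' @return `TRUE` when any phrase matched.
#' @export
check_draft <- function(draft_hits) {
  length(draft_hits) > 0
}

#' Run the full curation over a scanned collection
#'
#' Applies all nine flag categories to every sequence file and genome
#' folder of a scan, cross-checking against the bacteria and archaea
#' genome reports. For name and UID checks each folder is resolved to its
#' report record(s) by UID first, then by normalized organism name, against
#' the bacteria report and then the archaea report (so a correctly reported
#' archaeal genome is flagged only as archaea, not as a UID failure).
#' One human-readable report statement is rendered per raised flag.
#'
#' Errors *within* a genome report are invisible to this engine by design:
#' only disagreements between the downloaded data and the reports are
#' flagged.
#'
#' @param scan A `genome_scan` from [scan_genomes()].
#' @param bacteria_report,archaea_report Parsed `genome_report`s.
#' @return A `curation_result`: a list with `flags` (tibble, one row per
#'   file: identity columns, the nine logical flag columns in
#'   [flag_categories()] order, and a `details` list-column),
#'   `statements` (character), and `summary` (per-category raised counts
#'   at file and genome level).
#' @export
curate <- function(scan, bacteria_report, archaea_report) {
  stopifnot(inherits(bacteria_report, "genome_report"),
            inherits(archaea_report, "genome_report"))
  combined <- combine_reports(bacteria_report, archaea_report)

  folders <- unique(scan$folder)
  folder_info <- scan[!duplicated(scan$folder),
                      c("folder", "uid", "folder_genus", "folder_species")]
  # folder -> candidate report records: by UID first, then by name
  candidates <- purrr::map(seq_len(nrow(folder_info)), function(i) {
    recs <- lookup_by_uid(combined, folder_info$uid[[i]])
    if (nrow(recs) == 0) {
      tokens <- scan$folder_tokens[[match(folder_info$folder[[i]], scan$folder)]]
      recs <- lookup_by_name(combined, paste(tokens, collapse = " "))
    }
    recs
  })
  names(candidates) <- folder_info$folder

  plasmid_only <- tapply(scan$molecule_class, scan$folder,
                         check_chromosome_present)

  n <- nrow(scan)
  flags <- matrix(FALSE, nrow = n, ncol = 9,
                  dimnames = list(NULL, flag_categories()))
  details <- vector("list", n)

  for (i in seq_len(n)) {
    det <- character(0)
    note <- character(0)
    recs <- candidates[[scan$folder[[i]]]]

    if (check_accession_in_report(scan$header_accession[[i]],
                                  bacteria_report, archaea_report)) {
      flags[i, "accession_in_report"] <- TRUE
      det <- c(det, accession_in_report = sprintf(
        "accession %s not found in either genome report",
        scan$header_accession[[i]] %|NA|% "(none)"))
    }

    uid_chk <- check_uid_bioproject(scan$uid[[i]], scan$folder_genus[[i]],
                                    scan$header_accession[[i]], combined)
    if (uid_chk$flag) {
      flags[i, "bioproject_uid_match"] <- TRUE
      det <- c(det, bioproject_uid_match = uid_chk$detail)
    } else if (!is.na(uid_chk$detail)) {
      note <- c(note, uid_chk$detail)
    }

    acc_chk <- check_accession_consistency(scan$filename_accession[[i]],
                                           scan$header_accession[[i]],
                                           scan$malformed_header[[i]])
    if (acc_chk$flag) {
      flags[i, "original_accession_consistency"] <- TRUE
      det <- c(det, original_accession_consistency = acc_chk$detail)
    }

    name_chk <- check_name(recs$genus, scan$folder_genus[[i]],
                           scan$described_genus[[i]],
                           recs$species, scan$folder_species[[i]],
                           scan$described_species[[i]])
    if (name_chk$genus_flag) {
      flags[i, "genus_match"] <- TRUE
      det <- c(det, genus_match = name_chk$genus_detail)
    } else if (!is.na(name_chk$genus_detail)) {
      note <- c(note, name_chk$genus_detail)
    }
    if (name_chk$species_flag) {
      flags[i, "species_match"] <- TRUE
      det <- c(det, species_match = name_chk$species_detail)
    } else if (!is.na(name_chk$species_detail)) {
      note <- c(note, name_chk$species_detail)
    }

    if (check_archaea(scan$header_accession[[i]], archaea_report)) {
      flags[i, "archaea"] <- TRUE
      det <- c(det, archaea = sprintf(
        "accession %s is listed in the archaea genome report",
        scan$header_accession[[i]]))
    }

    if (check_refseq_prefix(scan$header_accession[[i]])) {
      flags[i, "refseq_reference_accession"] <- TRUE
      det <- c(det, refseq_reference_accession = sprintf(
        "accession %s is not a RefSeq reference assembly (NC_) accession",
        scan$header_accession[[i]] %|NA|% "(none)"))
    }

    if (isTRUE(plasmid_only[[scan$folder[[i]]]])) {
      flags[i, "chromosome_data_present"] <- TRUE
      det <- c(det, chromosome_data_present =
                 "folder contains only plasmid files; chromosome/genome data absent")
    }

    if (check_draft(scan$draft_hits[[i]])) {
      flags[i, "draft_or_partial"] <- TRUE
      det <- c(det, draft_or_partial = sprintf(
        "description matches draft keyword(s): %s",
        paste(scan$draft_hits[[i]], collapse = ", ")))
    }

    details[[i]] <- list(raised = det, notes = note)
  }

  flag_tbl <- dplyr::bind_cols(
    scan[, c("folder", "uid", "file", "header_accession", "description")],
    tibble::as_tibble(flags),
    tibble::tibble(details = details)
  )

  statements <- unlist(purrr::map(seq_len(n), function(i) {
    raised <- details[[i]]$raised
    if (length(raised) == 0) return(character(0))
    sprintf("[%s] %s/%s: %s", names(raised),
            scan$folder[[i]], scan$file[[i]], unname(raised))
  }), use.names = FALSE) %||% character(0)

  fl <- flag_tbl[, flag_categories()]
  genome_level <- rowsum(as.matrix(fl) + 0L, group = flag_tbl$folder) > 0
  summary_tbl <- tibble::tibble(
    category = flag_categories(),
    files_flagged = unname(colSums(as.matrix(fl))),
    genomes_flagged = unname(colSums(genome_level))
  )

  structure(
    list(flags = flag_tbl, statements = statements, summary = summary_tbl,
         n_files = n, n_folders = length(folders)),
    class = "curation_result"
  )
}

`%|NA|%` <- function(a, b) if (length(a) == 1 && is.na(a)) b else a

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf(
    "<curation_result: %d folders, %d files, %d flags raised>\n",
    x$n_folders, x$n_files, length(x$statements)))
  print(x$summary, ...)
  invisible(x)
}

#' Tidy a curation result into its per-file flag table
#'
#' @param x A `curation_result`.
#' @param ... Unused.
#' @return The per-file flag tibble (identity columns, nine logical flag
#'   columns, `details` list-column).
#' @method tidy curation_result
#' @export
tidy.curation_result <- function(x, ...) {
  x$flags
}

#' One-row summary of a curation result
#'
#' @param x A `curation_result`.
#' @param ... Unused.
#' @return A one-row tibble: folder and file totals, flagged-file and
#'   flagged-genome counts, and the total number of raised flags (equal to
#'   the number of report statements).
#' @method glance curation_result
#' @export
glance.curation_result <- function(x, ...) {
  fl <- as.matrix(x$flags[, flag_categories()])
  tibble::tibble(
    n_folders = x$n_folders,
    n_files = x$n_files,
    n_files_flagged = sum(rowSums(fl) > 0),
    n_genomes_flagged = sum(rowsum(rowSums(fl), x$flags$folder) > 0),
    n_flags = sum(fl),
    n_statements = length(x$statements)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot per-category flag counts
#'
#' Bar chart of the number of files (and genomes) raising each of the nine
#' flag categories.
#'
#' @param object A `curation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot curation_result
#' @export
autoplot.curation_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              c("files_flagged", "genomes_flagged"),
                              names_to = "level", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$category, .data$n),
    y = .data$n, fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flagged", fill = NULL,
                  title = "Curation flags by category") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write curation outputs to a directory
#'
#' Writes three files: `flags.tsv` (one row per sequence file; folder, UID,
#' file name, header accession, description, the nine flag columns as 0/1
#' in [flag_categories()] order, and a collapsed detail column),
#' `summary.tsv` (per-category raised counts at file and genome level), and
#' `statements.txt` (one report statement per raised flag).
#'
#' @param result A `curation_result`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_curation <- function(result, dir) {
  stopifnot(inherits(result, "curation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fl <- result$flags
  out <- fl[, c("folder", "uid", "file", "header_accession", "description")]
  for (cat in flag_categories()) out[[cat]] <- as.integer(fl[[cat]])
  out$details <- vapply(fl$details, function(d) {
    paste(sprintf("%s: %s", names(d$raised), unname(d$raised)), collapse = " | ")
  }, "")
  paths <- c(
    flags = file.path(dir, "flags.tsv"),
    summary = file.path(dir, "summary.tsv"),
    statements = file.path(dir, "statements.txt")
  )
  readr::write_tsv(out, paths[["flags"]], na = "")
  readr::write_tsv(result$summary, paths[["summary"]])
  readr::write_lines(result$statements, paths[["statements"]])
  invisible(paths)
}
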