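#' Parse an NCBI-style prokaryote genome-report table
#'
#' Reads the tab-separated genome summary table published for a domain
#' (bacteria or archaea): a header line beginning with `#`, then one row per
#' genome with organism name, BioProject identifiers, assembly status, and
#' comma-separated lists of chromosome and plasmid RefSeq accessions.
#' Columns are located by header name, case-insensitively, so column order
#' and unknown extra columns do not matter; the report dialect has changed
#' over the years and this keeps old and new snapshots parseable.
#'
#' Accession cells are split on commas and version suffixes (".N") are
#' stripped; a cell that is empty or "-" means no accessions are listed,
#' which does occur in real reports. Rows whose BioProject ID does not parse
#' as a positive integer are retained with `bioproject_uid = NA` and a
#' warning. Unrecognised status strings map to `"other"` with a warning.
#'
#' @param source Path to a report file, or a character vector of lines.
#' @param source_domain Either `"bacteria"` or `"archaea"`.
#' @return A `genome_report` object: a list carrying `records` (a tibble,
#'   one row per report row, with list-columns `chromosome_accessions` and
#'   `plasmid_accessions`) and accession/UID/name indexes used by the
#'   `lookup_*` helpers. Duplicate organism names and duplicate BioProject
#'   IDs are preserved: the indexes are multimaps.
#' @seealso [lookup_by_accession()], [write_genome_report()]
#' @export
parse_genome_report <- function(source, source_domain = c("bacteria", "archaea")) {
  source_domain <- match.arg(source_domain)
  if (length(source) == 1 && nzchar(source) && !grepl("[\t\n]", source)) {
    if (!file.exists(source)) {
      stop("genome report file not found: ", source, call. = FALSE)
    }
    lines <- readr::read_lines(source)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[!is.na(lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("empty genome report: no header line found", call. = FALSE)
  }
  header <- lines[[1]]
  if (!startsWith(header, "#")) {
    stop("genome report header must begin with '#', got: ",
         substr(header, 1, 40), call. = FALSE)
  }
  col_names <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  col_key <- tolower(gsub("[^a-z0-9]+", "", tolower(col_names)))

  find_col <- function(keys) {
    hit <- which(col_key %in% keys)
    if (length(hit) == 0) NA_integer_ else hit[[1]]
  }
  i_org    <- find_col(c("organismname", "organism", "name"))
  i_uid    <- find_col(c("bioprojectid", "bioprojectuid", "uid"))
  i_status <- find_col(c("status"))
  i_bpacc  <- find_col(c("bioprojectaccession"))
  i_chr    <- find_col(c("chromosomesrefseq", "chromosomerefseq", "chromosomes", "chromosomeaccessions"))
  i_pls    <- find_col(c("plasmidsrefseq", "plasmidrefseq", "plasmids", "plasmidaccessions"))
  i_date   <- find_col(c("modifydate"))

  required <- c("organism name" = i_org, "BioProject ID" = i_uid, "status" = i_status)
  if (anyNA(required)) {
    stop("genome report is missing required column(s): ",
         paste(names(required)[is.na(required)], collapse = ", "),
         call. = FALSE)
  }

  body <- lines[-1]
  body <- body[!startsWith(body, "#")]
  cells <- strsplit(body, "\t", fixed = TRUE)
  get <- function(row, i) {
    if (is.na(i) || i > length(row)) NA_character_ else {
      v <- trimws(row[[i]])
      if (!nzchar(v)) NA_character_ else v
    }
  }

  organism <- vapply(cells, get, "", i = i_org)
  uid_raw <- vapply(cells, get, "", i = i_uid)
  uid <- suppressWarnings(as.integer(uid_raw))
  uid[!is.na(uid) & uid <= 0] <- NA_integer_
  bad_uid <- !is.na(uid_raw) & is.na(uid)
  if (any(bad_uid)) {
    warning(sum(bad_uid), " report row(s) with unparseable BioProject ID; ",
            "kept with uid absent", call. = FALSE)
  }

  status <- normalize_status(vapply(cells, get, "", i = i_status))
  gs <- purrr::map(organism, function(nm) {
    if (is.na(nm)) list(genus = NA_character_, species = NA_character_)
    else extract_genus_species(strsplit(nm, "[[:space:]]+")[[1]])
  })

  records <- tibble::tibble(
    organism_name = organism,
    genus = purrr::map_chr(gs, "genus"),
    species = purrr::map_chr(gs, "species"),
    bioproject_accession = vapply(cells, get, "", i = i_bpacc),
    bioproject_uid = uid,
    status = status,
    chromosome_accessions = purrr::map(cells, function(r) split_accessions(get(r, i_chr))),
    plasmid_accessions = purrr::map(cells, function(r) split_accessions(get(r, i_pls))),
    modify_date = parse_report_date(vapply(cells, get, "", i = i_date)),
    source_domain = source_domain
  )
  new_genome_report(records)
}

# "-", "" -> no accessions; comma-separated otherwise; versions stripped
split_accessions <- function(cell) {
  if (is.na(cell) || cell %in% c("-", "")) return(character(0))
  parts <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts) & parts != "-"]
  strip_version(parts)
}

normalize_status <- function(x) {
  key <- gsub("[^a-z]+", " ", tolower(x))
  key <- trimws(gsub(" +", " ", key))
  out <- dplyr::case_match(
    key,
    c("complete", "complete genome") ~ "complete",
    "chromosome" ~ "chromosome",
    c("chromosome with gaps", "chromosome w gaps") ~ "chromosome_with_gaps",
    "scaffold" ~ "scaffold",
    "contig" ~ "contig",
    "other" ~ "other",
    .default = NA_character_
  )
  unknown <- is.na(out) & !is.na(x) & nzchar(key)
  if (any(unknown)) {
    warning("unrecognized genome status value(s): ",
            paste(unique(x[unknown]), collapse = ", "),
            "; mapped to 'other'", call. = FALSE)
  }
  out[is.na(out)] <- "other"
  out
}

parse_report_date <- function(x) {
  d <- as.Date(rep(NA_character_, length(x)))
  for (fmt in c("%Y/%m/%d", "%Y-%m-%d")) {
    miss <- is.na(d) & !is.na(x)
    if (!any(miss)) break
    d[miss] <- as.Date(x[miss], format = fmt)
  }
  d
}

new_genome_report <- function(records) {
  by_accession <- new.env(parent = emptyenv(), hash = TRUE)
  by_uid <- new.env(parent = emptyenv(), hash = TRUE)
  by_name <- new.env(parent = emptyenv(), hash = TRUE)
  push <- function(env, key, i) {
    if (is.na(key) || !nzchar(key)) return(invisible())
    assign(key, c(env[[key]], i), envir = env)
  }
  for (i in seq_len(nrow(records))) {
    for (acc in c(records$chromosome_accessions[[i]], records$plasmid_accessions[[i]])) {
      push(by_accession, acc, i)
    }
    if (!is.na(records$bioproject_uid[[i]])) {
      push(by_uid, as.character(records$bioproject_uid[[i]]), i)
    }
    nm <- norm_name(records$organism_name[[i]])
    if (!is.na(nm)) push(by_name, nm, i)
  }
  structure(
    list(records = records, by_accession = by_accession,
         by_uid = by_uid, by_name = by_name),
    class = "genome_report"
  )
}

#' Look up report records by RefSeq accession
#'
#' Returns every record whose chromosome or plasmid accession list contains
#' the given accession. The lookup is versionless: `"NC_016802.1"` and
#' `"NC_016802"` return the same records. Absence is not an error - an
#' empty tibble is returned.
#'
#' @param report A `genome_report`.
#' @param accession A single accession string, with or without a version
#'   suffix.
#' @return A tibble of matching records (zero or more rows).
#' @export
lookup_by_accession <- function(report, accession) {
  stopifnot(inherits(report, "genome_report"), length(accession) == 1)
  if (is.na(accession) || !nzchar(accession)) return(report$records[0, ])
  idx <- report$by_accession[[strip_version(accession)]]
  report$records[idx %||% integer(0), ]
}

#' Look up report records by BioProject UID
#'
#' @param report A `genome_report`.
#' @param uid A single numeric BioProject UID.
#' @return A tibble of matching records (zero or more rows); duplicate
#'   BioProject IDs do occur in real reports, so more than one row is
#'   possible.
#' @export
lookup_by_uid <- function(report, uid) {
  stopifnot(inherits(report, "genome_report"), length(uid) == 1)
  if (is.na(uid)) return(report$records[0, ])
  idx <- report$by_uid[[as.character(as.integer(uid))]]
  report$records[idx %||% integer(0), ]
}

#' Look up report records by organism name
#'
#' Matching is on the normalized name (lowercase, punctuation collapsed),
#' so sources differing only in case or punctuation match.
#'
#' @param report A `genome_report`.
#' @param name A single organism-name string.
#' @return A tibble of matching records (zero or more rows).
#' @export
lookup_by_name <- function(report, name) {
  stopifnot(inherits(report, "genome_report"), length(name) == 1)
  key <- norm_name(name)
  if (is.na(key)) return(report$records[0, ])
  idx <- report$by_name[[key]]
  report$records[idx %||% integer(0), ]
}

#' Write a genome report back to the tabular report dialect
#'
#' Emits the same tab-separated dialect [parse_genome_report()] reads
#' (header line starting with `#`, accession lists comma-joined, empty
#' lists as `-`), so a parsed report round-trips to field-equal records.
#'
#' @param report A `genome_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_report <- function(report, path) {
  stopifnot(inherits(report, "genome_report"))
  r <- report$records
  join_acc <- function(a) if (length(a) == 0) "-" else paste(a, collapse = ",")
  lines <- c(
    "#Organism/Name\tBioProject Accession\tBioProject ID\tStatus\tChromosomes/RefSeq\tPlasmids/RefSeq\tModify Date",
    sprintf(
      "%s\t%s\t%s\t%s\t%s\t%s\t%s",
      dplyr::coalesce(r$organism_name, ""),
      dplyr::coalesce(r$bioproject_accession, ""),
      ifelse(is.na(r$bioproject_uid), "-", as.character(r$bioproject_uid)),
      status_label(r$status),
      vapply(r$chromosome_accessions, join_acc, ""),
      vapply(r$plasmid_accessions, join_acc, ""),
      ifelse(is.na(r$modify_date), "-", format(r$modify_date, "%Y/%m/%d"))
    )
  )
  readr::write_lines(lines, path)
  invisible(path)
}

status_label <- function(status) {
  dplyr::case_match(
    status,
    "complete" ~ "Complete Genome",
    "chromosome" ~ "Chromosome",
    "chromosome_with_gaps" ~ "Chromosome with gaps",
    "scaffold" ~ "Scaffold",
    "contig" ~ "Contig",
    .default = "Other"
  )
}

#' @export
print.genome_report <- function(x, ...) {
  cat(sprintf(
    "<genome_report: %s, %d records, %d indexed accessions>\n",
    x$records$source_domain[1] %||% "empty",
    nrow(x$records),
    length(ls(x$by_accession))
  ))
  print(x$records, ...)
  invisible(x)
}

# concatenate reports into one lookup structure (records keep their
# source_domain); used when a check should consult both domains at once
combine_reports <- function(...) {
  recs <- dplyr::bind_rows(lapply(list(...), function(r) r$records))
  new_genome_report(recs)
}
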