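#' Default draft-sequence keyword vocabulary
#'
#' The six description phrases that mark a sequence file as a potential
#' draft or partial sequence rather than a finished assembly. The set is
#' closed by default but can be overridden wherever it is accepted; note
#' that out-of-vocabulary misspellings (the classic "drat genome") are a
#' documented false negative of keyword matching.
#'
#' @return Character vector of six phrases.
#' @export
draft_vocabulary <- function() {
  c("draft", "partial sequence", "provisional sequence",
    "nearly complete genome", "sequencing in progress",
    "non-contiguous finished genome")
}

#' Scan a downloaded genome directory tree
#'
#' Walks the immediate subdirectories of `root` (the layout of an NCBI ftp
#' genome download: one folder per genome, named
#' `Genus_species[_strain]_uid<digits>`, containing `.fna` FASTA files named
#' by versionless RefSeq accession). For every `.fna` file the first header
#' line is read and parsed into accession, version, and description, and the
#' description is classified (chromosome/plasmid, draft keywords, described
#' genus and species). Only the first line of each file is read, so scanning
#' cost does not grow with sequence length.
#'
#' The scan is strictly read-only: nothing under `root` is ever created,
#' renamed, or modified. Folders containing no `.fna` file produce a warning
#' and no rows; files with other extensions are ignored. Output order is
#' deterministic: folders sorted by name, files sorted by filename.
#'
#' @param root Path to the collection root.
#' @param draft_vocab Draft keyword vocabulary; see [draft_vocabulary()].
#' @return A tibble of class `genome_scan`, one row per sequence file, with
#'   folder-level columns (`folder`, `folder_path`, `folder_tokens`, `uid`,
#'   `folder_genus`, `folder_species`) and file-level columns (`file`,
#'   `path`, `filename_accession`, `header_accession`, `header_version`,
#'   `description`, `molecule_class`, `draft_hits`, `described_genus`,
#'   `described_species`, `malformed_header`).
#' @export
scan_genomes <- function(root, draft_vocab = draft_vocabulary()) {
  if (length(root) != 1 || is.na(root) || !dir.exists(root)) {
    stop("genome root directory not found or unreadable: ", root, call. = FALSE)
  }
  dirs <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  dirs <- dirs[order(basename(dirs), method = "radix")]

  rows <- vector("list", length(dirs))
  skipped <- character(0)
  for (k in seq_along(dirs)) {
    d <- dirs[[k]]
    fna <- list.files(d, pattern = "\\.fna$", full.names = TRUE)
    fna <- fna[order(basename(fna), method = "radix")]
    if (length(fna) == 0) {
      skipped <- c(skipped, basename(d))
      next
    }
    fold <- parse_folder_name(basename(d))
    frec <- purrr::map(fna, function(f) {
      hdr <- tryCatch(read_fasta_first_line(f), error = function(e) NULL)
      if (is.null(hdr)) return(NULL)
      cls <- classify_sequence_file(hdr$description, draft_vocab = draft_vocab)
      tibble::tibble(
        file = basename(f),
        path = f,
        filename_accession = strip_version(sub("\\.fna$", "", basename(f))),
        header_accession = hdr$header_accession,
        header_version = hdr$header_version,
        description = hdr$description,
        molecule_class = cls$molecule_class,
        draft_hits = list(cls$draft_hits),
        described_genus = cls$described_genus,
        described_species = cls$described_species,
        malformed_header = hdr$malformed
      )
    })
    unreadable <- vapply(frec, is.null, TRUE)
    if (any(unreadable)) {
      warning(sum(unreadable), " unreadable file(s) skipped in ", basename(d),
              call. = FALSE)
      frec <- frec[!unreadable]
      if (length(frec) == 0) {
        skipped <- c(skipped, basename(d))
        next
      }
    }
    files <- dplyr::bind_rows(frec)
    rows[[k]] <- dplyr::bind_cols(
      tibble::tibble(
        folder = basename(d),
        folder_path = d,
        folder_tokens = list(fold$name_tokens),
        uid = fold$uid,
        folder_genus = fold$genus,
        folder_species = fold$species
      )[rep(1, nrow(files)), ],
      files
    )
  }
  if (length(skipped) > 0) {
    warning("folder(s) without sequence files skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- empty_scan()
  class(out) <- c("genome_scan", class(out))
  out
}

empty_scan <- function() {
  tibble::tibble(
    folder = character(), folder_path = character(),
    folder_tokens = list(), uid = integer(),
    folder_genus = character(), folder_species = character(),
    file = character(), path = character(),
    filename_accession = character(), header_accession = character(),
    header_version = integer(), description = character(),
    molecule_class = character(), draft_hits = list(),
    described_genus = character(), described_species = character(),
    malformed_header = logical()
  )
}

#' Parse a genome folder name
#'
#' Folder names follow the download convention
#' `Genus_species[_strain]_uid<digits>`: a trailing `_uid<digits>` suffix
#' (case-insensitive) carries the BioProject UID, and the remaining
#' underscore-separated tokens are the organism name. Genus and species are
#' extracted with the same rule used for every other name source
#' ([extract_genus_species()]). A missing UID suffix is not an error; the
#' UID is simply absent.
#'
#' @param raw_name Folder name string (not a path).
#' @return A list with `name_tokens` (character vector), `uid` (integer or
#'   `NA`), `genus`, and `species` (comparison form, or `NA`).
#' @export
parse_folder_name <- function(raw_name) {
  stopifnot(length(raw_name) == 1, !is.na(raw_name), nzchar(raw_name))
  uid <- NA_integer_
  m <- regmatches(raw_name, regexpr("_[uU][iI][dD][0-9]+$", raw_name))
  base <- raw_name
  if (length(m) == 1 && nzchar(m)) {
    uid <- as.integer(sub("_[uU][iI][dD]", "", m))
    base <- substr(raw_name, 1, nchar(raw_name) - nchar(m))
  }
  tokens <- strsplit(base, "_", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  gs <- extract_genus_species(tokens)
  list(name_tokens = tokens, uid = uid, genus = gs$genus, species = gs$species)
}

#' Read and parse the first line of a FASTA sequence file
#'
#' Only the first line is read, so the call is O(1) in sequence length. Two
#' header dialects are supported: the classic NCBI pipe form
#' `>gi|<digits>|ref|<accession.version>| <description>` and the bare form
#' `><accession[.version]> <description>`. The accession is returned
#' versionless with the version (when present) as a separate integer.
#'
#' A file whose first line does not start with `>` is not an error: it is
#' returned with `malformed = TRUE` and no accession, which the curation
#' engine turns into a flag.
#'
#' @param file Path to a FASTA (`.fna`) file.
#' @return A list with `header_accession`, `header_version`, `description`,
#'   and `malformed`.
#' @export
read_fasta_first_line <- function(file) {
  if (!file.exists(file)) stop("sequence file not found: ", file, call. = FALSE)
  line <- readr::read_lines(file, n_max = 1)
  if (length(line) == 0) line <- ""
  parse_fasta_header(line)
}

parse_fasta_header <- function(line) {
  out <- list(header_accession = NA_character_, header_version = NA_integer_,
              description = NA_character_, malformed = FALSE)
  if (is.na(line) || !startsWith(line, ">")) {
    out$malformed <- TRUE
    return(out)
  }
  body <- sub("^>", "", line)
  m <- regexec("^gi\\|[0-9]+\\|ref\\|([A-Za-z0-9_]+)(\\.([0-9]+))?\\|\\s*(.*)$", body)[[1]]
  if (m[1] != -1) {
    g <- regmatches(body, regexec("^gi\\|[0-9]+\\|ref\\|([A-Za-z0-9_]+)(\\.([0-9]+))?\\|\\s*(.*)$", body))[[1]]
    out$header_accession <- g[2]
    if (nzchar(g[4])) out$header_version <- as.integer(g[4])
    out$description <- trimws(g[5])
  } else {
    g <- regmatches(body, regexec("^([A-Za-z0-9_]+)(\\.([0-9]+))?\\s*(.*)$", body))[[1]]
    if (length(g) == 0 || !nzchar(g[2])) {
      out$malformed <- TRUE
      return(out)
    }
    out$header_accession <- g[2]
    if (nzchar(g[4])) out$header_version <- as.integer(g[4])
    out$description <- trimws(g[5])
  }
  if (!nzchar(out$description)) out$description <- NA_character_
  out
}

#' Classify a sequence file from its description line
#'
#' Determines the molecule class (a whole-word, case-insensitive "plasmid"
#' in the description marks a plasmid file; any other non-empty description
#' is chromosome-or-genome data; an empty description is unknown), scans
#' for draft-sequence keywords (case-insensitive substring match against
#' the vocabulary), and extracts the genus and species the description
#' itself claims: the leading tokens up to the first molecule keyword
#' (chromosome, plasmid, genome, scaffold, contig, DNA, sequence) or comma,
#' passed through [extract_genus_species()].
#'
#' @param description Description text from the FASTA header (may be `NA`).
#' @param draft_vocab Draft keyword vocabulary; see [draft_vocabulary()].
#' @return A list with `molecule_class`, `draft_hits` (character vector of
#'   matched phrases), `described_genus`, and `described_species`.
#' @export
classify_sequence_file <- function(description, draft_vocab = draft_vocabulary()) {
  if (is.na(description) || !nzchar(trimws(description))) {
    return(list(molecule_class = "unknown", draft_hits = character(0),
                described_genus = NA_character_, described_species = NA_character_))
  }
  is_plasmid <- grepl("\\bplasmid\\b", description, ignore.case = TRUE)
  hits <- draft_vocab[vapply(
    draft_vocab,
    function(kw) grepl(kw, description, fixed = FALSE, ignore.case = TRUE),
    TRUE
  )]
  lead <- strsplit(description, ",", fixed = TRUE)[[1]][1]
  tokens <- strsplit(trimws(lead), "[[:space:]]+")[[1]]
  stopwords <- c("chromosome", "plasmid", "genome", "scaffold", "contig",
                 "dna", "sequence")
  cut <- which(tolower(tokens) %in% stopwords)
  if (length(cut) > 0) tokens <- tokens[seq_len(cut[1] - 1)]
  gs <- extract_genus_species(tokens)
  list(
    molecule_class = if (is_plasmid) "plasmid" else "chromosome_or_genome",
    draft_hits = unname(hits),
    described_genus = gs$genus,
    described_species = gs$species
  )
}
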