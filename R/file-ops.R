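#' Print a directory listing of a scanned collection
#'
#' One line per sequence file - folder name, file path, header accession -
#' in scan order, so the listing is byte-identical across runs on the same
#' tree. This is a read-only report; nothing is touched on disk unless
#' `out` is a file path.
#'
#' @param scan A `genome_scan`.
#' @param out A connection, a file path, or `NULL` to return the lines
#'   invisibly without printing.
#' @return The listing lines, invisibly.
#' @export
print_directory <- function(scan, out = stdout()) {
  lines <- sprintf("%s\t%s\t%s", scan$folder, scan$path,
                   dplyr::coalesce(scan$header_accession, ""))
  if (is.character(out)) {
    readr::write_lines(lines, out)
  } else if (!is.null(out)) {
    writeLines(lines, out)
  }
  invisible(lines)
}

#' Build a descriptive file name from a header description
#'
#' Copies of sequence files can be renamed to their description line so a
#' directory of copies is human-readable (`NC_016802.fna` says far less
#' than the organism and molecule it contains). Filesystem-unsafe
#' characters are replaced by `_`, runs collapse to a single `_`, and the
#' stem is truncated to 120 characters for cross-filesystem safety. When
#' the description is empty the accession is used instead. Renaming is
#' only ever applied to copies - the master tree is never touched.
#'
#' @param description Description text (may be `NA` or empty).
#' @param accession Fallback accession for empty descriptions.
#' @return A `.fna` file name string.
#' @seealso [copy_genomes()] for collision handling across a folder.
#' @export
descriptive_name <- function(description, accession = NA_character_) {
  stem <- description
  if (is.na(stem) || !nzchar(trimws(stem))) {
    stem <- accession %|NA|% "unnamed"
  }
  stem <- gsub("[^A-Za-z0-9._-]+", "_", stem)
  stem <- gsub("_+", "_", stem)
  stem <- sub("^_+", "", sub("_+$", "", stem))
  if (nchar(stem) > 120) stem <- substr(stem, 1, 120)
  paste0(stem, ".fna")
}

#' Copy selected genomes out of the master tree
#'
#' Copies each selected genome folder - all its sequence files - to a
#' destination directory for downstream use, leaving the master tree
#' untouched (the whole point: an unaltered master copy of the
#' collection). Genomes are selected by folder name or by UID,
#' interchangeably. With `rename = TRUE` the copies are given descriptive
#' names (see [descriptive_name()]); name collisions within a folder get
#' `_2`, `_3`, ... suffixes.
#'
#' @param scan A `genome_scan` of the master tree.
#' @param ids Character or numeric vector of folder names and/or UIDs.
#' @param dest Destination directory (created if needed). Must lie outside
#'   the master root.
#' @param rename Rename copies descriptively?
#' @return A manifest tibble (`genome`, `source`, `destination`), one row
#'   per copied file, invisibly written nowhere - pass it to
#'   [readr::write_tsv()] if a manifest file is wanted.
#' @export
copy_genomes <- function(scan, ids, dest, rename = FALSE) {
  if (nrow(scan) > 0) {
    roots <- unique(dirname(normalizePath(scan$folder_path, mustWork = FALSE)))
    dnorm <- file.path(normalizePath(dirname(dest), mustWork = FALSE),
                       basename(dest))
    inside <- vapply(roots, function(r) {
      startsWith(paste0(dnorm, "/"), paste0(r, "/"))
    }, TRUE)
    if (any(inside)) {
      stop("destination must be outside the master genome root", call. = FALSE)
    }
  }
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)

  ids <- unique(as.character(ids))
  if (length(ids) == 0) {
    return(tibble::tibble(genome = character(), source = character(),
                          destination = character()))
  }
  by_name <- ids %in% scan$folder
  by_uid <- !by_name & ids %in% as.character(scan$uid)
  unknown <- ids[!by_name & !by_uid]
  if (length(unknown) > 0) {
    stop("unknown genome identifier(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sel_folders <- unique(c(
    ids[by_name],
    scan$folder[match(ids[by_uid], as.character(scan$uid))]
  ))

  rows <- scan[scan$folder %in% sel_folders, ]
  rows <- rows[order(match(rows$folder, sort(sel_folders)), rows$file), ]
  manifest <- vector("list", length(sel_folders))
  for (k in seq_along(sort(sel_folders))) {
    fname <- sort(sel_folders)[k]
    fr <- rows[rows$folder == fname, ]
    target_dir <- file.path(dest, fname)
    dir.create(target_dir, recursive = TRUE, showWarnings = FALSE)
    seen <- character(0)
    dst_names <- character(nrow(fr))
    for (i in seq_len(nrow(fr))) {
      nm <- if (rename) {
        descriptive_name(fr$description[[i]], fr$header_accession[[i]] %|NA|%
                           fr$filename_accession[[i]])
      } else {
        fr$file[[i]]
      }
      if (nm %in% seen) {
        stem <- sub("\\.fna$", "", nm)
        j <- 2
        while (sprintf("%s_%d.fna", stem, j) %in% seen) j <- j + 1
        nm <- sprintf("%s_%d.fna", stem, j)
      }
      seen <- c(seen, nm)
      dst_names[[i]] <- nm
    }
    dst <- file.path(target_dir, dst_names)
    ok <- file.copy(fr$path, dst, overwrite = FALSE, copy.date = TRUE)
    if (!all(ok)) stop("copy failed for ", sum(!ok), " file(s) in ", fname,
                       call. = FALSE)
    manifest[[k]] <- tibble::tibble(genome = fname, source = fr$path,
                                    destination = dst)
  }
  dplyr::bind_rows(manifest)
}
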