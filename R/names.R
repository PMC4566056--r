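#' Extract genus and species from organism-name tokens
#'
#' One extraction rule is shared by every name source the curation engine
#' compares: the organism column of a genome report, a genome folder name,
#' and the description line of a sequence file. A leading "Candidatus"
#' (the provisional-taxon prefix) and any quoted or bracketed token are
#' skipped; the first remaining token is the genus. The next token is taken
#' as the species epithet only when it looks like one: purely alphabetic,
#' starting lowercase, and not a placeholder such as "sp." or "genomosp.".
#' Strain designations are never part of the result - strain naming is too
#' inconsistent across sources to compare mechanically.
#'
#' Both values are returned in comparison form: lowercase with punctuation
#' stripped, so that sources differing only in case or punctuation compare
#' equal.
#'
#' @param tokens Character vector of name tokens, in order (e.g. from
#'   splitting an organism name on whitespace or a folder name on
#'   underscores).
#' @return A list with elements `genus` and `species`, each a string or
#'   `NA_character_` when absent.
#' @examples
#' extract_genus_species(c("Candidatus", "Endolissoclinum", "faulkneri", "L2"))
#' extract_genus_species(c("Synechocystis", "sp.", "PCC", "6803"))
#' @export
extract_genus_species <- function(tokens) {
  tokens <- tokens[!is.na(tokens) & nzchar(tokens)]
  skip <- function(tok) {
    grepl("^candidatus$", tok, ignore.case = TRUE) ||
      grepl("^['\"\\[\\(]", tok)
  }
  while (length(tokens) > 0 && skip(tokens[1])) tokens <- tokens[-1]
  if (length(tokens) == 0) {
    return(list(genus = NA_character_, species = NA_character_))
  }
  genus <- norm_taxon(tokens[1])
  species <- NA_character_
  if (length(tokens) >= 2) {
    cand <- tokens[2]
    placeholder <- tolower(cand) %in% c("sp.", "sp", "genomosp.", "genomosp")
    if (!placeholder && grepl("^[a-z][A-Za-z]*$", cand)) {
      species <- norm_taxon(cand)
    }
  }
  if (!is.na(genus) && !nzchar(genus)) genus <- NA_character_
  list(genus = genus, species = species)
}

# comparison form for a single taxon token: lowercase, punctuation stripped
norm_taxon <- function(x) {
  out <- tolower(x)
  out <- gsub("[^a-z0-9]+", "", out)
  out[!nzchar(out)] <- NA_character_
  out
}

# comparison form for a whole organism name: lowercase alphanumeric tokens
# joined by single spaces (used for the report's by-name index)
norm_name <- function(x) {
  out <- tolower(enc2utf8(x))
  out <- gsub("[^a-z0-9]+", " ", out)
  out <- trimws(gsub(" +", " ", out))
  out[is.na(out) | !nzchar(out)] <- NA_character_
  out
}

# drop a trailing ".N" version suffix from accession strings
strip_version <- function(accession) {
  sub("\\.[0-9]+$", "", accession)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
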