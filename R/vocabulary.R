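#' Normalize a drug-name key
#'
#' Lower-cases, trims surrounding whitespace and punctuation, and collapses
#' internal whitespace runs. Used both when loading the synonym dictionary
#' and when looking up verbatim names, so matching is case- and
#' punctuation-insensitive at the edges.
#'
#' @param x Character vector of names.
#' @return Character vector of normalized keys.
#' @examples
#' normalize_name_key(" Spironolactone. ")
#' @export
normalize_name_key <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("^[[:space:][:punct:]]+|[[:space:][:punct:]]+$", "", x)
  gsub("[[:space:]]+", " ", x)
}

#' Load the drug-synonym dictionary and PT-to-SOC map
#'
#' Reads two delimited text files: a drug dictionary with columns
#' `synonym`, `ingredient` (many synonyms to one canonical active
#' ingredient) and an event vocabulary with columns `pt`, `soc` (each
#' preferred term maps to exactly one primary system organ class). Synonym
#' keys are normalized with [normalize_name_key()]; a synonym resolving to
#' two different ingredients, or a PT listed under two SOCs, is a
#' configuration error.
#'
#' @param drug_file Path to the synonym dictionary.
#' @param meddra_file Path to the PT/SOC table.
#' @param sep Field separator of both files (default tab).
#' @return An object of class `vocabulary_map`: a list with named character
#'   vectors `drug_synonyms` (normalized synonym -> ingredient) and
#'   `pt_to_soc`, plus `soc_names`.
#' @export
load_vocabulary <- function(drug_file, meddra_file, sep = "\t") {
  for (f in c(drug_file, meddra_file)) {
    if (!file.exists(f)) stop("vocabulary file not found: ", f, call. = FALSE)
  }
  syn <- data.table::fread(drug_file, sep = sep, colClasses = "character")
  ptm <- data.table::fread(meddra_file, sep = sep, colClasses = "character")
  if (!all(c("synonym", "ingredient") %in% names(syn))) {
    stop("drug dictionary must have columns 'synonym' and 'ingredient'",
         call. = FALSE)
  }
  if (!all(c("pt", "soc") %in% names(ptm))) {
    stop("PT/SOC table must have columns 'pt' and 'soc'", call. = FALSE)
  }
  if (nrow(syn) == 0L) stop("drug dictionary is empty", call. = FALSE)
  key <- normalize_name_key(syn$synonym)
  conf <- stats::aggregate(syn$ingredient, list(key = key),
                           function(v) length(unique(v)))
  bad <- conf$key[conf$x > 1L]
  if (length(bad)) {
    rows <- which(key %in% bad)
    stop("conflicting dictionary entries for synonym(s) ",
         paste(unique(bad), collapse = ", "),
         " (rows ", paste(rows, collapse = ", "), ")", call. = FALSE)
  }
  keep <- !duplicated(key)
  drug_synonyms <- stats::setNames(syn$ingredient[keep], key[keep])

  pconf <- stats::aggregate(ptm$soc, list(pt = ptm$pt),
                            function(v) length(unique(v)))
  pbad <- pconf$pt[pconf$x > 1L]
  if (length(pbad)) {
    stop("PT mapped to more than one SOC: ",
         paste(pbad, collapse = ", "), call. = FALSE)
  }
  pkeep <- !duplicated(ptm$pt)
  pt_to_soc <- stats::setNames(ptm$soc[pkeep], ptm$pt[pkeep])
  structure(list(drug_synonyms = drug_synonyms,
                 pt_to_soc = pt_to_soc,
                 soc_names = sort(unique(unname(pt_to_soc)))),
            class = "vocabulary_map")
}

#' Primary system organ class of a preferred term
#'
#' Total and deterministic: a PT absent from the vocabulary returns the
#' sentinel `"unmapped"` rather than raising, so unmapped terms can be
#' counted and reported downstream.
#'
#' @param pt Character vector of preferred terms.
#' @param vocab A `vocabulary_map` from [load_vocabulary()].
#' @return Character vector of SOC names (or `"unmapped"`).
#' @export
soc_of <- function(pt, vocab) {
  stopifnot(inherits(vocab, "vocabulary_map"))
  out <- unname(vocab$pt_to_soc[as.character(pt)])
  out[is.na(out)] <- "unmapped"
  out
}
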