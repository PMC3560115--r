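## Ontology catalogs for attribute-name suggestion.
##
## Only the [Term] stanzas' `id:` and `name:` lines of an OBO flat file are
## consumed: the engine needs controlled labels, not the ontology graph.

#' Load an ontology catalog from an OBO flat file
#'
#' @param path path to an OBO file.
#' @param ontology_id short identifier recorded on every term (e.g. `"OBI"`);
#'   defaults to the prefix of the first term id.
#' @return an object of class `xr_ontology`: a tibble of terms
#'   (`ontology_id`, `term_id`, `label`) plus the id.
#' @export
read_obo <- function(path, ontology_id = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  terms <- list()
  in_term <- FALSE
  cur_id <- NA_character_
  cur_name <- NA_character_
  flush <- function() {
    if (in_term && !is.na(cur_id) && !is.na(cur_name)) {
      terms[[length(terms) + 1L]] <<- c(id = cur_id, name = cur_name)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "[")) {
      flush()
      in_term <- identical(ln, "[Term]")
      cur_id <- NA_character_
      cur_name <- NA_character_
    } else if (in_term && startsWith(ln, "id:")) {
      cur_id <- trimws(sub("^id:", "", ln))
    } else if (in_term && startsWith(ln, "name:")) {
      cur_name <- trimws(sub("^name:", "", ln))
    }
  }
  flush()
  tab <- if (length(terms)) {
    tibble(
      term_id = vapply(terms, `[[`, character(1), "id"),
      label = vapply(terms, `[[`, character(1), "name")
    )
  } else {
    tibble(term_id = character(), label = character())
  }
  ontology_id <- ontology_id %||%
    (if (nrow(tab)) sub(":.*$", "", tab$term_id[1]) else "UNKNOWN")
  tab <- dplyr::mutate(tab, ontology_id = ontology_id, .before = 1)
  structure(list(ontology_id = ontology_id, terms = tab), class = "xr_ontology")
}

#' Suggest ontology terms for an attribute-name prefix
#'
#' Implements the suggest-as-you-type mechanism for attribute naming: terms
#' whose label starts with the typed prefix (case-insensitive), ordered
#' lexicographically by label, capped at `limit`.
#'
#' @param prefix typed text, length >= 1 character.
#' @param ontology an `xr_ontology` from [read_obo()], or `NULL`.
#' @param limit maximum number of suggestions.
#' @return a tibble of matching terms (`ontology_id`, `term_id`, `label`);
#'   empty when no ontology is loaded.
#' @export
suggest_terms <- function(prefix, ontology, limit = 20L) {
  empty <- tibble(ontology_id = character(), term_id = character(),
                  label = character())
  if (is.null(ontology)) {
    return(empty)
  }
  stopifnot(inherits(ontology, "xr_ontology"), nzchar(prefix))
  hits <- ontology$terms[
    startsWith(tolower(ontology$terms$label), tolower(prefix)), ,
    drop = FALSE
  ]
  hits <- hits[order(hits$label, method = "radix"), , drop = FALSE]
  head(hits, limit)
}
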