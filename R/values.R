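## Value kinds and canonical text encodings.
##
## Every attribute value in the engine has one of six kinds. Values travel
## through three representations (typed R scalar, XML text node, EAV row) and
## the canonical text encoding is the single injective bridge between them:
## whatever can be written can be parsed back to the identical typed value,
## which is what makes the dual XML/EAV representation checkable.

VALUE_KINDS <- c("text", "integer", "decimal", "date", "boolean", "enumeration")

xr_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "xr_error"), ...)
}

is_scalar <- function(x) length(x) == 1L && !is.list(x)

#' Canonically encode a typed value
#'
#' Produces the canonical text encoding used in XML documents and EAV rows:
#' integers in base 10, decimals normalized (no trailing zeros, no leading
#' `+`), dates as ISO-8601 `YYYY-MM-DD`, booleans as `"true"`/`"false"`,
#' text and enumeration labels verbatim. The encoding is injective per kind:
#' [decode_value()] recovers the identical typed value.
#'
#' @param value a single value (character, numeric, integer, logical or Date).
#' @param kind one of `"text"`, `"integer"`, `"decimal"`, `"date"`,
#'   `"boolean"`, `"enumeration"`.
#' @return a length-1 character vector, or `NA_character_` with attribute
#'   `reason` when the value does not satisfy the kind.
#' @export
encode_value <- function(value, kind) {
  stopifnot(kind %in% VALUE_KINDS)
  if (!is_scalar(value) || is.na(value)[1]) {
    return(bad_value("missing or non-scalar value"))
  }
  switch(kind,
    text = ,
    enumeration = as.character(value),
    integer = encode_integer(value),
    decimal = encode_decimal(value),
    date = encode_date(value),
    boolean = encode_boolean(value)
  )
}

bad_value <- function(reason) {
  structure(NA_character_, reason = reason)
}

encode_integer <- function(value) {
  if (is.character(value)) {
    if (!grepl("^[+-]?[0-9]+$", trimws(value))) {
      return(bad_value("not an integer"))
    }
    value <- suppressWarnings(as.numeric(trimws(value)))
  }
  if (!is.numeric(value) || is.na(value) || value != trunc(value)) {
    return(bad_value("not an integer"))
  }
  format(value, scientific = FALSE, trim = TRUE)
}

encode_decimal <- function(value) {
  if (is.character(value)) {
    v <- trimws(value)
    if (!grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", v)) {
      return(bad_value("not a decimal number"))
    }
    return(normalize_decimal(v))
  }
  if (!is.numeric(value) || is.na(value) || !is.finite(value)) {
    return(bad_value("not a decimal number"))
  }
  normalize_decimal(format(value, scientific = FALSE, trim = TRUE, digits = 15))
}

# strip sign-noise, leading and trailing zeros: "+01.50" -> "1.5", "3.0" -> "3"
normalize_decimal <- function(v) {
  neg <- grepl("^-", v)
  v <- sub("^[+-]", "", v)
  parts <- strsplit(v, ".", fixed = TRUE)[[1]]
  int <- sub("^0+(?=[0-9])", "", parts[1], perl = TRUE)
  frac <- if (length(parts) > 1) sub("0+$", "", parts[2]) else ""
  out <- if (nzchar(frac)) paste0(int, ".", frac) else int
  if (out == "0" || out == "") neg <- FALSE
  if (out == "") out <- "0"
  paste0(if (neg) "-" else "", out)
}

encode_date <- function(value) {
  if (inherits(value, "Date")) {
    return(format(value, "%Y-%m-%d"))
  }
  if (is.character(value) && grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", value)) {
    parsed <- tryCatch(as.Date(value), error = function(e) NA)
    if (!is.na(parsed)) {
      return(value)
    }
  }
  bad_value("not an ISO-8601 date")
}

encode_boolean <- function(value) {
  if (is.logical(value)) {
    return(if (value) "true" else "false")
  }
  if (is.character(value) && value %in% c("true", "false")) {
    return(value)
  }
  bad_value("not a boolean")
}

#' Decode a canonical text encoding back to a typed value
#'
#' @param text length-1 character in canonical encoding.
#' @param kind the value kind the text was encoded under.
#' @return the typed R scalar (character, integer-valued numeric, numeric,
#'   `Date`, or logical).
#' @export
decode_value <- function(text, kind) {
  stopifnot(kind %in% VALUE_KINDS, is.character(text), length(text) == 1L)
  switch(kind,
    text = ,
    enumeration = text,
    integer = as.integer(text),
    decimal = as.numeric(text),
    date = as.Date(text),
    boolean = identical(text, "true")
  )
}
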