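## Dynamic queries.
##
## A query is a conjunction of subject conditions (diagnosis, sex, birth
## date) and data conditions (per-datatype field or existence tests). Every
## data condition is independently existential over the subject's instances:
## a subject matches when at least one instance (and, for loop attributes, at
## least one iteration) satisfies it. Composition validates paths and
## operators against the stored schemas, so a composed query always executes.

SUBJECT_FIELDS <- c("diagnosis", "sex", "birth_date")
SUBJECT_OPERATORS <- list(
  diagnosis = c("eq", "ne", "contains"),
  sex = c("eq", "ne"),
  birth_date = c("eq", "ne", "lt", "le", "gt", "ge")
)
OPERATORS_BY_KIND <- list(
  text = c("eq", "ne", "contains", "in"),
  enumeration = c("eq", "ne", "in"),
  integer = c("eq", "ne", "lt", "le", "gt", "ge", "in"),
  decimal = c("eq", "ne", "lt", "le", "gt", "ge", "in"),
  date = c("eq", "ne", "lt", "le", "gt", "ge"),
  boolean = c("eq", "ne")
)

#' Build a subject condition
#'
#' @param field `"diagnosis"`, `"sex"` or `"birth_date"`.
#' @param operator comparison operator; ordering operators (`lt`, `le`, `gt`,
#'   `ge`) apply to `birth_date` only.
#' @param value comparison value.
#' @return an `xr_subject_condition`.
#' @export
subject_condition <- function(field, operator, value) {
  if (!field %in% SUBJECT_FIELDS) {
    xr_abort(paste0("unknown subject field '", field, "'"), "xr_composition_error")
  }
  if (!operator %in% SUBJECT_OPERATORS[[field]]) {
    xr_abort(
      paste0("operator '", operator, "' is not valid for subject field '",
             field, "'"),
      "xr_composition_error"
    )
  }
  if (field == "birth_date") {
    value <- encode_date(value)
    if (is.na(value)) {
      xr_abort("birth_date conditions need an ISO-8601 date value",
               "xr_composition_error")
    }
  }
  structure(list(field = field, operator = operator, value = value),
            class = "xr_subject_condition")
}

#' Build a data condition
#'
#' `mode = "exists"` asks for at least one instance of the data type;
#' `mode = "field"` compares one attribute (identified by its
#' `"group.attribute"` or `"group.loop.attribute"` path) against a value.
#'
#' @param datatype data type name.
#' @param path attribute path string (field mode only).
#' @param operator comparison operator (field mode only); valid operators
#'   depend on the attribute's value kind.
#' @param value comparison value; for `"in"` a vector.
#' @return an `xr_data_condition`.
#' @export
data_condition <- function(datatype, path = NULL, operator = NULL, value = NULL) {
  mode <- if (is.null(path)) "exists" else "field"
  if (mode == "exists" && (!is.null(operator) || !is.null(value))) {
    xr_abort("existence conditions carry no operator or value", "xr_composition_error")
  }
  structure(
    list(datatype = datatype, mode = mode, path = path, operator = operator,
         value = value),
    class = "xr_data_condition"
  )
}

#' Compose a validated query
#'
#' Every condition is checked against the store's schemas at composition
#' time: unknown data types or paths and operator/kind mismatches are
#' rejected here, never at execution time. Conditions combine as a
#' conjunction; an empty specification matches all subjects.
#'
#' @param store a store handle.
#' @param subject_conditions list of [subject_condition()] objects.
#' @param data_conditions list of [data_condition()] objects.
#' @return an `xr_query` specification.
#' @export
compose_query <- function(store, subject_conditions = list(),
                          data_conditions = list()) {
  for (sc in subject_conditions) {
    if (!inherits(sc, "xr_subject_condition")) {
      xr_abort("subject_conditions must be built with subject_condition()",
               "xr_composition_error")
    }
  }
  data_conditions <- lapply(data_conditions, function(dc) {
    if (!inherits(dc, "xr_data_condition")) {
      xr_abort("data_conditions must be built with data_condition()",
               "xr_composition_error")
    }
    schema <- tryCatch(
      load_schema(store, dc$datatype),
      xr_not_found_error = function(e) {
        xr_abort(paste0("unknown data type '", dc$datatype, "' in condition"),
                 "xr_composition_error")
      }
    )
    dc$datatype <- schema$header$datatype_name
    if (dc$mode == "field") {
      p <- parse_path_string(dc$path)
      a <- schema_find_attribute(schema, p$group, p$attribute, loop = p$loop)
      if (is.null(a)) {
        xr_abort(
          paste0("no attribute at path '", dc$path, "' in data type '",
                 dc$datatype, "'"),
          "xr_composition_error"
        )
      }
      if (is.null(dc$operator) || !dc$operator %in% OPERATORS_BY_KIND[[a$kind]]) {
        xr_abort(
          paste0("operator '", dc$operator %||% "<none>", "' is not valid for ",
                 a$kind, " attribute '", dc$path, "'"),
          "xr_composition_error"
        )
      }
      vals <- if (identical(dc$operator, "in")) dc$value else dc$value[1]
      enc <- vapply(vals, function(v) as.character(encode_value(v, a$kind)),
                    character(1))
      if (anyNA(enc)) {
        xr_abort(
          paste0("condition value for '", dc$path, "' does not satisfy kind ",
                 a$kind),
          "xr_composition_error"
        )
      }
      dc$kind <- a$kind
      dc$encoded <- unname(enc)
      norm <- parse_path_string(dc$path)
      dc$group <- norm$group
      dc$loop <- norm$loop
      dc$attribute <- norm$attribute
    }
    dc
  })
  structure(
    list(subject_conditions = subject_conditions,
         data_conditions = data_conditions),
    class = "xr_query"
  )
}

compare_encoded <- function(values, operator, targets, kind) {
  num <- function(x) suppressWarnings(as.numeric(x))
  lhs <- values
  rhs <- targets[1]
  ord_lhs <- switch(kind,
    integer = ,
    decimal = num(lhs),
    lhs
  )
  ord_rhs <- switch(kind,
    integer = ,
    decimal = num(rhs),
    rhs
  )
  switch(operator,
    eq = if (kind %in% c("text", "enumeration")) {
      tolower(lhs) == tolower(rhs)
    } else if (kind %in% c("integer", "decimal")) {
      ord_lhs == ord_rhs
    } else {
      lhs == rhs
    },
    ne = if (kind %in% c("text", "enumeration")) {
      tolower(lhs) != tolower(rhs)
    } else if (kind %in% c("integer", "decimal")) {
      ord_lhs != ord_rhs
    } else {
      lhs != rhs
    },
    lt = ord_lhs < ord_rhs,
    le = ord_lhs <= ord_rhs,
    gt = ord_lhs > ord_rhs,
    ge = ord_lhs >= ord_rhs,
    contains = grepl(tolower(rhs), tolower(lhs), fixed = TRUE),
    `in` = tolower(lhs) %in% tolower(targets),
    xr_abort(paste0("unknown operator '", operator, "'"), "xr_usage_error")
  )
}

#' Execute a composed query
#'
#' A subject is returned iff it satisfies every subject condition and, for
#' each data condition, owns at least one data instance satisfying it (for
#' loop attributes: some iteration matches). Results are sorted by subject
#' id and deterministic.
#'
#' @param store a store handle.
#' @param spec an `xr_query` from [compose_query()].
#' @return a character vector of subject ids.
#' @export
execute_query <- function(store, spec) {
  stopifnot(inherits(spec, "xr_query"))
  tabs <- store$tables
  ids <- tabs$subjects$subject_id
  for (sc in spec$subject_conditions) {
    col <- tabs$subjects[[sc$field]]
    kind <- if (sc$field == "birth_date") "date" else "text"
    keep <- compare_encoded(col, sc$operator, sc$value, kind)
    keep[is.na(keep)] <- FALSE
    ids <- intersect(ids, tabs$subjects$subject_id[keep])
  }
  for (dc in spec$data_conditions) {
    inst <- tabs$instances[tolower(tabs$instances$datatype) ==
      tolower(dc$datatype), , drop = FALSE]
    if (dc$mode == "exists") {
      ids <- intersect(ids, unique(inst$subject_id))
      next
    }
    rows <- tabs$eav[tabs$eav$instance_id %in% inst$instance_id &
      tolower(tabs$eav$grp) == tolower(dc$group) &
      tolower(tabs$eav$attribute) == tolower(dc$attribute), , drop = FALSE]
    rows <- if (is.na(dc$loop)) {
      rows[is.na(rows$loop), , drop = FALSE]
    } else {
      rows[!is.na(rows$loop) & tolower(rows$loop) == tolower(dc$loop), ,
           drop = FALSE]
    }
    keep <- compare_encoded(rows$value, dc$operator, dc$encoded, dc$kind)
    keep[is.na(keep)] <- FALSE
    matching_instances <- unique(rows$instance_id[keep])
    subj <- unique(inst$subject_id[inst$instance_id %in% matching_instances])
    ids <- intersect(ids, subj)
  }
  sort(unique(ids), method = "radix")
}

#' List the queryable attribute paths of a data type
#'
#' This is the auto-fill behind condition building: choosing a data type
#' enumerates its field parameters from the latest schema version.
#'
#' @param store a store handle.
#' @param datatype_name the data type.
#' @return a tibble of paths (see [schema_paths()]), stable order.
#' @export
list_fields <- function(store, datatype_name) {
  schema <- load_schema(store, datatype_name)
  schema_paths(schema)
}

## ---- integrated subject overview -------------------------------------------

#' Integrated overview of one subject
#'
#' All of a subject's data instances grouped by data type — each with its
#' metadata values and file URIs — plus the subject's process/event timeline.
#' When `user` is given, access control applies: data types the user may not
#' view are omitted and personal fields are masked unless the user holds the
#' personal-data permission.
#'
#' @param store a store handle.
#' @param subject_id the subject.
#' @param user optional user id for permission filtering.
#' @return an `xr_overview`: list with `subject` (one-row tibble), `sections`
#'   (named list, one tibble of EAV values per data type), `files`
#'   (tibble), `timeline` (tibble of events).
#' @export
subject_overview <- function(store, subject_id, user = NULL) {
  tabs <- store$tables
  if (!subject_id %in% tabs$subjects$subject_id) {
    xr_abort(paste0("no subject '", subject_id, "'"), "xr_not_found_error")
  }
  subj_row <- if (is.null(user)) {
    as_tibble(tabs$subjects[tabs$subjects$subject_id == subject_id, ,
                            drop = FALSE])
  } else {
    masked_view(store, user, subject_id)
  }
  inst <- tabs$instances[tabs$instances$subject_id == subject_id, , drop = FALSE]
  if (!is.null(user)) {
    visible <- vapply(unique(inst$datatype), function(dt) {
      check_access(store, user, paste0("datatype:", dt), "view")
    }, logical(1))
    inst <- inst[inst$datatype %in% names(visible)[visible], , drop = FALSE]
  }
  sections <- list()
  for (dt in sort(unique(inst$datatype), method = "radix")) {
    iids <- inst$instance_id[inst$datatype == dt]
    rows <- tabs$eav[tabs$eav$instance_id %in% iids, , drop = FALSE]
    sections[[dt]] <- as_tibble(rows)
  }
  files <- tabs$files[tabs$files$instance_id %in% inst$instance_id, , drop = FALSE]
  roots <- tabs$processes[
    !is.na(tabs$processes$subject_id) &
      tabs$processes$subject_id == subject_id & is.na(tabs$processes$parent_id),
    , drop = FALSE
  ]
  tl <- if (nrow(roots)) {
    bind_rows(lapply(roots$process_id, function(p) timeline(store, p)))
  } else {
    timeline_prototype()
  }
  structure(
    list(subject = subj_row, sections = sections, files = as_tibble(files),
         timeline = tl),
    class = "xr_overview"
  )
}

timeline_prototype <- function() {
  tibble(event_id = character(), type = character(), process_id = character(),
         occurred_at = character(), note = character(), depth = integer())
}

#' @export
print.xr_overview <- function(x, ...) {
  cat(format_overview_text(x), sep = "\n")
  invisible(x)
}

#' Render an overview as plain text
#'
#' @param overview an `xr_overview`.
#' @return character vector of lines.
#' @export
format_overview_text <- function(overview) {
  s <- overview$subject
  lines <- c(
    paste0("subject ", s$subject_id, "  sex=", s$sex, "  birth_date=",
           s$birth_date, "  diagnosis=", s$diagnosis),
    paste0(length(overview$sections), " data section(s)")
  )
  for (dt in names(overview$sections)) {
    sec <- overview$sections[[dt]]
    lines <- c(lines, paste0("== ", dt, " (",
                             length(unique(sec$instance_id)), " instance(s))"))
    for (iid in unique(sec$instance_id)) {
      rows <- sec[sec$instance_id == iid, , drop = FALSE]
      lines <- c(lines, paste0("  -- ", iid))
      for (i in seq_len(nrow(rows))) {
        lines <- c(lines, paste0(
          "     ", rows$grp[i],
          ifelse(is.na(rows$loop[i]), "",
                 paste0(".", rows$loop[i], "[", rows$iteration[i] + 1L, "]")),
          ".", rows$attribute[i], " = ", rows$value[i]
        ))
      }
      furis <- overview$files$uri[overview$files$instance_id == iid]
      for (u in furis) lines <- c(lines, paste0("     file: ", u))
    }
  }
  if (nrow(overview$timeline)) {
    lines <- c(lines, "== timeline")
    for (i in seq_len(nrow(overview$timeline))) {
      ev <- overview$timeline[i, ]
      lines <- c(lines, paste0("  ", ev$occurred_at %|NA|% "(undated)", "  [",
                               ev$type, "] ", ev$event_id))
    }
  }
  lines
}

#' Render an overview as a minimal HTML document
#'
#' @param overview an `xr_overview`.
#' @return length-1 character of HTML.
#' @export
format_overview_html <- function(overview) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  body <- paste0("<li>", esc(format_overview_text(overview)), "</li>",
                 collapse = "\n")
  paste0("<!DOCTYPE html>\n<html><body><ul>\n", body, "\n</ul></body></html>\n")
}
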