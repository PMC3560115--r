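## The "meta" data model: data types are defined at runtime as a header plus
## ordered groups, each group holding typed attributes and repeatable loops.
## Nothing here touches storage; a schema is a plain validated S3 object.

#' Reference to an ontology term
#'
#' Attribute names can be annotated with a term drawn from an OBO ontology
#' (e.g. OBI, SO), so that runtime-defined data types carry standard
#' annotations.
#'
#' @param ontology_id short ontology identifier, e.g. `"OBI"`.
#' @param term_id the term accession, e.g. `"OBI:0000070"`.
#' @param label the human-readable term name.
#' @return an object of class `xr_ontology_ref`.
#' @export
ontology_ref <- function(ontology_id, term_id, label) {
  if (!nzchar(term_id) || !nzchar(label)) {
    xr_abort("ontology term_id and label must be non-empty", "xr_structural_error")
  }
  structure(
    list(ontology_id = ontology_id, term_id = term_id, label = label),
    class = "xr_ontology_ref"
  )
}

#' Define an attribute of a data type
#'
#' An attribute is a single piece of metadata: a name, a value kind, whether
#' it is required, and (for enumerations) the set of allowed values.
#'
#' @param name attribute name; unique (case-insensitively) within its group
#'   or loop.
#' @param kind one of `"text"`, `"integer"`, `"decimal"`, `"date"`,
#'   `"boolean"`, `"enumeration"`.
#' @param required is a value mandatory in every instance?
#' @param allowed_values character vector of permitted values
#'   (enumeration kind only).
#' @param unit optional unit of measure, display-only.
#' @param ontology optional [ontology_ref()] annotating the attribute name.
#' @param default optional default value, must satisfy `kind` and
#'   `allowed_values`.
#' @return an object of class `xr_attribute`.
#' @export
attribute_def <- function(name, kind, required = FALSE, allowed_values = NULL,
                          unit = NULL, ontology = NULL, default = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    xr_abort("attribute name must be non-empty", "xr_structural_error")
  }
  if (!kind %in% VALUE_KINDS) {
    xr_abort(
      paste0("unknown value kind '", kind, "' for attribute '", name, "'"),
      "xr_structural_error"
    )
  }
  if (kind == "enumeration") {
    allowed_values <- unique(as.character(allowed_values))
    if (length(allowed_values) < 1L) {
      xr_abort(
        paste0("enumeration attribute '", name, "' needs at least one allowed value"),
        "xr_structural_error"
      )
    }
  } else if (!is.null(allowed_values)) {
    xr_abort(
      paste0("allowed_values only applies to enumeration attributes ('", name, "')"),
      "xr_structural_error"
    )
  }
  if (!is.null(default)) {
    enc <- encode_value(default, kind)
    if (is.na(enc)) {
      xr_abort(
        paste0("default for '", name, "' does not satisfy kind ", kind, ": ",
               attr(enc, "reason")),
        "xr_structural_error"
      )
    }
    if (kind == "enumeration" && !enc %in% allowed_values) {
      xr_abort(
        paste0("default for '", name, "' is not among its allowed values"),
        "xr_structural_error"
      )
    }
    default <- enc
  }
  structure(
    list(
      name = name, kind = kind, required = isTRUE(required),
      allowed_values = allowed_values, unit = unit,
      ontology = ontology, default = default
    ),
    class = "xr_attribute"
  )
}

#' Define a loop (repeatable attribute block)
#'
#' A loop models information whose structure is known but whose multiplicity
#' is not: one reagent per iteration, one risk factor per iteration. Loops
#' hold attributes only — they do not nest.
#'
#' @param name loop name, sharing a namespace with sibling attributes.
#' @param attributes list of [attribute_def()] objects, at least one.
#' @return an object of class `xr_loop`.
#' @export
loop_def <- function(name, attributes) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    xr_abort("loop name must be non-empty", "xr_structural_error")
  }
  if (length(attributes) < 1L) {
    xr_abort(paste0("loop '", name, "' must contain at least one attribute"),
             "xr_structural_error")
  }
  ok <- vapply(attributes, inherits, logical(1), what = "xr_attribute")
  if (!all(ok)) {
    xr_abort(paste0("loop '", name, "' may only contain attributes (loops do not nest)"),
             "xr_structural_error")
  }
  check_unique_names(
    vapply(attributes, `[[`, character(1), "name"),
    where = paste0("loop '", name, "'")
  )
  structure(list(name = name, attributes = attributes), class = "xr_loop")
}

#' Define a metadata group
#'
#' @param name group name, unique within the schema.
#' @param members list of [attribute_def()] and/or [loop_def()] objects;
#'   attributes and loops share one (case-insensitive) namespace.
#' @return an object of class `xr_group`.
#' @export
metadata_group <- function(name, members) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    xr_abort("group name must be non-empty", "xr_structural_error")
  }
  if (length(members) < 1L) {
    xr_abort(paste0("group '", name, "' must have at least one member"),
             "xr_structural_error")
  }
  ok <- vapply(
    members, function(m) inherits(m, "xr_attribute") || inherits(m, "xr_loop"),
    logical(1)
  )
  if (!all(ok)) {
    xr_abort(paste0("group '", name, "' members must be attributes or loops"),
             "xr_structural_error")
  }
  check_unique_names(
    vapply(members, `[[`, character(1), "name"),
    where = paste0("group '", name, "'")
  )
  structure(list(name = name, members = members), class = "xr_group")
}

#' Schema header
#'
#' General information about a data type: its unique name, version,
#' description, whether instances carry physical files, and provenance.
#'
#' @param datatype_name data type name, unique (case-insensitively) in a store.
#' @param description free-text description.
#' @param file_associated do instances of this type reference physical files
#'   (e.g. MRI scans), or are they pure metadata (e.g. clinical evaluations)?
#' @param created_by author identifier.
#' @param created_at ISO-8601 timestamp; defaults to the current time.
#' @param version positive integer; [define_datatype()] forces 1.
#' @return an object of class `xr_header`.
#' @export
schema_header <- function(datatype_name, description = "",
                          file_associated = FALSE, created_by = "unknown",
                          created_at = NULL, version = 1L) {
  if (!is.character(datatype_name) || length(datatype_name) != 1L ||
    !nzchar(trimws(datatype_name))) {
    xr_abort("datatype_name must be non-empty", "xr_structural_error")
  }
  version <- as.integer(version)
  if (is.na(version) || version < 1L) {
    xr_abort("schema version must be a positive integer", "xr_structural_error")
  }
  created_at <- created_at %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  structure(
    list(
      datatype_name = datatype_name, version = version,
      description = description, file_associated = isTRUE(file_associated),
      created_by = created_by, created_at = created_at
    ),
    class = "xr_header"
  )
}

check_unique_names <- function(names, where) {
  folded <- tolower(names)
  dup <- names[duplicated(folded)]
  if (length(dup)) {
    xr_abort(
      paste0(
        "duplicate name (case-insensitive) in ", where, ": '",
        paste(unique(dup), collapse = "', '"), "'"
      ),
      "xr_structural_error"
    )
  }
  invisible(names)
}

#' Define a data type
#'
#' Validates the header and groups against all structural invariants and
#' returns a schema that is usable immediately — there is no rebuild or
#' redeploy step. The version is forced to 1; later versions come from
#' [evolve_datatype()].
#'
#' @param header a [schema_header()].
#' @param groups list of [metadata_group()] objects, at least one.
#' @return an object of class `xr_schema`.
#' @seealso [serialize_schema()], [parse_schema()], [schema_paths()]
#' @examples
#' mri <- define_datatype(
#'   schema_header("MRI", file_associated = TRUE),
#'   list(metadata_group("acquisition", list(
#'     attribute_def("field_strength", "decimal", unit = "T"),
#'     attribute_def("sequence", "text")
#'   )))
#' )
#' nrow(schema_paths(mri))
#' @export
define_datatype <- function(header, groups) {
  if (!inherits(header, "xr_header")) {
    xr_abort("header must be a schema_header()", "xr_structural_error")
  }
  if (length(groups) < 1L) {
    xr_abort("a data type needs at least one group", "xr_structural_error")
  }
  ok <- vapply(groups, inherits, logical(1), what = "xr_group")
  if (!all(ok)) {
    xr_abort("groups must be metadata_group() objects", "xr_structural_error")
  }
  check_unique_names(
    vapply(groups, `[[`, character(1), "name"),
    where = paste0("data type '", header$datatype_name, "'")
  )
  header$version <- 1L
  schema <- structure(list(header = header, groups = groups), class = "xr_schema")
  # full-path uniqueness across the schema (group, loop?, attribute)
  paths <- schema_paths(schema)
  key <- tolower(paste(paths$group, paths$loop %|NA|% "", paths$attribute, sep = "\r"))
  if (anyDuplicated(key)) {
    offending <- path_string(paths[duplicated(key), ][1, ])
    xr_abort(paste0("duplicate attribute path in schema: ", offending),
             "xr_structural_error")
  }
  schema
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Enumerate the attribute paths of a schema
#'
#' @param schema an `xr_schema`.
#' @return a tibble with columns `group`, `loop` (`NA` for plain attributes),
#'   `attribute`, `kind`, `required`, `path` (display string), in schema order.
#' @export
schema_paths <- function(schema) {
  stopifnot(inherits(schema, "xr_schema"))
  rows <- list()
  for (g in schema$groups) {
    for (m in g$members) {
      if (inherits(m, "xr_attribute")) {
        rows[[length(rows) + 1L]] <- tibble(
          group = g$name, loop = NA_character_, attribute = m$name,
          kind = m$kind, required = m$required
        )
      } else {
        for (a in m$attributes) {
          rows[[length(rows) + 1L]] <- tibble(
            group = g$name, loop = m$name, attribute = a$name,
            kind = a$kind, required = a$required
          )
        }
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(group = character(), loop = character(), attribute = character(),
           kind = character(), required = logical())
  }
  out$path <- path_string(out)
  out
}

path_string <- function(paths) {
  ifelse(
    is.na(paths$loop),
    paste(paths$group, paths$attribute, sep = "."),
    paste(paths$group, paths$loop, paths$attribute, sep = ".")
  )
}

# locate an attribute definition; returns NULL when absent
schema_find_attribute <- function(schema, group, attribute, loop = NA) {
  for (g in schema$groups) {
    if (tolower(g$name) != tolower(group)) next
    for (m in g$members) {
      if (is.na(loop) || is.null(loop)) {
        if (inherits(m, "xr_attribute") &&
          tolower(m$name) == tolower(attribute)) {
          return(m)
        }
      } else if (inherits(m, "xr_loop") && tolower(m$name) == tolower(loop)) {
        for (a in m$attributes) {
          if (tolower(a$name) == tolower(attribute)) return(a)
        }
      }
    }
  }
  NULL
}

schema_find_loop <- function(schema, group, loop) {
  for (g in schema$groups) {
    if (tolower(g$name) != tolower(group)) next
    for (m in g$members) {
      if (inherits(m, "xr_loop") && tolower(m$name) == tolower(loop)) return(m)
    }
  }
  NULL
}

#' @export
print.xr_schema <- function(x, ...) {
  h <- x$header
  cat(sprintf(
    "<data type '%s' v%d%s>\n", h$datatype_name, h$version,
    if (h$file_associated) ", file-associated" else ""
  ))
  p <- schema_paths(x)
  for (i in seq_len(nrow(p))) {
    cat(sprintf(
      "  %s%s : %s%s\n", p$path[i], if (!is.na(p$loop[i])) " [loop]" else "",
      p$kind[i], if (p$required[i]) " (required)" else ""
    ))
  }
  invisible(x)
}

## ---- schema evolution -------------------------------------------------------

#' Describe a schema change
#'
#' Change descriptors consumed by [evolve_datatype()]. Additive changes keep
#' existing instances valid; destructive ones are only applied when the store
#' holds no instances of the type.
#'
#' @param group,loop,path,value,attribute,loop_def,group_def change targets;
#'   `path` is a `"group.attribute"` or `"group.loop.attribute"` string.
#' @return a change descriptor (class `xr_change`).
#' @name schema-changes
NULL

xr_change <- function(op, ...) {
  structure(list(op = op, ...), class = "xr_change")
}

#' @rdname schema-changes
#' @export
change_add_attribute <- function(group, attribute, loop = NULL) {
  stopifnot(inherits(attribute, "xr_attribute"))
  xr_change("add_attribute", group = group, loop = loop, attribute = attribute)
}

#' @rdname schema-changes
#' @export
change_add_loop <- function(group, loop_def) {
  stopifnot(inherits(loop_def, "xr_loop"))
  xr_change("add_loop", group = group, loop_def = loop_def)
}

#' @rdname schema-changes
#' @export
change_add_group <- function(group_def) {
  stopifnot(inherits(group_def, "xr_group"))
  xr_change("add_group", group_def = group_def)
}

#' @rdname schema-changes
#' @export
change_add_enum_value <- function(path, value) {
  xr_change("add_enum_value", path = path, value = value)
}

#' @rdname schema-changes
#' @export
change_relax_required <- function(path) {
  xr_change("relax_required", path = path)
}

#' @rdname schema-changes
#' @export
change_remove_attribute <- function(path) {
  xr_change("remove_attribute", path = path)
}

ADDITIVE_OPS <- c("add_attribute", "add_loop", "add_group", "add_enum_value",
                  "relax_required")

#' Evolve a data type without rebuilding the store
#'
#' Applies a list of schema changes and returns a new schema with the version
#' incremented by one. Additive changes are always safe: added attributes must
#' be optional or carry a default, so every instance recorded under the old
#' version remains valid under the new one. Destructive changes (removing a
#' path, tightening required) are rejected whenever the store already holds
#' instances of the type.
#'
#' @param schema the current `xr_schema`.
#' @param changes list of change descriptors (see [schema-changes]).
#' @param store optional store handle; when given, instance existence is
#'   checked and the evolved schema is saved as the new latest version.
#' @return the evolved `xr_schema` (version + 1), or `schema` unchanged when
#'   `changes` is empty.
#' @export
evolve_datatype <- function(schema, changes, store = NULL) {
  stopifnot(inherits(schema, "xr_schema"))
  if (length(changes) == 0L) {
    return(schema)
  }
  has_instances <- FALSE
  if (!is.null(store)) {
    has_instances <- nrow(dplyr::filter(
      store$tables$instances,
      tolower(.data$datatype) == tolower(schema$header$datatype_name)
    )) > 0L
  }
  for (ch in changes) {
    if (!inherits(ch, "xr_change")) {
      xr_abort("changes must be built with the change_*() helpers", "xr_evolution_error")
    }
    if (!ch$op %in% ADDITIVE_OPS && has_instances) {
      xr_abort(
        paste0("destructive change '", ch$op,
               "' rejected: store holds instances of '",
               schema$header$datatype_name, "'"),
        "xr_evolution_error"
      )
    }
    schema <- apply_change(schema, ch)
  }
  schema$header$version <- schema$header$version + 1L
  # re-run full structural validation on the result
  evolved <- define_datatype(schema$header, schema$groups)
  evolved$header$version <- schema$header$version
  if (!is.null(store)) save_schema(store, evolved)
  evolved
}

apply_change <- function(schema, ch) {
  switch(ch$op,
    add_attribute = {
      a <- ch$attribute
      if (a$required && is.null(a$default)) {
        xr_abort(
          paste0("added attribute '", a$name,
                 "' is required but has no default; existing instances would break"),
          "xr_evolution_error"
        )
      }
      gi <- group_index(schema, ch$group)
      if (is.null(ch$loop)) {
        schema$groups[[gi]]$members <-
          c(schema$groups[[gi]]$members, list(a))
      } else {
        found <- FALSE
        for (mi in seq_along(schema$groups[[gi]]$members)) {
          m <- schema$groups[[gi]]$members[[mi]]
          if (inherits(m, "xr_loop") && tolower(m$name) == tolower(ch$loop)) {
            m$attributes <- c(m$attributes, list(a))
            schema$groups[[gi]]$members[[mi]] <- m
            found <- TRUE
          }
        }
        if (!found) {
          xr_abort(paste0("no loop '", ch$loop, "' in group '", ch$group, "'"),
                   "xr_evolution_error")
        }
      }
      schema
    },
    add_loop = {
      for (a in ch$loop_def$attributes) {
        if (a$required && is.null(a$default)) {
          # iterations of pre-existing instances have zero rows of this loop,
          # which stays valid; required applies within each new iteration only
          break
        }
      }
      gi <- group_index(schema, ch$group)
      schema$groups[[gi]]$members <-
        c(schema$groups[[gi]]$members, list(ch$loop_def))
      schema
    },
    add_group = {
      schema$groups <- c(schema$groups, list(ch$group_def))
      schema
    },
    add_enum_value = {
      modify_attribute(schema, ch$path, function(a) {
        if (a$kind != "enumeration") {
          xr_abort(paste0("'", ch$path, "' is not an enumeration"), "xr_evolution_error")
        }
        a$allowed_values <- unique(c(a$allowed_values, ch$value))
        a
      })
    },
    relax_required = {
      modify_attribute(schema, ch$path, function(a) {
        a$required <- FALSE
        a
      })
    },
    remove_attribute = {
      remove_attribute_at(schema, ch$path)
    },
    xr_abort(paste0("unknown change op '", ch$op, "'"), "xr_evolution_error")
  )
}

group_index <- function(schema, group) {
  for (i in seq_along(schema$groups)) {
    if (tolower(schema$groups[[i]]$name) == tolower(group)) {
      return(i)
    }
  }
  xr_abort(paste0("no group '", group, "' in data type '",
                  schema$header$datatype_name, "'"), "xr_evolution_error")
}

parse_path_string <- function(path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2L) {
    list(group = parts[1], loop = NA_character_, attribute = parts[2])
  } else if (length(parts) == 3L) {
    list(group = parts[1], loop = parts[2], attribute = parts[3])
  } else {
    xr_abort(paste0("malformed attribute path '", path, "'"), "xr_error")
  }
}

modify_attribute <- function(schema, path, f) {
  p <- parse_path_string(path)
  gi <- group_index(schema, p$group)
  members <- schema$groups[[gi]]$members
  for (mi in seq_along(members)) {
    m <- members[[mi]]
    if (is.na(p$loop) && inherits(m, "xr_attribute") &&
      tolower(m$name) == tolower(p$attribute)) {
      members[[mi]] <- f(m)
      schema$groups[[gi]]$members <- members
      return(schema)
    }
    if (!is.na(p$loop) && inherits(m, "xr_loop") &&
      tolower(m$name) == tolower(p$loop)) {
      for (ai in seq_along(m$attributes)) {
        if (tolower(m$attributes[[ai]]$name) == tolower(p$attribute)) {
          m$attributes[[ai]] <- f(m$attributes[[ai]])
          members[[mi]] <- m
          schema$groups[[gi]]$members <- members
          return(schema)
        }
      }
    }
  }
  xr_abort(paste0("no attribute at path '", path, "'"), "xr_evolution_error")
}

remove_attribute_at <- function(schema, path) {
  p <- parse_path_string(path)
  gi <- group_index(schema, p$group)
  members <- schema$groups[[gi]]$members
  for (mi in seq_along(members)) {
    m <- members[[mi]]
    if (is.na(p$loop) && inherits(m, "xr_attribute") &&
      tolower(m$name) == tolower(p$attribute)) {
      schema$groups[[gi]]$members <- members[-mi]
      return(schema)
    }
    if (!is.na(p$loop) && inherits(m, "xr_loop") &&
      tolower(m$name) == tolower(p$loop)) {
      keep <- vapply(m$attributes, function(a) {
        tolower(a$name) != tolower(p$attribute)
      }, logical(1))
      if (!all(keep)) {
        m$attributes <- m$attributes[keep]
        members[[mi]] <- m
        schema$groups[[gi]]$members <- members
        return(schema)
      }
    }
  }
  xr_abort(paste0("no attribute at path '", path, "'"), "xr_evolution_error")
}
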