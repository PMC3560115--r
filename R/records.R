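## Data instances: records conforming to a runtime-defined data type.
##
## A Subject deliberately has no slot for a personal name: subjects are known
## to the repository only by an opaque anonymous identifier; the link to a
## person exists only outside the system, with the clinicians.

SEX_LEVELS <- c("male", "female", "other/unknown")

#' Create a study subject
#'
#' @param subject_id opaque anonymous identifier (unique in a store).
#' @param sex one of `"male"`, `"female"`, `"other/unknown"`.
#' @param birth_date ISO-8601 date (`Date` or `"YYYY-MM-DD"`).
#' @param diagnosis free-text diagnosis label.
#' @return an object of class `xr_subject`. Note the type has no field for a
#'   personal name — anonymity is structural, not a rendering choice.
#' @export
subject <- function(subject_id, sex = "other/unknown", birth_date = NA,
                    diagnosis = "") {
  if (!nzchar(subject_id)) xr_abort("subject_id must be non-empty", "xr_structural_error")
  if (!sex %in% SEX_LEVELS) {
    xr_abort(paste0("sex must be one of: ", paste(SEX_LEVELS, collapse = ", ")),
             "xr_structural_error")
  }
  if (!is.na(birth_date[1])) {
    bd <- encode_date(birth_date)
    if (is.na(bd)) xr_abort("birth_date must be an ISO-8601 date", "xr_structural_error")
    birth_date <- bd
  } else {
    birth_date <- NA_character_
  }
  structure(
    list(subject_id = subject_id, sex = sex, birth_date = birth_date,
         diagnosis = diagnosis),
    class = "xr_subject"
  )
}

#' A single attribute value inside an instance
#'
#' @param group group name; `loop` the loop name for loop attributes.
#' @param attribute attribute name.
#' @param value the typed value (validated against the schema later).
#' @param loop optional loop name.
#' @return an `xr_value`.
#' @export
attribute_value <- function(group, attribute, value, loop = NULL) {
  structure(
    list(group = group, loop = loop %||% NA_character_, attribute = attribute,
         value = value),
    class = "xr_value"
  )
}

#' A loop instance: ordered iterations of attribute values
#'
#' @param group,loop the loop's path.
#' @param iterations a list of iterations; each iteration is a named list
#'   `attribute -> value`.
#' @return an `xr_loop_instance`. Zero iterations is valid.
#' @export
loop_instance <- function(group, loop, iterations = list()) {
  structure(
    list(group = group, loop = loop, iterations = iterations),
    class = "xr_loop_instance"
  )
}

#' A reference to a stored file
#'
#' The engine stores file URIs only, never payloads.
#'
#' @param uri the file URI.
#' @param declared_format optional format label (e.g. `"DICOM"`).
#' @param checksum optional checksum string.
#' @return an `xr_file_ref`.
#' @export
file_ref <- function(uri, declared_format = NULL, checksum = NULL) {
  if (!is.character(uri) || length(uri) != 1L || !nzchar(uri) ||
    !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", uri)) {
    xr_abort(paste0("not a URI: '", uri, "'"), "xr_structural_error")
  }
  structure(
    list(uri = uri, declared_format = declared_format, checksum = checksum),
    class = "xr_file_ref"
  )
}

#' Create a data instance
#'
#' One record conforming to a data type at a pinned schema version, owned by
#' a subject and optionally attached to a provenance event.
#'
#' @param datatype data type name.
#' @param subject_id owning subject.
#' @param values list of [attribute_value()] objects (plain attributes).
#' @param loops list of [loop_instance()] objects.
#' @param files list of [file_ref()] objects (file-associated types only).
#' @param version schema version the instance conforms to.
#' @param event_id optional owning event.
#' @param instance_id optional; assigned by the store when saved.
#' @return an `xr_instance` (not yet validated; see [validate_instance()]).
#' @export
data_instance <- function(datatype, subject_id, values = list(), loops = list(),
                          files = list(), version = 1L, event_id = NA,
                          instance_id = NA) {
  structure(
    list(
      instance_id = instance_id, datatype = datatype,
      version = as.integer(version), subject_id = subject_id,
      event_id = if (is.na(event_id[1])) NA_character_ else event_id,
      values = values, loops = loops, files = files
    ),
    class = "xr_instance"
  )
}

empty_report <- function() {
  tibble(path = character(), rule = character(), message = character())
}

violation <- function(path, rule, message) {
  tibble(path = path, rule = rule, message = message)
}

#' Validate a data instance against its schema
#'
#' Validation is total and deterministic: every (instance, schema) pair yields
#' a report. The report is empty exactly when every required attribute is
#' present, every value satisfies its kind and enumeration, no unknown paths
#' occur, every loop iteration is complete, and files appear only on
#' file-associated types.
#'
#' @param instance an `xr_instance`.
#' @param schema the `xr_schema` version pinned by the instance.
#' @return a tibble with columns `path`, `rule`, `message`; zero rows means
#'   valid. A datatype/version mismatch between instance and schema is a usage
#'   error (condition `xr_usage_error`), not a violation.
#' @export
validate_instance <- function(instance, schema) {
  stopifnot(inherits(instance, "xr_instance"), inherits(schema, "xr_schema"))
  if (tolower(instance$datatype) != tolower(schema$header$datatype_name) ||
    instance$version != schema$header$version) {
    xr_abort(
      sprintf(
        "instance pins '%s' v%d but schema is '%s' v%d",
        instance$datatype, instance$version,
        schema$header$datatype_name, schema$header$version
      ),
      "xr_usage_error"
    )
  }
  report <- list()
  paths <- schema_paths(schema)
  plain <- paths[is.na(paths$loop), , drop = FALSE]

  seen <- character()
  for (v in instance$values) {
    a <- schema_find_attribute(schema, v$group, v$attribute)
    p <- paste(v$group, v$attribute, sep = ".")
    if (!is.na(v$loop)) {
      report[[length(report) + 1L]] <- violation(
        paste(v$group, v$loop, v$attribute, sep = "."), "unknown_path",
        "loop attributes must be supplied through loop iterations"
      )
      next
    }
    if (is.null(a)) {
      report[[length(report) + 1L]] <-
        violation(p, "unknown_path", "no such attribute in the data type")
      next
    }
    seen <- c(seen, tolower(p))
    report <- c(report, check_value(v$value, a, p))
  }
  dup <- unique(seen[duplicated(seen)])
  for (d in dup) {
    report[[length(report) + 1L]] <-
      violation(d, "duplicate_value", "attribute supplied more than once")
  }

  # required plain attributes (a default satisfies the requirement)
  for (i in seq_len(nrow(plain))) {
    if (!plain$required[i]) next
    p <- paste(plain$group[i], plain$attribute[i], sep = ".")
    a <- schema_find_attribute(schema, plain$group[i], plain$attribute[i])
    if (!tolower(p) %in% seen && is.null(a$default)) {
      report[[length(report) + 1L]] <-
        violation(p, "missing_required", "required attribute not supplied")
    }
  }

  # loops
  seen_loops <- character()
  for (li in instance$loops) {
    ldef <- schema_find_loop(schema, li$group, li$loop)
    lpath <- paste(li$group, li$loop, sep = ".")
    if (is.null(ldef)) {
      report[[length(report) + 1L]] <-
        violation(lpath, "unknown_path", "no such loop in the data type")
      next
    }
    seen_loops <- c(seen_loops, tolower(lpath))
    for (it_idx in seq_along(li$iterations)) {
      iter <- li$iterations[[it_idx]]
      nm <- names(iter) %||% character()
      for (an in nm) {
        a <- NULL
        for (cand in ldef$attributes) {
          if (tolower(cand$name) == tolower(an)) a <- cand
        }
        p <- paste0(lpath, ".", an, "[", it_idx, "]")
        if (is.null(a)) {
          report[[length(report) + 1L]] <-
            violation(p, "unknown_path", "no such attribute in the loop")
        } else {
          report <- c(report, check_value(iter[[an]], a, p))
        }
      }
      for (a in ldef$attributes) {
        if (a$required && !tolower(a$name) %in% tolower(nm) && is.null(a$default)) {
          report[[length(report) + 1L]] <- violation(
            paste0(lpath, ".", a$name, "[", it_idx, "]"),
            "missing_required", "required loop attribute missing in iteration"
          )
        }
      }
    }
  }
  if (anyDuplicated(seen_loops)) {
    d <- seen_loops[duplicated(seen_loops)][1]
    report[[length(report) + 1L]] <-
      violation(d, "duplicate_value", "loop supplied more than once")
  }

  # files only on file-associated types
  if (length(instance$files) && !schema$header$file_associated) {
    report[[length(report) + 1L]] <- violation(
      "<files>", "file_not_allowed",
      paste0("data type '", schema$header$datatype_name, "' is not file-associated")
    )
  }
  if (length(report)) bind_rows(report) else empty_report()
}

check_value <- function(value, attr_def, path) {
  enc <- encode_value(value, attr_def$kind)
  if (is.na(enc)) {
    return(list(violation(
      path, "kind",
      paste0("value does not satisfy kind '", attr_def$kind, "': ", attr(enc, "reason"))
    )))
  }
  if (attr_def$kind == "enumeration" && !enc %in% attr_def$allowed_values) {
    return(list(violation(
      path, "enum",
      paste0("'", enc, "' is not an allowed value of ", path)
    )))
  }
  list()
}

#' Attach a file reference to an instance
#'
#' Only data types flagged `file_associated` in their header accept files
#' (imaging types do; purely clinical types do not).
#'
#' @param instance an `xr_instance`.
#' @param file a [file_ref()].
#' @param schema the instance's schema.
#' @return the instance with `file` appended; otherwise unchanged.
#' @export
attach_file <- function(instance, file, schema) {
  stopifnot(inherits(instance, "xr_instance"), inherits(file, "xr_file_ref"))
  if (!schema$header$file_associated) {
    xr_abort(
      paste0("data type '", schema$header$datatype_name,
             "' is not file-associated; cannot attach '", file$uri, "'"),
      "xr_association_error"
    )
  }
  instance$files <- c(instance$files, list(file))
  instance
}

#' @export
print.xr_instance <- function(x, ...) {
  cat(sprintf(
    "<instance %s of '%s' v%d, subject %s>\n",
    if (is.na(x$instance_id)) "(unsaved)" else x$instance_id,
    x$datatype, x$version, x$subject_id
  ))
  for (v in x$values) {
    cat(sprintf("  %s.%s = %s\n", v$group, v$attribute, format(v$value)))
  }
  for (l in x$loops) {
    cat(sprintf("  %s.%s: %d iteration(s)\n", l$group, l$loop, length(l$iterations)))
  }
  for (f in x$files) cat(sprintf("  file: %s\n", f$uri))
  invisible(x)
}
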