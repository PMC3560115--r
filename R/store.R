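## The repository store.
##
## A store is a set of relational tables (tibbles) held in an environment and
## persisted as one JSON file. Metadata lives in a dual representation: the
## canonical XML document of every instance in the `instances` table plus its
## flattened projection in the `eav` table. Each mutating operation is
## transactional per call: tables are copied, modified, and committed only on
## success, so a failed save leaves no partial rows.

store_prototypes <- function() {
  list(
    schemas = tibble(name = character(), version = integer(),
                     created_at = character(), xml = character()),
    subjects = tibble(subject_id = character(), sex = character(),
                      birth_date = character(), diagnosis = character()),
    instances = tibble(instance_id = character(), datatype = character(),
                       version = integer(), subject_id = character(),
                       event_id = character(), xml = character()),
    eav = eav_prototype(),
    files = tibble(instance_id = character(), uri = character(),
                   format = character(), checksum = character()),
    process_types = tibble(type_name = character(), description = character(),
                           allowed_children = character()),
    event_types = tibble(type_name = character(), description = character()),
    processes = tibble(process_id = character(), type = character(),
                       label = character(), subject_id = character(),
                       parent_id = character(), seq = integer(),
                       started_at = character(), ended_at = character()),
    events = tibble(event_id = character(), type = character(),
                    process_id = character(), seq = integer(),
                    occurred_at = character(), note = character()),
    event_data = tibble(event_id = character(), instance_id = character()),
    freezers = tibble(freezer_id = character(), temperature_class = character(),
                      layout = character()),
    samples = tibble(sample_id = character(), material = character(),
                     subject_id = character(), freezer_id = character(),
                     rack_id = character(), slot = integer(), x = integer(),
                     y = integer(), courier_number = character(),
                     status = character()),
    sample_history = tibble(sample_id = character(), seq = integer(),
                            timestamp = character(), action = character(),
                            freezer_id = character(), rack_id = character(),
                            slot = integer(), x = integer(), y = integer()),
    groups = tibble(group_name = character(), description = character()),
    members = tibble(user_id = character(), group_name = character()),
    permissions = tibble(group_name = character(), resource = character(),
                         action = character()),
    functions = tibble(function_name = character()),
    oplog = tibble(seq = integer(), timestamp = character(), user = character(),
                   op = character(), detail = character()),
    meta = tibble(key = character(), value = character())
  )
}

DEFAULT_FUNCTIONS <- c(
  "datatype.define", "datatype.evolve", "data.insert", "data.view",
  "query.run", "process.manage", "sample.manage", "acl.manage",
  "imaging.register", "store.export"
)

#' Open (or create) a repository store
#'
#' @param path path of the store file (JSON). `NULL` keeps the store purely
#'   in memory. An existing file is loaded.
#' @return a store handle (class `xr_store`), an environment carrying the
#'   tables and id counters. Mutations are in-memory; [store_flush()] /
#'   [store_close()] persist to `path`.
#' @export
store_open <- function(path = NULL) {
  store <- new.env(parent = emptyenv())
  store$path <- path
  store$tables <- store_prototypes()
  store$tables$functions <- tibble(function_name = DEFAULT_FUNCTIONS)
  store$counters <- c(instance = 0L, process = 0L, event = 0L, sample = 0L,
                      oplog = 0L)
  class(store) <- "xr_store"
  if (!is.null(path) && file.exists(path)) {
    store_load_file(store, path)
  }
  store
}

#' @export
print.xr_store <- function(x, ...) {
  cat(sprintf(
    "<repository store %s>\n", if (is.null(x$path)) "(in-memory)" else x$path
  ))
  for (nm in names(x$tables)) {
    n <- nrow(x$tables[[nm]])
    if (n > 0) cat(sprintf("  %-14s %5d row(s)\n", nm, n))
  }
  invisible(x)
}

#' Persist a store to its file
#'
#' Writes the whole store as one JSON document, atomically (temp file +
#' rename). A store opened on the same path reproduces the tables exactly.
#'
#' @param store a store handle.
#' @return the store, invisibly.
#' @export
store_flush <- function(store) {
  if (is.null(store$path)) {
    return(invisible(store))
  }
  payload <- list(
    format = "xrepo-store-1",
    counters = as.list(store$counters),
    tables = lapply(store$tables, as.data.frame)
  )
  tmp <- paste0(store$path, ".tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA)
  file.rename(tmp, store$path)
  invisible(store)
}

#' @rdname store_flush
#' @export
store_close <- function(store) {
  store_flush(store)
}

store_load_file <- function(store, path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "xrepo-store-1")) {
    xr_abort(paste0("'", path, "' is not a repository store file"), "xr_io_error")
  }
  protos <- store_prototypes()
  for (nm in names(protos)) {
    proto <- protos[[nm]]
    raw <- payload$tables[[nm]]
    if (is.null(raw) || (is.data.frame(raw) && nrow(raw) == 0) ||
      (!is.data.frame(raw) && length(raw) == 0)) {
      store$tables[[nm]] <- proto
      next
    }
    df <- as_tibble(raw)
    for (col in names(proto)) {
      if (!col %in% names(df)) {
        df[[col]] <- rep(proto[[col]][NA_integer_], nrow(df))
      }
      mode_target <- class(proto[[col]])[1]
      df[[col]] <- switch(mode_target,
        character = as.character(df[[col]]),
        integer = as.integer(df[[col]]),
        numeric = as.numeric(df[[col]]),
        logical = as.logical(df[[col]]),
        df[[col]]
      )
    }
    store$tables[[nm]] <- df[, names(proto)]
  }
  counters <- unlist(payload$counters)
  store$counters[names(counters)] <- as.integer(counters)
  invisible(store)
}

next_id <- function(store, kind, prefix) {
  store$counters[[kind]] <- store$counters[[kind]] + 1L
  sprintf("%s-%06d", prefix, store$counters[[kind]])
}

# run a mutation transactionally: `f(tabs)` returns modified tables, committed
# only if no condition is raised
store_txn <- function(store, f) {
  tabs <- store$tables
  counters <- store$counters
  result <- tryCatch(
    f(tabs),
    error = function(e) {
      store$counters <- counters
      stop(e)
    }
  )
  store$tables <- result$tables
  result$value
}

log_op <- function(tabs, store, op, detail, user = "system") {
  store$counters[["oplog"]] <- store$counters[["oplog"]] + 1L
  tabs$oplog <- bind_rows(tabs$oplog, tibble(
    seq = store$counters[["oplog"]],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    user = user, op = op, detail = detail
  ))
  tabs
}

## ---- schemas ----------------------------------------------------------------

#' Save a data-type schema
#'
#' Stored (name, version) pairs are immutable: saving an existing pair is a
#' conflict. The schema is usable immediately after saving.
#'
#' @param store a store handle.
#' @param schema a valid `xr_schema`.
#' @return the datatype key `"name@version"`, invisibly.
#' @export
save_schema <- function(store, schema) {
  stopifnot(inherits(store, "xr_store"), inherits(schema, "xr_schema"))
  name <- schema$header$datatype_name
  version <- schema$header$version
  invisible(store_txn(store, function(tabs) {
    clash <- tabs$schemas[tolower(tabs$schemas$name) == tolower(name) &
      tabs$schemas$version == version, , drop = FALSE]
    if (nrow(clash)) {
      xr_abort(paste0("data type '", name, "' v", version, " already stored"),
               "xr_conflict_error")
    }
    tabs$schemas <- bind_rows(tabs$schemas, tibble(
      name = name, version = as.integer(version),
      created_at = schema$header$created_at, xml = serialize_schema(schema)
    ))
    tabs <- log_op(tabs, store, "schema.save", paste0(name, "@", version))
    list(tables = tabs, value = invisible(paste0(name, "@", version)))
  }))
}

#' Load a data-type schema
#'
#' @param store a store handle.
#' @param name data type name (case-insensitive).
#' @param version schema version; omitted loads the latest.
#' @return an `xr_schema`.
#' @export
load_schema <- function(store, name, version = NULL) {
  hit <- store$tables$schemas[
    tolower(store$tables$schemas$name) == tolower(name), , drop = FALSE
  ]
  if (!nrow(hit)) {
    xr_abort(paste0("no data type named '", name, "'"), "xr_not_found_error")
  }
  if (is.null(version)) {
    hit <- hit[which.max(hit$version), , drop = FALSE]
  } else {
    hit <- hit[hit$version == version, , drop = FALSE]
    if (!nrow(hit)) {
      xr_abort(paste0("no version ", version, " of data type '", name, "'"),
               "xr_not_found_error")
    }
  }
  parse_schema(hit$xml[1])
}

#' List stored data types
#'
#' @param store a store handle.
#' @return a tibble `name`, `version` (latest), `n_versions`.
#' @export
list_datatypes <- function(store) {
  s <- store$tables$schemas
  if (!nrow(s)) {
    return(tibble(name = character(), version = integer(), n_versions = integer()))
  }
  s |>
    group_by(.data$name) |>
    summarise(version = max(.data$version), n_versions = n(), .groups = "drop") |>
    arrange(.data$name)
}

## ---- subjects ---------------------------------------------------------------

#' Save a subject
#'
#' @param store a store handle.
#' @param subj an [subject()] object.
#' @return the subject id, invisibly.
#' @export
save_subject <- function(store, subj) {
  stopifnot(inherits(subj, "xr_subject"))
  invisible(store_txn(store, function(tabs) {
    if (subj$subject_id %in% tabs$subjects$subject_id) {
      xr_abort(paste0("subject '", subj$subject_id, "' already exists"),
               "xr_conflict_error")
    }
    tabs$subjects <- bind_rows(tabs$subjects, tibble(
      subject_id = subj$subject_id, sex = subj$sex,
      birth_date = subj$birth_date, diagnosis = subj$diagnosis
    ))
    tabs <- log_op(tabs, store, "subject.save", subj$subject_id)
    list(tables = tabs, value = invisible(subj$subject_id))
  }))
}

load_subject <- function(store, subject_id) {
  hit <- store$tables$subjects[
    store$tables$subjects$subject_id == subject_id, , drop = FALSE
  ]
  if (!nrow(hit)) {
    xr_abort(paste0("no subject '", subject_id, "'"), "xr_not_found_error")
  }
  subject(hit$subject_id, hit$sex,
          if (is.na(hit$birth_date)) NA else hit$birth_date, hit$diagnosis)
}

## ---- instances --------------------------------------------------------------

#' Save a data instance (dual representation)
#'
#' Validates the instance against its pinned schema, then writes the XML
#' document, the complete EAV projection and the file URIs in one
#' transaction. A validation failure persists nothing.
#'
#' @param store a store handle.
#' @param instance an `xr_instance`.
#' @return the assigned instance id, invisibly.
#' @export
save_instance <- function(store, instance) {
  stopifnot(inherits(instance, "xr_instance"))
  schema <- load_schema(store, instance$datatype, instance$version)
  rep <- validate_instance(instance, schema)
  if (nrow(rep)) {
    xr_abort(
      paste0("instance rejected: ", nrow(rep), " violation(s), first: ",
             rep$path[1], " (", rep$rule[1], ")"),
      "xr_validation_error", report = rep
    )
  }
  invisible(store_txn(store, function(tabs) {
    if (!instance$subject_id %in% tabs$subjects$subject_id) {
      xr_abort(paste0("no subject '", instance$subject_id, "' in store"),
               "xr_integrity_error")
    }
    iid <- if (is.na(instance$instance_id[1])) {
      next_id(store, "instance", "D")
    } else {
      instance$instance_id
    }
    if (iid %in% tabs$instances$instance_id) {
      xr_abort(paste0("instance id '", iid, "' already exists"), "xr_conflict_error")
    }
    instance$instance_id <- iid
    rows <- eav_flatten(instance, schema)
    rows$instance_id <- iid
    tabs$instances <- bind_rows(tabs$instances, tibble(
      instance_id = iid, datatype = schema$header$datatype_name,
      version = instance$version, subject_id = instance$subject_id,
      event_id = instance$event_id, xml = serialize_instance(instance, schema)
    ))
    tabs$eav <- bind_rows(tabs$eav, rows)
    if (length(instance$files)) {
      tabs$files <- bind_rows(tabs$files, tibble(
        instance_id = iid,
        uri = vapply(instance$files, `[[`, character(1), "uri"),
        format = vapply(instance$files, function(f) f$declared_format %||%
          NA_character_, character(1)),
        checksum = vapply(instance$files, function(f) f$checksum %||%
          NA_character_, character(1))
      ))
    }
    tabs <- log_op(tabs, store, "data.insert",
                   paste0(iid, " (", schema$header$datatype_name, ")"))
    list(tables = tabs, value = invisible(iid))
  }))
}

#' Load a data instance
#'
#' Reconstruction is transparent: the XML-backed and EAV-backed paths return
#' structurally identical instances, so callers cannot tell which
#' representation served the request.
#'
#' @param store a store handle.
#' @param instance_id the instance id.
#' @param from `"xml"` (parse the stored document) or `"eav"` (rebuild from
#'   the flattened rows).
#' @return an `xr_instance`.
#' @export
load_instance <- function(store, instance_id, from = c("xml", "eav")) {
  from <- match.arg(from)
  hit <- store$tables$instances[
    store$tables$instances$instance_id == instance_id, , drop = FALSE
  ]
  if (!nrow(hit)) {
    xr_abort(paste0("no instance '", instance_id, "'"), "xr_not_found_error")
  }
  schema <- load_schema(store, hit$datatype[1], hit$version[1])
  if (from == "xml") {
    return(parse_instance(hit$xml[1], schema))
  }
  rows <- store$tables$eav[store$tables$eav$instance_id == instance_id, , drop = FALSE]
  frows <- store$tables$files[store$tables$files$instance_id == instance_id, ,
                              drop = FALSE]
  files <- lapply(seq_len(nrow(frows)), function(i) {
    file_ref(
      frows$uri[i],
      declared_format = if (is.na(frows$format[i])) NULL else frows$format[i],
      checksum = if (is.na(frows$checksum[i])) NULL else frows$checksum[i]
    )
  })
  eav_to_instance(rows, schema, instance_id, hit$subject_id[1],
                  event_id = hit$event_id[1], files = files)
}

#' Check the dual representation of every stored instance
#'
#' Re-derives the EAV projection of each instance from its stored XML
#' document and compares it with the stored EAV rows. A healthy store yields
#' an empty report.
#'
#' @param store a store handle.
#' @return a tibble of divergent instances (`instance_id`, `problem`); zero
#'   rows when consistent.
#' @export
consistency_check <- function(store) {
  out <- list()
  for (i in seq_len(nrow(store$tables$instances))) {
    row <- store$tables$instances[i, ]
    schema <- load_schema(store, row$datatype, row$version)
    derived <- tryCatch(
      eav_flatten(parse_instance(row$xml, schema), schema),
      error = function(e) NULL
    )
    if (is.null(derived)) {
      out[[length(out) + 1L]] <- tibble(
        instance_id = row$instance_id, problem = "stored XML no longer parses"
      )
      next
    }
    derived$instance_id <- row$instance_id
    stored <- store$tables$eav[store$tables$eav$instance_id == row$instance_id, ,
                               drop = FALSE]
    if (!eav_rows_equal(derived, stored)) {
      out[[length(out) + 1L]] <- tibble(
        instance_id = row$instance_id,
        problem = "EAV rows diverge from the XML document"
      )
    }
  }
  if (length(out)) bind_rows(out) else tibble(instance_id = character(),
                                              problem = character())
}

eav_rows_equal <- function(a, b) {
  key <- function(d) {
    sort(paste(d$grp, d$loop %|NA|% "", d$iteration %|NA|% -1L, d$attribute,
               d$kind, d$value, sep = "\r"))
  }
  identical(key(a), key(b))
}

## ---- export / import --------------------------------------------------------

#' Export a store as a directory of XML documents plus a manifest
#'
#' Schemas and instances are written as individual XML files; every other
#' table goes into `manifest.json`. [store_import()] reproduces the store.
#'
#' @param store a store handle.
#' @param dir destination directory (created if missing).
#' @return `dir`, invisibly.
#' @export
store_export <- function(store, dir) {
  dir.create(file.path(dir, "schemas"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "instances"), recursive = TRUE, showWarnings = FALSE)
  s <- store$tables$schemas
  for (i in seq_len(nrow(s))) {
    writeLines(s$xml[i], file.path(dir, "schemas", sprintf(
      "%s-v%d.xml", gsub("[^A-Za-z0-9_-]", "_", s$name[i]), s$version[i]
    )))
  }
  d <- store$tables$instances
  for (i in seq_len(nrow(d))) {
    writeLines(d$xml[i], file.path(dir, "instances",
                                   paste0(d$instance_id[i], ".xml")))
  }
  # the operation log is operational telemetry, not repository content;
  # exports of two stores with identical content are byte-identical
  manifest <- lapply(
    store$tables[setdiff(names(store$tables), c("schemas", "instances", "oplog"))],
    as.data.frame
  )
  manifest$counters <- as.list(store$counters)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null", digits = NA)
  invisible(dir)
}

#' Import a store from an export directory
#'
#' @param dir a directory written by [store_export()].
#' @param path optional backing file for the new store.
#' @return a store handle.
#' @export
store_import <- function(dir, path = NULL) {
  store <- store_open(path)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  protos <- store_prototypes()
  # eav and files are rebuilt from the instance XML documents below
  for (nm in setdiff(names(protos), c("schemas", "instances", "eav", "files"))) {
    raw <- manifest[[nm]]
    if (is.null(raw) || NROW(raw) == 0) next
    df <- as_tibble(raw)
    proto <- protos[[nm]]
    for (col in names(proto)) {
      if (!col %in% names(df)) df[[col]] <- rep(proto[[col]][NA_integer_], nrow(df))
      df[[col]] <- switch(class(proto[[col]])[1],
        character = as.character(df[[col]]),
        integer = as.integer(df[[col]]),
        df[[col]]
      )
    }
    store$tables[[nm]] <- df[, names(proto)]
  }
  counters <- unlist(manifest$counters)
  store$counters[names(counters)] <- as.integer(counters)
  for (f in sort(list.files(file.path(dir, "schemas"), full.names = TRUE))) {
    schema <- parse_schema(paste(readLines(f, warn = FALSE), collapse = "\n"))
    store$tables$schemas <- bind_rows(store$tables$schemas, tibble(
      name = schema$header$datatype_name, version = schema$header$version,
      created_at = schema$header$created_at, xml = serialize_schema(schema)
    ))
  }
  for (f in sort(list.files(file.path(dir, "instances"), full.names = TRUE))) {
    xml <- paste(readLines(f, warn = FALSE), collapse = "\n")
    x <- xml2::read_xml(xml)
    dt <- xml2::xml_attr(x, "datatype")
    version <- as.integer(xml2::xml_attr(x, "version"))
    schema <- load_schema(store, dt, version)
    inst <- parse_instance(xml, schema)
    rows <- eav_flatten(inst, schema)
    rows$instance_id <- inst$instance_id
    store$tables$instances <- bind_rows(store$tables$instances, tibble(
      instance_id = inst$instance_id, datatype = schema$header$datatype_name,
      version = inst$version, subject_id = inst$subject_id,
      event_id = inst$event_id, xml = xml
    ))
    store$tables$eav <- bind_rows(store$tables$eav, rows)
    if (length(inst$files)) {
      store$tables$files <- bind_rows(store$tables$files, tibble(
        instance_id = inst$instance_id,
        uri = vapply(inst$files, `[[`, character(1), "uri"),
        format = vapply(inst$files, function(fl) fl$declared_format %||%
          NA_character_, character(1)),
        checksum = vapply(inst$files, function(fl) fl$checksum %||%
          NA_character_, character(1))
      ))
    }
  }
  store
}
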