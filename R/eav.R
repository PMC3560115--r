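## Entity-attribute-value projection.
##
## Each instance is persisted twice: as a canonical XML document (fast
## integrated display) and as flattened EAV rows (fast dynamic querying).
## eav_flatten() is the single definition of the projection; the store's
## consistency check re-derives rows from the XML and compares.

eav_prototype <- function() {
  tibble(
    instance_id = character(), datatype = character(), grp = character(),
    loop = character(), iteration = integer(), attribute = character(),
    kind = character(), value = character()
  )
}

#' Flatten a data instance to EAV rows
#'
#' One row per supplied attribute value: plain values carry `loop = NA`,
#' `iteration = NA`; loop values carry the loop name and a 0-based iteration
#' index (displayed 1-based elsewhere). Values are in canonical text encoding.
#'
#' @param instance a valid `xr_instance`.
#' @param schema its schema (source of value kinds).
#' @return a tibble with columns `instance_id`, `datatype`, `grp`, `loop`,
#'   `iteration`, `attribute`, `kind`, `value`.
#' @export
eav_flatten <- function(instance, schema) {
  rows <- list()
  iid <- if (is.na(instance$instance_id[1])) NA_character_ else instance$instance_id
  dt <- schema$header$datatype_name
  for (v in instance$values) {
    a <- schema_find_attribute(schema, v$group, v$attribute)
    if (is.null(a)) {
      xr_abort(paste0("cannot flatten unknown path ", v$group, ".", v$attribute),
               "xr_usage_error")
    }
    rows[[length(rows) + 1L]] <- tibble(
      instance_id = iid, datatype = dt, grp = v$group, loop = NA_character_,
      iteration = NA_integer_, attribute = v$attribute, kind = a$kind,
      value = as.character(encode_value(v$value, a$kind))
    )
  }
  for (li in instance$loops) {
    ldef <- schema_find_loop(schema, li$group, li$loop)
    if (is.null(ldef)) {
      xr_abort(paste0("cannot flatten unknown loop ", li$group, ".", li$loop),
               "xr_usage_error")
    }
    kinds <- setNames(
      vapply(ldef$attributes, `[[`, character(1), "kind"),
      tolower(vapply(ldef$attributes, `[[`, character(1), "name"))
    )
    for (i in seq_along(li$iterations)) {
      iter <- li$iterations[[i]]
      for (an in names(iter)) {
        rows[[length(rows) + 1L]] <- tibble(
          instance_id = iid, datatype = dt, grp = li$group, loop = li$loop,
          iteration = i - 1L, attribute = an, kind = kinds[[tolower(an)]],
          value = as.character(encode_value(iter[[an]], kinds[[tolower(an)]]))
        )
      }
    }
  }
  if (length(rows)) bind_rows(rows) else eav_prototype()
}

# rebuild an instance from its EAV rows, ordering values by schema order
eav_to_instance <- function(rows, schema, instance_id, subject_id,
                            event_id = NA, files = list()) {
  paths <- schema_paths(schema)
  values <- list()
  loops <- list()
  for (gi in seq_along(schema$groups)) {
    g <- schema$groups[[gi]]
    for (m in g$members) {
      if (inherits(m, "xr_attribute")) {
        hit <- rows[rows$grp == g$name & is.na(rows$loop) &
          rows$attribute == m$name, , drop = FALSE]
        if (nrow(hit)) {
          values[[length(values) + 1L]] <- attribute_value(
            g$name, m$name, decode_value(hit$value[1], m$kind)
          )
        }
      } else {
        hit <- rows[rows$grp == g$name & !is.na(rows$loop) &
          rows$loop == m$name, , drop = FALSE]
        if (!nrow(hit)) next
        iterations <- list()
        for (it in sort(unique(hit$iteration))) {
          sub <- hit[hit$iteration == it, , drop = FALSE]
          iter <- list()
          for (a in m$attributes) {
            r <- sub[sub$attribute == a$name, , drop = FALSE]
            if (nrow(r)) iter[[a$name]] <- decode_value(r$value[1], a$kind)
          }
          iterations[[length(iterations) + 1L]] <- iter
        }
        loops[[length(loops) + 1L]] <- loop_instance(g$name, m$name, iterations)
      }
    }
  }
  data_instance(
    datatype = schema$header$datatype_name, subject_id = subject_id,
    values = values, loops = loops, files = files,
    version = schema$header$version, event_id = event_id,
    instance_id = instance_id
  )
}

# canonical comparable projection of an instance: sorted EAV rows + files.
# Structural equality of instances is defined as equality of projections.
instance_projection <- function(instance, schema) {
  rows <- eav_flatten(instance, schema)
  rows <- rows[order(rows$grp, rows$loop %|NA|% "", rows$iteration %|NA|% -1L,
                     rows$attribute, method = "radix"), , drop = FALSE]
  list(
    datatype = tolower(instance$datatype), version = instance$version,
    subject_id = instance$subject_id,
    event_id = instance$event_id,
    rows = as.data.frame(rows[, c("grp", "loop", "iteration", "attribute", "value")]),
    files = vapply(instance$files, `[[`, character(1), "uri")
  )
}

#' Structural equality of two instances
#'
#' Two instances are structurally equal when their canonical EAV projections,
#' subject/event linkage and file URI lists coincide.
#'
#' @param a,b `xr_instance` objects.
#' @param schema the shared schema.
#' @return `TRUE` or `FALSE`.
#' @export
instance_equal <- function(a, b, schema) {
  isTRUE(all.equal(instance_projection(a, schema), instance_projection(b, schema)))
}
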