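## XML dialect for data instances.
##
## Root <data datatype=... version=... subject=... [event=...]> with
## <group name=...> children holding <attribute name=...>value</attribute>
## and <loop name=...> > <iteration> > <attribute> elements, then
## <file uri=.../> elements. Values are canonical text encodings.

#' Serialize a data instance to its XML document
#'
#' @param instance a valid `xr_instance`.
#' @param schema its schema (drives value encoding and element order).
#' @return a length-1 character vector with the UTF-8 XML document.
#' @export
serialize_instance <- function(instance, schema) {
  stopifnot(inherits(instance, "xr_instance"))
  rep <- validate_instance(instance, schema)
  if (nrow(rep)) {
    xr_abort(
      paste0("cannot serialize invalid instance: ", rep$path[1], " (", rep$rule[1], ")"),
      "xr_usage_error"
    )
  }
  attrs <- list(
    datatype = instance$datatype, version = as.character(instance$version),
    subject = instance$subject_id
  )
  if (!is.na(instance$event_id)) attrs$event <- instance$event_id
  if (!is.na(instance$instance_id[1])) attrs$id <- instance$instance_id
  doc <- do.call(xml2::xml_new_root, c(list("data"), attrs))

  # emit group elements in schema order; within a group, plain values then loops
  for (g in schema$groups) {
    vals <- Filter(function(v) tolower(v$group) == tolower(g$name), instance$values)
    loops <- Filter(function(l) tolower(l$group) == tolower(g$name), instance$loops)
    if (!length(vals) && !length(loops)) next
    gnode <- xml2::xml_add_child(doc, "group", name = g$name)
    for (m in g$members) {
      if (inherits(m, "xr_attribute")) {
        for (v in vals) {
          if (tolower(v$attribute) == tolower(m$name)) {
            xml2::xml_add_child(
              gnode, "attribute", encode_value(v$value, m$kind), name = m$name
            )
          }
        }
      } else {
        for (l in loops) {
          if (tolower(l$loop) != tolower(m$name)) next
          lnode <- xml2::xml_add_child(gnode, "loop", name = m$name)
          for (iter in l$iterations) {
            inode <- xml2::xml_add_child(lnode, "iteration")
            for (a in m$attributes) {
              for (an in names(iter)) {
                if (tolower(an) == tolower(a$name)) {
                  xml2::xml_add_child(
                    inode, "attribute", encode_value(iter[[an]], a$kind),
                    name = a$name
                  )
                }
              }
            }
          }
        }
      }
    }
  }
  for (f in instance$files) {
    fattrs <- list(uri = f$uri)
    if (!is.null(f$declared_format)) fattrs$format <- f$declared_format
    if (!is.null(f$checksum)) fattrs$checksum <- f$checksum
    do.call(xml2::xml_add_child, c(list(doc, "file"), fattrs))
  }
  as.character(doc)
}

#' Parse a data instance from its XML document
#'
#' Parsing validates against the given schema and fails on any violation; a
#' datatype mismatch between document and schema is an error.
#'
#' @param doc XML (character, raw, connection or `xml_document`).
#' @param schema the `xr_schema` the document claims to conform to.
#' @return a valid `xr_instance`.
#' @export
parse_instance <- function(doc, schema) {
  x <- as_xml(doc)
  if (xml2::xml_name(x) != "data") {
    xr_abort("root element must be <data>", "xr_parse_error")
  }
  dt <- xml2::xml_attr(x, "datatype")
  if (is.na(dt) || tolower(dt) != tolower(schema$header$datatype_name)) {
    xr_abort(
      paste0("document datatype '", dt, "' does not match schema '",
             schema$header$datatype_name, "'"),
      "xr_parse_error"
    )
  }
  version <- as.integer(xml2::xml_attr(x, "version"))
  if (is.na(version)) version <- schema$header$version
  subject_id <- xml2::xml_attr(x, "subject")
  event_id <- xml2::xml_attr(x, "event")

  values <- list()
  loops <- list()
  for (gnode in xml2::xml_find_all(x, "./group")) {
    gname <- xml2::xml_attr(gnode, "name")
    for (ch in xml2::xml_children(gnode)) {
      nm <- xml2::xml_name(ch)
      if (nm == "attribute") {
        values[[length(values) + 1L]] <- attribute_value(
          gname, xml2::xml_attr(ch, "name"),
          decode_known(schema, gname, NA, xml2::xml_attr(ch, "name"), xml2::xml_text(ch))
        )
      } else if (nm == "loop") {
        lname <- xml2::xml_attr(ch, "name")
        iterations <- lapply(xml2::xml_find_all(ch, "./iteration"), function(inode) {
          iter <- list()
          for (anode in xml2::xml_find_all(inode, "./attribute")) {
            an <- xml2::xml_attr(anode, "name")
            iter[[an]] <- decode_known(schema, gname, lname, an, xml2::xml_text(anode))
          }
          iter
        })
        loops[[length(loops) + 1L]] <- loop_instance(gname, lname, iterations)
      } else {
        xr_abort(paste0("unknown element <", nm, "> in group '", gname, "'"),
                 "xr_parse_error")
      }
    }
  }
  files <- lapply(xml2::xml_find_all(x, "./file"), function(fnode) {
    fmt <- xml2::xml_attr(fnode, "format")
    cks <- xml2::xml_attr(fnode, "checksum")
    file_ref(
      xml2::xml_attr(fnode, "uri"),
      declared_format = if (is.na(fmt)) NULL else fmt,
      checksum = if (is.na(cks)) NULL else cks
    )
  })
  iid <- xml2::xml_attr(x, "id")
  inst <- data_instance(
    datatype = dt, subject_id = subject_id, values = values, loops = loops,
    files = files, version = version,
    event_id = if (is.na(event_id)) NA else event_id,
    instance_id = if (is.na(iid)) NA else iid
  )
  rep <- validate_instance(inst, schema)
  if (nrow(rep)) {
    xr_abort(
      paste0("instance document violates its schema: ", rep$path[1],
             " (", rep$rule[1], "): ", rep$message[1]),
      "xr_parse_error"
    )
  }
  inst
}

# decode text through the schema's kind when the path is known; otherwise pass
# the raw text through so validation can report the unknown path itself
decode_known <- function(schema, group, loop, attribute, text) {
  a <- schema_find_attribute(schema, group, attribute,
                             loop = if (is.na(loop[1])) NA else loop)
  if (is.null(a)) {
    return(text)
  }
  enc <- encode_value(text, a$kind)
  if (is.na(enc)) {
    return(text) # invalid for the kind; keep raw so validation flags it
  }
  decode_value(enc, a$kind)
}
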