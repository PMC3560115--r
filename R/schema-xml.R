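## XML dialect for data-type schemas.
##
## Root <datatype dialect="xtens-1"> with exactly two sections:
##   <header>   name, version, description, fileAssociated, createdBy, createdAt
##   <metadata> group* > (attribute | loop)*
## Element order is fixed, so serialization is deterministic: serializing,
## parsing and serializing again yields byte-identical output.

DIALECT <- "xtens-1"

#' Serialize a data-type schema to its XML document
#'
#' @param schema a valid `xr_schema`.
#' @return a length-1 character vector holding the UTF-8 XML document.
#' @seealso [parse_schema()]
#' @export
serialize_schema <- function(schema) {
  stopifnot(inherits(schema, "xr_schema"))
  doc <- xml2::xml_new_root("datatype", dialect = DIALECT)
  h <- schema$header
  hdr <- xml2::xml_add_child(doc, "header")
  xml2::xml_add_child(hdr, "name", h$datatype_name)
  xml2::xml_add_child(hdr, "version", as.character(h$version))
  xml2::xml_add_child(hdr, "description", h$description)
  xml2::xml_add_child(hdr, "fileAssociated", if (h$file_associated) "true" else "false")
  xml2::xml_add_child(hdr, "createdBy", h$created_by)
  xml2::xml_add_child(hdr, "createdAt", h$created_at)
  meta <- xml2::xml_add_child(doc, "metadata")
  for (g in schema$groups) {
    gnode <- xml2::xml_add_child(meta, "group", name = g$name)
    for (m in g$members) {
      if (inherits(m, "xr_attribute")) {
        add_attribute_node(gnode, m)
      } else {
        lnode <- xml2::xml_add_child(gnode, "loop", name = m$name)
        for (a in m$attributes) add_attribute_node(lnode, a)
      }
    }
  }
  as.character(doc)
}

add_attribute_node <- function(parent, a) {
  node <- xml2::xml_add_child(
    parent, "attribute",
    name = a$name, type = a$kind, required = if (a$required) "true" else "false"
  )
  if (!is.null(a$unit)) xml2::xml_add_child(node, "unit", a$unit)
  for (v in a$allowed_values %||% character()) {
    xml2::xml_add_child(node, "allowedValue", v)
  }
  if (!is.null(a$ontology)) {
    xml2::xml_add_child(
      node, "ontology",
      source = a$ontology$ontology_id, termId = a$ontology$term_id,
      label = a$ontology$label
    )
  }
  if (!is.null(a$default)) xml2::xml_add_child(node, "default", a$default)
  invisible(node)
}

#' Parse a data-type schema from its XML document
#'
#' The result passes all structural invariants; `parse_schema(serialize_schema(s))`
#' is structurally identical to `s`.
#'
#' @param doc XML as a character scalar, raw vector, connection or `xml_document`.
#' @return an `xr_schema`.
#' @export
parse_schema <- function(doc) {
  x <- as_xml(doc)
  if (xml2::xml_name(x) != "datatype") {
    xr_abort("root element must be <datatype>", "xr_parse_error")
  }
  hdr <- xml2::xml_find_first(x, "./header")
  if (inherits(hdr, "xml_missing")) {
    xr_abort("missing <header> section in datatype document", "xr_parse_error")
  }
  meta <- xml2::xml_find_first(x, "./metadata")
  if (inherits(meta, "xml_missing")) {
    xr_abort("missing <metadata> section in datatype document", "xr_parse_error")
  }
  known <- c("header", "metadata")
  extra <- setdiff(xml2::xml_name(xml2::xml_children(x)), known)
  if (length(extra)) {
    xr_abort(paste0("unknown element <", extra[1], "> under <datatype>"),
             "xr_parse_error")
  }
  header <- schema_header(
    datatype_name = header_field(hdr, "name"),
    description = header_field(hdr, "description", ""),
    file_associated = identical(header_field(hdr, "fileAssociated", "false"), "true"),
    created_by = header_field(hdr, "createdBy", "unknown"),
    created_at = header_field(hdr, "createdAt", NULL),
    version = as.integer(header_field(hdr, "version", "1"))
  )
  groups <- lapply(xml2::xml_find_all(meta, "./group"), parse_group_node)
  extra <- setdiff(xml2::xml_name(xml2::xml_children(meta)), "group")
  if (length(extra)) {
    xr_abort(paste0("unknown element <", extra[1], "> under <metadata>"), "xr_parse_error")
  }
  version <- header$version
  schema <- define_datatype(header, groups)
  schema$header$version <- version
  schema
}

as_xml <- function(doc) {
  if (inherits(doc, "xml_document")) {
    xml2::xml_root(doc)
  } else {
    tryCatch(
      xml2::xml_root(xml2::read_xml(doc)),
      error = function(e) xr_abort(paste0("not well-formed XML: ", conditionMessage(e)),
                                   "xr_parse_error")
    )
  }
}

header_field <- function(hdr, name, default = NA) {
  node <- xml2::xml_find_first(hdr, paste0("./", name))
  if (inherits(node, "xml_missing")) {
    if (is.na(default[1]) && !is.null(default)) {
      xr_abort(paste0("missing header element <", name, ">"), "xr_parse_error")
    }
    return(default)
  }
  xml2::xml_text(node)
}

parse_group_node <- function(gnode) {
  members <- lapply(xml2::xml_children(gnode), function(ch) {
    switch(xml2::xml_name(ch),
      attribute = parse_attribute_node(ch),
      loop = {
        attrs <- lapply(xml2::xml_children(ch), function(a) {
          if (xml2::xml_name(a) != "attribute") {
            xr_abort(paste0("unknown element <", xml2::xml_name(a), "> inside loop '",
                            xml2::xml_attr(ch, "name"), "'"), "xr_parse_error")
          }
          parse_attribute_node(a)
        })
        loop_def(xml2::xml_attr(ch, "name"), attrs)
      },
      xr_abort(paste0("unknown element <", xml2::xml_name(ch), "> in group '",
                      xml2::xml_attr(gnode, "name"), "'"), "xr_parse_error")
    )
  })
  metadata_group(xml2::xml_attr(gnode, "name"), members)
}

parse_attribute_node <- function(node) {
  allowed <- xml2::xml_text(xml2::xml_find_all(node, "./allowedValue"))
  if (!length(allowed)) allowed <- NULL
  unit <- xml2::xml_find_first(node, "./unit")
  ont <- xml2::xml_find_first(node, "./ontology")
  default <- xml2::xml_find_first(node, "./default")
  attribute_def(
    name = xml2::xml_attr(node, "name"),
    kind = xml2::xml_attr(node, "type"),
    required = identical(xml2::xml_attr(node, "required"), "true"),
    allowed_values = allowed,
    unit = if (inherits(unit, "xml_missing")) NULL else xml2::xml_text(unit),
    ontology = if (inherits(ont, "xml_missing")) NULL else {
      ontology_ref(
        xml2::xml_attr(ont, "source"), xml2::xml_attr(ont, "termId"),
        xml2::xml_attr(ont, "label")
      )
    },
    default = if (inherits(default, "xml_missing")) NULL else xml2::xml_text(default)
  )
}
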