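## Data-entry form rendering: the HTML skeleton a portal would serve for a
## runtime-defined data type. One input control per attribute, selection
## lists for enumerations, a visible marker on required attributes, and a
## repeatable row template per loop.

#' Render an HTML entry form for a data type
#'
#' @param schema a valid `xr_schema`.
#' @return a length-1 character vector of HTML. Controls carry
#'   `name="group.attribute"` (or `group.loop.attribute` inside the loop
#'   template); enumerations become `<select>` with one `<option>` per
#'   allowed value; required attributes get `class="required"` and a `*`
#'   label marker; each loop is a `<fieldset class="loop">` holding a
#'   `<template>` row to be repeated client-side.
#' @export
render_entry_form <- function(schema) {
  stopifnot(inherits(schema, "xr_schema"))
  doc <- xml2::xml_new_root("form", class = "xr-entry-form",
                            `data-datatype` = schema$header$datatype_name,
                            `data-version` = as.character(schema$header$version))
  xml2::xml_add_child(doc, "h1", schema$header$datatype_name)
  for (g in schema$groups) {
    gset <- xml2::xml_add_child(doc, "fieldset", class = "group")
    xml2::xml_add_child(gset, "legend", g$name)
    for (m in g$members) {
      if (inherits(m, "xr_attribute")) {
        add_control(gset, m, paste(g$name, m$name, sep = "."))
      } else {
        lset <- xml2::xml_add_child(gset, "fieldset", class = "loop",
                                    `data-loop` = m$name)
        xml2::xml_add_child(lset, "legend", m$name)
        tmpl <- xml2::xml_add_child(lset, "template", class = "loop-row")
        for (a in m$attributes) {
          add_control(tmpl, a, paste(g$name, m$name, a$name, sep = "."))
        }
        xml2::xml_add_child(lset, "button", "add row", type = "button",
                            class = "add-iteration")
      }
    }
  }
  xml2::xml_add_child(doc, "button", "save", type = "submit")
  as.character(doc)
}

add_control <- function(parent, a, name) {
  label_text <- if (a$required) paste0(a$name, " *") else a$name
  label <- xml2::xml_add_child(parent, "label", label_text)
  if (!is.null(a$unit)) xml2::xml_add_child(label, "span", a$unit, class = "unit")
  cls <- if (a$required) "required" else ""
  if (a$kind == "enumeration") {
    sel <- xml2::xml_add_child(parent, "select", name = name, class = cls)
    for (v in a$allowed_values) {
      opt <- xml2::xml_add_child(sel, "option", v, value = v)
      if (!is.null(a$default) && identical(v, a$default)) {
        xml2::xml_set_attr(opt, "selected", "selected")
      }
    }
  } else {
    type <- switch(a$kind,
      integer = ,
      decimal = "number",
      date = "date",
      boolean = "checkbox",
      "text"
    )
    node <- xml2::xml_add_child(parent, "input", name = name, type = type,
                                class = cls)
    if (a$kind == "decimal") xml2::xml_set_attr(node, "step", "any")
    if (!is.null(a$default)) xml2::xml_set_attr(node, "value", a$default)
    if (a$required) xml2::xml_set_attr(node, "required", "required")
  }
  invisible(parent)
}
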