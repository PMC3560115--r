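test_that("well-formed data types validate and enumerate their paths", {
  mri <- mri_schema()
  expect_s3_class(mri, "xr_schema")
  expect_equal(mri$header$version, 1L)
  expect_equal(nrow(schema_paths(mri)), 2L)

  reagent <- reagent_schema()
  p <- schema_paths(reagent)
  expect_equal(sum(!is.na(p$loop)), 3L)
  expect_setequal(
    p$attribute[!is.na(p$loop)],
    c("description", "concentration", "amount")
  )

  risk <- risk_schema()
  expect_equal(nrow(schema_paths(risk)), 2L)
  factor_def <- schema_find_attribute(risk, "history", "factor", loop = "risk_factor")
  expect_setequal(factor_def$allowed_values, c("smoke", "alchool", "sedentary job"))
})

test_that("structural invariants reject bad definitions with named paths", {
  # case-insensitive duplicate attribute names in one group
  expect_error(
    metadata_group("dosing", list(
      attribute_def("Dose", "decimal"), attribute_def("dose", "decimal")
    )),
    regexp = "[Dd]ose", class = "xr_structural_error"
  )
  # attributes and loops share one namespace
  expect_error(
    metadata_group("g", list(
      attribute_def("reagent", "text"),
      loop_def("Reagent", list(attribute_def("a", "text")))
    )),
    class = "xr_structural_error"
  )
  # loops do not nest: loop_def accepts attributes only
  expect_error(
    loop_def("outer", list(loop_def("inner", list(attribute_def("a", "text"))))),
    class = "xr_structural_error"
  )
  # enumeration needs allowed values; defaults must satisfy them
  expect_error(attribute_def("e", "enumeration"), class = "xr_structural_error")
  expect_error(
    attribute_def("e", "enumeration", allowed_values = c("a", "b"), default = "c"),
    class = "xr_structural_error"
  )
  # empty group list
  expect_error(define_datatype(schema_header("X"), list()),
               class = "xr_structural_error")
  # duplicate group names
  expect_error(
    define_datatype(schema_header("X"), list(
      metadata_group("g", list(attribute_def("a", "text"))),
      metadata_group("G", list(attribute_def("b", "text")))
    )),
    class = "xr_structural_error"
  )
})

test_that("additive evolution bumps the version and keeps old instances valid", {
  store <- store_open()
  save_schema(store, mri_schema())
  save_subject(store, subject("S1"))
  save_instance(store, mri_instance("S1"))

  v2 <- evolve_datatype(
    load_schema(store, "MRI"),
    list(change_add_attribute(
      "acquisition", attribute_def("contrast_agent", "text")
    )),
    store = store
  )
  expect_equal(v2$header$version, 2L)
  expect_equal(load_schema(store, "MRI")$header$version, 2L)

  # the v1 instance revalidates cleanly under the evolved definition
  v1_inst <- load_instance(store, store$tables$instances$instance_id[1])
  v1_inst$version <- 2L
  expect_equal(nrow(validate_instance(v1_inst, v2)), 0L)
  # and v1 remains loadable, immutable
  expect_equal(load_schema(store, "MRI", version = 1L)$header$version, 1L)
})

test_that("empty change list is the identity", {
  mri <- mri_schema()
  expect_identical(serialize_schema(evolve_datatype(mri, list())),
                   serialize_schema(mri))
})

test_that("unsafe evolution is rejected while instances exist", {
  store <- store_open()
  save_schema(store, mri_schema())
  save_subject(store, subject("S1"))
  save_instance(store, mri_instance("S1"))
  schema <- load_schema(store, "MRI")

  # required attribute without a default would break the stored instance
  expect_error(
    evolve_datatype(schema, list(change_add_attribute(
      "acquisition", attribute_def("dose", "decimal", required = TRUE)
    )), store = store),
    class = "xr_evolution_error"
  )
  # destructive change with instances present
  expect_error(
    evolve_datatype(schema, list(change_remove_attribute("acquisition.sequence")),
                    store = store),
    class = "xr_evolution_error"
  )
  # but destructive is allowed on an instance-free type
  empty_store <- store_open()
  save_schema(empty_store, mri_schema())
  pruned <- evolve_datatype(
    load_schema(empty_store, "MRI"),
    list(change_remove_attribute("acquisition.sequence")),
    store = empty_store
  )
  expect_equal(nrow(schema_paths(pruned)), 1L)
})

test_that("ontology suggestion equals a brute-force prefix filter", {
  ont <- read_obo(fixture_obo())
  expect_equal(ont$ontology_id, "XF")
  expect_equal(nrow(ont$terms), 5L) # the Typedef stanza is ignored

  hits <- suggest_terms("a", ont)
  brute <- sort(ont$terms$label[startsWith(tolower(ont$terms$label), "a")],
                method = "radix")
  expect_equal(hits$label, brute)
  expect_equal(hits$label, c("Age at onset", "apolipoprotein measurement", "assay"))

  full <- suggest_terms("diagnosis", ont)
  expect_equal(full$term_id, "XF:0000005")
  expect_equal(nrow(suggest_terms("zzzz_nonexistent", ont)), 0L)
  expect_equal(nrow(suggest_terms("a", NULL)), 0L)
  expect_equal(nrow(suggest_terms("a", ont, limit = 2L)), 2L)
})

test_that("entry forms expose one control per attribute", {
  html <- render_entry_form(mri_schema())
  doc <- xml2::read_xml(html)
  controls <- xml2::xml_find_all(doc, "//input|//select")
  expect_equal(length(controls), 2L)
  expect_setequal(
    xml2::xml_attr(controls, "name"),
    c("acquisition.field_strength", "acquisition.sequence")
  )
  # required attribute visibly marked
  req <- xml2::xml_find_first(doc, "//input[@name='acquisition.field_strength']")
  expect_equal(xml2::xml_attr(req, "class"), "required")

  # enumeration renders as a selection list with one option per value
  risk_html <- render_entry_form(risk_schema())
  rdoc <- xml2::read_xml(risk_html)
  options <- xml2::xml_find_all(rdoc, "//select/option")
  expect_setequal(xml2::xml_text(options), c("smoke", "alchool", "sedentary job"))

  # a loop renders as a repeatable template holding its controls
  reagent_html <- render_entry_form(reagent_schema())
  tdoc <- xml2::read_xml(reagent_html)
  tmpl <- xml2::xml_find_all(tdoc, "//fieldset[@class='loop']/template")
  expect_equal(length(tmpl), 1L)
  expect_equal(length(xml2::xml_find_all(tmpl[[1]], ".//input")), 3L)
})
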