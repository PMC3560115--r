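test_that("conforming instances validate cleanly", {
  expect_equal(nrow(validate_instance(mri_instance(), mri_schema())), 0L)
  expect_equal(nrow(validate_instance(reagent_instance(), reagent_schema())), 0L)
  # an empty loop (zero iterations) is valid
  empty_loop <- data_instance(
    "Microarray Protocol", "S1",
    loops = list(loop_instance("protocol", "reagent", list()))
  )
  expect_equal(nrow(validate_instance(empty_loop, reagent_schema())), 0L)
})

test_that("violations name the offending path and reason", {
  schema <- mri_schema()
  # missing required attribute: exactly one violation naming it
  inst <- data_instance("MRI", "S1", values = list(
    attribute_value("acquisition", "sequence", "T2")
  ))
  rep <- validate_instance(inst, schema)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$rule, "missing_required")
  expect_equal(rep$path, "acquisition.field_strength")

  # kind violation
  bad_kind <- data_instance("MRI", "S1", values = list(
    attribute_value("acquisition", "field_strength", "abc")
  ))
  rep <- validate_instance(bad_kind, schema)
  expect_equal(rep$rule, "kind")
  expect_equal(rep$path, "acquisition.field_strength")

  # unknown paths are violations, never silently ignored
  unknown <- data_instance("MRI", "S1", values = list(
    attribute_value("acquisition", "field_strength", 3),
    attribute_value("acquisition", "made_up", 1)
  ))
  rep <- validate_instance(unknown, schema)
  expect_equal(rep$rule, "unknown_path")
  expect_equal(rep$path, "acquisition.made_up")

  # incomplete loop iteration
  short_iter <- data_instance(
    "Microarray Protocol", "S1",
    loops = list(loop_instance("protocol", "reagent", list(
      list(description = "dye") # concentration and amount missing
    )))
  )
  rep <- validate_instance(short_iter, reagent_schema())
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$rule == "missing_required"))
  expect_true(all(grepl("^protocol\\.reagent\\.", rep$path)))

  # enumeration outside its allowed set
  bad_enum <- data_instance(
    "Clinical History", "S1",
    loops = list(loop_instance("history", "risk_factor", list(
      list(factor = "caffeine", present = TRUE)
    )))
  )
  rep <- validate_instance(bad_enum, risk_schema())
  expect_equal(rep$rule, "enum")

  # schema/instance mismatch is a usage error, not a violation
  expect_error(validate_instance(mri_instance(), reagent_schema()),
               class = "xr_usage_error")
})

test_that("random conforming instances pass; one mutation is reported at its path", {
  set.seed(4417)
  for (i in 1:25) {
    schema <- random_schema()
    inst <- random_instance(schema)
    expect_equal(nrow(validate_instance(inst, schema)), 0L)
    mut <- mutate_instance(inst, schema)
    rep <- validate_instance(mut$instance, schema)
    expect_gte(nrow(rep), 1L)
    expect_true(any(startsWith(rep$path, mut$expected_path)),
                label = paste0("violation at ", mut$expected_path,
                               " (", mut$mutation, ")"))
  }
})

test_that("file attachment honours the file_associated flag", {
  schema <- mri_schema()
  inst <- mri_instance()
  inst <- attach_file(inst, file_ref("xr://images/a.dcm"), schema)
  inst <- attach_file(inst, file_ref("xr://images/b.dcm"), schema)
  expect_equal(vapply(inst$files, `[[`, character(1), "uri"),
               c("xr://images/a.dcm", "xr://images/b.dcm"))

  clinical <- reagent_schema() # file_associated = FALSE
  expect_error(
    attach_file(reagent_instance(), file_ref("file:///tmp/x"), clinical),
    class = "xr_association_error"
  )
  expect_error(file_ref("not a uri"), class = "xr_structural_error")
})

test_that("the subject type has no slot for a personal name", {
  s <- subject("S1", "female", "1950-02-03", "Control")
  expect_setequal(names(s), c("subject_id", "sex", "birth_date", "diagnosis"))
  expect_false(any(grepl("name", names(s), ignore.case = TRUE)))
  expect_error(subject("S1", sex = "unknown"), class = "xr_structural_error")
  expect_error(subject(""), class = "xr_structural_error")
})

test_that("canonical value encodings are injective and normalized", {
  expect_identical(encode_value(1.50, "decimal"), "1.5")
  expect_identical(encode_value("3.0", "decimal"), "3")
  expect_identical(encode_value("-0.250", "decimal"), "-0.25")
  expect_identical(encode_value("+01.5", "decimal"), "1.5")
  expect_identical(encode_value(TRUE, "boolean"), "true")
  expect_identical(encode_value(as.Date("2010-03-02"), "date"), "2010-03-02")
  expect_identical(encode_value(42L, "integer"), "42")
  expect_true(is.na(encode_value("abc", "decimal")))
  expect_true(is.na(encode_value(1.5, "integer")))
  expect_true(is.na(encode_value("2010-13-40", "date")))

  set.seed(99)
  for (kind in c("integer", "decimal", "date", "boolean", "text")) {
    for (i in 1:20) {
      v <- random_value_of_kind(kind)
      enc <- encode_value(v, kind)
      expect_identical(encode_value(decode_value(enc, kind), kind), enc)
    }
  }
})
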