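test_that("bootstrapping installs the study data types idempotently", {
  store <- store_open()
  keys <- bootstrap_datatypes(store)
  expect_true(all(c("Clinical Evaluation@1", "Genetic Variant@1", "MRI@1",
                    "Serum Biomarker@1") %in% keys))
  expect_true("variant.gene" %in% list_fields(store, "Genetic Variant")$path)
  expect_true(load_schema(store, "MRI")$header$file_associated)
  factor_def <- schema_find_attribute(load_schema(store, "Clinical Evaluation"),
                                      "evaluation", "factor", loop = "risk_factor")
  expect_setequal(factor_def$allowed_values, c("smoke", "alchool", "sedentary job"))

  # second run adds no versions
  before <- nrow(store$tables$schemas)
  bootstrap_datatypes(store)
  expect_equal(nrow(store$tables$schemas), before)

  # a user-defined type under a fixture name is a listed collision
  clash <- store_open()
  save_schema(clash, define_datatype(
    schema_header("MRI", created_at = "2011-05-05T00:00:00Z"),
    list(metadata_group("other", list(attribute_def("x", "text"))))
  ))
  expect_error(bootstrap_datatypes(clash), regexp = "MRI",
               class = "xr_conflict_error")
})

test_that("cohort generation is deterministic per seed, down to the export", {
  spec <- cohort_spec(n_subjects = 8, seed = 1001)
  s1 <- store_open()
  s2 <- store_open()
  generate_cohort(s1, spec)
  generate_cohort(s2, spec)
  expect_identical(s1$tables$eav, s2$tables$eav)
  expect_identical(s1$tables$subjects, s2$tables$subjects)
  expect_identical(s1$tables$files, s2$tables$files)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  store_export(s1, d1)
  store_export(s2, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  for (f in list.files(file.path(d1, "instances"))) {
    expect_identical(readLines(file.path(d1, "instances", f)),
                     readLines(file.path(d2, "instances", f)))
  }

  # a different seed produces a different population
  s3 <- store_open()
  generate_cohort(s3, cohort_spec(n_subjects = 8, seed = 2002))
  expect_false(identical(s1$tables$eav, s3$tables$eav))
})

test_that("the generated cohort is internally valid", {
  store <- store_open()
  report <- generate_cohort(store, cohort_spec(n_subjects = 10, seed = 7))
  expect_equal(report$count[report$entity == "subjects"], 10L)
  expect_equal(report$count[report$entity == "samples"], 10L)

  # report counts equal store row counts per datatype
  for (dt in unique(store$tables$instances$datatype)) {
    expect_equal(
      report$count[report$entity == paste0("instances:", dt)],
      sum(store$tables$instances$datatype == dt)
    )
  }

  # every instance re-validates against its pinned schema
  for (iid in store$tables$instances$instance_id) {
    inst <- load_instance(store, iid)
    schema <- load_schema(store, inst$datatype, inst$version)
    expect_equal(nrow(validate_instance(inst, schema)), 0L)
  }
  # the dual representation is consistent and occupancy holds
  expect_equal(nrow(consistency_check(store)), 0L)
  located <- store$tables$samples[store$tables$samples$status == "located", ]
  coords <- paste(located$freezer_id, located$rack_id, located$slot,
                  located$x, located$y)
  expect_false(anyDuplicated(coords) > 0)
  # every located sample resolves to a stored subject
  expect_true(all(store$tables$samples$subject_id %in%
    store$tables$subjects$subject_id))
  # imaging instances carry repository URIs and acquisition events
  mri_ids <- store$tables$instances$instance_id[
    store$tables$instances$datatype == "MRI"
  ]
  expect_true(all(mri_ids %in% store$tables$files$instance_id))
  expect_true(all(startsWith(
    store$tables$files$uri[store$tables$files$instance_id %in% mri_ids],
    "xr://images/"
  )))
})
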