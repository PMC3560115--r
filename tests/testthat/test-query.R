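test_that("field listing enumerates the latest schema's paths", {
  store <- tiny_store()
  expect_equal(nrow(list_fields(store, "MRI")), 2L)
  reagent_fields <- list_fields(store, "Microarray Protocol")
  expect_equal(sum(!is.na(reagent_fields$loop)), 3L)
  expect_error(list_fields(store, "nope"), class = "xr_not_found_error")
})

test_that("composition validates paths and operators up front", {
  store <- tiny_store()
  expect_error(subject_condition("sex", "lt", "male"),
               class = "xr_composition_error")
  expect_error(subject_condition("shoe_size", "eq", 42),
               class = "xr_composition_error")
  expect_error(
    compose_query(store, data_conditions = list(
      data_condition("MRI", path = "acquisition.nope", operator = "eq", value = 1)
    )),
    class = "xr_composition_error"
  )
  expect_error(
    compose_query(store, data_conditions = list(
      data_condition("MRI", path = "acquisition.sequence", operator = "lt",
                     value = "x")
    )),
    class = "xr_composition_error"
  )
  expect_error(
    compose_query(store, data_conditions = list(data_condition("ghost"))),
    class = "xr_composition_error"
  )
  # a composed spec always executes
  spec <- compose_query(
    store,
    list(subject_condition("sex", "eq", "male")),
    list(data_condition("MRI", path = "acquisition.field_strength",
                        operator = "ge", value = 1))
  )
  expect_type(execute_query(store, spec), "character")
})

test_that("an empty specification matches every subject", {
  store <- tiny_store()
  spec <- compose_query(store)
  expect_equal(execute_query(store, spec), c("S1", "S2", "S3"))
  expect_equal(query_reference(store, spec), c("S1", "S2", "S3"))
})

test_that("conditions conjoin; each data condition is existential", {
  store <- tiny_store()
  males <- compose_query(store, list(subject_condition("sex", "eq", "male")))
  expect_equal(execute_query(store, males), c("S1", "S3"))

  with_mri <- compose_query(store, data_conditions = list(data_condition("MRI")))
  expect_equal(execute_query(store, with_mri), c("S1", "S3"))

  both <- compose_query(
    store,
    list(subject_condition("diagnosis", "contains", "amnestic")),
    list(data_condition("MRI"))
  )
  expect_equal(execute_query(store, both), "S3")

  # loop condition: some iteration matches
  loopy <- compose_query(store, data_conditions = list(
    data_condition("Microarray Protocol", path = "protocol.reagent.description",
                   operator = "contains", value = "buffer")
  ))
  expect_equal(execute_query(store, loopy), "S2")

  # adding a condition never enlarges the result set
  narrowed <- compose_query(
    store,
    list(subject_condition("diagnosis", "contains", "amnestic")),
    list(data_condition("MRI"),
         data_condition("Microarray Protocol"))
  )
  expect_true(all(execute_query(store, narrowed) %in% execute_query(store, both)))
})

test_that("EAV execution equals the reference scan on random stores and specs", {
  set.seed(8712)
  store <- store_open()
  schemas <- lapply(1:3, function(i) random_schema())
  for (s in schemas) save_schema(store, s)
  for (i in 1:30) {
    sid <- sprintf("R%02d", i)
    save_subject(store, subject(
      sid, sample(c("male", "female", "other/unknown"), 1),
      as.Date("1930-01-01") + sample(0:15000, 1),
      sample(c("Control", "Amnestic MCI", "Alzheimer's Disease"), 1)
    ))
    for (k in seq_len(sample(0:3, 1))) {
      save_instance(store, random_instance(sample(schemas, 1)[[1]], sid))
    }
  }
  for (i in 1:40) {
    spec <- random_query_spec(store)
    expect_identical(execute_query(store, spec), query_reference(store, spec))
  }
})

test_that("subject overviews group instances by data type", {
  store <- tiny_store()
  ov <- subject_overview(store, "S3")
  expect_s3_class(ov, "xr_overview")
  expect_equal(names(ov$sections), "MRI")
  expect_equal(length(unique(ov$sections$MRI$instance_id)), 1L)

  # subject with no data: empty sections, no error
  ov_empty <- subject_overview(store, "S2")
  expect_equal(names(ov_empty$sections), "Microarray Protocol")
  save_subject(store, subject("S4"))
  expect_equal(length(subject_overview(store, "S4")$sections), 0L)
  expect_error(subject_overview(store, "S99"), class = "xr_not_found_error")

  # section count equals per-datatype instance count
  save_instance(store, mri_instance("S3"))
  ov2 <- subject_overview(store, "S3")
  expect_equal(length(unique(ov2$sections$MRI$instance_id)), 2L)
  text <- format_overview_text(ov2)
  expect_true(any(grepl("== MRI \\(2 instance", text)))
  html <- format_overview_html(ov2)
  expect_true(grepl("<!DOCTYPE html>", html, fixed = TRUE))
})
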