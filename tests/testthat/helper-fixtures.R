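# Shared fixtures, built in code at test time.

# minimal imaging-style type: one group, two plain attributes
mri_schema <- function(name = "MRI") {
  define_datatype(
    schema_header(name, file_associated = TRUE, created_by = "tester",
                  created_at = "2010-01-01T00:00:00Z"),
    list(metadata_group("acquisition", list(
      attribute_def("field_strength", "decimal", required = TRUE, unit = "T"),
      attribute_def("sequence", "text")
    )))
  )
}

# microarray-style type: a loop recording description/concentration/amount
# for every used reagent
reagent_schema <- function() {
  define_datatype(
    schema_header("Microarray Protocol", created_at = "2010-01-01T00:00:00Z"),
    list(metadata_group("protocol", list(
      attribute_def("array_batch", "text"),
      loop_def("reagent", list(
        attribute_def("description", "text", required = TRUE),
        attribute_def("concentration", "decimal", required = TRUE),
        attribute_def("amount", "decimal", required = TRUE)
      ))
    )))
  )
}

# clinical type with the risk-factor loop (smoke / alchool / sedentary job)
risk_schema <- function() {
  define_datatype(
    schema_header("Clinical History", created_at = "2010-01-01T00:00:00Z"),
    list(metadata_group("history", list(
      loop_def("risk_factor", list(
        attribute_def("factor", "enumeration", required = TRUE,
                      allowed_values = c("smoke", "alchool", "sedentary job")),
        attribute_def("present", "boolean", required = TRUE)
      ))
    )))
  )
}

mri_instance <- function(subject_id = "SUBJ-001", version = 1L) {
  data_instance(
    "MRI", subject_id, version = version,
    values = list(
      attribute_value("acquisition", "field_strength", 1.5),
      attribute_value("acquisition", "sequence", "T1 MPRAGE")
    )
  )
}

reagent_instance <- function(subject_id = "SUBJ-001") {
  data_instance(
    "Microarray Protocol", subject_id,
    loops = list(loop_instance("protocol", "reagent", list(
      list(description = "Cy3 dye", concentration = 0.5, amount = 10),
      list(description = "Cy5 dye", concentration = 0.5, amount = 10),
      list(description = "hybridization buffer", concentration = 2, amount = 50)
    )))
  )
}

# a small populated store: two datatypes, three subjects, mixed instances
tiny_store <- function() {
  store <- store_open()
  save_schema(store, mri_schema())
  save_schema(store, reagent_schema())
  save_subject(store, subject("S1", "male", "1950-01-01", "Control"))
  save_subject(store, subject("S2", "female", "1940-06-15", "Alzheimer's Disease"))
  save_subject(store, subject("S3", "male", "1945-03-20", "Amnestic MCI"))
  save_instance(store, mri_instance("S1"))
  save_instance(store, mri_instance("S3"))
  save_instance(store, reagent_instance("S2"))
  store
}

# five-term OBO catalog written to a temp file
fixture_obo <- function() {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: XF:0000001", "name: assay",
    "",
    "[Term]", "id: XF:0000002", "name: Age at onset",
    "",
    "[Term]", "id: XF:0000003", "name: apolipoprotein measurement",
    "",
    "[Term]", "id: XF:0000004", "name: brain volume",
    "",
    "[Typedef]", "id: XF:9000001", "name: part_of",
    "",
    "[Term]", "id: XF:0000005", "name: diagnosis"
  ), path)
  path
}

# independent timeline oracle: flat scan of all events, keep those whose
# owning process has `root` among its ancestors, order by the path of
# sibling sequence numbers from the root
oracle_timeline_ids <- function(store, root) {
  procs <- store$tables$processes
  events <- store$tables$events
  path_of <- function(pid) {
    path <- integer()
    while (!is.na(pid)) {
      row <- procs[procs$process_id == pid, ]
      path <- c(row$seq, path)
      pid <- row$parent_id
    }
    path
  }
  in_subtree <- function(pid) {
    while (!is.na(pid)) {
      if (pid == root) return(TRUE)
      pid <- procs$parent_id[procs$process_id == pid]
    }
    FALSE
  }
  keep <- vapply(events$process_id, in_subtree, logical(1))
  evs <- events[keep, , drop = FALSE]
  if (!nrow(evs)) return(character())
  keys <- vapply(seq_len(nrow(evs)), function(i) {
    paste(sprintf("%09d", c(path_of(evs$process_id[i]), evs$seq[i])),
          collapse = "/")
  }, character(1))
  evs$event_id[order(keys, method = "radix")]
}
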