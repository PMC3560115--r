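imaging_store <- function() {
  store <- store_open()
  bootstrap_datatypes(store)
  save_subject(store, subject("S1", "male", "1950-01-01", "Control"))
  create_process(store, "visit", "Baseline visit", subject_id = "S1")
  store
}

write_mr_fixture <- function(path, tags = list()) {
  defaults <- list(
    StudyDate = "20100302", SeriesDescription = "T1 MPRAGE",
    EchoTime = "30", RepetitionTime = "2000"
  )
  defaults[names(tags)] <- tags
  write_synthetic_dicom(path, "MR", defaults)
  path
}

test_that("synthetic files round-trip through the header reader", {
  path <- withr::local_tempfile(fileext = ".dcm")
  write_mr_fixture(path, list(EchoTime = "30"))
  header <- read_dicom(path)
  expect_equal(header$value[match("Modality", header$keyword)], "MR")
  expect_equal(header$value[match("EchoTime", header$keyword)], "30")
  expect_equal(header$value[match("StudyDate", header$keyword)], "20100302")

  # randomized tag values come back exactly as written
  set.seed(37)
  for (i in 1:10) {
    tags <- list(
      StudyDate = format(as.Date("2009-01-01") + sample(0:700, 1), "%Y%m%d"),
      SeriesDescription = paste0("series ", sample(1000:9999, 1)),
      EchoTime = as.character(sample(5:120, 1)),
      RepetitionTime = as.character(sample(500:4000, 1))
    )
    p <- withr::local_tempfile(fileext = ".dcm")
    write_synthetic_dicom(p, "MR", tags)
    h <- read_dicom(p)
    for (k in names(tags)) {
      expect_equal(h$value[match(k, h$keyword)], tags[[k]], label = k)
    }
  }
  expect_error(write_synthetic_dicom(tempfile(), "CT"), class = "xr_usage_error")
})

test_that("the header layout is readable by an independent DICOM parser", {
  path <- withr::local_tempfile(fileext = ".dcm")
  write_mr_fixture(path, list(SeriesDescription = "cross check"))
  script <- paste(
    "import sys, pydicom",
    "d = pydicom.dcmread(sys.argv[1])",
    "print(d.Modality); print(d.SeriesDescription); print(d.EchoTime)",
    sep = "; "
  )
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(path)),
            stdout = TRUE, stderr = TRUE)
  )
  expect_equal(tail(out, 3), c("MR", "cross check", "30"))
})

test_that("distinct identifiers are generated for batches of files", {
  dir <- withr::local_tempdir()
  uids <- vapply(1:5, function(i) {
    p <- file.path(dir, paste0("f", i, ".dcm"))
    write_synthetic_dicom(p, "PT", list(Radiopharmaceutical = "18F-FDG"))
    h <- read_dicom(p)
    h$value[match("SOPInstanceUID", h$keyword)]
  }, character(1))
  expect_equal(length(unique(uids)), 5L)
})

test_that("modality detection maps codes and applies the functional-MR rule", {
  dir <- withr::local_tempdir()
  mr <- file.path(dir, "a.dcm")
  write_mr_fixture(mr)
  expect_equal(detect_modality(mr)$modality, "MRI")

  fmri <- file.path(dir, "b.dcm")
  write_mr_fixture(fmri, list(SeriesDescription = "resting state fMRI"))
  expect_equal(detect_modality(fmri)$modality, "fMRI")
  bold <- file.path(dir, "b2.dcm")
  write_mr_fixture(bold, list(SeriesDescription = "task BOLD run 1"))
  expect_equal(detect_modality(bold)$modality, "fMRI")

  pt <- file.path(dir, "c.dcm")
  write_synthetic_dicom(pt, "PT", list(Radiopharmaceutical = "18F-FDG"))
  expect_equal(detect_modality(pt)$modality, "PET")
  nm <- file.path(dir, "d.dcm")
  write_synthetic_dicom(nm, "NM", list())
  expect_equal(detect_modality(nm)$modality, "SPECT")

  # a text file renamed .dcm is rejected, not an error
  fake <- file.path(dir, "fake.dcm")
  writeLines("definitely not imaging data", fake)
  rejection <- detect_modality(fake)
  expect_s3_class(rejection, "xr_rejection")
  expect_match(rejection$reason, "not DICOM")

  # unmapped modality: drop the PET profile and present a PT file
  profiles <- default_modality_profiles()
  profiles$PET <- NULL
  rej2 <- detect_modality(pt, profiles)
  expect_s3_class(rej2, "xr_rejection")
  expect_match(rej2$reason, "unmapped")

  # unreadable path is an I/O error, distinct from rejection
  expect_error(detect_modality(file.path(dir, "missing.dcm")),
               class = "xr_io_error")
})

test_that("extraction converts values and enforces required tags", {
  dir <- withr::local_tempdir()
  mr <- file.path(dir, "a.dcm")
  write_mr_fixture(mr, list(EchoTime = "12.50"))
  profile <- default_modality_profiles()$MRI
  values <- extract_metadata(mr, profile)
  byname <- stats::setNames(values, vapply(values, `[[`, character(1), "attribute"))
  expect_equal(byname$study_date$value, as.Date("2010-03-02"))
  expect_equal(byname$echo_time$value, 12.5)

  # missing optional tag: skipped without error
  sparse <- file.path(dir, "sparse.dcm")
  write_synthetic_dicom(sparse, "MR", list(StudyDate = "20100302"))
  v2 <- extract_metadata(sparse, profile)
  expect_false("echo_time" %in% vapply(v2, `[[`, character(1), "attribute"))

  # missing required tag: extraction error naming the attribute
  strict <- profile
  strict$tag_map$required[strict$tag_map$keyword == "EchoTime"] <- TRUE
  expect_error(extract_metadata(sparse, strict), regexp = "echo_time",
               class = "xr_extraction_error")

  # unconvertible value for a decimal target
  bad <- file.path(dir, "bad.dcm")
  write_synthetic_dicom(bad, "MR", list(SliceThickness = "abc"))
  with_bad_map <- profile
  with_bad_map$tag_map <- rbind(with_bad_map$tag_map, tibble::tibble(
    keyword = "SliceThickness", group = "acquisition",
    attribute = "echo_time", kind = "decimal", required = FALSE
  ))
  expect_error(extract_metadata(bad, with_bad_map), class = "xr_extraction_error")

  # patient-identifying tags are never extracted, whatever the profile says
  leaky <- profile
  leaky$tag_map <- rbind(leaky$tag_map, tibble::tibble(
    keyword = "PatientName", group = "acquisition",
    attribute = "series_description", kind = "text", required = FALSE
  ))
  named <- file.path(dir, "named.dcm")
  write_synthetic_dicom(named, "MR", list(PatientName = "Doe^Jane",
                                          StudyDate = "20100302"))
  vals <- extract_metadata(named, leaky)
  expect_false(any(vapply(vals, function(v) identical(v$value, "Doe^Jane"),
                          logical(1))))
})

test_that("registration creates one instance and one modality event, atomically", {
  store <- imaging_store()
  proc <- store$tables$processes$process_id[1]
  dir <- withr::local_tempdir()
  mr <- write_mr_fixture(file.path(dir, "a.dcm"))

  out <- register_imaging(store, mr, "S1", proc, uri = "xr://images/a.dcm")
  inst <- load_instance(store, out$instance_id)
  expect_equal(inst$datatype, "MRI")
  expect_equal(inst$files[[1]]$uri, "xr://images/a.dcm")
  ev <- store$tables$events[store$tables$events$event_id == out$event_id, ]
  expect_equal(ev$type, "MRI acquisition")
  expect_equal(store$tables$event_data$instance_id[
    store$tables$event_data$event_id == out$event_id
  ], out$instance_id)

  # second file of the same subject: timeline ordered by insertion
  pt <- file.path(dir, "b.dcm")
  write_synthetic_dicom(pt, "PT", list(Radiopharmaceutical = "18F-FDG"))
  out2 <- register_imaging(store, pt, "S1", proc, uri = "xr://images/b.dcm")
  tl <- timeline(store, proc)
  expect_equal(tl$event_id, c(out$event_id, out2$event_id))
  expect_equal(tl$type, c("MRI acquisition", "PET acquisition"))

  # a rejected file leaves every table untouched
  fake <- file.path(dir, "fake.dcm")
  writeLines("nope", fake)
  counts <- vapply(store$tables, nrow, integer(1))
  expect_error(register_imaging(store, fake, "S1", proc),
               class = "xr_rejection_error")
  expect_identical(vapply(store$tables, nrow, integer(1)), counts)
  # so does a failure halfway through (unknown process: event creation fails)
  expect_error(register_imaging(store, mr, "S1", "P-404404"),
               class = "xr_not_found_error")
  expect_identical(vapply(store$tables, nrow, integer(1)), counts)
})
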