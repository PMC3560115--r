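## Synthetic study cohort.
##
## A seeded generator emulating a small multi-centre early-Alzheimer study:
## controls, amnestic-MCI and Alzheimer patients with clinical evaluations
## (including a risk-factor loop), a neuropsychological battery (Rey
## auditory-verbal delayed recall among them), candidate-gene variant
## screening, synthetic DICOM-backed imaging, and frozen blood samples
## tracked in a configured freezer. Attribute names and score ranges are
## test scaffolding modeled on that scenario, not claimed clinical
## standards. Everything is deterministic for a given seed, down to a
## byte-identical store export.

FIXTURE_TIMESTAMP <- "2010-01-01T00:00:00Z"
RISK_FACTORS <- c("smoke", "alchool", "sedentary job")
DIAGNOSIS_LABELS <- list(
  Control = "Control",
  aMCI = c("Single-domain Amnestic MCI", "Multi-domain Amnestic MCI"),
  AD = "Alzheimer's Disease"
)

fixture_header <- function(name, description, file_associated = FALSE) {
  schema_header(
    name, description = description, file_associated = file_associated,
    created_by = "fixture", created_at = FIXTURE_TIMESTAMP
  )
}

acquisition_group_mr <- function() {
  metadata_group("acquisition", list(
    attribute_def("study_date", "date"),
    attribute_def("series_description", "text"),
    attribute_def("echo_time", "decimal", unit = "ms"),
    attribute_def("repetition_time", "decimal", unit = "ms")
  ))
}

acquisition_group_nuclear <- function() {
  metadata_group("acquisition", list(
    attribute_def("study_date", "date"),
    attribute_def("series_description", "text"),
    attribute_def("radiopharmaceutical", "text")
  ))
}

fixture_schemas <- function() {
  list(
    define_datatype(
      fixture_header("Clinical Evaluation",
                     "clinical history and risk factors; no file association"),
      list(metadata_group("evaluation", list(
        attribute_def("visit_date", "date", required = TRUE),
        attribute_def("clinical_notes", "text"),
        loop_def("risk_factor", list(
          attribute_def("factor", "enumeration", required = TRUE,
                        allowed_values = RISK_FACTORS),
          attribute_def("present", "boolean", required = TRUE)
        ))
      )))
    ),
    define_datatype(
      fixture_header("Neuropsychological Tests", "neuropsychological battery"),
      list(metadata_group("battery", list(
        attribute_def("test_date", "date"),
        attribute_def("mmse", "integer"),
        attribute_def("rey_delayed_recall", "integer", required = TRUE),
        attribute_def("rey_immediate_recall", "integer")
      )))
    ),
    define_datatype(
      fixture_header("Genetic Variant", "variant found in a screened gene"),
      list(metadata_group("variant", list(
        attribute_def("gene", "text", required = TRUE),
        attribute_def("variant", "text", required = TRUE),
        attribute_def("status", "enumeration", required = TRUE,
                      allowed_values = c("known", "novel")),
        attribute_def("gene_url", "text"),
        attribute_def("variants_url", "text")
      )))
    ),
    define_datatype(
      fixture_header("Gene Screening Setup",
                     "genes to screen, their exons and relevant known variants"),
      list(metadata_group("setup", list(
        attribute_def("gene", "text", required = TRUE),
        loop_def("exon", list(
          attribute_def("exon_number", "integer", required = TRUE),
          attribute_def("primer", "text")
        )),
        loop_def("known_variant", list(
          attribute_def("variant", "text", required = TRUE),
          attribute_def("source", "text")
        ))
      )))
    ),
    define_datatype(
      fixture_header("MRI", "structural magnetic resonance imaging", TRUE),
      list(acquisition_group_mr())
    ),
    define_datatype(
      fixture_header("fMRI", "functional magnetic resonance imaging", TRUE),
      list(acquisition_group_mr())
    ),
    define_datatype(
      fixture_header("PET", "positron emission tomography", TRUE),
      list(acquisition_group_nuclear())
    ),
    define_datatype(
      fixture_header("SPECT", "single-photon emission computed tomography", TRUE),
      list(acquisition_group_nuclear())
    ),
    define_datatype(
      fixture_header("Serum Biomarker", "generic serum biomarker measurement"),
      list(metadata_group("measurement", list(
        attribute_def("marker", "text", required = TRUE),
        attribute_def("concentration", "decimal", required = TRUE),
        attribute_def("unit", "text")
      )))
    )
  )
}

FIXTURE_PROCESS_TYPES <- list(
  visit = list(description = "a subject visit", allowed_children = "study"),
  study = list(description = "a study within a visit", allowed_children = character())
)

FIXTURE_EVENT_TYPES <- c(
  "clinical evaluation", "neuropsychological assessment", "genetic screening",
  "blood draw", "MRI acquisition", "fMRI acquisition", "PET acquisition",
  "SPECT acquisition", "data upload"
)

#' Install the fixture data types and taxonomy
#'
#' Defines the study's data types (clinical evaluation with a risk-factor
#' loop, neuropsychological battery, genetic variant, gene screening setup,
#' the four imaging types, serum biomarker), the visit/study process types
#' and the event vocabulary. Idempotent: re-running adds nothing; a
#' pre-existing *different* data type under one of these names is a
#' conflict.
#'
#' @param store a store handle.
#' @return character vector of datatype keys (`name@version`), invisibly.
#' @export
bootstrap_datatypes <- function(store) {
  keys <- character()
  collisions <- character()
  for (schema in fixture_schemas()) {
    name <- schema$header$datatype_name
    existing <- tryCatch(load_schema(store, name, 1L),
                         xr_not_found_error = function(e) NULL)
    if (is.null(existing)) {
      keys <- c(keys, save_schema(store, schema))
    } else if (!identical(serialize_schema(existing), serialize_schema(schema))) {
      collisions <- c(collisions, name)
    } else {
      keys <- c(keys, paste0(name, "@1"))
    }
  }
  if (length(collisions)) {
    xr_abort(
      paste0("user-defined data type(s) collide with fixture names: ",
             paste(collisions, collapse = ", ")),
      "xr_conflict_error"
    )
  }
  for (tn in names(FIXTURE_PROCESS_TYPES)) {
    if (!tolower(tn) %in% tolower(store$tables$process_types$type_name)) {
      register_process_type(store, tn, FIXTURE_PROCESS_TYPES[[tn]]$description,
                            FIXTURE_PROCESS_TYPES[[tn]]$allowed_children)
    }
  }
  for (tn in FIXTURE_EVENT_TYPES) {
    if (!tolower(tn) %in% tolower(store$tables$event_types$type_name)) {
      register_event_type(store, tn)
    }
  }
  invisible(keys)
}

#' Describe a synthetic cohort
#'
#' @param n_subjects number of subjects (the study inserted a first set of
#'   20 patients; default matches).
#' @param diagnosis_mix proportions over Control / aMCI / AD; must sum to 1.
#' @param seed integer driving all randomness.
#' @param variant_genes candidate genes sampled for variant records.
#' @param rey_range integer score range of the delayed-recall measure.
#' @return an `xr_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L,
                        diagnosis_mix = c(Control = 0.35, aMCI = 0.40, AD = 0.25),
                        seed = 42L,
                        variant_genes = c("MAPT", "GRN", "APP", "PSEN1", "APOE"),
                        rey_range = 0:15) {
  if (n_subjects < 1L) {
    xr_abort("n_subjects must be >= 1", "xr_structural_error")
  }
  if (!setequal(names(diagnosis_mix), c("Control", "aMCI", "AD")) ||
    abs(sum(diagnosis_mix) - 1) > 1e-9) {
    xr_abort("diagnosis_mix must cover Control/aMCI/AD and sum to 1",
             "xr_structural_error")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), diagnosis_mix = diagnosis_mix,
         seed = as.integer(seed), variant_genes = variant_genes,
         rey_range = rey_range),
    class = "xr_cohort_spec"
  )
}

COHORT_FREEZER <- function(n_subjects = 20L) {
  # racks of 2 slots x 9x9 boxes (162 positions each); as many as the cohort needs
  n_racks <- max(1L, ceiling(n_subjects / 162))
  racks <- setNames(rep(2L, n_racks), sprintf("R%d", seq_len(n_racks)))
  freezer_layout("FRZ-GE-01", "-80C", racks = racks, box_grid = c(9L, 9L))
}

slot_for_position <- function(k) {
  # sequential fill of 2-slot x 9x9 racks R1, R2, ...
  per_box <- 81L
  per_rack <- 2L * per_box
  within <- (k - 1L) %% per_rack
  list(
    rack = sprintf("R%d", (k - 1L) %/% per_rack + 1L),
    slot = within %/% per_box + 1L,
    x = (within %% per_box) %% 9L + 1L,
    y = (within %% per_box) %/% 9L + 1L
  )
}

#' Generate a seeded synthetic cohort
#'
#' Populates the store with subjects (sex, birth date, diagnosis drawn from
#' the spec's mix), a visit/study process per subject, clinical +
#' neuropsychological + genetic instances attached to events, imaging
#' instances registered from synthetic DICOM files (with modality-dependent
#' events), and one placed blood sample per subject (every fourth shipped by
#' courier). Deterministic for a given seed: two runs into two stores export
#' byte-identically.
#'
#' @param store a store handle with [bootstrap_datatypes()] applied (applied
#'   automatically when missing).
#' @param spec an [cohort_spec()].
#' @param image_dir directory for the synthetic DICOM files (transient
#'   scratch; the store records deterministic `xr://images/...` URIs).
#' @return a population report: tibble of per-table/datatype counts.
#' @export
generate_cohort <- function(store, spec = cohort_spec(),
                            image_dir = tempfile("xr-dicom-")) {
  stopifnot(inherits(spec, "xr_cohort_spec"))
  bootstrap_datatypes(store)
  configure_freezer(store, COHORT_FREEZER(spec$n_subjects), replace = TRUE)
  dir.create(image_dir, recursive = TRUE, showWarnings = FALSE)
  mix <- spec$diagnosis_mix

  withr::with_seed(spec$seed, {
    placed <- 0L
    for (i in seq_len(spec$n_subjects)) {
      sid <- sprintf("SUBJ-%03d", i)
      category <- sample(names(mix), 1, prob = mix)
      diagnosis <- sample(DIAGNOSIS_LABELS[[category]], 1)
      birth <- as.Date("1928-01-01") + sample(0:11000, 1)
      sex <- sample(c("male", "female"), 1)
      save_subject(store, subject(sid, sex, birth, diagnosis))
      visit_date <- as.Date("2010-03-01") + i
      visit_iso <- format(visit_date, "%Y-%m-%d")
      ts <- function(h) paste0(visit_iso, "T", sprintf("%02d", h), ":00:00Z")

      visit <- create_process(store, "visit", paste0("Baseline visit ", sid),
                              subject_id = sid, started_at = ts(8))
      study <- create_process(store, "study", "Baseline assessment",
                              parent = visit, subject_id = sid)

      # clinical evaluation with the risk-factor loop
      smoker <- stats::runif(1) < 0.4
      risk <- lapply(RISK_FACTORS, function(f) {
        list(factor = f, present = if (f == "smoke") smoker else stats::runif(1) < 0.35)
      })
      clin <- data_instance(
        "Clinical Evaluation", sid,
        values = list(attribute_value("evaluation", "visit_date", visit_date)),
        loops = list(loop_instance("evaluation", "risk_factor", risk))
      )
      clin_id <- save_instance(store, clin)
      add_event(store, study, "clinical evaluation", occurred_at = ts(9),
                data = clin_id)

      # neuropsychological battery, diagnosis-dependent score ranges
      rey_pool <- switch(category,
        Control = intersect(spec$rey_range, 6:15),
        aMCI = intersect(spec$rey_range, 2:10),
        AD = intersect(spec$rey_range, 0:7)
      )
      npsy <- data_instance(
        "Neuropsychological Tests", sid,
        values = list(
          attribute_value("battery", "test_date", visit_date),
          attribute_value("battery", "mmse", switch(category,
            Control = sample(26:30, 1), aMCI = sample(22:28, 1),
            AD = sample(12:24, 1)
          )),
          attribute_value("battery", "rey_delayed_recall", sample(rey_pool, 1)),
          attribute_value("battery", "rey_immediate_recall", sample(15:60, 1))
        )
      )
      npsy_id <- save_instance(store, npsy)
      add_event(store, study, "neuropsychological assessment",
                occurred_at = ts(10), data = npsy_id)

      # genetic screening: 0-2 candidate-gene variants
      n_var <- sample(0:2, 1)
      var_ids <- character()
      genes <- sample(spec$variant_genes, n_var)
      for (g in genes) {
        v <- data_instance(
          "Genetic Variant", sid,
          values = list(
            attribute_value("variant", "gene", g),
            attribute_value("variant", "variant",
                            sprintf("c.%dC>T", sample(100:2000, 1))),
            attribute_value("variant", "status",
                            sample(c("known", "novel"), 1, prob = c(0.8, 0.2))),
            attribute_value("variant", "gene_url",
                            paste0("https://www.ncbi.nlm.nih.gov/gene/?term=", g)),
            attribute_value("variant", "variants_url",
                            paste0("https://www.molgen.vib-ua.be/ADMutations/gene/",
                                   g, "#variants"))
          )
        )
        var_ids <- c(var_ids, save_instance(store, v))
      }
      if (length(var_ids)) {
        add_event(store, study, "genetic screening", occurred_at = ts(11),
                  data = var_ids)
      }

      # imaging: structural MRI (most subjects), FDG-PET (about half),
      # resting-state fMRI (a quarter)
      study_date_tag <- format(visit_date, "%Y%m%d")
      img <- 0L
      register <- function(modality_code, tags, label) {
        img <<- img + 1L
        fname <- sprintf("%s-%s.dcm", sid, label)
        fpath <- file.path(image_dir, fname)
        write_synthetic_dicom(
          fpath, modality_code, tags,
          sop_instance_uid = paste(UID_ROOT, spec$seed, i, img, sep = ".")
        )
        register_imaging(store, fpath, sid, study,
                         uri = paste0("xr://images/", fname),
                         occurred_at = ts(12L + img))
      }
      if (stats::runif(1) < 0.85) {
        register("MR", list(
          StudyDate = study_date_tag, SeriesDescription = "T1 MPRAGE sagittal",
          EchoTime = format(round(stats::runif(1, 2, 5), 1)),
          RepetitionTime = format(round(stats::runif(1, 1800, 2500)))
        ), "mri")
      }
      if (stats::runif(1) < 0.5) {
        register("PT", list(
          StudyDate = study_date_tag, SeriesDescription = "FDG brain",
          Radiopharmaceutical = "18F-FDG"
        ), "pet")
      }
      if (stats::runif(1) < 0.25) {
        register("MR", list(
          StudyDate = study_date_tag,
          SeriesDescription = "resting state fMRI EPI",
          EchoTime = "30", RepetitionTime = "2000"
        ), "fmri")
      }

      # occasional serum biomarker measurement
      if (stats::runif(1) < 0.3) {
        serum <- data_instance(
          "Serum Biomarker", sid,
          values = list(
            attribute_value("measurement", "marker", "generic serum biomarker"),
            attribute_value("measurement", "concentration",
                            round(stats::runif(1, 0.1, 40), 2)),
            attribute_value("measurement", "unit", "ng/mL")
          )
        )
        save_instance(store, serum)
      }

      # blood sample, frozen and tracked; every fourth shipped by courier
      sample_id <- sprintf("SAMP-%03d", i)
      register_sample(store, sample_id, "blood", sid, timestamp = ts(14))
      placed <- placed + 1L
      pos <- slot_for_position(placed)
      place_sample(store, sample_id, "FRZ-GE-01", pos$rack, pos$slot, pos$x,
                   pos$y, timestamp = ts(15))
      add_event(store, visit, "blood draw", occurred_at = ts(14))
      if (i %% 4L == 0L) {
        register_shipment(store, sample_id, sprintf("CN-%05d", 77000L + i),
                          timestamp = ts(16))
      }
    }
  })
  cohort_report(store)
}

#' Per-table population report of a store
#'
#' @param store a store handle.
#' @return a tibble `entity`, `count`: subjects, samples, processes, events,
#'   and instances per data type.
#' @export
cohort_report <- function(store) {
  tabs <- store$tables
  per_type <- tabs$instances |>
    group_by(entity = paste0("instances:", .data$datatype)) |>
    summarise(count = n(), .groups = "drop")
  bind_rows(
    tibble(entity = "subjects", count = nrow(tabs$subjects)),
    tibble(entity = "samples", count = nrow(tabs$samples)),
    tibble(entity = "processes", count = nrow(tabs$processes)),
    tibble(entity = "events", count = nrow(tabs$events)),
    per_type |> arrange(.data$entity)
  )
}
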