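## Automatic metadata extraction for imaging data types.
##
## A modality profile maps DICOM header tags onto the attribute paths of a
## file-associated data type and names the event type created on upload.
## Registration is atomic: either one validated instance plus one modality
## event land in the store, or nothing does. Patient-identifying DICOM tags
## (PatientName, PatientID) are never extracted, whatever the profile says —
## subjects are known by anonymous identifiers only.

EXCLUDED_KEYWORDS <- c("PatientName", "PatientID")

#' Describe a modality profile
#'
#' @param modality one of `"MRI"`, `"fMRI"`, `"PET"`, `"SPECT"`.
#' @param datatype_name the target (file-associated) data type.
#' @param event_type event type created when a file of this modality is
#'   registered.
#' @param tag_map a data frame with columns `keyword` (DICOM keyword),
#'   `group`, `attribute` (target path), `kind` (target value kind) and
#'   `required`.
#' @return an `xr_modality_profile`.
#' @export
modality_profile <- function(modality, datatype_name, event_type, tag_map) {
  stopifnot(modality %in% c("MRI", "fMRI", "PET", "SPECT"))
  tag_map <- as_tibble(tag_map)
  stopifnot(all(c("keyword", "group", "attribute", "kind", "required") %in%
    names(tag_map)))
  structure(
    list(modality = modality, datatype_name = datatype_name,
         event_type = event_type, tag_map = tag_map),
    class = "xr_modality_profile"
  )
}

mr_tag_map <- tibble::tribble(
  ~keyword,            ~group,        ~attribute,           ~kind,     ~required,
  "StudyDate",         "acquisition", "study_date",         "date",    FALSE,
  "SeriesDescription", "acquisition", "series_description", "text",    FALSE,
  "EchoTime",          "acquisition", "echo_time",          "decimal", FALSE,
  "RepetitionTime",    "acquisition", "repetition_time",    "decimal", FALSE
)

nuclear_tag_map <- tibble::tribble(
  ~keyword,             ~group,        ~attribute,            ~kind,  ~required,
  "StudyDate",          "acquisition", "study_date",          "date", FALSE,
  "SeriesDescription",  "acquisition", "series_description",  "text", FALSE,
  "Radiopharmaceutical", "acquisition", "radiopharmaceutical", "text", FALSE
)

#' The default modality profile set
#'
#' MR maps to the MRI data type (or fMRI when the series description matches
#' `fmri_pattern`), PT to PET and NM to SPECT, with a minimal tag map
#' (study date, series description, echo/repetition time for MR,
#' radiopharmaceutical for PT/NM). User-extensible: pass your own list to
#' [detect_modality()] / [register_imaging()].
#'
#' @param fmri_pattern case-insensitive regular expression on
#'   SeriesDescription distinguishing functional from structural MR; the
#'   imaging standard itself has no functional-MRI modality code.
#' @return named list of [modality_profile()] objects keyed by modality.
#' @export
default_modality_profiles <- function(fmri_pattern = "fmri|bold") {
  profiles <- list(
    MRI = modality_profile("MRI", "MRI", "MRI acquisition", mr_tag_map),
    fMRI = modality_profile("fMRI", "fMRI", "fMRI acquisition", mr_tag_map),
    PET = modality_profile("PET", "PET", "PET acquisition", nuclear_tag_map),
    SPECT = modality_profile("SPECT", "SPECT", "SPECT acquisition",
                             nuclear_tag_map)
  )
  attr(profiles, "fmri_pattern") <- fmri_pattern
  profiles
}

#' Detect the modality of an uploaded file
#'
#' Reads the file's Modality tag and maps it through the profile set
#' (MR -> MRI or fMRI by the series-description rule, PT -> PET,
#' NM -> SPECT). Non-DICOM input or an unmapped modality yields a rejection
#' (class `xr_rejection`), distinct from an I/O error on an unreadable path.
#'
#' @param path the uploaded file.
#' @param profiles a profile set (see [default_modality_profiles()]).
#' @return the matching `xr_modality_profile`, or an `xr_rejection` with a
#'   `reason`.
#' @export
detect_modality <- function(path, profiles = default_modality_profiles()) {
  header <- tryCatch(
    read_dicom(path),
    xr_dicom_format_error = function(e) e
  )
  if (inherits(header, "error")) {
    return(structure(
      list(reason = paste0("not DICOM: ", conditionMessage(header))),
      class = "xr_rejection"
    ))
  }
  modality_code <- header$value[match("Modality", header$keyword)]
  if (is.na(modality_code)) {
    return(structure(list(reason = "no Modality tag"), class = "xr_rejection"))
  }
  target <- switch(modality_code,
    MR = {
      pattern <- attr(profiles, "fmri_pattern") %||% "fmri|bold"
      series <- header$value[match("SeriesDescription", header$keyword)]
      if (!is.na(series) && grepl(pattern, series, ignore.case = TRUE)) {
        "fMRI"
      } else {
        "MRI"
      }
    },
    PT = "PET",
    NM = "SPECT",
    NULL
  )
  if (is.null(target) || is.null(profiles[[target]])) {
    return(structure(
      list(reason = paste0("unmapped modality '", modality_code, "'")),
      class = "xr_rejection"
    ))
  }
  profiles[[target]]
}

#' Extract metadata from a DICOM file through a modality profile
#'
#' One attribute value per mapped tag present in the header; missing optional
#' tags are skipped, a missing required tag is an extraction error. Values
#' are converted to the target attribute kind (DICOM `DA` dates become
#' ISO-8601, decimal strings are normalized). Patient-identifying tags are
#' never extracted.
#'
#' @param path the DICOM file.
#' @param profile an `xr_modality_profile` matching the file's modality.
#' @return a list of [attribute_value()] objects.
#' @export
extract_metadata <- function(path, profile) {
  stopifnot(inherits(profile, "xr_modality_profile"))
  header <- read_dicom(path)
  values <- list()
  for (i in seq_len(nrow(profile$tag_map))) {
    row <- profile$tag_map[i, ]
    if (row$keyword %in% EXCLUDED_KEYWORDS) next
    raw_value <- header$value[match(row$keyword, header$keyword)]
    if (is.na(raw_value) || !nzchar(raw_value)) {
      if (row$required) {
        xr_abort(
          paste0("required tag ", row$keyword, " (for attribute '",
                 row$group, ".", row$attribute, "') missing from '", path, "'"),
          "xr_extraction_error"
        )
      }
      next
    }
    converted <- convert_dicom_value(raw_value, row$kind)
    if (is.na(converted[1]) && row$kind != "text") {
      xr_abort(
        paste0("tag ", row$keyword, " value '", raw_value,
               "' cannot be converted to ", row$kind, " for attribute '",
               row$group, ".", row$attribute, "'"),
        "xr_extraction_error"
      )
    }
    values[[length(values) + 1L]] <-
      attribute_value(row$group, row$attribute, converted)
  }
  values
}

convert_dicom_value <- function(value, kind) {
  if (kind == "date" && grepl("^[0-9]{8}$", value)) {
    value <- paste(substr(value, 1, 4), substr(value, 5, 6),
                   substr(value, 7, 8), sep = "-")
  }
  enc <- encode_value(value, kind)
  if (is.na(enc)) {
    return(NA)
  }
  decode_value(enc, kind)
}

# run several store mutations as one atomic unit
with_store_transaction <- function(store, expr) {
  tabs <- store$tables
  counters <- store$counters
  tryCatch(
    force(expr),
    error = function(e) {
      store$tables <- tabs
      store$counters <- counters
      stop(e)
    }
  )
}

#' Register an imaging file: instance plus modality event, atomically
#'
#' Detects the modality, extracts the mapped metadata, creates a validated
#' data instance of the profile's data type with the file URI attached, and
#' adds an event of the profile's event type to the given process, linked to
#' the instance. Any failure (rejection, extraction error, validation error)
#' leaves the store untouched.
#'
#' @param store a store handle.
#' @param path the DICOM file.
#' @param subject_id owning subject (must exist).
#' @param process_id process receiving the acquisition event.
#' @param profiles profile set for detection.
#' @param uri URI recorded for the file; defaults to `file://<absolute path>`.
#' @param occurred_at event timestamp.
#' @return list with `instance_id` and `event_id`.
#' @export
register_imaging <- function(store, path, subject_id, process_id,
                             profiles = default_modality_profiles(),
                             uri = NULL, occurred_at = NA) {
  profile <- detect_modality(path, profiles)
  if (inherits(profile, "xr_rejection")) {
    xr_abort(paste0("file rejected: ", profile$reason), "xr_rejection_error")
  }
  values <- extract_metadata(path, profile)
  schema <- load_schema(store, profile$datatype_name)
  uri <- uri %||% paste0("file://", normalizePath(path, winslash = "/"))
  instance <- data_instance(
    datatype = profile$datatype_name, subject_id = subject_id,
    values = values, version = schema$header$version
  )
  instance <- attach_file(instance, file_ref(uri, declared_format = "DICOM"),
                          schema)
  with_store_transaction(store, {
    iid <- save_instance(store, instance)
    eid <- add_event(store, process_id, profile$event_type,
                     occurred_at = occurred_at, data = iid)
    list(instance_id = iid, event_id = eid)
  })
}
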