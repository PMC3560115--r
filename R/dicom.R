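## Minimal DICOM support: explicit-VR little-endian read and write of header
## elements. This is deliberately small — enough to write valid synthetic
## fixture files and to read back the header tags the metadata extractor
## maps. No pixel data, no sequences, no other transfer syntaxes.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
UID_ROOT <- "1.2.826.0.1.3680043.10.424" # generic org root for synthetic UIDs

# the tag dictionary the engine knows; group/element in hex
DICOM_DICT <- tibble::tribble(
  ~keyword,                  ~group,  ~element, ~vr,
  "SOPClassUID",             0x0008L, 0x0016L,  "UI",
  "SOPInstanceUID",          0x0008L, 0x0018L,  "UI",
  "StudyDate",               0x0008L, 0x0020L,  "DA",
  "Modality",                0x0008L, 0x0060L,  "CS",
  "Manufacturer",            0x0008L, 0x0070L,  "LO",
  "StudyDescription",        0x0008L, 0x1030L,  "LO",
  "SeriesDescription",       0x0008L, 0x103EL,  "LO",
  "PatientName",             0x0010L, 0x0010L,  "PN",
  "PatientID",               0x0010L, 0x0020L,  "LO",
  "Radiopharmaceutical",     0x0018L, 0x0031L,  "LO",
  "SliceThickness",          0x0018L, 0x0050L,  "DS",
  "RepetitionTime",          0x0018L, 0x0080L,  "DS",
  "EchoTime",                0x0018L, 0x0081L,  "DS",
  "MagneticFieldStrength",   0x0018L, 0x0087L,  "DS"
)

uint16_le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

encode_element <- function(group, element, vr, value) {
  bytes <- if (is.raw(value)) value else charToRaw(enc2utf8(as.character(value)))
  if (length(bytes) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  header <- c(uint16_le(group), uint16_le(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(header, as.raw(c(0L, 0L)), uint32_le(length(bytes)), bytes)
  } else {
    c(header, uint16_le(length(bytes)), bytes)
  }
}

#' Write a synthetic DICOM file
#'
#' Produces a minimal, standard-conformant DICOM Part 10 file (128-byte
#' preamble, `DICM` magic, explicit-VR little-endian) whose header contains
#' exactly the given tags. Used as the fixture generator for the metadata
#' extractor; files contain no pixel data and no real patient information.
#'
#' @param path destination file.
#' @param modality DICOM modality code: `"MR"`, `"PT"` or `"NM"`.
#' @param tags named list of tag values keyed by DICOM keyword (see
#'   `xrepo:::DICOM_DICT`), e.g. `list(EchoTime = "30", StudyDate = "20100302")`.
#' @param sop_instance_uid optional unique instance identifier; generated
#'   (uniquely per call) when omitted.
#' @return `path`, invisibly.
#' @export
write_synthetic_dicom <- function(path, modality, tags = list(),
                                  sop_instance_uid = NULL) {
  if (!modality %in% c("MR", "PT", "NM")) {
    xr_abort(paste0("unsupported modality code '", modality, "'"), "xr_usage_error")
  }
  sop_instance_uid <- sop_instance_uid %||% synthetic_uid()
  dataset_tags <- c(
    list(
      SOPClassUID = SOP_CLASS_SECONDARY_CAPTURE,
      SOPInstanceUID = sop_instance_uid,
      Modality = modality
    ),
    tags
  )
  dataset_tags <- dataset_tags[!duplicated(names(dataset_tags))]
  unknown <- setdiff(names(dataset_tags), DICOM_DICT$keyword)
  if (length(unknown)) {
    xr_abort(paste0("unknown DICOM keyword(s): ", paste(unknown, collapse = ", ")),
             "xr_usage_error")
  }
  dict <- DICOM_DICT[match(names(dataset_tags), DICOM_DICT$keyword), ]
  ord <- order(dict$group, dict$element)
  dataset <- unlist(lapply(ord, function(i) {
    encode_element(dict$group[i], dict$element[i], dict$vr[i], dataset_tags[[i]])
  }))

  meta_elements <- c(
    encode_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    encode_element(0x0002L, 0x0002L, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    encode_element(0x0002L, 0x0003L, "UI", sop_instance_uid),
    encode_element(0x0002L, 0x0010L, "UI", TRANSFER_SYNTAX_EXPLICIT_LE)
  )
  # (0002,0000) holds the byte length of the remaining meta group
  meta <- c(
    c(uint16_le(0x0002L), uint16_le(0x0000L), charToRaw("UL"), uint16_le(4L),
      uint32_le(length(meta_elements))),
    meta_elements
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

# process-unique UID: root + pid + time + counter
synthetic_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste(UID_ROOT, Sys.getpid(),
          as.integer(Sys.time()) %% 100000L, counter, sep = ".")
  }
})

#' Read the header of a DICOM file
#'
#' Reads explicit-VR little-endian data elements (the only transfer syntax
#' the synthetic writer emits) and resolves known tags to keywords.
#'
#' @param path a DICOM file.
#' @return a tibble `group`, `element`, `vr`, `keyword` (`NA` if not in the
#'   dictionary), `value` (trimmed string).
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) {
    xr_abort(paste0("cannot read '", path, "'"), "xr_io_error")
  }
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 132L ||
    !identical(rawToChar(bytes[129:132]), "DICM")) {
    xr_abort(paste0("'", path, "' is not a DICOM file (missing DICM magic)"),
             "xr_dicom_format_error")
  }
  pos <- 133L
  rows <- list()
  n <- length(bytes)
  u16 <- function(at) {
    readBin(bytes[at:(at + 1L)], integer(), size = 2, endian = "little",
            signed = FALSE)
  }
  u32 <- function(at) {
    readBin(bytes[at:(at + 3L)], integer(), size = 4, endian = "little")
  }
  while (pos + 7L <= n) {
    group <- u16(pos)
    element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      xr_abort(
        paste0("'", path, "' is not explicit-VR little-endian (offset ", pos, ")"),
        "xr_dicom_format_error"
      )
    }
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      value_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      value_at <- pos + 8L
    }
    if (value_at + len - 1L > n) break
    value <- if (len > 0L) {
      chunk <- bytes[value_at:(value_at + len - 1L)]
      rawToChar(chunk[chunk != as.raw(0L)])
    } else {
      ""
    }
    rows[[length(rows) + 1L]] <- tibble(
      group = group, element = element, vr = vr,
      value = trimws(value)
    )
    pos <- value_at + len
  }
  out <- if (length(rows)) {
    bind_rows(rows)
  } else {
    tibble(group = integer(), element = integer(), vr = character(),
           value = character())
  }
  out$keyword <- DICOM_DICT$keyword[
    match(paste(out$group, out$element), paste(DICOM_DICT$group, DICOM_DICT$element))
  ]
  out[, c("group", "element", "vr", "keyword", "value")]
}
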