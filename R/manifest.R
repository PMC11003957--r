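MANIFEST_COLS <- c("slide_id", "patient_id", "cohort", "specimen_type",
  "pixel_spacing_um", "cms_label", "qc_pass")

LABEL_LEVELS <- c(CMS_CLASSES, "unlabeled")
SPECIMEN_TYPES <- c("resection", "biopsy")

#' Read and validate a slide manifest
#'
#' The manifest is the per-slide table driving the pipeline: one row per
#' slide with its patient, cohort, specimen type (`resection` or `biopsy`),
#' native pixel spacing in micrometres per pixel, transcriptional CMS label
#' (`CMS1`..`CMS4` or `unlabeled`) and a manual quality-control flag.
#' Every invariant violation is reported with the offending row index.
#'
#' @param path Path to a CSV file with columns `slide_id`, `patient_id`,
#'   `cohort`, `specimen_type`, `pixel_spacing_um`, `cms_label`, `qc_pass`.
#' @return A tibble of validated slide records.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(tibble::as_tibble(df))
}

#' @rdname read_manifest
#' @param manifest A manifest tibble (e.g. from [synth_cohort()]).
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @export
validate_manifest <- function(manifest) {
  missing <- setdiff(MANIFEST_COLS, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("Manifest is missing column(s): ", paste(missing, collapse = ", ")),
      class = "cms_schema_error")
  }
  m <- tibble::as_tibble(manifest)[MANIFEST_COLS]
  m$slide_id <- as.character(m$slide_id)
  m$patient_id <- as.character(m$patient_id)
  m$cohort <- as.character(m$cohort)
  m$specimen_type <- as.character(m$specimen_type)
  m$cms_label <- as.character(m$cms_label)
  m$qc_pass <- as.logical(m$qc_pass)
  m$pixel_spacing_um <- as.numeric(m$pixel_spacing_um)

  fail <- function(rows, what) {
    abort(sprintf("Manifest row(s) %s: %s", paste(rows, collapse = ", "), what),
      class = "cms_validation_error")
  }
  dup <- m$slide_id[duplicated(m$slide_id)]
  if (length(dup) > 0) {
    fail(which(m$slide_id %in% dup), paste0("duplicated slide_id ",
      paste(unique(dup), collapse = ", ")))
  }
  bad <- which(!m$specimen_type %in% SPECIMEN_TYPES)
  if (length(bad) > 0) fail(bad, "specimen_type must be 'resection' or 'biopsy'")
  bad <- which(!m$cms_label %in% LABEL_LEVELS)
  if (length(bad) > 0) {
    fail(bad, paste0("cms_label must be one of ", paste(LABEL_LEVELS, collapse = ", ")))
  }
  bad <- which(!is.finite(m$pixel_spacing_um) | m$pixel_spacing_um <= 0)
  if (length(bad) > 0) fail(bad, "pixel_spacing_um must be a positive real")
  bad <- which(is.na(m$qc_pass))
  if (length(bad) > 0) fail(bad, "qc_pass must be TRUE or FALSE")
  m
}
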