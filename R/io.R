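# Cohort I/O: NIfTI volumes/masks plus a CSV manifest, with strict
# validation. Geometry mismatches are rejected, never silently resampled.

VALID_STAGES <- c("I", "II", "IV")
VALID_SUBTYPES <- c("GCB", "nonGCB")

#' Classify interim response from the Deauville score
#'
#' Complete response (CR) under the PET-based Lugano criteria is a
#' Deauville 5-point score of 1--3, with or without a residual mass, and no
#' FDG-avid disease in the bone marrow. Everything else is non-CR.
#'
#' @param deauville Integer score(s) in 1..5.
#' @param marrow_fdg_avid Logical: FDG-avid marrow disease present?
#'   Defaults to `FALSE`.
#' @return Character vector, `"CR"` or `"nonCR"`.
#' @examples
#' classify_response(3, FALSE)  # "CR"
#' classify_response(4, FALSE)  # "nonCR"
#' classify_response(2, TRUE)   # "nonCR": marrow involvement overrides
#' @export
classify_response <- function(deauville, marrow_fdg_avid = FALSE) {
  deauville <- as.integer(deauville)
  if (anyNA(deauville) || any(deauville < 1L | deauville > 5L)) {
    pettex_error("Deauville score must be an integer in 1..5",
                 "pettex_domain_error")
  }
  marrow_fdg_avid <- rep_len(as.logical(marrow_fdg_avid), length(deauville))
  ifelse(deauville <= 3L & !marrow_fdg_avid, "CR", "nonCR")
}

#' Assemble and validate a patient record
#'
#' Bundles a patient's PET volume and 3-D masks (two readers), single-slice
#' CT and 2-D masks, and clinical covariates. The response label, if not
#' supplied, is derived from the Deauville score via [classify_response()].
#'
#' @param id Patient identifier (string).
#' @param pet,ct_slice [image_volume()] objects; the CT slice must have
#'   z-extent 1.
#' @param pet_mask,pet_mask_reader2,ct_mask,ct_mask_reader2 [roi_mask()]
#'   objects congruent with their image.
#' @param stage Lugano stage, one of `"I"`, `"II"`, `"IV"`.
#' @param ipi International Prognostic Index, 0..5.
#' @param intestinal_involvement Logical.
#' @param ki67_percent Ki67 proliferation index in percent, 0..100.
#' @param subtype `"GCB"` or `"nonGCB"`.
#' @param deauville Interim Deauville score 1..5.
#' @param marrow_fdg_avid Logical; defaults to `FALSE` (no marrow-driven
#'   reclassification).
#' @param response Optional `"CR"`/`"nonCR"`; defaults to the classification
#'   rule applied to `deauville` and `marrow_fdg_avid`.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(id, pet, pet_mask, pet_mask_reader2,
                           ct_slice, ct_mask, ct_mask_reader2,
                           stage, ipi, intestinal_involvement,
                           ki67_percent, subtype, deauville,
                           marrow_fdg_avid = FALSE, response = NULL) {
  id <- as.character(id)
  check_congruent(pet, pet_mask, sprintf("PET mask of patient %s", id))
  check_congruent(pet, pet_mask_reader2,
                  sprintf("PET reader-2 mask of patient %s", id))
  if (dim(ct_slice$values)[1] != 1L) {
    pettex_error(sprintf("CT of patient %s must be a single slice", id),
                 "pettex_geometry_error")
  }
  check_congruent(ct_slice, ct_mask, sprintf("CT mask of patient %s", id))
  check_congruent(ct_slice, ct_mask_reader2,
                  sprintf("CT reader-2 mask of patient %s", id))
  stage <- match.arg(as.character(stage), VALID_STAGES)
  subtype <- match.arg(as.character(subtype), VALID_SUBTYPES)
  ipi <- as.integer(ipi)
  if (is.na(ipi) || ipi < 0L || ipi > 5L) {
    pettex_error(sprintf("IPI of patient %s outside 0..5", id),
                 "pettex_domain_error")
  }
  deauville <- as.integer(deauville)
  if (is.na(deauville) || deauville < 1L || deauville > 5L) {
    pettex_error(sprintf("Deauville score of patient %s outside 1..5", id),
                 "pettex_domain_error")
  }
  ki67_percent <- as.numeric(ki67_percent)
  if (is.na(ki67_percent) || ki67_percent < 0 || ki67_percent > 100) {
    pettex_error(sprintf("Ki67 of patient %s outside 0..100", id),
                 "pettex_domain_error")
  }
  if (is.null(response)) {
    response <- classify_response(deauville, marrow_fdg_avid)
  } else {
    response <- match.arg(as.character(response), c("CR", "nonCR"))
  }
  structure(list(
    id = id, pet = pet, pet_mask = pet_mask,
    pet_mask_reader2 = pet_mask_reader2,
    ct_slice = ct_slice, ct_mask = ct_mask,
    ct_mask_reader2 = ct_mask_reader2,
    stage = stage, ipi = ipi,
    intestinal_involvement = as.logical(intestinal_involvement),
    ki67_percent = ki67_percent, subtype = subtype,
    deauville = deauville, marrow_fdg_avid = as.logical(marrow_fdg_avid),
    response = response), class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(
    "patient %s: stage %s, IPI %d, Deauville %d -> %s; PET %s (%d vox ROI)\n",
    x$id, x$stage, x$ipi, x$deauville, x$response,
    paste(dim(x$pet$values), collapse = "x"), sum(x$pet_mask$flags)))
  invisible(x)
}

# internal: write a volume as NIfTI with spacing in the header.
# Arrays are (z,y,x) internally; NIfTI stores (x,y,z).
write_volume_nifti <- function(vol, path, datatype = "double") {
  arr <- aperm(vol$values, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(vol$spacing_mm)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_volume_nifti <- function(path) {
  if (!file.exists(path)) {
    pettex_error(sprintf("image file not found: %s", path),
                 "pettex_missing_file_error")
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  # NIfTI drops trailing singleton dimensions (single-slice CT)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L) spacing <- c(spacing, 1)[1:3]
  image_volume(aperm(arr, c(3, 2, 1)), rev(spacing[1:3]))
}

read_mask_nifti <- function(path) {
  vol <- read_volume_nifti(path)
  roi_mask(array(vol$values != 0, dim(vol$values)), vol$spacing_mm)
}

cohort_image_files <- function(id) {
  c(pet = paste0(id, "_pet.nii.gz"),
    pet_mask = paste0(id, "_pet_mask.nii.gz"),
    pet_mask_reader2 = paste0(id, "_pet_mask_r2.nii.gz"),
    ct_slice = paste0(id, "_ct.nii.gz"),
    ct_mask = paste0(id, "_ct_mask.nii.gz"),
    ct_mask_reader2 = paste0(id, "_ct_mask_r2.nii.gz"))
}

#' Save a cohort to disk
#'
#' Writes each patient's PET volume and masks, CT slice and masks as NIfTI
#' files (float64 images, uint8 masks, voxel spacing in the header), plus a
#' `cohort.csv` manifest with one row per patient holding the covariates
#' and relative file names.
#'
#' @param records List of [patient_record()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @seealso [load_cohort()] for the inverse; the pair is an identity on
#'   valid cohorts.
#' @export
save_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    files <- cohort_image_files(r$id)
    write_volume_nifti(r$pet, file.path(dir, files["pet"]))
    write_volume_nifti(mask_as_volume(r$pet_mask),
                       file.path(dir, files["pet_mask"]), "uint8")
    write_volume_nifti(mask_as_volume(r$pet_mask_reader2),
                       file.path(dir, files["pet_mask_reader2"]), "uint8")
    write_volume_nifti(r$ct_slice, file.path(dir, files["ct_slice"]))
    write_volume_nifti(mask_as_volume(r$ct_mask),
                       file.path(dir, files["ct_mask"]), "uint8")
    write_volume_nifti(mask_as_volume(r$ct_mask_reader2),
                       file.path(dir, files["ct_mask_reader2"]), "uint8")
    data.frame(id = r$id, stage = r$stage, ipi = r$ipi,
               intestinal_involvement = r$intestinal_involvement,
               ki67_percent = r$ki67_percent, subtype = r$subtype,
               deauville = r$deauville,
               marrow_fdg_avid = r$marrow_fdg_avid,
               response = r$response,
               t(files), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "cohort.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

mask_as_volume <- function(mask) {
  image_volume(array(as.double(mask$flags), dim(mask$flags)),
               mask$spacing_mm)
}

#' Load a cohort from a manifest
#'
#' Reads the `cohort.csv` manifest written by [save_cohort()] and all
#' referenced NIfTI files, and returns fully validated patient records.
#' Missing files, geometry mismatches, and out-of-domain covariates each
#' raise a distinct, named error (`pettex_missing_file_error`,
#' `pettex_geometry_error`, `pettex_domain_error`).
#'
#' @param manifest_path Path to the cohort CSV manifest.
#' @return List of [patient_record()] objects.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    pettex_error(sprintf("manifest not found: %s", manifest_path),
                 "pettex_missing_file_error")
  }
  dir <- dirname(manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  needed <- c("id", "stage", "ipi", "intestinal_involvement",
              "ki67_percent", "subtype", "deauville", "marrow_fdg_avid",
              "pet", "pet_mask", "pet_mask_reader2",
              "ct_slice", "ct_mask", "ct_mask_reader2")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols)) {
    pettex_error(paste("manifest lacks columns:",
                       paste(missing_cols, collapse = ", ")),
                 "pettex_domain_error")
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    patient_record(
      id = row$id,
      pet = read_volume_nifti(file.path(dir, row$pet)),
      pet_mask = read_mask_nifti(file.path(dir, row$pet_mask)),
      pet_mask_reader2 = read_mask_nifti(file.path(dir, row$pet_mask_reader2)),
      ct_slice = read_volume_nifti(file.path(dir, row$ct_slice)),
      ct_mask = read_mask_nifti(file.path(dir, row$ct_mask)),
      ct_mask_reader2 = read_mask_nifti(file.path(dir, row$ct_mask_reader2)),
      stage = row$stage, ipi = row$ipi,
      intestinal_involvement = row$intestinal_involvement,
      ki67_percent = row$ki67_percent, subtype = row$subtype,
      deauville = row$deauville, marrow_fdg_avid = row$marrow_fdg_avid)
  })
}

#' Export patient metadata as JSON
#'
#' Serializes the non-image fields of validated records (covariates,
#' Deauville score, response label) to a JSON file or string.
#'
#' @param records List of [patient_record()] objects.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
export_cohort_json <- function(records, path = NULL) {
  meta <- lapply(records, function(r) {
    r[c("id", "stage", "ipi", "intestinal_involvement", "ki67_percent",
        "subtype", "deauville", "marrow_fdg_avid", "response")]
  })
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
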