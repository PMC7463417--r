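# Per-patient feature extraction: the full PET (3-D ROI) and CT (2-D ROI)
# feature vector, plus SUVmax and MTV.

glcm_quartet <- function(image, mask, disc, distance, prefix) {
  out <- numeric(0)
  for (dir in names(GLCM_DIRECTIONS)) {
    g <- glcm_features(glcm_matrix(image, mask,
                                   glcm_spec(distance, dir), disc))
    names(g) <- sprintf("%s%s_glcm%s", prefix,
                        sub("_glcm$", "", names(g)), dir)
    out <- c(out, g)
  }
  out
}

#' Extract the full feature vector for one patient
#'
#' Computes, for the selected reader's masks: PET first-order features,
#' ROI volume and maximal 3-D diameter, the four-direction PET GLCM
#' quartet, SUVmax and MTV; and the CT first-order features (no
#' percentiles or volume for the single slice), maximal in-plane diameter
#' and the CT GLCM quartet. Deterministic given its inputs.
#'
#' @param record A [patient_record()].
#' @param disc A [discretization_spec()] shared by PET and CT.
#' @param glcm_distance Offset length in voxels for the GLCM quartet.
#' @param reader 1 or 2: which reader's masks to use.
#' @param mtv_fraction Threshold fraction for [metabolic_tumor_volume()].
#' @return Named numeric vector of all features.
#' @export
extract_patient_features <- function(record, disc = discretization_spec(),
                                     glcm_distance = 1L, reader = 1L,
                                     mtv_fraction = 0.41) {
  stopifnot(inherits(record, "patient_record"), reader %in% c(1L, 2L))
  pet_mask <- if (reader == 1L) record$pet_mask else record$pet_mask_reader2
  ct_mask <- if (reader == 1L) record$ct_mask else record$ct_mask_reader2
  pet_vals <- masked_values(record$pet, pet_mask)
  pet_fo <- suppressWarnings(first_order_features(pet_vals, disc))
  names(pet_fo) <- paste0("pet_", names(pet_fo))
  pet <- c(pet_fo,
           pet_volume_mm3 = roi_volume(pet_mask),
           pet_max_diameter_mm = max_diameter(pet_mask),
           glcm_quartet(record$pet, pet_mask, disc, glcm_distance, "pet_"),
           suvmax = suv_max(record$pet, pet_mask),
           mtv_mm3 = metabolic_tumor_volume(record$pet, pet_mask,
                                            mtv_fraction))
  ct_vals <- masked_values(record$ct_slice, ct_mask)
  ct_fo <- suppressWarnings(first_order_features(ct_vals, disc))
  ct_fo <- ct_fo[c("mean", "sd", "max_frequency", "mode", "maximum",
                   "minimum", "skewness", "kurtosis", "entropy")]
  names(ct_fo) <- paste0("ct_", names(ct_fo))
  ct <- c(ct_fo,
          ct_max_diameter_mm = max_diameter(ct_mask),
          glcm_quartet(record$ct_slice, ct_mask, disc, glcm_distance,
                       "ct_"))
  c(pet, ct)
}

#' Feature table for a whole cohort
#'
#' One row per patient; columns `id`, `response`, `intestinal_involvement`
#' and every feature from [extract_patient_features()].
#'
#' @inheritParams extract_patient_features
#' @param records List of [patient_record()] objects.
#' @return A `data.frame`.
#' @export
extract_cohort_features <- function(records, disc = discretization_spec(),
                                    glcm_distance = 1L, reader = 1L,
                                    mtv_fraction = 0.41) {
  feats <- do.call(rbind, lapply(
    records, extract_patient_features, disc = disc,
    glcm_distance = glcm_distance, reader = reader,
    mtv_fraction = mtv_fraction))
  data.frame(id = vapply(records, `[[`, "", "id"),
             response = vapply(records, `[[`, "", "response"),
             intestinal_involvement =
               vapply(records, `[[`, NA, "intestinal_involvement"),
             feats, stringsAsFactors = FALSE)
}
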