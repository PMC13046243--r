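#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `laminar_volume` (data array + voxel-to-world affine).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = NULL)
  laminar_volume(array(as.numeric(img), dim = dim(img)), affine)
}

#' Write a NIfTI-1 volume
#'
#' @param volume A `laminar_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "laminar_volume")) stop_contract("`volume` must be a laminar_volume")
  img <- RNifti::asNifti(volume$data)
  # pixdim must match the affine column norms before the xform is set, or
  # the writer rescales the rotation part back to unit spacing
  RNifti::pixdim(img) <- sqrt(colSums(volume$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

cohort_columns <- c("subject_id", "ga_weeks", "pna_weeks", "pma_weeks",
                    "sex", "thickness_mm")

#' Write a cohort table to CSV
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!all(cohort_columns %in% names(cohort))) {
    stop_format(sprintf("cohort table must have columns: %s",
                        paste(cohort_columns, collapse = ", ")))
  }
  readr::write_csv(cohort[cohort_columns], path)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the cohort invariants: PMA = GA + PNA exactly, PNA within its
#' range, and unique subject ids.
#'
#' @param path CSV path with the standard cohort header.
#' @return Cohort tibble.
#' @export
read_cohort <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(cohort_columns %in% names(tab))) {
    stop_format(sprintf("cohort CSV must have columns: %s",
                        paste(cohort_columns, collapse = ", ")))
  }
  if (anyDuplicated(tab$subject_id)) stop_format("duplicate subject ids")
  if (max(abs(tab$pma_weeks - (tab$ga_weeks + tab$pna_weeks))) > 1e-8) {
    stop_format("PMA != GA + PNA in cohort CSV")
  }
  tab[cohort_columns]
}
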