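#' Lesion images
#'
#' A `lesion_image` holds one patient's 3D map of structural abnormality on a
#' common grid: either a *fuzzy* image, with per-voxel abnormality on a
#' continuous scale from 0 (normal) to 1 (completely abnormal), or its
#' thresholded *binary* counterpart (lesion / no lesion). The voxel-to-world
#' affine (mm) travels with the values; voxel volume is derived from it.
#'
#' @param values 3D numeric array with values in `[0, 1]`.
#' @param affine 4x4 voxel-to-world transform in mm (0-based voxel convention).
#' @param patient_id identifier for the patient.
#' @param kind `"fuzzy"` or `"binary"`.
#' @return An object of class `lesion_image` with fields `values`, `affine`,
#'   `patient_id`, `kind` and `voxel_volume` (mm^3 per voxel).
#' @export
lesion_image <- function(values, affine, patient_id = NA_character_,
                         kind = c("fuzzy", "binary")) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L)
    stop_iterlesion("lesion image values must be a 3D array", "dimensionality_error")
  if (!all(is.finite(values)))
    stop_iterlesion("lesion image contains non-finite values", "validation_error")
  tol <- 1e-6
  if (min(values) < -tol || max(values) > 1 + tol)
    stop_iterlesion(sprintf(
      "lesion values outside [0,1]: range [%g, %g]", min(values), max(values)),
      "validation_error")
  values[values < 0] <- 0
  values[values > 1] <- 1
  if (kind == "binary" && !all(values %in% c(0, 1)))
    stop_iterlesion("binary lesion image has values outside {0,1}", "validation_error")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop_iterlesion("affine must be a 4x4 matrix", "validation_error")
  structure(list(patient_id = patient_id, values = values, affine = affine,
                 kind = kind,
                 voxel_volume = abs(det(affine[1:3, 1:3]))),
            class = "lesion_image")
}

#' @export
print.lesion_image <- function(x, ...) {
  cat(sprintf("<lesion_image> patient %s, %s, grid %s, voxel %.3g mm^3\n",
              x$patient_id, x$kind, paste(dim(x$values), collapse = "x"),
              x$voxel_volume))
  invisible(x)
}

#' Read a lesion image from a NIfTI file
#'
#' Reads a 3D NIfTI volume, validates that voxel values lie in `[0, 1]`
#' (to a tolerance of 1e-6), and extracts the affine and voxel volume from
#' the header.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param kind `"fuzzy"` or `"binary"`.
#' @param patient_id optional identifier; defaults to the file name stem.
#' @return A [lesion_image].
#' @export
read_lesion_image <- function(path, kind = c("fuzzy", "binary"),
                              patient_id = NULL) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop_iterlesion(sprintf("%s is a %dD volume; expected 3D",
                            path, length(dim(img))), "dimensionality_error")
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  lesion_image(array(as.numeric(img), dim = dim(img)), aff,
               patient_id = patient_id, kind = kind)
}

#' Write a 3D grid as NIfTI
#'
#' Writes any 3D scalar grid (lesion values, overlap counts, statistic maps,
#' region labels) with the given affine. Round-trips bit-exactly through
#' [read_lesion_image] for values in `[0, 1]`.
#'
#' @param grid 3D numeric array (finite values).
#' @param affine 4x4 voxel-to-world transform in mm.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(grid, affine, path) {
  if (is.logical(grid)) grid <- array(as.numeric(grid), dim = dim(grid))
  if (length(dim(grid)) != 3L)
    stop_iterlesion("grid must be 3D", "dimensionality_error")
  if (!all(is.finite(grid)))
    stop_iterlesion("grid contains non-finite values", "validation_error")
  img <- RNifti::asNifti(grid)
  RNifti::pixdim(img) <- c(sqrt(sum(affine[1:3, 1]^2)),
                           sqrt(sum(affine[1:3, 2]^2)),
                           sqrt(sum(affine[1:3, 3]^2)))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  tryCatch(RNifti::writeNifti(img, path, datatype = "double"),
           error = function(e) stop_iterlesion(
             sprintf("cannot write %s: %s", path, conditionMessage(e)),
             "io_error"))
  invisible(path)
}

#' Binarize a fuzzy lesion image
#'
#' A voxel is lesioned iff its fuzzy abnormality *strictly exceeds* the
#' threshold `u` (default 0.3); a value exactly at the threshold stays 0.
#'
#' @param img a fuzzy [lesion_image].
#' @param u threshold in `[0, 1)`.
#' @return A binary [lesion_image] on the same grid and affine.
#' @export
binarize <- function(img, u = 0.3) {
  stopifnot(inherits(img, "lesion_image"))
  if (img$kind != "fuzzy")
    stop_iterlesion("binarize expects a fuzzy image", "kind_error")
  if (length(u) != 1L || !is.finite(u) || u < 0 || u >= 1)
    stop_iterlesion("binarization threshold must lie in [0, 1)", "parameter_error")
  out <- img
  out$values <- array(as.numeric(img$values > u), dim = dim(img$values))
  out$kind <- "binary"
  out
}

#' Lesion volume in cm^3
#'
#' Number of lesioned voxels times the voxel volume, in cm^3. Defined for
#' binary images only; binarize a fuzzy image first.
#'
#' @param img a binary [lesion_image].
#' @return Volume in cm^3.
#' @export
lesion_volume <- function(img) {
  stopifnot(inherits(img, "lesion_image"))
  if (img$kind != "binary")
    stop_iterlesion("lesion_volume requires a binary image; binarize first",
                    "kind_error")
  sum(img$values) * img$voxel_volume / 1000
}

#' Lesion overlap map
#'
#' Per-voxel count of patients with a binary lesion. Fuzzy cohorts are
#' binarized at `u` first: overlap maps and analysis masks are always based
#' on binary lesion indicators, whichever image kind the regression uses.
#'
#' @param cohort a [lesion_cohort].
#' @param u binarization threshold used when the cohort holds fuzzy images.
#' @return An `overlap_map`: integer 3D `counts` plus grid metadata.
#' @export
overlap_map <- function(cohort, u = 0.3) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  les <- cohort_binary_matrix(cohort, u)
  counts <- array(as.integer(round(colSums(les))), dim = cohort$dim)
  structure(list(counts = counts, n_patients = n_patients(cohort),
                 affine = cohort$affine), class = "overlap_map")
}

#' Analysis mask from an overlap map
#'
#' Includes exactly the voxels damaged in at least `min_overlap` patients
#' (default 5); the mass-univariate search is restricted to this mask.
#'
#' @param om an [overlap_map].
#' @param min_overlap minimum patient count (>= 1).
#' @return An `analysis_mask` with logical 3D `include`.
#' @export
build_analysis_mask <- function(om, min_overlap = 5L) {
  stopifnot(inherits(om, "overlap_map"))
  if (min_overlap < 1)
    stop_iterlesion("min_overlap must be >= 1", "parameter_error")
  structure(list(include = om$counts >= min_overlap,
                 min_overlap = as.integer(min_overlap),
                 affine = om$affine), class = "analysis_mask")
}

#' Labeled regions of interest
#'
#' @param labels 3D integer array; 0 is background, k is region k.
#' @param names character vector naming labels `1..max(labels)` present.
#' @param affine optional 4x4 affine.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, names = NULL, affine = NULL) {
  if (length(dim(labels)) != 3L)
    stop_iterlesion("ROI labels must be a 3D array", "dimensionality_error")
  if (min(labels) < 0)
    stop_iterlesion("ROI labels must be non-negative", "validation_error")
  present <- sort(unique(as.integer(labels[labels > 0])))
  if (is.null(names)) names <- paste0("roi", present)
  if (length(names) != length(present))
    stop_iterlesion("one name required per non-background label", "validation_error")
  structure(list(labels = array(as.integer(labels), dim = dim(labels)),
                 ids = present, names = setNames(names, present),
                 affine = affine),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  sizes <- tabulate(x$labels[x$labels > 0], nbins = max(c(x$ids, 0L)))
  cat(sprintf("<roi_set> %d region(s)\n", length(x$ids)))
  for (k in x$ids)
    cat(sprintf("  [%d] %s: %d voxels\n", k, x$names[as.character(k)], sizes[k]))
  invisible(x)
}

n_rois <- function(rois) length(rois$ids)

#' Damage fraction of a region
#'
#' For a binary image, the proportion of the region's voxels that are
#' lesioned; for a fuzzy image, the mean abnormality over the region (the
#' continuous analogue). Drives the ">25% damage" exclusion rule and the
#' post-hoc damage grouping.
#'
#' @param img a [lesion_image].
#' @param rois a [roi_set].
#' @param label region label (integer) to evaluate.
#' @return Fraction in `[0, 1]`.
#' @export
roi_damage_fraction <- function(img, rois, label) {
  stopifnot(inherits(img, "lesion_image"), inherits(rois, "roi_set"))
  sel <- rois$labels == label
  nv <- sum(sel)
  if (nv == 0L)
    stop_iterlesion(sprintf("ROI label %s is empty", label), "degenerate_roi_error")
  sum(img$values[sel]) / nv
}

#' Damage profile of a cohort over a set of regions
#'
#' @param cohort a [lesion_cohort].
#' @param rois a [roi_set].
#' @return Numeric matrix, patients x regions, of damage fractions
#'   (rownames = patient ids, colnames = region names).
#' @export
damage_profile <- function(cohort, rois) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(rois, "roi_set"))
  if (!identical(dim(rois$labels), cohort$dim))
    stop_iterlesion("ROI grid does not match cohort grid", "grid_mismatch_error")
  out <- matrix(NA_real_, n_patients(cohort), n_rois(rois),
                dimnames = list(cohort$ids, unname(rois$names)))
  for (j in seq_along(rois$ids)) {
    sel <- which(rois$labels == rois$ids[j])
    if (length(sel) == 0L)
      stop_iterlesion("empty ROI in damage_profile", "degenerate_roi_error")
    out[, j] <- rowSums(cohort$lesions[, sel, drop = FALSE]) / length(sel)
  }
  out
}
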