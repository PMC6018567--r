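#' Behavioural task names
#'
#' The six Comprehensive Aphasia Test (CAT) tasks used throughout: spoken
#' picture naming, written picture naming, nonword repetition, semantic
#' associations, spoken word comprehension, and writing copy. All scores are
#' norm-referenced T-scores.
#' @export
cat_task_names <- c("spk_pn", "writt_pn", "rep_n", "sem_m", "cspk_w",
                    "writt_copy")

#' Impairment cut-offs
#'
#' The highest T-score still counted as impaired, per task (inclusive:
#' a score equal to the cut-off is impaired). Defaults are read from the
#' packaged config (`extdata/cat_cutoffs.yaml`) so that other normings can
#' be swapped in: spoken naming 61, written naming 54, nonword repetition 52,
#' semantic associations 50, spoken word comprehension 52, writing copy 51.
#'
#' @param path optional path to a YAML file mapping task names to cut-offs.
#' @return Named numeric vector over [cat_task_names].
#' @export
default_cutoffs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cat_cutoffs.yaml", package = "iterlesion",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  co <- unlist(raw[cat_task_names])
  if (length(co) != length(cat_task_names) || anyNA(co))
    stop_iterlesion("cut-off config must name all six tasks", "config_error")
  if (any(co <= 0 | co >= 100))
    stop_iterlesion("cut-offs must lie in (0, 100)", "config_error")
  co
}

#' Composite naming score
#'
#' The arithmetic mean of the spoken and written picture naming T-scores —
#' the regressor of interest indexing word retrieval. Missing scores are an
#' error; no imputation is performed.
#'
#' @param spk_pn,writt_pn T-scores (vectorized).
#' @return Mean of the two scores.
#' @export
composite_score <- function(spk_pn, writt_pn) {
  if (anyNA(spk_pn) || anyNA(writt_pn) ||
      !all(is.finite(spk_pn)) || !all(is.finite(writt_pn)))
    stop_iterlesion("missing or non-finite naming score", "missing_data_error")
  (spk_pn + writt_pn) / 2
}

#' Per-task impairment flags
#'
#' A task is impaired iff its T-score is less than or equal to the task's
#' cut-off (inclusive boundary).
#'
#' @param scores data frame (or single row) with the six task columns.
#' @param cutoffs named cut-off vector, as from [default_cutoffs].
#' @return Logical matrix, patients x tasks.
#' @export
impairment_flags <- function(scores, cutoffs = default_cutoffs()) {
  scores <- as.data.frame(scores)
  missing_cols <- setdiff(cat_task_names, names(scores))
  if (length(missing_cols))
    stop_iterlesion(paste("missing score columns:",
                          paste(missing_cols, collapse = ", ")),
                    "missing_data_error")
  m <- as.matrix(scores[cat_task_names])
  if (!all(is.finite(m)))
    stop_iterlesion("non-finite T-scores", "missing_data_error")
  if (any(m < 0 | m > 100))
    warning("T-scores outside the plausible [0, 100] range")
  flags <- sweep(m, 2L, cutoffs[cat_task_names], `<=`)
  rownames(flags) <- rownames(scores)
  flags
}

#' Deficit of interest
#'
#' TRUE iff both spoken and written picture naming are impaired (the
#' conjunction indexing word-finding difficulty beyond articulation,
#' semantics or motor writing).
#'
#' @param flags logical matrix from [impairment_flags].
#' @return Logical vector per patient.
#' @export
deficit_of_interest <- function(flags) {
  flags[, "spk_pn"] & flags[, "writt_pn"]
}

# internal cohort constructor: lesions as a patients x voxels matrix
new_cohort <- function(ids, lesions, dim3, affine, kind, scores, volumes) {
  stopifnot(!anyDuplicated(ids), nrow(lesions) == length(ids),
            ncol(lesions) == prod(dim3), nrow(scores) == length(ids))
  structure(list(ids = as.character(ids), lesions = lesions,
                 dim = as.integer(dim3), affine = affine, kind = kind,
                 voxel_volume = abs(det(affine[1:3, 1:3])),
                 scores = scores, volumes = volumes),
            class = "lesion_cohort")
}

#' Number of patients in a cohort
#' @param cohort a [lesion_cohort].
#' @export
n_patients <- function(cohort) length(cohort$ids)

# binary patients x voxels matrix (binarize fuzzy cohorts at u, strict >)
cohort_binary_matrix <- function(cohort, u = 0.3) {
  if (cohort$kind == "binary") cohort$lesions
  else (cohort$lesions > u) * 1
}

#' Convert a cohort to a given image kind
#'
#' Binarizes fuzzy lesions at `u` when `kind = "binary"`; a binary cohort
#' cannot be converted back to fuzzy.
#'
#' @param cohort a [lesion_cohort].
#' @param kind `"fuzzy"` or `"binary"`.
#' @param u binarization threshold.
#' @export
cohort_as_kind <- function(cohort, kind = c("fuzzy", "binary"), u = 0.3) {
  kind <- match.arg(kind)
  if (kind == cohort$kind) return(cohort)
  if (kind == "fuzzy")
    stop_iterlesion("cannot recover fuzzy values from a binary cohort",
                    "kind_error")
  cohort$lesions <- cohort_binary_matrix(cohort, u)
  cohort$kind <- "binary"
  cohort
}

#' Extract one patient's lesion image
#' @param cohort a [lesion_cohort].
#' @param id patient id or index.
#' @export
patient_image <- function(cohort, id) {
  i <- if (is.character(id)) match(id, cohort$ids) else as.integer(id)
  if (is.na(i) || i < 1L || i > n_patients(cohort))
    stop_iterlesion(sprintf("unknown patient '%s'", id), "lookup_error")
  lesion_image(array(cohort$lesions[i, ], dim = cohort$dim), cohort$affine,
               patient_id = cohort$ids[i], kind = cohort$kind)
}

#' Subset a cohort by patient
#' @param cohort a [lesion_cohort].
#' @param keep logical vector, integer indices, or patient ids.
#' @export
subset_cohort <- function(cohort, keep) {
  if (is.character(keep)) keep <- match(keep, cohort$ids)
  if (is.logical(keep)) keep <- which(keep)
  if (anyNA(keep)) stop_iterlesion("unknown patient id in subset", "lookup_error")
  cohort$ids <- cohort$ids[keep]
  cohort$lesions <- cohort$lesions[keep, , drop = FALSE]
  cohort$scores <- cohort$scores[keep, , drop = FALSE]
  cohort$volumes <- cohort$volumes[keep]
  cohort
}

#' Assemble a cohort from an image manifest and a scores table
#'
#' The manifest (data frame or CSV/TSV path) lists `patient_id` and `path`
#' per NIfTI lesion image; the scores table (data frame or CSV/TSV path)
#' carries one row per patient with the six task T-score columns. All images
#' must share one grid and affine (mismatches are rejected, never resampled).
#' Lesion volumes are computed from the binarized images.
#'
#' @param manifest data frame with columns `patient_id`, `path`, or a file.
#' @param scores data frame with `patient_id` plus [cat_task_names], or a file.
#' @param kind image kind on disk, `"fuzzy"` or `"binary"`.
#' @param binarize_u threshold used for lesion volumes (and to validate
#'   binary images).
#' @return A `lesion_cohort`.
#' @export
assemble_cohort <- function(manifest, scores, kind = c("fuzzy", "binary"),
                            binarize_u = 0.3) {
  kind <- match.arg(kind)
  read_tab <- function(x) {
    if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE,
                                         sep = if (grepl("\\.tsv$", x)) "\t" else ",")
    else as.data.frame(x)
  }
  manifest <- read_tab(manifest)
  scores <- read_tab(scores)
  if (!all(c("patient_id", "path") %in% names(manifest)))
    stop_iterlesion("manifest needs patient_id and path columns", "assembly_error")
  miss <- setdiff(manifest$patient_id, scores$patient_id)
  if (length(miss))
    stop_iterlesion(paste("no scores row for:", paste(miss, collapse = ", ")),
                    "assembly_error")
  scores <- scores[match(manifest$patient_id, scores$patient_id), , drop = FALSE]
  invisible(impairment_flags(scores))  # validates columns and finiteness

  n <- nrow(manifest)
  imgs <- vector("list", n)
  for (i in seq_len(n))
    imgs[[i]] <- read_lesion_image(manifest$path[i], kind = kind,
                                   patient_id = manifest$patient_id[i])
  dim3 <- dim(imgs[[1]]$values)
  aff <- imgs[[1]]$affine
  for (i in seq_len(n))
    if (!identical(dim(imgs[[i]]$values), dim3) ||
        max(abs(imgs[[i]]$affine - aff)) > 1e-6)
      stop_iterlesion(sprintf("grid/affine mismatch for patient %s",
                              manifest$patient_id[i]), "grid_mismatch_error")
  lesions <- t(vapply(imgs, function(im) as.numeric(im$values),
                      numeric(prod(dim3))))
  vols <- vapply(imgs, function(im) {
    b <- if (im$kind == "fuzzy") binarize(im, binarize_u) else im
    lesion_volume(b)
  }, numeric(1))
  cohort <- new_cohort(manifest$patient_id, lesions, dim3, aff, kind,
                       scores, vols)
  message(format(summary(cohort)))
  cohort
}

#' Cohort summary
#'
#' Sample size, lesion volume range and per-task impaired/non-impaired
#' counts at the default cut-offs.
#'
#' @param object a [lesion_cohort].
#' @param cutoffs impairment cut-offs.
#' @param ... unused.
#' @export
summary.lesion_cohort <- function(object, cutoffs = default_cutoffs(), ...) {
  flags <- impairment_flags(object$scores, cutoffs)
  imp <- colSums(flags)
  structure(list(n = n_patients(object), kind = object$kind,
                 volume_range = range(object$volumes),
                 impaired = imp, non_impaired = n_patients(object) - imp,
                 deficit_of_interest = sum(deficit_of_interest(flags))),
            class = "summary.lesion_cohort")
}

#' @export
format.summary.lesion_cohort <- function(x, ...) {
  lines <- c(
    sprintf("lesion cohort: n = %d (%s images), lesion volume %.1f-%.1f cm^3",
            x$n, x$kind, x$volume_range[1], x$volume_range[2]),
    sprintf("  %-10s impaired/non-impaired: %d/%d",
            names(x$impaired), x$impaired, x$non_impaired),
    sprintf("  deficit of interest (both naming tasks impaired): %d/%d",
            x$deficit_of_interest, x$n))
  paste(lines, collapse = "\n")
}

#' @export
print.summary.lesion_cohort <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("<lesion_cohort> n = %d, %s, grid %s\n", n_patients(x), x$kind,
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one NIfTI per patient plus `manifest.csv` and `scores.csv` in a
#' layout consumable by [assemble_cohort].
#'
#' @param cohort a [lesion_cohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(cohort$ids, ".nii.gz"))
  for (i in seq_len(n_patients(cohort)))
    write_image(array(cohort$lesions[i, ], dim = cohort$dim), cohort$affine,
                paths[i])
  utils::write.csv(data.frame(patient_id = cohort$ids, path = paths),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cbind(patient_id = cohort$ids,
                         cohort$scores[cat_task_names]),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  invisible(dir)
}
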