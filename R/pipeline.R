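#' Pipeline configuration
#'
#' All tunable parameters of one iterative lesion-deficit mapping run.
#' Defaults follow the standard recipe: fuzzy images binarized at 0.3 (for
#' masks and volumes), search restricted to voxels damaged in at least five
#' patients, voxel-level FWE alpha 0.05, cluster-forming threshold p < 0.001
#' uncorrected, and exclusion of patients with more than 25% damage to any
#' previously identified region. The cohort floor stops iteration before
#' permutation inference becomes vacuous on tiny samples.
#'
#' @param image_kind `"fuzzy"` or `"binary"` — which images enter the GLM.
#' @param binarize_u fuzzy-to-binary threshold (strict `>`).
#' @param min_overlap analysis-mask threshold (>= this many patients damaged).
#' @param alpha_fwe corrected significance level.
#' @param forming_p cluster-forming uncorrected threshold.
#' @param exclusion_fraction damage fraction above which a patient is
#'   excluded (strictly greater; exactly this fraction is retained).
#' @param n_perm permutations per analysis.
#' @param seed master seed; each iteration draws a child seed from it.
#' @param min_cohort_size smallest cohort the analysis will run on.
#' @param roi_rule `"voxel"` (default) or `"cluster"` ROI extraction.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(image_kind = c("fuzzy", "binary"),
                            binarize_u = 0.3, min_overlap = 5L,
                            alpha_fwe = 0.05, forming_p = 0.001,
                            exclusion_fraction = 0.25, n_perm = 5000L,
                            seed = 1L, min_cohort_size = 30L,
                            roi_rule = c("voxel", "cluster"),
                            connectivity = 26L) {
  image_kind <- match.arg(image_kind)
  roi_rule <- match.arg(roi_rule)
  stopifnot(exclusion_fraction > 0, exclusion_fraction < 1,
            alpha_fwe > 0, alpha_fwe < 1, forming_p > 0, forming_p < 1,
            binarize_u >= 0, binarize_u < 1, min_overlap >= 1,
            n_perm >= 1, min_cohort_size >= 10)
  structure(list(image_kind = image_kind, binarize_u = binarize_u,
                 min_overlap = as.integer(min_overlap),
                 alpha_fwe = alpha_fwe, forming_p = forming_p,
                 exclusion_fraction = exclusion_fraction,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 min_cohort_size = as.integer(min_cohort_size),
                 roi_rule = roi_rule, connectivity = as.integer(connectivity)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' One lesion-deficit analysis
#'
#' The single-pass recipe: overlap map (from binary images) -> analysis mask
#' -> design matrix -> voxelwise GLM -> permutation maxT FWE -> cluster-level
#' FWE -> significant-ROI extraction. Returns everything needed for
#' reporting and for exclusion-based iteration.
#'
#' @param cohort a [lesion_cohort].
#' @param config a [pipeline_config].
#' @return A `lesion_analysis`: `stat_map`, `clusters`, `rois`, `mask`,
#'   `design`, sample size `n`, and `empty_mask` flag. If the mask is empty
#'   the statistical fields are NULL and `empty_mask` is TRUE.
#' @export
run_single_analysis <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(config, "pipeline_config"))
  if (n_patients(cohort) < config$min_cohort_size)
    stop_iterlesion(sprintf("cohort size %d below the floor of %d",
                            n_patients(cohort), config$min_cohort_size),
                    "precondition_error")
  acohort <- cohort_as_kind(cohort, config$image_kind, config$binarize_u)
  om <- overlap_map(cohort, config$binarize_u)
  mask <- build_analysis_mask(om, config$min_overlap)
  if (!any(mask$include)) {
    return(structure(list(stat_map = NULL, clusters = NULL, rois = NULL,
                          mask = mask, design = NULL, n = n_patients(cohort),
                          empty_mask = TRUE, config = config),
                     class = "lesion_analysis"))
  }
  design <- build_design_matrix(acohort)
  contrast <- lesion_deficit_contrast(design)
  sm <- permutation_maxT_fwe(acohort, design, contrast, mask,
                             n_perm = config$n_perm, seed = config$seed,
                             forming_p = config$forming_p,
                             connectivity = config$connectivity)
  cs <- cluster_level_fwe(sm)
  rois <- threshold_and_extract_rois(sm, cs, alpha = config$alpha_fwe,
                                     rule = config$roi_rule)
  structure(list(stat_map = sm, clusters = cs, rois = rois, mask = mask,
                 design = design, n = n_patients(cohort), empty_mask = FALSE,
                 config = config),
            class = "lesion_analysis")
}

#' @export
print.lesion_analysis <- function(x, ...) {
  cat(sprintf("<lesion_analysis> n = %d, %d in-mask voxels\n",
              x$n, sum(x$mask$include)))
  if (isTRUE(x$empty_mask)) cat("  empty analysis mask\n")
  else cat(sprintf("  %d cluster(s) above forming threshold, %d significant ROI(s)\n",
                   nrow(x$clusters), n_rois(x$rois)))
  invisible(x)
}

#' Exclude patients by region damage
#'
#' A patient is retained iff their damage fraction is at most
#' `exclusion_fraction` for *every* region (strictly more than the fraction
#' on any region excludes; exactly the fraction retains). Fractions use the
#' configured image kind: lesioned proportion for binary, mean abnormality
#' for fuzzy.
#'
#' @param cohort a [lesion_cohort].
#' @param rois a non-empty [roi_set].
#' @param config a [pipeline_config].
#' @return List with the retained `cohort` and a `report` data frame
#'   (patient id, per-region fractions, `max_fraction`, `excluded`).
#' @export
exclude_by_roi_damage <- function(cohort, rois, config = pipeline_config()) {
  if (n_rois(rois) == 0L)
    stop_iterlesion("ROI set is empty", "precondition_error")
  acohort <- cohort_as_kind(cohort, config$image_kind, config$binarize_u)
  prof <- damage_profile(acohort, rois)
  maxf <- apply(prof, 1L, max)
  excluded <- maxf > config$exclusion_fraction
  report <- data.frame(patient_id = cohort$ids, prof,
                       max_fraction = maxf, excluded = excluded,
                       row.names = NULL, check.names = FALSE)
  list(cohort = subset_cohort(cohort, !excluded), report = report)
}

#' Iterative lesion-deficit mapping
#'
#' Runs [run_single_analysis], excludes every patient with more than
#' `exclusion_fraction` damage to the union of all regions identified so far
#' (regions accumulate across iterations), and repeats until an analysis
#' finds nothing, the mask empties, nobody new can be excluded, or the
#' cohort falls below the floor. Fully deterministic given the master seed:
#' each iteration's permutation stream uses an independent child seed.
#'
#' @param cohort a [lesion_cohort].
#' @param config a [pipeline_config].
#' @param max_iter hard cap on iterations.
#' @return An `iteration_trace`: list of per-iteration records (included
#'   patient ids, analysis, regions found this pass, cumulative regions,
#'   exclusion report) and a `stop_reason` in `no_significant_voxels`,
#'   `empty_mask`, `cohort_floor`, `no_new_exclusions`.
#' @export
iterative_mapping <- function(cohort, config = pipeline_config(),
                              max_iter = 20L) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- child_seeds(config$seed, max_iter)
  records <- list()
  cum_labels <- array(0L, dim = cohort$dim)
  n_cum <- 0L
  stop_reason <- NULL
  current <- cohort
  for (k in seq_len(max_iter)) {
    iter_config <- config
    iter_config$seed <- seeds[k]
    ana <- run_single_analysis(current, iter_config)
    rec <- list(iteration = k, included = current$ids, n = n_patients(current),
                n_mask_voxels = sum(ana$mask$include), analysis = ana,
                rois = ana$rois, excluded = character(0), report = NULL)
    if (isTRUE(ana$empty_mask)) {
      records[[k]] <- rec; stop_reason <- "empty_mask"; break
    }
    if (n_rois(ana$rois) == 0L) {
      records[[k]] <- rec; stop_reason <- "no_significant_voxels"; break
    }
    # accumulate this pass's regions into the running union
    new3 <- ana$rois$labels
    fresh <- new3 > 0L & cum_labels == 0L
    cum_labels[fresh] <- new3[fresh] + n_cum
    n_cum <- max(cum_labels)
    cum_rois <- roi_set(cum_labels, affine = cohort$affine)
    rec$cumulative_rois <- cum_rois
    ex <- exclude_by_roi_damage(current, cum_rois, config)
    rec$excluded <- current$ids[ex$report$excluded]
    rec$report <- ex$report
    records[[k]] <- rec
    if (length(rec$excluded) == 0L) { stop_reason <- "no_new_exclusions"; break }
    if (n_patients(ex$cohort) < config$min_cohort_size) {
      stop_reason <- "cohort_floor"; break
    }
    current <- ex$cohort
  }
  if (is.null(stop_reason)) stop_reason <- "no_significant_voxels"
  structure(list(records = records, stop_reason = stop_reason,
                 config = config), class = "iteration_trace")
}

#' @export
print.iteration_trace <- function(x, ...) {
  cat(sprintf("<iteration_trace> %d iteration(s), stopped: %s\n",
              length(x$records), x$stop_reason))
  for (r in x$records)
    cat(sprintf("  iteration %d: n = %d, %d ROI(s), %d excluded\n",
                r$iteration, r$n,
                if (is.null(r$rois)) 0L else n_rois(r$rois),
                length(r$excluded)))
  invisible(x)
}

#' Productive iterations of a trace
#'
#' An iteration is productive when it identified at least one significant
#' region.
#'
#' @param trace an `iteration_trace`.
#' @return Integer vector of productive iteration indices.
#' @export
productive_iterations <- function(trace) {
  which(vapply(trace$records,
               function(r) !is.null(r$rois) && n_rois(r$rois) > 0L, logical(1)))
}

#' Write the outputs of an iterative run
#'
#' One numbered directory per iteration with the t/Z/p maps and ROI labels
#' as NIfTI, the cluster table as CSV, plus a `trace.json` summarizing
#' inclusion, exclusion and the stop reason.
#'
#' @param trace an `iteration_trace`.
#' @param dir output directory.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(stop_reason = trace$stop_reason, iterations = list())
  for (r in trace$records) {
    d <- file.path(dir, sprintf("iteration_%02d", r$iteration))
    dir.create(d, showWarnings = FALSE)
    ana <- r$analysis
    if (!isTRUE(ana$empty_mask)) {
      sm <- ana$stat_map
      blank <- function(a) { a[is.na(a)] <- 0; a }
      write_image(blank(sm$t), sm$affine, file.path(d, "tmap.nii.gz"))
      write_image(blank(sm$z), sm$affine, file.path(d, "zmap.nii.gz"))
      write_image(blank(1 - sm$p_fwe), sm$affine,
                  file.path(d, "one_minus_p_fwe.nii.gz"))
      write_image(array(as.numeric(ana$rois$labels), dim = sm$dim), sm$affine,
                  file.path(d, "roi_labels.nii.gz"))
      write_cluster_table(ana$clusters, file.path(d, "clusters.csv"))
    }
    summ$iterations[[r$iteration]] <-
      list(iteration = r$iteration, n = r$n, n_mask_voxels = r$n_mask_voxels,
           n_rois = if (is.null(r$rois)) 0L else n_rois(r$rois),
           included = r$included, excluded = r$excluded)
  }
  jsonlite::write_json(summ, file.path(dir, "trace.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
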