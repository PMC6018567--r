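#' Synthetic cohort configuration
#'
#' Defines the generative model for synthetic stroke-lesion cohorts with the
#' statistical structure that makes pooled voxel-based analyses miss
#' distributed causes: three disjoint ground-truth critical regions (two
#' "cortical" boxes T and F of 8^3 voxels and one small "deep" box P of 4^3
#' voxels on a 32^3 grid of 2 mm voxels), whose damage each *independently*
#' produces the deficit (OR structure); four vascular-territory-like lesion
#' classes (posterior, centred on T; anterior, centred on F; deep, centred
#' on P and rarely reaching T or F; large, covering all three) so that deep
#' damage usually co-occurs with cortical damage in the pooled sample;
#' ellipsoidal lesions with sigmoidal fuzzy borders; and T-scores with
#' Gaussian noise around the task-specific impairment cut-offs.
#'
#' The latent deficit is D = 1 iff any true region's (binary) damage
#' fraction exceeds `theta`; the two naming scores are then
#' `baseline - effect*D - volume_slope*n_lesioned_voxels + noise`, and each
#' nuisance task couples to the region it nominally probes. Scores are not
#' truncated: T-scores are unbounded in principle.
#'
#' @param n number of patients.
#' @param seed master seed; the whole cohort is reproducible from it.
#' @param dim grid shape (3 integers).
#' @param voxel_mm isotropic voxel size in mm.
#' @param theta damage-fraction threshold for the latent deficit.
#' @param binarize_u fuzzy-to-binary threshold used for damage fractions and
#'   lesion volumes inside the generator.
#' @param baseline,effect,volume_slope,noise_sd naming-score model: baseline
#'   T-score, deficit effect (subtracted), slope per lesioned voxel
#'   (subtracted), residual noise SD.
#' @param border_width fuzzy border scale in voxels (sigmoid over signed
#'   distance to the ellipsoid surface).
#' @return A `synth_config` list (regions, territories, weights and the
#'   score model; see the fields).
#' @export
synth_config <- function(n = 300L, seed = 1L,
                         dim = c(32L, 32L, 32L), voxel_mm = 2,
                         theta = 0.5, binarize_u = 0.3,
                         baseline = 70, effect = 12,
                         volume_slope = 0.002, noise_sd = 3,
                         border_width = 1) {
  stopifnot(theta > 0, theta < 1, length(dim) == 3L)
  regions <- list(
    T = list(origin = c(9L, 21L, 13L), size = c(8L, 8L, 8L)),
    F = list(origin = c(9L, 5L, 13L), size = c(8L, 8L, 8L)),
    P = list(origin = c(15L, 15L, 13L), size = c(4L, 4L, 4L)))
  territories <- list(
    posterior = list(weight = 0.30, center = c(12.5, 24.5, 16.5),
                     center_sd = c(1.5, 1.5, 1.5),
                     radius_meanlog = log(5.2), radius_sdlog = 0.2),
    anterior = list(weight = 0.30, center = c(12.5, 8.5, 16.5),
                    center_sd = c(1.5, 1.5, 1.5),
                    radius_meanlog = log(5.2), radius_sdlog = 0.2),
    deep = list(weight = 0.15, center = c(16.5, 16.5, 14.5),
                center_sd = c(1.5, 1.5, 1.5),
                radius_meanlog = log(2.0), radius_sdlog = 0.25),
    large = list(weight = 0.25, center = c(13, 16, 15.5),
                 center_sd = c(1, 1, 1),
                 radius_meanlog = log(10), radius_sdlog = 0.12))
  # nuisance task models: base + coupling to region fractions + volume term
  nuisance <- list(
    rep_n = c(base = 62, T = 0, F = -3, vol = 0),
    sem_m = c(base = 60, T = -1.5, F = 0, vol = 0),
    cspk_w = c(base = 62, T = -3, F = 0, vol = 0),
    writt_copy = c(base = 60, T = 0, F = 0, vol = -0.002))
  affine <- rbind(c(voxel_mm, 0, 0, -voxel_mm * (dim[1] - 1) / 2),
                  c(0, voxel_mm, 0, -voxel_mm * (dim[2] - 1) / 2),
                  c(0, 0, voxel_mm, -voxel_mm * (dim[3] - 1) / 2),
                  c(0, 0, 0, 1))
  cfg <- structure(list(n = as.integer(n), seed = as.integer(seed),
                        dim = as.integer(dim), voxel_mm = voxel_mm,
                        affine = affine, regions = regions,
                        territories = territories, theta = theta,
                        binarize_u = binarize_u, baseline = baseline,
                        effect = effect, volume_slope = volume_slope,
                        noise_sd = noise_sd, nuisance = nuisance,
                        nuisance_noise_sd = 3, border_width = border_width),
                   class = "synth_config")
  w <- vapply(cfg$territories, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop_iterlesion("territory weights must sum to 1", "config_error")
  cfg
}

#' Ground-truth region layout
#'
#' The three true critical regions as a labeled [roi_set]
#' (1 = T, 2 = F, 3 = P). Deterministic; overlapping or out-of-grid region
#' specs are a configuration error.
#'
#' @param config a [synth_config].
#' @export
make_region_layout <- function(config = synth_config()) {
  labels <- array(0L, dim = config$dim)
  k <- 0L
  for (nm in names(config$regions)) {
    k <- k + 1L
    r <- config$regions[[nm]]
    hi <- r$origin + r$size - 1L
    if (any(r$origin < 1L) || any(hi > config$dim))
      stop_iterlesion(sprintf("region %s extends outside the grid", nm),
                      "config_error")
    sl <- labels[r$origin[1]:hi[1], r$origin[2]:hi[2], r$origin[3]:hi[3]]
    if (any(sl != 0L))
      stop_iterlesion(sprintf("region %s overlaps another region", nm),
                      "config_error")
    labels[r$origin[1]:hi[1], r$origin[2]:hi[2], r$origin[3]:hi[3]] <- k
  }
  roi_set(labels, names = names(config$regions), affine = config$affine)
}

#' Sample one synthetic lesion
#'
#' Draws a territory from the mixture, then an ellipsoid (jittered centre,
#' log-normal radii with mild anisotropy) and returns the fuzzy image
#' `plogis(-d / width)` of the signed distance d to the ellipsoid surface —
#' a gradual rather than categorical lesion border. Uses (and advances) the
#' current RNG state; seed the RNG for reproducibility.
#'
#' @param config a [synth_config].
#' @return List with the fuzzy `image` ([lesion_image]) and the `territory`
#'   name drawn.
#' @export
sample_lesion_image <- function(config = synth_config()) {
  w <- vapply(config$territories, `[[`, numeric(1), "weight")
  terr <- sample(names(config$territories), 1L, prob = w)
  tt <- config$territories[[terr]]
  center <- rnorm(3, tt$center, tt$center_sd)
  base_r <- rlnorm(1, tt$radius_meanlog, tt$radius_sdlog)
  radii <- base_r * exp(rnorm(3, 0, 0.1))
  vals <- fuzzy_ellipsoid(config$dim, center, radii, config$border_width)
  list(image = lesion_image(vals, config$affine, kind = "fuzzy"),
       territory = terr)
}

# fuzzy ellipsoid field: sigmoid of signed distance (voxel units)
fuzzy_ellipsoid <- function(dim3, center, radii, width) {
  qx <- ((seq_len(dim3[1]) - center[1]) / radii[1])^2
  qy <- ((seq_len(dim3[2]) - center[2]) / radii[2])^2
  qz <- ((seq_len(dim3[3]) - center[3]) / radii[3])^2
  q2 <- outer(outer(qx, qy, `+`), qz, `+`)
  d <- (sqrt(q2) - 1) * mean(radii)
  plogis(-d / width)
}

#' Sample behavioural scores for one patient
#'
#' Applies the OR deficit rule (D = 1 iff any true-region fraction exceeds
#' `theta`), draws the two naming scores around
#' `baseline - effect*D - volume_slope*n_vox`, and the four nuisance scores
#' from their own couplings. Uses the current RNG state.
#'
#' @param fractions named damage fractions for the true regions (`T, F, P`).
#' @param n_vox number of binarized lesion voxels.
#' @param config a [synth_config].
#' @return One-row data frame over [cat_task_names], plus the latent
#'   `deficit` attribute.
#' @export
sample_behavior <- function(fractions, n_vox, config = synth_config()) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  D <- any(fractions > config$theta)
  mu <- config$baseline - config$effect * D - config$volume_slope * n_vox
  out <- data.frame(
    spk_pn = mu + rnorm(1, 0, config$noise_sd),
    writt_pn = mu + rnorm(1, 0, config$noise_sd),
    rep_n = NA_real_, sem_m = NA_real_, cspk_w = NA_real_,
    writt_copy = NA_real_)
  for (task in names(config$nuisance)) {
    cf <- config$nuisance[[task]]
    out[[task]] <- cf[["base"]] + cf[["T"]] * fractions[["T"]] +
      cf[["F"]] * fractions[["F"]] + cf[["vol"]] * n_vox +
      rnorm(1, 0, config$nuisance_noise_sd)
  }
  attr(out, "deficit") <- D
  out
}

#' Generate a synthetic cohort with ground truth
#'
#' Samples `config$n` patients independently (lesion, then scores), computes
#' binary damage fractions to the true regions and lesion volumes, and
#' returns the cohort together with its ground truth. Bit-reproducible from
#' the master seed.
#'
#' @param config a [synth_config].
#' @return List with `cohort` (a fuzzy [lesion_cohort]) and `truth`
#'   (`regions` [roi_set], per-patient `territory`, `fractions` matrix over
#'   T/F/P, latent `deficit` logical).
#' @export
generate_cohort <- function(config = synth_config()) {
  set.seed(config$seed)
  generate_cohort_impl(config, null = FALSE)
}

#' Generate a matched null cohort
#'
#' Lesions are sampled exactly as in [generate_cohort], but every
#' behavioural score is drawn independently of the lesion (task baseline
#' plus noise): no voxel carries any true association, so any significant
#' finding is a false positive.
#'
#' @param config a [synth_config].
#' @return A fuzzy [lesion_cohort].
#' @export
generate_null_cohort <- function(config = synth_config()) {
  set.seed(config$seed)
  generate_cohort_impl(config, null = TRUE)$cohort
}

generate_cohort_impl <- function(config, null) {
  n <- config$n
  V <- prod(config$dim)
  regions <- make_region_layout(config)
  reg_idx <- lapply(regions$ids, function(k) which(regions$labels == k))
  names(reg_idx) <- unname(regions$names)

  lesions <- matrix(0, n, V)
  territory <- character(n)
  fractions <- matrix(0, n, 3, dimnames = list(NULL, c("T", "F", "P")))
  nvox <- numeric(n)
  score_rows <- vector("list", n)
  deficit <- logical(n)
  for (i in seq_len(n)) {
    s <- sample_lesion_image(config)
    v <- as.numeric(s$image$values)
    lesions[i, ] <- v
    territory[i] <- s$territory
    b <- v > config$binarize_u
    nvox[i] <- sum(b)
    for (r in c("T", "F", "P"))
      fractions[i, r] <- mean(b[reg_idx[[r]]])
    if (null) {
      score_rows[[i]] <- data.frame(
        spk_pn = config$baseline + rnorm(1, 0, config$noise_sd),
        writt_pn = config$baseline + rnorm(1, 0, config$noise_sd),
        rep_n = config$nuisance$rep_n[["base"]] +
          rnorm(1, 0, config$nuisance_noise_sd),
        sem_m = config$nuisance$sem_m[["base"]] +
          rnorm(1, 0, config$nuisance_noise_sd),
        cspk_w = config$nuisance$cspk_w[["base"]] +
          rnorm(1, 0, config$nuisance_noise_sd),
        writt_copy = config$nuisance$writt_copy[["base"]] +
          rnorm(1, 0, config$nuisance_noise_sd))
      deficit[i] <- FALSE
    } else {
      sc <- sample_behavior(fractions[i, ], nvox[i], config)
      deficit[i] <- attr(sc, "deficit")
      score_rows[[i]] <- sc
    }
  }
  scores <- do.call(rbind, score_rows)
  rownames(scores) <- NULL
  ids <- sprintf("S%04d", seq_len(n))
  cohort <- new_cohort(ids, lesions, config$dim, config$affine, "fuzzy",
                       scores, nvox * config$voxel_mm^3 / 1000)
  truth <- structure(list(regions = regions, territory = territory,
                          fractions = fractions, deficit = deficit),
                     class = "synth_truth")
  list(cohort = cohort, truth = truth)
}

#' Dice overlap between a labeled region and a ground-truth region
#'
#' @param rois a [roi_set] (e.g. data-defined significant regions).
#' @param truth_rois the ground-truth [roi_set].
#' @param truth_label ground-truth region label or name.
#' @return Dice coefficient between the union of `rois` voxels and the
#'   ground-truth region.
#' @export
dice_overlap <- function(rois, truth_rois, truth_label) {
  if (is.character(truth_label))
    truth_label <- truth_rois$ids[match(truth_label, truth_rois$names)]
  a <- rois$labels > 0
  b <- truth_rois$labels == truth_label
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
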