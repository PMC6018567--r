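#' Design matrix for the lesion-deficit regression
#'
#' One row per patient; columns, in fixed order: the composite naming score
#' (regressor of interest), the four nuisance T-scores (nonword repetition,
#' semantic associations, spoken word comprehension, writing copy), lesion
#' volume (cm^3) and an intercept. Predictors are mean-centered by default
#' (the intercept absorbs the means; contrast t-statistics are unaffected).
#'
#' @param cohort a [lesion_cohort].
#' @param center mean-center the predictor columns.
#' @return Numeric matrix n x 7 with column names
#'   `composite, rep_n, sem_m, cspk_w, writt_copy, lesion_volume, intercept`.
#' @export
build_design_matrix <- function(cohort, center = TRUE) {
  sc <- cohort$scores
  X <- cbind(composite = composite_score(sc$spk_pn, sc$writt_pn),
             rep_n = sc$rep_n, sem_m = sc$sem_m, cspk_w = sc$cspk_w,
             writt_copy = sc$writt_copy, lesion_volume = cohort$volumes)
  if (!all(is.finite(X)))
    stop_iterlesion("non-finite values in the design", "design_error")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop_iterlesion(paste("constant design column:",
                          paste(colnames(X)[sds == 0], collapse = ", ")),
                    "design_error")
  if (center) X <- sweep(X, 2L, colMeans(X))
  X <- cbind(X, intercept = 1)
  if (qr(X)$rank < ncol(X)) {
    # name a culprit: a column explained by the others
    for (j in seq_len(ncol(X) - 1L)) {
      r <- qr(X[, -j, drop = FALSE])$rank
      if (r == qr(X)$rank)
        stop_iterlesion(sprintf("design is rank deficient (column '%s' is redundant)",
                                colnames(X)[j]), "design_error")
    }
    stop_iterlesion("design is rank deficient", "design_error")
  }
  X
}

#' Contrast for the lesion-deficit association
#'
#' Weight vector over the design columns with the test's sidedness. The
#' default tests the damage-impairs direction: a *negative* slope of lesion
#' abnormality on the composite naming score (weight -1 on `composite`), so
#' larger t means more abnormality with worse naming.
#'
#' @param design a design matrix from [build_design_matrix].
#' @param weights named numeric weights (unnamed columns get 0).
#' @return Numeric contrast vector aligned to the design columns.
#' @export
lesion_deficit_contrast <- function(design, weights = c(composite = -1)) {
  cvec <- setNames(numeric(ncol(design)), colnames(design))
  bad <- setdiff(names(weights), colnames(design))
  if (length(bad))
    stop_iterlesion(paste("unknown design column:", paste(bad, collapse = ", ")),
                    "design_error")
  cvec[names(weights)] <- weights
  if (all(cvec == 0))
    stop_iterlesion("contrast is all zero", "design_error")
  cvec
}

# core voxelwise OLS t for a response matrix Y (n x V); returns list(t, num)
ols_t <- function(Y, X, cvec, pinv, XtXi, df) {
  cxx <- drop(crossprod(cvec, XtXi %*% cvec))
  B <- pinv %*% Y
  num <- drop(crossprod(cvec, B))
  rss <- .colSums((Y - X %*% B)^2, nrow(Y), ncol(Y))
  se <- sqrt(rss / df * cxx)
  t <- num / se
  deg <- rss < 1e-12
  if (any(deg)) {
    # zero residual variance: +-Inf if the contrast estimate is nonzero,
    # 0 (no evidence either way) for the fully constant 0/0 case
    t[deg] <- ifelse(abs(num[deg]) < 1e-12, 0, sign(num[deg]) * Inf)
  }
  list(t = t, degenerate = sum(deg))
}

#' Mass-univariate voxelwise GLM
#'
#' At every voxel inside the analysis mask, ordinary least squares of the
#' lesion values (fuzzy abnormality or binary indicator — the cohort's kind)
#' on the design; t = c'beta / se(c'beta) with df = n - rank(X); one-sided
#' uncorrected p in the contrast's direction, and Z-equivalents
#' z = qnorm(1 - p_unc) for reporting.
#'
#' @param cohort a [lesion_cohort].
#' @param design design matrix from [build_design_matrix].
#' @param contrast contrast vector from [lesion_deficit_contrast].
#' @param mask an [build_analysis_mask] result.
#' @return A `stat_map`: 3D grids `t`, `z`, `p_unc`, `p_fwe` (NA until
#'   [permutation_maxT_fwe] fills it), residual `df`, and the mask.
#' @export
fit_voxelwise_glm <- function(cohort, design, contrast, mask) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(mask, "analysis_mask"))
  n <- n_patients(cohort)
  if (nrow(design) != n)
    stop_iterlesion("design rows != patients", "design_error")
  if (n <= ncol(design))
    stop_iterlesion("need more patients than design columns", "design_error")
  idx <- which(mask$include)
  if (length(idx) == 0L)
    stop_iterlesion("analysis mask is empty", "empty_mask_error")
  X <- design
  df <- n - qr(X)$rank
  XtXi <- solve(crossprod(X))
  pinv <- XtXi %*% t(X)
  Y <- cohort$lesions[, idx, drop = FALSE]
  fit <- ols_t(Y, X, contrast, pinv, XtXi, df)
  if (fit$degenerate > 0)
    message(sprintf("%d in-mask voxel(s) with zero residual variance", fit$degenerate))
  t3 <- p3 <- z3 <- f3 <- array(NA_real_, dim = cohort$dim)
  t3[idx] <- fit$t
  lp <- pt(fit$t, df, lower.tail = FALSE, log.p = TRUE)
  p3[idx] <- exp(lp)
  z3[idx] <- qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  structure(list(t = t3, z = z3, p_unc = p3, p_fwe = f3, df = df,
                 mask = mask, dim = cohort$dim, affine = cohort$affine,
                 contrast = contrast, perm = NULL),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  idx <- which(x$mask$include)
  cat(sprintf("<stat_map> %d in-mask voxels, df = %d, max t = %.2f\n",
              length(idx), x$df, max(x$t[idx])))
  if (!all(is.na(x$p_fwe[idx])))
    cat(sprintf("  min p_fwe = %.4g (%d permutations%s)\n",
                min(x$p_fwe[idx]), x$perm$n_perm,
                if (isTRUE(x$perm$exhaustive)) ", exhaustive" else ""))
  invisible(x)
}

# connected components of a voxel index set; returns membership per index
label_components <- function(idx, dim3, connectivity = 26L) {
  nv <- length(idx)
  if (nv == 0L) return(integer(0))
  if (nv == 1L) return(1L)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  else if (connectivity == 18L) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  else if (connectivity != 26L)
    stop_iterlesion("connectivity must be 6, 18 or 26", "parameter_error")
  # keep one of each +-pair
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  lookup <- integer(prod(dim3))
  lookup[idx] <- seq_len(nv)
  coords <- arrayInd(idx, dim3)
  from <- to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[r, ], `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= dim3[1] &
      nb[, 2] >= 1L & nb[, 2] <= dim3[2] &
      nb[, 3] >= 1L & nb[, 3] <= dim3[3]
    if (!any(ok)) next
    j <- lookup[coords_to_linear(nb[ok, , drop = FALSE], dim3)]
    hit <- j > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, j[hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = nv, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

# Freedman-Lane permutation engine: null distributions of max t and of the
# maximum supra-threshold cluster extent, over one shared permutation stream.
perm_engine <- function(Y, X, cvec, df, n_perm, seed, forming_t, dim3, idx,
                        connectivity) {
  n <- nrow(X)
  XtXi <- solve(crossprod(X))
  pinv <- XtXi %*% t(X)
  Z <- X[, cvec == 0, drop = FALSE]
  Rz <- diag(n) - Z %*% solve(crossprod(Z)) %*% t(Z)
  Yr <- Rz %*% Y

  exhaustive <- n <= 8 && factorial(n) <= n_perm
  if (exhaustive) {
    P <- all_permutations(n)
  } else {
    set.seed(seed)
    P <- t(replicate(n_perm, sample.int(n)))
  }
  np <- nrow(P)
  maxT <- numeric(np)
  maxC <- integer(np)
  look <- integer(prod(dim3))  # reusable cluster scratch not needed; labels fresh
  for (i in seq_len(np)) {
    res <- ols_t(Yr[P[i, ], , drop = FALSE], X, cvec, pinv, XtXi, df)
    ts <- res$t
    ts[!is.finite(ts)] <- 0  # degenerate permuted voxels carry no evidence
    maxT[i] <- max(ts)
    supra <- which(ts > forming_t)
    maxC[i] <- if (length(supra) == 0L) 0L else {
      memb <- label_components(idx[supra], dim3, connectivity)
      max(tabulate(memb))
    }
  }
  list(maxT = maxT, max_cluster = maxC, n_perm = np, exhaustive = exhaustive,
       forming_t = forming_t, connectivity = connectivity, seed = seed)
}

# permutation p-value: exact count/N over an exhaustive enumeration
# (identity included, so p > 0), add-one Monte-Carlo otherwise
perm_pval <- function(stat, null, exhaustive) {
  cnt <- count_ge(stat, null)
  if (exhaustive) cnt / length(null) else (1 + cnt) / (length(null) + 1)
}

#' Permutation maxT family-wise error correction
#'
#' Fits the voxelwise GLM, then builds the null distribution of the maximum
#' t over the mask by Freedman-Lane residual permutation: the nuisance-only
#' model is fitted, its residuals are row-permuted, and the full model is
#' refitted per permutation. The corrected p at voxel v is the exceedance
#' rank of t(v) in that null. The same permutation stream also records the
#' maximum supra-threshold cluster extent (at the `forming_p` uncorrected
#' threshold) for [cluster_level_fwe]. When all distinct permutations number
#' no more than `n_perm`, they are enumerated exhaustively and p-values are
#' exact.
#'
#' Tie handling: a permutation statistic equal to the observed one counts
#' toward the p-value (so p > 0 always), with equality assessed at a 1e-8
#' relative tolerance so that structurally tied statistics computed along
#' different floating-point paths are treated identically.
#'
#' @param cohort,design,contrast,mask as in [fit_voxelwise_glm].
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed for the permutation stream.
#' @param forming_p one-sided uncorrected cluster-forming threshold
#'   (default 0.001).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default).
#' @return A `stat_map` with `p_fwe` filled and the permutation null
#'   distributions stored in `$perm`.
#' @export
permutation_maxT_fwe <- function(cohort, design, contrast, mask,
                                 n_perm = 5000L, seed = 1L,
                                 forming_p = 0.001, connectivity = 26L) {
  if (n_perm < 1) stop_iterlesion("n_perm must be >= 1", "parameter_error")
  sm <- fit_voxelwise_glm(cohort, design, contrast, mask)
  idx <- which(mask$include)
  forming_t <- qt(forming_p, sm$df, lower.tail = FALSE)
  pe <- perm_engine(cohort$lesions[, idx, drop = FALSE], design, contrast,
                    sm$df, n_perm, seed, forming_t, cohort$dim, idx,
                    connectivity)
  sm$p_fwe[idx] <- perm_pval(sm$t[idx], pe$maxT, pe$exhaustive)
  sm$perm <- pe
  sm$perm$forming_p <- forming_p
  sm
}

#' Critical t at a corrected alpha
#'
#' Smallest t whose maxT-corrected p-value is at most `alpha` — the
#' (1 - alpha) quantile (of type 1) of the permutation maxT null.
#'
#' @param statmap a `stat_map` with permutations run.
#' @param alpha corrected significance level.
#' @export
fwe_critical_t <- function(statmap, alpha = 0.05) {
  if (is.null(statmap$perm))
    stop_iterlesion("run permutation_maxT_fwe first", "state_error")
  null <- statmap$perm$maxT
  n <- length(null)
  k <- if (statmap$perm$exhaustive) floor(alpha * n) else floor(alpha * (n + 1)) - 1
  if (k < 1) return(Inf)
  sort(null, decreasing = TRUE)[k]
}

#' Cluster-level family-wise error
#'
#' Extracts connected supra-threshold clusters (t above the cluster-forming
#' threshold used during permutation) and assigns each a corrected p from
#' the permutation null of the maximum cluster extent. Clusters are sorted
#' by peak t, descending.
#'
#' @param statmap a `stat_map` from [permutation_maxT_fwe].
#' @return A `cluster_set`: data frame with one row per cluster (label,
#'   `n_voxels`, peak voxel index and world mm coordinate, peak t and Z,
#'   voxel-level `p_fwe_peak`, `p_fwe_cluster`), with the 3D label array in
#'   `attr(, "labels")`. Empty (zero rows) when nothing survives the forming
#'   threshold.
#' @export
cluster_level_fwe <- function(statmap) {
  if (is.null(statmap$perm))
    stop_iterlesion("run permutation_maxT_fwe first", "state_error")
  pe <- statmap$perm
  idx <- which(statmap$mask$include)
  tv <- statmap$t[idx]
  supra <- which(tv > pe$forming_t)
  labels3 <- array(0L, dim = statmap$dim)
  if (length(supra) == 0L) {
    out <- empty_cluster_df()
  } else {
    vox <- idx[supra]
    memb <- label_components(vox, statmap$dim, pe$connectivity)
    ncl <- max(memb)
    rows <- lapply(seq_len(ncl), function(k) {
      v <- vox[memb == k]
      pk <- v[which.max(statmap$t[v])]
      co <- arrayInd(pk, statmap$dim)
      w <- voxel_to_world(co, statmap$affine)
      data.frame(label = k, n_voxels = length(v), peak_index = pk,
                 peak_x = w[1], peak_y = w[2], peak_z = w[3],
                 peak_t = statmap$t[pk], peak_z_equiv = statmap$z[pk],
                 p_fwe_peak = statmap$p_fwe[pk],
                 p_fwe_cluster = perm_pval(length(v), pe$max_cluster,
                                           pe$exhaustive))
    })
    out <- do.call(rbind, rows)
    ord <- order(out$peak_t, decreasing = TRUE)
    out <- out[ord, , drop = FALSE]
    relab <- integer(ncl)
    relab[out$label] <- seq_len(ncl)
    out$label <- seq_len(ncl)
    rownames(out) <- NULL
    labels3[vox] <- relab[memb]
  }
  structure(out, labels = labels3, class = c("cluster_set", "data.frame"))
}

empty_cluster_df <- function() {
  data.frame(label = integer(0), n_voxels = integer(0), peak_index = integer(0),
             peak_x = numeric(0), peak_y = numeric(0), peak_z = numeric(0),
             peak_t = numeric(0), peak_z_equiv = numeric(0),
             p_fwe_peak = numeric(0), p_fwe_cluster = numeric(0))
}

#' Extract significant regions of interest
#'
#' Under the `"voxel"` rule (default), the ROIs are the connected components
#' of the voxels with voxel-level corrected p at most `alpha`. Under the
#' `"cluster"` rule, every voxel of each cluster whose cluster-level
#' corrected p is at most `alpha`. Labels are assigned in descending peak-t
#' order. An empty set (nothing significant) is a valid result.
#'
#' @param statmap a `stat_map` from [permutation_maxT_fwe].
#' @param clusterset a `cluster_set` from [cluster_level_fwe].
#' @param alpha corrected significance level (default 0.05).
#' @param rule `"voxel"` or `"cluster"`.
#' @return A [roi_set] (possibly with zero regions).
#' @export
threshold_and_extract_rois <- function(statmap, clusterset, alpha = 0.05,
                                       rule = c("voxel", "cluster")) {
  rule <- match.arg(rule)
  labels3 <- array(0L, dim = statmap$dim)
  if (rule == "voxel") {
    idx <- which(statmap$mask$include)
    sig <- idx[!is.na(statmap$p_fwe[idx]) & statmap$p_fwe[idx] <= alpha]
    if (length(sig)) {
      memb <- label_components(sig, statmap$dim, statmap$perm$connectivity)
      peaks <- vapply(seq_len(max(memb)),
                      function(k) max(statmap$t[sig[memb == k]]), numeric(1))
      relab <- integer(max(memb))
      relab[order(peaks, decreasing = TRUE)] <- seq_along(peaks)
      labels3[sig] <- relab[memb]
    }
  } else {
    keep <- clusterset$label[clusterset$p_fwe_cluster <= alpha]
    cl3 <- attr(clusterset, "labels")
    new <- 0L
    for (k in keep) {  # already in descending peak-t order
      new <- new + 1L
      labels3[cl3 == k] <- new
    }
  }
  if (!any(labels3 > 0)) {
    return(structure(list(labels = labels3, ids = integer(0),
                          names = setNames(character(0), character(0)),
                          affine = statmap$affine), class = "roi_set"))
  }
  roi_set(labels3, affine = statmap$affine)
}

#' Statistical power map
#'
#' At each in-mask voxel where k of n patients carry a binary lesion, the
#' most favourable lesion-deficit association the sampling allows is the
#' two-sample pooled-t obtained by assigning the k lowest observed composite
#' naming scores to the lesioned group (this assignment maximizes the t over
#' all assignments of the observed scores). The voxel is powered iff that
#' best-case t reaches the corrected critical value. Voxels lesioned in no
#' patient or in all patients admit no contrast and are unpowered.
#'
#' @param cohort a [lesion_cohort].
#' @param mask an analysis mask.
#' @param critical_t corrected critical value, e.g. from [fwe_critical_t].
#' @param binarize_u threshold applied to fuzzy cohorts.
#' @return A `power_map` with logical 3D grid `powered`.
#' @export
power_map <- function(cohort, mask, critical_t, binarize_u = 0.3) {
  stopifnot(inherits(mask, "analysis_mask"))
  n <- n_patients(cohort)
  comp <- sort(composite_score(cohort$scores$spk_pn, cohort$scores$writt_pn))
  best_t <- best_case_t(comp)  # indexed by k = 1..n-1
  les <- cohort_binary_matrix(cohort, binarize_u)
  idx <- which(mask$include)
  counts <- round(colSums(les[, idx, drop = FALSE]))
  pow <- rep(FALSE, length(idx))
  inner <- counts >= 1 & counts <= n - 1
  pow[inner] <- best_t[counts[inner]] >= critical_t
  grid <- array(FALSE, dim = cohort$dim)
  grid[idx] <- pow
  structure(list(powered = grid, critical_t = critical_t,
                 affine = cohort$affine), class = "power_map")
}

# best-case pooled two-sample t for every split size k of sorted scores:
# group 1 = the k lowest scores (lesioned), group 2 = the rest
best_case_t <- function(sorted_scores) {
  n <- length(sorted_scores)
  cs <- cumsum(sorted_scores)
  cs2 <- cumsum(sorted_scores^2)
  k <- seq_len(n - 1L)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  ss1 <- cs2[k] - k * m1^2
  ss2 <- (cs2[n] - cs2[k]) - (n - k) * m2^2
  sp2 <- (ss1 + ss2) / (n - 2L)
  tt <- (m2 - m1) / sqrt(sp2 * (1 / k + 1 / (n - k)))
  tt[sp2 <= 0] <- ifelse(m2[sp2 <= 0] > m1[sp2 <= 0], Inf, 0)
  tt
}

#' Write a cluster table as CSV
#'
#' Columns mirror the conventional report: region label, peak world
#' coordinate (mm), peak Z, voxel-level corrected p, cluster extent in
#' voxels, cluster-level corrected p.
#'
#' @param clusterset a `cluster_set`.
#' @param path output CSV path.
#' @export
write_cluster_table <- function(clusterset, path) {
  df <- as.data.frame(clusterset)[, c("label", "peak_x", "peak_y", "peak_z",
                                      "peak_z_equiv", "p_fwe_peak",
                                      "n_voxels", "p_fwe_cluster")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
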