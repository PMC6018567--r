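test_that("design matrix has the fixed column order and validates rank", {
  set.seed(2)
  co <- random_cohort(n = 10)
  X <- build_design_matrix(co)
  expect_equal(dim(X), c(10L, 7L))
  expect_identical(colnames(X), c("composite", "rep_n", "sem_m", "cspk_w",
                                  "writt_copy", "lesion_volume", "intercept"))
  expect_equal(unname(X[, "intercept"]), rep(1, 10))
  # uncentered design carries the raw volumes
  X0 <- build_design_matrix(co, center = FALSE)
  expect_equal(unname(X0[, "lesion_volume"]), unname(co$volumes))
  expect_equal(unname(X0[, "composite"]),
               composite_score(co$scores$spk_pn, co$scores$writt_pn))

  # duplicated patients are fine; a constant column is not
  co2 <- co
  co2$scores[2, ] <- co2$scores[1, ]
  expect_silent(build_design_matrix(co2))
  co3 <- co
  co3$scores$writt_copy <- 55
  expect_error(build_design_matrix(co3), class = "design_error")
  expect_match(tryCatch(build_design_matrix(co3), error = conditionMessage),
               "writt_copy")
})

test_that("voxelwise OLS t matches the normal-equations oracle to 1e-10", {
  for (seed in 1:3) {
    co <- random_cohort(n = 8, dim3 = c(3, 3, 3), seed = seed)
    mask <- full_mask(co)
    X <- build_design_matrix(co)
    cv <- lesion_deficit_contrast(X)
    sm <- fit_voxelwise_glm(co, X, cv, mask)
    idx <- which(mask$include)
    for (v in idx)
      expect_equal(sm$t[v], ols_t_oracle(co$lesions[, v], X, cv),
                   tolerance = 1e-10)
    expect_equal(sm$df, 8 - 7)
    # z-equivalents invert the one-sided p
    expect_equal(qnorm(sm$p_unc[idx], lower.tail = FALSE), sm$z[idx],
                 tolerance = 1e-8)
  }
})

test_that("uncorrected p-values are roughly uniform under independence", {
  # i.i.d. response independent of all regressors: parametric p close to
  # uniform (for sparse bounded lesion responses only the permutation p is
  # calibrated, which test-acceptance exercises)
  co <- random_cohort(n = 120, dim3 = c(4, 4, 4), seed = 31)
  mask <- full_mask(co)
  X <- build_design_matrix(co)
  sm <- fit_voxelwise_glm(co, X, lesion_deficit_contrast(X), mask)
  p <- sm$p_unc[mask$include]
  expect_gt(mean(p), 0.35)
  expect_lt(mean(p), 0.65)
  expect_lt(max(abs(quantile(p, c(0.25, 0.75)) - c(0.25, 0.75))), 0.15)
})

test_that("constant lesion values at a voxel are handled without NaN", {
  co <- random_cohort(n = 9, dim3 = c(3, 3, 3), seed = 4)
  co$lesions[, 5] <- 0.7  # constant voxel: zero residual variance, zero effect
  mask <- full_mask(co)
  X <- build_design_matrix(co)
  expect_message(sm <- fit_voxelwise_glm(co, X, lesion_deficit_contrast(X), mask),
                 "zero residual variance")
  expect_equal(sm$t[5], 0)
  expect_false(anyNA(sm$t[mask$include]))
})

test_that("Monte-Carlo maxT with all permutations equals exhaustive enumeration", {
  co <- random_cohort(n = 5, dim3 = c(3, 3, 1), seed = 6)
  mask <- full_mask(co)
  sc <- co$scores
  # design small enough to leave residual df at n = 5
  X <- cbind(composite = composite_score(sc$spk_pn, sc$writt_pn),
             lesion_volume = co$volumes, intercept = 1)
  cv <- lesion_deficit_contrast(X)
  sm <- permutation_maxT_fwe(co, X, cv, mask, n_perm = 120, seed = 99)
  expect_true(sm$perm$exhaustive)
  expect_equal(sm$perm$n_perm, 120L)
  idx <- which(mask$include)
  oracle <- fl_maxT_oracle(co$lesions[, idx], X, cv)
  expect_equal(unname(sm$p_fwe[idx]), oracle, tolerance = 1e-12)
})

test_that("permutation p-values are deterministic, bounded and ordered", {
  co <- random_cohort(n = 12, dim3 = c(4, 4, 2), seed = 8)
  mask <- full_mask(co)
  X <- build_design_matrix(co)
  cv <- lesion_deficit_contrast(X)
  a <- permutation_maxT_fwe(co, X, cv, mask, n_perm = 200, seed = 42)
  b <- permutation_maxT_fwe(co, X, cv, mask, n_perm = 200, seed = 42)
  expect_identical(a$p_fwe, b$p_fwe)
  idx <- which(mask$include)
  expect_true(all(a$p_fwe[idx] >= 1 / 201))
  expect_true(all(a$p_fwe[idx] >= a$p_unc[idx]))
  # monotone non-increasing in t
  ord <- order(a$t[idx])
  expect_true(all(diff(a$p_fwe[idx][ord]) <= 0))
})

test_that("cluster extraction agrees with a BFS connected-components oracle", {
  set.seed(13)
  dim3 <- c(7, 7, 7)
  for (rep in 1:5) {
    idx <- sort(sample(prod(dim3), 25))
    mine <- iterlesion:::label_components(idx, dim3, 26L)
    expect_true(same_partition(mine, bfs_components(idx, dim3)))
  }
  # a single voxel forms a cluster of size one
  expect_identical(iterlesion:::label_components(17L, dim3, 26L), 1L)

  # end-to-end: cluster voxel counts match the oracle partition of the
  # supra-threshold set
  co <- random_cohort(n = 12, dim3 = c(4, 4, 3), seed = 14)
  mask <- full_mask(co)
  X <- build_design_matrix(co)
  sm <- permutation_maxT_fwe(co, X, lesion_deficit_contrast(X), mask,
                             n_perm = 100, seed = 5, forming_p = 0.3)
  cs <- cluster_level_fwe(sm)
  idx <- which(mask$include)
  supra <- idx[sm$t[idx] > sm$perm$forming_t]
  if (length(supra)) {
    oracle_sizes <- sort(tabulate(bfs_components(supra, c(4, 4, 3))))
    expect_equal(sort(cs$n_voxels), oracle_sizes)
    expect_true(all(diff(cs$peak_t) <= 0))  # sorted by peak statistic
  } else {
    expect_equal(nrow(cs), 0L)
  }
})

test_that("ROI extraction returns exactly the significant voxels", {
  co <- random_cohort(n = 12, dim3 = c(4, 4, 3), seed = 15)
  mask <- full_mask(co)
  X <- build_design_matrix(co)
  sm <- permutation_maxT_fwe(co, X, lesion_deficit_contrast(X), mask,
                             n_perm = 100, seed = 5)
  cs <- cluster_level_fwe(sm)
  # nothing significant at a tiny alpha -> empty ROI set
  empty <- threshold_and_extract_rois(sm, cs, alpha = 1e-6)
  expect_equal(iterlesion:::n_rois(empty), 0L)
  # generous alpha: ROI voxels are exactly those with p_fwe <= alpha
  rois <- threshold_and_extract_rois(sm, cs, alpha = 0.8)
  sig <- which(!is.na(sm$p_fwe) & sm$p_fwe <= 0.8)
  expect_setequal(which(rois$labels > 0), sig)
})

test_that("an orthogonal noise column changes t only through df", {
  co <- random_cohort(n = 12, dim3 = c(3, 3, 1), seed = 16)
  mask <- full_mask(co)
  X <- build_design_matrix(co)
  cv <- lesion_deficit_contrast(X)
  v <- which(mask$include)[1]
  y <- co$lesions[, v]
  set.seed(1)
  w <- stats::residuals(stats::lm(rnorm(12) ~ X + y - 1))
  t1 <- ols_t_oracle(y, X, cv)
  t2 <- ols_t_oracle(y, cbind(X, w), c(cv, 0))
  df1 <- 12 - qr(X)$rank
  expect_equal(t2, t1 * sqrt((df1 - 1) / df1), tolerance = 1e-10)
})

test_that("best-case power-map t equals exhaustive assignment search", {
  set.seed(17)
  scores <- sort(rnorm(7, 60, 8))
  for (k in 1:6) {
    best <- iterlesion:::best_case_t(scores)[k]
    combos <- utils::combn(7, k)
    oracle <- max(apply(combos, 2L, function(g) {
      a <- scores[g]; b <- scores[-g]
      sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 5
      (mean(b) - mean(a)) / sqrt(sp2 * (1 / k + 1 / (7 - k)))
    }))
    expect_equal(best, oracle, tolerance = 1e-10)
  }
})

test_that("power map is FALSE where no contrast is possible", {
  dim3 <- c(3, 3, 1)
  les <- rbind(rep(1, 9), rep(1, 9), rep(1, 9),
               rep(0, 9), rep(0, 9), rep(0, 9), rep(0, 9), rep(0, 9))
  les[4:5, 1] <- 1  # voxel 1 lesioned in 5/8; the rest in 3/8
  set.seed(18)
  co <- make_cohort(les, dim3, rand_scores(8))
  mask <- build_analysis_mask(overlap_map(co), 1L)
  pm <- power_map(co, mask, critical_t = 0)   # any positive t passes
  expect_true(pm$powered[1, 1, 1])
  pm_inf <- power_map(co, mask, critical_t = Inf)
  expect_false(any(pm_inf$powered))

  co_all <- make_cohort(matrix(1, 4, 9), dim3, rand_scores(4))
  m_all <- build_analysis_mask(overlap_map(co_all), 1L)
  expect_false(any(power_map(co_all, m_all, critical_t = 0)$powered))
})
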