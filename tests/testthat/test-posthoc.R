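# damage-fraction profiles engineered to reproduce the canonical five-group
# incidence table (group sizes 68/23/71/70/127, impaired 18/10/48/13/9)
table3a_fixture <- function() {
  sizes <- c(68, 23, 71, 70, 127)
  impaired_n <- c(18, 10, 48, 13, 9)
  fF <- c(rep(0.80, 68), rep(0.10, 23), rep(0.90, 71), rep(0.50, 70),
          rep(0.10, 127))
  fT <- c(rep(0.10, 68), rep(0.80, 23), rep(0.90, 71), rep(0.10, 70),
          rep(0.10, 127))
  deficits <- unlist(mapply(function(n, k) c(rep(TRUE, k), rep(FALSE, n - k)),
                            sizes, impaired_n))
  list(fF = fF, fT = fT, deficits = deficits)
}

test_that("five-way grouping matches the damage-fraction rules", {
  expect_equal(assign_damage_groups(0.80, 0.10), 1L)
  expect_equal(assign_damage_groups(0.10, 0.80), 2L)
  expect_equal(assign_damage_groups(0.90, 0.90), 3L)
  expect_equal(assign_damage_groups(0.50, 0.50), 4L)
  expect_equal(assign_damage_groups(0.10, 0.10), 5L)
  # boundaries: 0.25 counts as spared, 0.75 as substantial
  expect_equal(assign_damage_groups(0.75, 0.25), 1L)
  expect_equal(assign_damage_groups(0.25, 0.75), 2L)
  expect_equal(assign_damage_groups(0.75, 0.75), 3L)
  expect_equal(assign_damage_groups(0.25, 0.25), 5L)
  expect_equal(assign_damage_groups(0.26, 0.10), 4L)

  # the groups always partition: every fraction pair gets exactly one group
  set.seed(41)
  f1 <- runif(500); f2 <- runif(500)
  g <- assign_damage_groups(f1, f2)
  expect_true(all(g %in% 1:5))
  expect_equal(length(g), 500L)
})

test_that("incidence table reproduces the canonical counts and percentages", {
  fx <- table3a_fixture()
  g <- assign_damage_groups(fx$fF, fx$fT)
  expect_equal(as.integer(table(g)), c(68L, 23L, 71L, 70L, 127L))
  inc <- incidence_table(g, fx$deficits)
  expect_equal(inc$n[1:5], c(68, 23, 71, 70, 127))
  expect_equal(inc$impaired[1:5], c(18, 10, 48, 13, 9))
  expect_equal(inc$pct_impaired[1:5], c(26, 43, 68, 19, 7))
  expect_equal(inc$n[6], 359)
  expect_equal(inc$impaired[6], 98)
  # counts partition the cohort
  expect_equal(sum(inc$n[1:5]), inc$n[6])

  # invariant to patient order
  perm <- sample(length(g))
  inc2 <- incidence_table(g[perm], fx$deficits[perm])
  expect_equal(inc2, inc)

  # a group with zero impaired reports 0%
  inc0 <- incidence_table(c(1, 1, 5), c(FALSE, FALSE, TRUE))
  expect_equal(inc0$pct_impaired[1], 0)
  expect_true(is.na(inc0$pct_impaired[2]))
})

test_that("Pearson chi-square matches the from-scratch formula and chance", {
  # property: equals sum((O-E)^2/E) on random tables
  set.seed(42)
  for (i in 1:20) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(pearson_chi2_2x2(tab)$statistic, sum((tab - E)^2 / E),
                 tolerance = 1e-12)
  }
  expect_equal(pearson_chi2_2x2(matrix(c(10, 20, 10, 20), 2))$statistic, 0)
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 5, 7), 2)),
               class = "degenerate_table_error")
  expect_error(pearson_chi2_2x2(matrix(1:6, 2)), class = "parameter_error")
})

test_that("group-versus-spared chi-squares reproduce the reference values", {
  fx <- table3a_fixture()
  g <- assign_damage_groups(fx$fF, fx$fT)
  inc <- incidence_table(g, fx$deficits)
  expect_equal(group_vs_reference_chi2(inc, 1)$statistic, 13.95,
               tolerance = 0.05 / 13.95)
  expect_equal(group_vs_reference_chi2(inc, 2)$statistic, 23.3,
               tolerance = 0.05 / 23.3)
  expect_equal(group_vs_reference_chi2(inc, 3)$statistic, 81.4,
               tolerance = 0.05 / 81.4)
  expect_lt(group_vs_reference_chi2(inc, 1)$p_value, 0.001)
})

test_that("severity ANCOVA matches a closed-form least-squares oracle", {
  set.seed(43)
  n <- 60
  g <- sample(1:3, n, replace = TRUE)
  vol <- runif(n, 1, 60)
  y <- 65 - 0.1 * vol - 3 * (g == 2) - 6 * (g == 3) + rnorm(n, 0, 2)
  res <- severity_ancova(g, y, vol)
  # oracle: extra-sum-of-squares F between nested models
  X0 <- cbind(1, vol)
  X1 <- cbind(1, vol, g == 2, g == 3)
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  df1 <- 2; df2 <- n - 4
  F_oracle <- ((rss(X0) - rss(X1)) / df1) / (rss(X1) / df2)
  expect_equal(res$F, F_oracle, tolerance = 1e-8)
  expect_equal(res$df1, df1)
  expect_equal(res$df2, df2)
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_bonferroni > 0 & res$pairwise$p_bonferroni <= 1))
})

test_that("severity ANCOVA: identical group patterns give F = 0, and the F
           grows with the group effect", {
  # two groups with identical within-group score/volume patterns
  y <- c(50, 60, 55, 50, 60, 55)
  vol <- c(10, 20, 12, 10, 20, 12)
  g <- c(1, 1, 1, 2, 2, 2)
  expect_equal(severity_ancova(g, y, vol)$F, 0, tolerance = 1e-10)

  set.seed(44)
  n <- 90
  gg <- sample(1:3, n, replace = TRUE)
  vv <- runif(n, 1, 50)
  Fs <- vapply(c(1, 4, 8), function(eff) {
    yy <- 65 - 0.05 * vv - eff * (gg == 2) - 2 * eff * (gg == 3) + rnorm(n, 0, 3)
    severity_ancova(gg, yy, vv)$F
  }, numeric(1))
  expect_true(all(diff(Fs) > 0))

  expect_warning(severity_ancova(c(1, 1, 1, 2, 2, 2, 3), rnorm(7), runif(7)),
                 "dropping group")
})

test_that("smallest-lesion report finds the minimal qualifying lesion", {
  dim3 <- c(5, 5, 5)
  labels <- box_array(dim3, c(2, 2, 2), c(3, 3, 3))  # 8-voxel ROI
  rois <- roi_set(labels, names = "R")
  roi_idx <- which(labels == 1)
  mk <- function(extra) {
    a <- array(0, dim3)
    a[roi_idx] <- 1                     # full ROI coverage
    if (extra > 0) a[setdiff(seq_len(125), roi_idx)[seq_len(extra)]] <- 1
    as.numeric(a)
  }
  les <- rbind(mk(40), mk(5), mk(0), mk(100))
  set.seed(45)
  co <- make_cohort(les, dim3, rand_scores(4))
  deficits <- c(TRUE, TRUE, FALSE, TRUE)  # p03 qualifies on damage, not deficit

  rep1 <- smallest_lesion_report(co, rois, deficits)
  expect_equal(rep1$n_qualifying, 3L)
  expect_identical(rep1$patient_id, "p02")  # smallest qualifying lesion
  expect_equal(rep1$min_volume_cm3, 13 * 8 / 1000)
  expect_true(rep1$extends_beyond_roi)

  # a lesion identical to the ROI does not extend beyond it
  rep2 <- smallest_lesion_report(co, rois, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(rep2$patient_id, "p03")
  expect_false(rep2$extends_beyond_roi)

  # nobody qualifies -> NA row
  rep3 <- smallest_lesion_report(co, rois, rep(FALSE, 4))
  expect_equal(rep3$n_qualifying, 0L)
  expect_true(is.na(rep3$min_volume_cm3))
})
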