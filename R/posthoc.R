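#' Five-way damage grouping
#'
#' Assigns each patient to one of five groups from their damage fractions to
#' the frontal and temporal regions: Group 1, >= 75% frontal with <= 25%
#' temporal; Group 2, >= 75% temporal with <= 25% frontal; Group 3, >= 75%
#' to both; Group 5, <= 25% to both; Group 4, every remaining combination
#' (partial damage to one or both). The five groups partition any cohort.
#'
#' @param f_frontal,f_temporal damage fractions in `[0, 1]` (vectorized).
#' @return Integer group labels 1-5.
#' @export
assign_damage_groups <- function(f_frontal, f_temporal) {
  stopifnot(length(f_frontal) == length(f_temporal),
            all(f_frontal >= 0 & f_frontal <= 1),
            all(f_temporal >= 0 & f_temporal <= 1))
  g <- rep(4L, length(f_frontal))
  g[f_frontal >= 0.75 & f_temporal <= 0.25] <- 1L
  g[f_temporal >= 0.75 & f_frontal <= 0.25] <- 2L
  g[f_frontal >= 0.75 & f_temporal >= 0.75] <- 3L
  g[f_frontal <= 0.25 & f_temporal <= 0.25] <- 5L
  g
}

#' Incidence of the deficit per damage group
#'
#' Counts and integer percentages of patients with the deficit of interest
#' in each group, plus a totals row.
#'
#' @param groups integer group labels (1-5) per patient.
#' @param deficits logical deficit-of-interest indicator per patient.
#' @return Data frame with columns `group`, `n`, `impaired`, `not_impaired`,
#'   `pct_impaired` (NA for empty groups) and a `"total"` row.
#' @export
incidence_table <- function(groups, deficits) {
  stopifnot(length(groups) == length(deficits))
  rows <- lapply(1:5, function(g) {
    sel <- groups == g
    n <- sum(sel)
    imp <- sum(deficits[sel])
    data.frame(group = as.character(g), n = n, impaired = imp,
               not_impaired = n - imp,
               pct_impaired = if (n > 0) round(100 * imp / n) else NA_real_)
  })
  out <- do.call(rbind, rows)
  tot <- data.frame(group = "total", n = length(groups),
                    impaired = sum(deficits),
                    not_impaired = sum(!deficits),
                    pct_impaired = round(100 * mean(deficits)))
  rbind(out, tot)
}

#' Pearson chi-square on a 2x2 table
#'
#' Pearson's X^2 = sum (O - E)^2 / E *without* continuity correction, with
#' 1 degree of freedom. Rows are groups, columns impaired / not impaired.
#'
#' @param tab 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @return List with `statistic`, `p_value`, `df = 1`.
#' @export
pearson_chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)))
    stop_iterlesion("expected a 2x2 table", "parameter_error")
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_iterlesion("all margins must be positive", "degenerate_table_error")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value), df = 1L)
}

#' Compare one damage group's incidence against a reference group
#'
#' Builds the 2x2 table (group vs reference, impaired vs not) from an
#' incidence table and applies [pearson_chi2_2x2].
#'
#' @param inc an [incidence_table] result.
#' @param group group to test.
#' @param reference reference group (default 5, relative sparing).
#' @export
group_vs_reference_chi2 <- function(inc, group, reference = 5) {
  r1 <- inc[inc$group == as.character(group), ]
  r2 <- inc[inc$group == as.character(reference), ]
  pearson_chi2_2x2(rbind(c(r1$impaired, r1$not_impaired),
                         c(r2$impaired, r2$not_impaired)))
}

#' Severity comparison across damage groups, adjusting for lesion size
#'
#' Linear model of the composite naming score on lesion volume and the group
#' factor; the group effect is tested by the F for the factor entered after
#' volume, and all pairwise differences of adjusted group means are reported
#' with Bonferroni-corrected p-values. Groups with fewer than two members
#' are dropped with a warning.
#'
#' @param groups integer group labels per patient.
#' @param composite composite naming scores.
#' @param volumes lesion volumes (cm^3).
#' @return A `severity_result`: `F`, `df1`, `df2`, `p_value`, `pairwise`
#'   data frame (`group_a`, `group_b`, `difference`, `t`, `p_bonferroni`),
#'   and the fitted `model`.
#' @export
severity_ancova <- function(groups, composite, volumes) {
  stopifnot(length(groups) == length(composite),
            length(groups) == length(volumes))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("dropping group(s) with < 2 members: %s",
                    paste(small, collapse = ", ")))
    keep <- !(groups %in% as.integer(small))
    groups <- groups[keep]; composite <- composite[keep]
    volumes <- volumes[keep]
  }
  if (length(unique(groups)) < 2)
    stop_iterlesion("need at least two non-empty groups", "precondition_error")
  d <- data.frame(y = composite, vol = volumes, g = factor(groups))
  fit <- lm(y ~ vol + g, data = d)
  an <- anova(fit)
  Fg <- an["g", "F value"]
  df1 <- an["g", "Df"]; df2 <- an["Residuals", "Df"]
  p <- an["g", "Pr(>F)"]

  lv <- levels(d$g)
  V <- vcov(fit); b <- coef(fit)
  cn <- names(b)
  eff <- setNames(numeric(length(lv)), lv)  # group effects vs baseline
  for (l in lv[-1]) eff[l] <- b[paste0("g", l)]
  pairs <- t(utils::combn(lv, 2))
  m <- nrow(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- pairs[i, 1]; bb <- pairs[i, 2]
    cv <- setNames(numeric(length(b)), cn)
    if (a != lv[1]) cv[paste0("g", a)] <- 1
    if (bb != lv[1]) cv[paste0("g", bb)] <- -1
    est <- sum(cv * b)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    tt <- est / se
    data.frame(group_a = a, group_b = bb, difference = est, t = tt,
               p_bonferroni = min(1, 2 * pt(abs(tt), df2, lower.tail = FALSE) * m))
  })
  structure(list(F = Fg, df1 = df1, df2 = df2, p_value = p,
                 pairwise = do.call(rbind, rows), model = fit),
            class = "severity_result")
}

#' @export
print.severity_result <- function(x, ...) {
  cat(sprintf("severity ANCOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p_value))
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Smallest lesion associated with the deficit, per region
#'
#' For each region, among the patients who have the deficit of interest and
#' more than `damage_cutoff` damage to that region, reports the minimum
#' (binary) lesion volume, the patient carrying it, and whether that lesion
#' extends beyond the region (any lesioned voxel outside it) — probing
#' whether focal damage to the identified region is ever observed.
#'
#' @param cohort a [lesion_cohort].
#' @param rois a non-empty [roi_set].
#' @param deficits logical deficit indicator per patient.
#' @param damage_cutoff fraction above which a region counts as damaged.
#' @param binarize_u threshold for fuzzy cohorts.
#' @return Data frame per region: `roi`, `n_qualifying`,
#'   `min_volume_cm3`, `patient_id`, `extends_beyond_roi` (NA row when no
#'   patient qualifies).
#' @export
smallest_lesion_report <- function(cohort, rois, deficits,
                                   damage_cutoff = 0.25, binarize_u = 0.3) {
  if (n_rois(rois) == 0L)
    stop_iterlesion("ROI set is empty", "precondition_error")
  stopifnot(length(deficits) == n_patients(cohort))
  bin <- cohort_as_kind(cohort, "binary", binarize_u)
  prof <- damage_profile(bin, rois)
  vols <- rowSums(bin$lesions) * bin$voxel_volume / 1000
  rows <- lapply(seq_along(rois$ids), function(j) {
    qual <- which(deficits & prof[, j] > damage_cutoff)
    if (length(qual) == 0L)
      return(data.frame(roi = unname(rois$names[j]), n_qualifying = 0L,
                        min_volume_cm3 = NA_real_, patient_id = NA_character_,
                        extends_beyond_roi = NA))
    i <- qual[which.min(vols[qual])]
    inroi <- rois$labels == rois$ids[j]
    outside <- any(bin$lesions[i, ] > 0 & !as.vector(inroi))
    data.frame(roi = unname(rois$names[j]), n_qualifying = length(qual),
               min_volume_cm3 = vols[i], patient_id = bin$ids[i],
               extends_beyond_roi = outside)
  })
  do.call(rbind, rows)
}

#' Full post-hoc report for a first-pass analysis
#'
#' Convenience wrapper: five-way grouping on the two top regions (by label
#' order: 1 = first, 2 = second), incidence table, group-versus-spared
#' chi-squares, severity ANCOVA and smallest-lesion report.
#'
#' @param cohort a [lesion_cohort].
#' @param rois a [roi_set] with at least two regions (first treated as the
#'   primary region pair analogue of frontal/temporal ordering: label 1 ->
#'   frontal slot, label 2 -> temporal slot).
#' @param config a [pipeline_config] (image kind drives damage fractions).
#' @return List with `groups`, `incidence`, `chi2` (groups 1-3 vs 5),
#'   `severity`, `smallest_lesion`.
#' @export
posthoc_report <- function(cohort, rois, config = pipeline_config()) {
  if (n_rois(rois) < 2L)
    stop_iterlesion("need two regions for the five-way grouping",
                    "precondition_error")
  acohort <- cohort_as_kind(cohort, config$image_kind, config$binarize_u)
  prof <- damage_profile(acohort, rois)
  flags <- impairment_flags(cohort$scores)
  def <- deficit_of_interest(flags)
  groups <- assign_damage_groups(prof[, 1], prof[, 2])
  inc <- incidence_table(groups, def)
  chi2 <- lapply(1:3, function(g)
    tryCatch(group_vs_reference_chi2(inc, g), error = function(e) NULL))
  names(chi2) <- paste0("group", 1:3, "_vs_5")
  sev <- severity_ancova(groups,
                         composite_score(cohort$scores$spk_pn,
                                         cohort$scores$writt_pn),
                         cohort$volumes)
  sl <- smallest_lesion_report(cohort, rois, def,
                               damage_cutoff = config$exclusion_fraction,
                               binarize_u = config$binarize_u)
  list(groups = groups, incidence = inc, chi2 = chi2, severity = sev,
       smallest_lesion = sl)
}
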