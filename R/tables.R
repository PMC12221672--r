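fmt_mean_sd <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"), mean(x), sd(x))
}

#' Demographics comparison table
#'
#' One row per variable: per-group mean (SD) (or % female for sex), the
#' one-way ANOVA (continuous) or Pearson chi-square (categorical) p-value,
#' and a Bonferroni post hoc pattern for significant continuous variables.
#'
#' @param subjects tibble with `group`, `age`, `sex`, `education` and
#'   optionally `mmse`, `tbv_cc`.
#' @param alpha significance level for the post hoc pattern (default 0.05).
#' @return tibble with one row per demographic variable.
#' @export
demographics_table <- function(subjects, alpha = 0.05) {
  group <- factor(subjects$group, levels = unique(subjects$group))
  lv <- levels(group)
  cont <- intersect(c("age", "education", "tbv_cc", "mmse"), names(subjects))
  rows <- list()
  for (v in cont) {
    y <- subjects[[v]]
    aov_res <- one_way_anova(y, group)
    pat <- ""
    if (aov_res$p < alpha) {
      fit <- ancova_group_test(y, group)
      pat <- bonferroni_posthoc(fit, alpha = alpha)$pattern
    }
    summ <- tapply(y, group, fmt_mean_sd)
    rows[[v]] <- tibble::tibble(
      variable = v, !!!setNames(as.list(summ[lv]), lv),
      statistic = aov_res$F, p = aov_res$p, posthoc = pat
    )
  }
  tab <- table(factor(subjects$sex, levels = c("F", "M")), group)
  chi <- chi_square_test(tab)
  pctF <- setNames(sprintf("%.1f", 100 * tab["F", ] / colSums(tab)),
                   colnames(tab))
  rows[["sex"]] <- tibble::tibble(
    variable = "sex_female_pct", !!!setNames(as.list(pctF[lv]), lv),
    statistic = chi$chi2, p = chi$p, posthoc = ""
  )
  dplyr::bind_rows(rows)
}

lobe_display_order <- c("temporal", "frontal", "parietal", "occipital",
                        "subcortical", "cerebellum")

order_for_display <- function(rois) {
  # lobe aggregate row first, then member ROIs, lobe groups in canonical order
  rois <- rois[rois$lobe %in% lobe_display_order, , drop = FALSE]
  out <- list()
  for (lb in intersect(lobe_display_order, unique(rois$lobe))) {
    sub <- rois[rois$lobe == lb, , drop = FALSE]
    out[[lb]] <- rbind(sub[sub$lobe_row, , drop = FALSE],
                       sub[!sub$lobe_row, , drop = FALSE])
  }
  do.call(rbind, out)
}

#' Build a per-ROI group-comparison results table
#'
#' For every ROI (and lobe aggregate row) fits the ANCOVA
#' `y ~ group + age + sex + education + (TBV | regional volume)` — TBV as the
#' volumetric covariate for volume analyses, the ROI's own volume for texture
#' analyses — and reports per-group mean (SD), the omnibus F, p, partial eta
#' squared and the Bonferroni post hoc pattern.
#'
#' @param features per subject x ROI feature tibble from [run_extract()].
#' @param subjects subject table with `subject_id`, `group`, `age`, `sex`,
#'   `education`.
#' @param kind `"volume"` or `"texture"`.
#' @param feature texture feature column for `kind = "texture"` (default
#'   `"contrast"`).
#' @param alpha,m post hoc significance level and Bonferroni multiplier.
#' @return list with `table` (display tibble, ROIs grouped by lobe) and
#'   `stats` (long tibble with raw and adjusted pairwise p-values).
#' @export
build_results_table <- function(features, subjects,
                                kind = c("volume", "texture"),
                                feature = "contrast", alpha = 0.05, m = 3) {
  kind <- match.arg(kind)
  needed <- c("age", "sex", "education")
  if (!all(needed %in% names(subjects))) {
    stop("missing covariate columns: ",
         paste(setdiff(needed, names(subjects)), collapse = ", "))
  }
  df <- dplyr::inner_join(
    features,
    subjects[, c("subject_id", "group", needed)],
    by = "subject_id"
  )
  df$group <- factor(df$group, levels = unique(subjects$group))
  lv <- levels(df$group)
  rois <- unique(df[, c("roi", "lobe", "lobe_row")])
  rois <- order_for_display(as.data.frame(rois))
  rows <- list(); stats <- list()
  for (i in seq_len(nrow(rois))) {
    rn <- rois$roi[i]
    sub <- df[df$roi == rn, , drop = FALSE]
    y <- if (kind == "volume") sub$volume_cc else sub[[feature]]
    covs <- data.frame(age = sub$age, sex = factor(sub$sex),
                       education = sub$education)
    covs$volcov <- if (kind == "volume") sub$tbv_cc else sub$volume_cc
    ok <- complete.cases(y, covs)
    fit <- ancova_group_test(y[ok], sub$group[ok], covs[ok, , drop = FALSE])
    ph <- bonferroni_posthoc(fit, alpha = alpha, m = m)
    summ <- tapply(y[ok], sub$group[ok], fmt_mean_sd,
                   digits = if (kind == "volume") 3 else 1)
    rows[[i]] <- tibble::tibble(
      roi = rn, lobe = rois$lobe[i], lobe_row = rois$lobe_row[i],
      !!!setNames(as.list(summ[lv]), lv),
      F = fit$F, p = fit$p, partial_eta_sq = fit$partial_eta_sq,
      posthoc = ph$pattern
    )
    stats[[i]] <- dplyr::bind_cols(
      tibble::tibble(roi = rn, kind = kind, omnibus_F = fit$F,
                     omnibus_p = fit$p,
                     partial_eta_sq = fit$partial_eta_sq),
      ph$pairs
    )
  }
  list(table = dplyr::bind_rows(rows), stats = dplyr::bind_rows(stats))
}

#' Fit the group ANCOVA for one ROI from a feature table
#'
#' Convenience wrapper used in simulation studies: selects one ROI's rows,
#' joins the subject covariates, and fits the study ANCOVA (volume analyses
#' adjust for age, sex, education and TBV; texture analyses for age, sex,
#' education and the ROI's own volume).
#'
#' @param features feature tibble from [run_extract()].
#' @param subjects subject table with `group`, `age`, `sex`, `education`.
#' @param roi ROI name.
#' @param kind `"volume"` or `"texture"`.
#' @param feature texture feature column (default `"contrast"`).
#' @param group_levels optional explicit group level order.
#' @return an [ancova_group_test()] result.
#' @export
roi_group_ancova <- function(features, subjects, roi,
                             kind = c("volume", "texture"),
                             feature = "contrast", group_levels = NULL) {
  kind <- match.arg(kind)
  sub <- features[features$roi == roi, , drop = FALSE]
  if (nrow(sub) == 0L) stop("ROI not present in feature table: ", roi)
  df <- dplyr::inner_join(sub, subjects[, c("subject_id", "group", "age",
                                            "sex", "education")],
                          by = "subject_id")
  if (is.null(group_levels)) group_levels <- unique(subjects$group)
  covs <- data.frame(age = df$age, sex = factor(df$sex),
                     education = df$education)
  covs$volcov <- if (kind == "volume") df$tbv_cc else df$volume_cc
  y <- if (kind == "volume") df$volume_cc else df[[feature]]
  ok <- complete.cases(y, covs)
  ancova_group_test(y[ok], factor(df$group, levels = group_levels)[ok],
                    covs[ok, , drop = FALSE])
}
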