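#' Summary statistics of the published reference cohort
#'
#' Printed group-level statistics from the three-group elderly SNAP cohort
#' the default phantom emulates (N-CN n=183, N+CN n=111, N+MCI n=155):
#' demographic distributions, reconstructed sex counts, and per-ROI ANCOVA F
#' statistics with their printed partial eta squared effect sizes for
#' representative regional volume and texture rows. The ANCOVA denominator
#' degrees of freedom are `n - groups - 4 covariates = 449 - 3 - 4 = 442`.
#' These are inputs for effect-size recomputation, not outputs of this
#' package.
#'
#' @return list with elements `n_per_group`, `sex_female_counts`,
#'   `demographics` (tibble) and `roi_stats` (tibble with `measure`, `roi`,
#'   `F`, `effect_size_printed`, `df1`, `df2`).
#' @export
reference_cohort_stats <- function() {
  list(
    n_per_group = c("N-CN" = 183L, "N+CN" = 111L, "N+MCI" = 155L),
    sex_female_counts = c("N-CN" = 116L, "N+CN" = 57L, "N+MCI" = 96L),
    demographics = tibble::tibble(
      variable = c("age", "education", "mmse", "tbv_cc"),
      mean_ncn = c(74.4, 12.0, 27.6, 985.5),
      sd_ncn = c(4.5, 4.8, 2.1, 86.8),
      mean_npcn = c(75.3, 12.1, 26.9, 980.7),
      sd_npcn = c(4.4, 5.0, 2.8, 91.5),
      mean_npmci = c(74.8, 10.9, 24.1, 962.7),
      sd_npmci = c(4.4, 5.2, 3.5, 91.2),
      p_printed = c(0.224, 0.061, NA, 0.055)
    ),
    roi_stats = tibble::tibble(
      measure = c(rep("volume", 5L), rep("texture", 5L)),
      roi = c("temporal_lobe", "insula", "amygdala", "hippocampus",
              "entorhinal",
              "hippocampus", "entorhinal", "superior_frontal", "putamen",
              "caudate"),
      F = c(15.573, 7.068, 8.427, 50.755, 16.517,
            5.739, 19.839, 17.610, 11.326, 9.438),
      effect_size_printed = c(0.066, 0.031, 0.037, 0.187, 0.070,
                              0.025, 0.082, 0.074, 0.049, 0.041),
      df1 = 2L,
      df2 = 442L
    )
  )
}
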