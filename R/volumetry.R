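#' ROI volume in cubic centimetres
#'
#' Count-based volumetry: `n_voxels * voxel volume / 1000`, with voxel
#' dimensions in mm. An `intensity_sum` mode is provided for the alternative
#' reading in which "volume" is the sum of voxel intensities inside the ROI;
#' the count-based definition is the default because reported volumes are in
#' cc.
#'
#' @param labels integer 3D label array.
#' @param roi_label integer label id(s); several ids are pooled.
#' @param voxel_dims length-3 voxel dimensions in mm (default 1 mm isotropic).
#' @param mode `"count"` (default) or `"intensity_sum"`.
#' @param intensity 3D array, required for `mode = "intensity_sum"`.
#' @return tibble with `n_voxels`, `volume_cc`, `flagged` (TRUE when the
#'   label is absent).
#' @export
roi_volume_cc <- function(labels, roi_label, voxel_dims = c(1, 1, 1),
                          mode = c("count", "intensity_sum"),
                          intensity = NULL) {
  mode <- match.arg(mode)
  if (any(voxel_dims <= 0)) stop("voxel_dims must be positive")
  sel <- labels %in% roi_label & labels != 0L
  n <- sum(sel)
  if (n == 0L) {
    warning("ROI label absent; zero-count record")
    return(tibble::new_tibble(list(n_voxels = 0L, volume_cc = 0,
                                   flagged = TRUE), nrow = 1L))
  }
  vol <- if (mode == "count") {
    n * prod(voxel_dims) / 1000
  } else {
    if (is.null(intensity)) stop("intensity required for intensity_sum mode")
    sum(intensity[sel]) * prod(voxel_dims) / 1000
  }
  tibble::new_tibble(list(n_voxels = n, volume_cc = vol, flagged = FALSE),
                     nrow = 1L)
}

#' Total brain volume
#'
#' Sum of the volumes of all member structures, mirroring the
#' whole-segmentation (aseg-style) TBV definition: by default every nonzero
#' label, including ventricular CSF structures, contributes.
#'
#' @param labels integer 3D label array.
#' @param voxel_dims length-3 voxel dimensions in mm.
#' @param tbv_labels labels to include; `NULL` (default) means all nonzero.
#' @return TBV in cc.
#' @export
total_brain_volume <- function(labels, voxel_dims = c(1, 1, 1),
                               tbv_labels = NULL) {
  if (any(voxel_dims <= 0)) stop("voxel_dims must be positive")
  sel <- if (is.null(tbv_labels)) labels != 0L else labels %in% tbv_labels
  sum(sel) * prod(voxel_dims) / 1000
}

#' Normalize an ROI volume to total brain volume
#'
#' @param volume_cc ROI volume (cc).
#' @param tbv_cc total brain volume (cc), > 0.
#' @return dimensionless fraction `volume_cc / tbv_cc`.
#' @export
normalize_to_tbv <- function(volume_cc, tbv_cc) {
  if (any(!is.finite(tbv_cc)) || any(tbv_cc <= 0)) stop("TBV must be > 0")
  volume_cc / tbv_cc
}

#' Lobe grouping of the cortical/subcortical ROI inventory
#'
#' Maps each grey-matter ROI name to its lobe-level row group (temporal,
#' frontal, parietal, occipital, subcortical grey matter, cerebellum), the
#' grouping used for the lobe aggregate rows of the results tables.
#'
#' @return tibble with columns `name`, `lobe`.
#' @export
dkt_lobe_map <- function() {
  tibble::tibble(
    name = c(
      "insula", "amygdala", "hippocampus", "entorhinal", "parahippocampal",
      "fusiform", "bankssts", "inferior_temporal", "middle_temporal",
      "superior_temporal", "transverse_temporal", "temporal_pole",
      "orbitofrontal", "inferior_frontal", "middle_frontal",
      "superior_frontal", "precentral", "paracentral", "frontal_pole",
      "anterior_cingulate",
      "inferior_parietal", "superior_parietal", "postcentral", "precuneus",
      "supramarginal", "isthmus_cingulate", "posterior_cingulate",
      "cuneus", "lingual", "lateral_occipital", "pericalcarine",
      "accumbens", "caudate", "putamen", "pallidum", "thalamus",
      "cerebellum"
    ),
    lobe = c(
      rep("temporal", 12L),
      rep("frontal", 8L),
      rep("parietal", 7L),
      rep("occipital", 4L),
      rep("subcortical", 5L),
      "cerebellum"
    )
  )
}

#' Lobe-level aggregation of volumes or textures
#'
#' Volumes aggregate by exact addition of member-ROI volumes. Textures
#' aggregate by running the full texture chain once on the merged mask (the
#' union of member ROIs), so trimming and quantization happen at the lobe
#' granularity rather than averaging per-ROI features (an `roi_mean` mode is
#' provided as the alternative).
#'
#' @param roi_table tibble with at least `name`, `lobe`, `label_id` and, for
#'   volume mode, `volume_cc`.
#' @param mode `"volume_sum"`, `"texture_merged_mask"`, or `"texture_roi_mean"`.
#' @param intensity,labels,csf_labels,L,trim_sigma passed to
#'   [roi_texture_profile()] in merged-mask mode.
#' @param feature_table per-ROI feature tibble (with `lobe`, `contrast`,
#'   `entropy`, `autocorrelation`) for `texture_roi_mean` mode.
#' @return tibble of per-lobe records.
#' @export
lobe_aggregate <- function(roi_table,
                           mode = c("volume_sum", "texture_merged_mask",
                                    "texture_roi_mean"),
                           intensity = NULL, labels = NULL, csf_labels = NULL,
                           L = 32L, trim_sigma = 3, feature_table = NULL) {
  mode <- match.arg(mode)
  grey <- roi_table[roi_table$lobe != "csf", , drop = FALSE]
  if (anyNA(grey$lobe)) stop("ROI missing from lobe map")
  lobes <- unique(grey$lobe)
  if (mode == "volume_sum") {
    stopifnot("volume_cc" %in% names(grey))
    out <- dplyr::summarise(
      dplyr::group_by(grey, .data$lobe),
      n_voxels = sum(.data$n_voxels),
      volume_cc = sum(.data$volume_cc),
      .groups = "drop"
    )
    return(out[match(lobes, out$lobe), , drop = FALSE])
  }
  if (mode == "texture_roi_mean") {
    stopifnot(!is.null(feature_table))
    out <- dplyr::summarise(
      dplyr::group_by(feature_table[feature_table$lobe != "csf", ], .data$lobe),
      contrast = mean(.data$contrast, na.rm = TRUE),
      entropy = mean(.data$entropy, na.rm = TRUE),
      autocorrelation = mean(.data$autocorrelation, na.rm = TRUE),
      .groups = "drop"
    )
    return(out[match(lobes, out$lobe), , drop = FALSE])
  }
  stopifnot(!is.null(intensity), !is.null(labels), !is.null(csf_labels))
  rows <- lapply(lobes, function(lb) {
    ids <- grey$label_id[grey$lobe == lb]
    prof <- roi_texture_profile(intensity, labels, ids, csf_labels,
                                L = L, trim_sigma = trim_sigma)
    dplyr::bind_cols(tibble::tibble(lobe = lb), prof)
  })
  dplyr::bind_rows(rows)
}
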