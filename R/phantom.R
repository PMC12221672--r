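#' ROI specification for the phantom
#'
#' Describes one region of the synthetic labeled-brain phantom: its label id,
#' name and lobe group, mean T1-like intensity, nominal size in voxels, and
#' the two texture dials — `texture_sigma`, the standard deviation of the
#' spatially smooth intensity fluctuation field added inside the ROI, and
#' `smooth_fwhm_vox`, the FWHM of the Gaussian smoothing that sets the
#' field's spatial correlation length.
#'
#' @param label_id positive integer, unique within a parcellation.
#' @param name region name (snake_case, DKT-style).
#' @param lobe one of temporal, frontal, parietal, occipital, subcortical,
#'   cerebellum, csf, other.
#' @param base_mean_intensity mean intensity (arbitrary units).
#' @param base_voxel_count nominal ROI size in voxels (>= 27 so a 3x3x3 cube
#'   fits).
#' @param texture_sigma fluctuation-field SD in intensity units (>= 0).
#' @param smooth_fwhm_vox smoothing FWHM of the texture field in voxels
#'   (>= 0).
#' @param anatomy_sigma SD of a fixed broad intensity gradient (FWHM
#'   `anatomy_fwhm_vox`) present in every group. It anchors the per-ROI
#'   quantization range, so the fine-scale texture dial maps monotonically
#'   onto GLCM contrast; without it, min-max re-quantization absorbs any
#'   amplitude change of a single fluctuation field.
#' @param anatomy_fwhm_vox smoothing FWHM of the anatomy gradient, voxels.
#' @return a `roi_spec` list.
#' @export
roi_spec <- function(label_id, name, lobe, base_mean_intensity,
                     base_voxel_count, texture_sigma = 0,
                     smooth_fwhm_vox = 0, anatomy_sigma = 0,
                     anatomy_fwhm_vox = 6) {
  lobe <- match.arg(lobe, c("temporal", "frontal", "parietal", "occipital",
                            "subcortical", "cerebellum", "csf", "other"))
  stopifnot(label_id >= 1, base_voxel_count >= 27, texture_sigma >= 0,
            smooth_fwhm_vox >= 0, anatomy_sigma >= 0, anatomy_fwhm_vox >= 0)
  structure(list(label_id = as.integer(label_id), name = name, lobe = lobe,
                 base_mean_intensity = base_mean_intensity,
                 base_voxel_count = as.integer(base_voxel_count),
                 texture_sigma = texture_sigma,
                 smooth_fwhm_vox = smooth_fwhm_vox,
                 anatomy_sigma = anatomy_sigma,
                 anatomy_fwhm_vox = anatomy_fwhm_vox),
            class = "roi_spec")
}

validate_roi_specs <- function(roi_specs) {
  stopifnot(length(roi_specs) >= 1L)
  ids <- vapply(roi_specs, function(r) r$label_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate ROI label ids")
  lobes <- vapply(roi_specs, function(r) r$lobe, character(1))
  if (sum(lobes == "csf") != 1L) {
    stop("exactly one ROI must have lobe = 'csf' (the ventricle reference)")
  }
  invisible(roi_specs)
}

#' Group-level effect recipe
#'
#' Per-ROI multiplicative texture effect and boundary-erosion atrophy
#' fraction for one diagnostic group. ROIs not named default to multiplier 1
#' and atrophy 0. The reference group must carry no effects.
#'
#' @param group group label (e.g. `"N-CN"`, `"N+CN"`, `"N+MCI"`).
#' @param texture_multiplier named numeric vector (names = ROI names), each
#'   >= 0; scales that ROI's `texture_sigma`.
#' @param atrophy_fraction named numeric vector in `[0, 1)`; fraction of the
#'   ROI's voxels removed by boundary erosion.
#' @param reference logical; reference groups must have all multipliers 1 and
#'   atrophy 0.
#' @return a `group_effect` list.
#' @export
group_effect <- function(group, texture_multiplier = numeric(),
                         atrophy_fraction = numeric(), reference = FALSE) {
  stopifnot(all(texture_multiplier >= 0),
            all(atrophy_fraction >= 0), all(atrophy_fraction < 1))
  if (reference &&
      (any(texture_multiplier != 1) || any(atrophy_fraction != 0))) {
    stop("reference group must have multipliers 1 and atrophy 0")
  }
  structure(list(group = group, texture_multiplier = texture_multiplier,
                 atrophy_fraction = atrophy_fraction, reference = reference),
            class = "group_effect")
}

effect_multiplier <- function(group_effect, roi_name) {
  if (is.null(group_effect)) return(1)
  m <- group_effect$texture_multiplier
  if (roi_name %in% names(m)) unname(m[[roi_name]]) else 1
}

effect_atrophy <- function(group_effect, roi_name) {
  if (is.null(group_effect)) return(0)
  a <- group_effect$atrophy_fraction
  if (roi_name %in% names(a)) unname(a[[roi_name]]) else 0
}

#' Cohort recipe for the phantom generator
#'
#' Everything [generate_cohort()] needs: group sizes, per-group covariate
#' distributions, the ROI inventory, per-group effect recipes, the noise
#' floor, subject-level volume variability, and the seed. A fixed spec
#' (including seed) reproduces the cohort exactly.
#'
#' @param n_per_group integer vector of 3 group sizes, named by group.
#' @param age_mean,age_sd,education_mean,education_sd,mmse_mean,mmse_sd
#'   numeric vectors of 3 (per group, years / points).
#' @param sex_female_prop numeric vector of 3 in `[0, 1]`.
#' @param roi_specs list of [roi_spec()] objects (exactly one CSF ROI).
#' @param group_effects named list of [group_effect()] per group.
#' @param noise_floor_sigma i.i.d. voxel noise SD (intensity units).
#' @param baseline_atrophy mean subject-level erosion fraction applied to
#'   every grey-matter ROI in every group (individual anatomical
#'   variability); group atrophy adds on top.
#' @param atrophy_jitter_sd SD of the subject-level erosion fraction.
#' @param seed integer RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group, age_mean, age_sd, education_mean,
                        education_sd, sex_female_prop, mmse_mean, mmse_sd,
                        roi_specs, group_effects, noise_floor_sigma = 5,
                        baseline_atrophy = 0.05, atrophy_jitter_sd = 0.02,
                        seed = 1L) {
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 2L),
            all(sex_female_prop >= 0), all(sex_female_prop <= 1),
            noise_floor_sigma >= 0, baseline_atrophy >= 0,
            atrophy_jitter_sd >= 0)
  validate_roi_specs(roi_specs)
  groups <- names(n_per_group)
  stopifnot(!is.null(groups), all(groups %in% names(group_effects)))
  structure(list(
    n_per_group = n_per_group, groups = groups,
    age_mean = age_mean, age_sd = age_sd,
    education_mean = education_mean, education_sd = education_sd,
    sex_female_prop = sex_female_prop,
    mmse_mean = mmse_mean, mmse_sd = mmse_sd,
    roi_specs = roi_specs, group_effects = group_effects,
    noise_floor_sigma = noise_floor_sigma,
    baseline_atrophy = baseline_atrophy,
    atrophy_jitter_sd = atrophy_jitter_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default ROI inventory at study-like magnitudes
#'
#' The full cortical/subcortical inventory of [dkt_lobe_map()] plus a
#' lateral-ventricle CSF reference region. Nominal voxel counts are the
#' reference-group mean regional volumes (cc) of a published elderly cohort
#' times 1000 voxels/cc at 1 mm isotropic, scaled by `voxel_scale`; summed
#' they put TBV in the human range. CSF sits well below all grey-matter
#' means, as on T1.
#'
#' @param voxel_scale scale factor on all voxel counts (use < 1 for fast
#'   simulation studies; counts are floored at 27 voxels).
#' @param texture_sigma,smooth_fwhm_vox texture dials shared by all
#'   grey-matter ROIs.
#' @param anatomy_sigma,anatomy_fwhm_vox broad fixed-gradient dials shared
#'   by all grey-matter ROIs.
#' @return list of [roi_spec()] objects.
#' @export
default_roi_specs <- function(voxel_scale = 1, texture_sigma = 15,
                              smooth_fwhm_vox = 2, anatomy_sigma = 20,
                              anatomy_fwhm_vox = 6) {
  mean_cc <- c(
    insula = 12.8, amygdala = 2.7, hippocampus = 7.2, entorhinal = 3.8,
    parahippocampal = 3.3, fusiform = 16.3, bankssts = 3.9,
    inferior_temporal = 19.2, middle_temporal = 19.7,
    superior_temporal = 20.2, transverse_temporal = 1.7, temporal_pole = 4.7,
    orbitofrontal = 21.9, inferior_frontal = 17.8, middle_frontal = 35.3,
    superior_frontal = 36.6, precentral = 23.8, paracentral = 6.8,
    frontal_pole = 1.9, anterior_cingulate = 6.9,
    inferior_parietal = 22.9, superior_parietal = 22.6, postcentral = 16.2,
    precuneus = 16.7, supramarginal = 18.2, isthmus_cingulate = 4.4,
    posterior_cingulate = 5.5,
    cuneus = 5.4, lingual = 11.3, lateral_occipital = 19.8,
    pericalcarine = 3.9,
    accumbens = 0.8, caudate = 6.5, putamen = 8.4, pallidum = 3.3,
    thalamus = 11.7, cerebellum = 117.9
  )
  lobes <- dkt_lobe_map()
  gm_intensity <- c(temporal = 280, frontal = 285, parietal = 285,
                    occipital = 290, subcortical = 320, cerebellum = 275)
  specs <- lapply(seq_along(mean_cc), function(i) {
    nm <- names(mean_cc)[i]
    lb <- lobes$lobe[match(nm, lobes$name)]
    roi_spec(label_id = i, name = nm, lobe = lb,
             base_mean_intensity = gm_intensity[[lb]],
             base_voxel_count = max(27L, round(mean_cc[[i]] * 1000 * voxel_scale)),
             texture_sigma = texture_sigma,
             smooth_fwhm_vox = smooth_fwhm_vox,
             anatomy_sigma = anatomy_sigma,
             anatomy_fwhm_vox = anatomy_fwhm_vox)
  })
  c(specs, list(roi_spec(label_id = length(mean_cc) + 1L,
                         name = "lateral_ventricle", lobe = "csf",
                         base_mean_intensity = 100,
                         base_voxel_count = max(27L, round(15000 * voxel_scale)),
                         texture_sigma = 0, smooth_fwhm_vox = 0)))
}

#' Default cohort recipe mirroring a three-group SNAP study design
#'
#' Group sizes 183 / 111 / 155 (N-CN, N+CN, N+MCI) and per-group age, sex,
#' education and MMSE distributions parameterized from the published
#' reference cohort (see [reference_cohort_stats()]). Group effects encode
#' the texture-before-volume progression: temporal texture heterogeneity
#' rises at both neurodegeneration-positive stages, while boundary-erosion
#' atrophy is confined to the hippocampus/entorhinal cortex at the N+CN
#' stage and spreads across temporal ROIs at the N+MCI stage.
#'
#' @param voxel_scale passed to [default_roi_specs()].
#' @param seed integer seed.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(voxel_scale = 1, seed = 1L) {
  temporal <- c("insula", "amygdala", "hippocampus", "entorhinal",
                "parahippocampal", "inferior_temporal", "middle_temporal")
  tex_cn <- setNames(rep(1.3, length(temporal)), temporal)
  tex_mci <- setNames(rep(1.6, length(temporal)), temporal)
  atr_cn <- c(hippocampus = 0.05, entorhinal = 0.03)
  atr_mci <- c(insula = 0.05, amygdala = 0.07, hippocampus = 0.11,
               entorhinal = 0.10, inferior_temporal = 0.06,
               middle_temporal = 0.06)
  cohort_spec(
    n_per_group = c("N-CN" = 183L, "N+CN" = 111L, "N+MCI" = 155L),
    age_mean = c(74.4, 75.3, 74.8), age_sd = c(4.5, 4.4, 4.4),
    education_mean = c(12.0, 12.1, 10.9), education_sd = c(4.8, 5.0, 5.2),
    sex_female_prop = c(0.634, 0.514, 0.619),
    mmse_mean = c(27.6, 26.9, 24.1), mmse_sd = c(2.1, 2.8, 3.5),
    roi_specs = default_roi_specs(voxel_scale = voxel_scale),
    group_effects = list(
      "N-CN" = group_effect("N-CN", reference = TRUE),
      "N+CN" = group_effect("N+CN", texture_multiplier = tex_cn,
                            atrophy_fraction = atr_cn),
      "N+MCI" = group_effect("N+MCI", texture_multiplier = tex_mci,
                             atrophy_fraction = atr_mci)
    ),
    seed = seed
  )
}

cuboid_dims <- function(n) {
  if (n < 27L) stop("ROI too small to form a 3x3x3 block")
  a <- max(3L, as.integer(round(n^(1 / 3))))
  b <- max(3L, as.integer(round(sqrt(n / a))))
  cc <- max(3L, as.integer(round(n / (a * b))))
  c(a, b, cc)
}

#' Generate the phantom label volume
#'
#' Places each ROI as a compact cuboid of approximately `base_voxel_count`
#' voxels (cuboid rounding; the realized count is stored in the attached ROI
#' table) on a non-overlapping 3D grid at 1 mm isotropic, background 0.
#' Deterministic: the layout depends only on the spec order.
#'
#' @param roi_specs list of [roi_spec()] (unique label ids, one CSF ROI for
#'   downstream use; uniqueness enforced here).
#' @param gap background margin between blocks, voxels (default 2).
#' @param seed accepted for interface symmetry; the construction is
#'   deterministic.
#' @return integer 3D label array with attribute `roi_table`: tibble with
#'   `label_id`, `name`, `lobe`, `n_voxels` (realized), block dims/origin.
#' @export
generate_label_volume <- function(roi_specs, gap = 2L, seed = NULL) {
  ids <- vapply(roi_specs, function(r) r$label_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate ROI label ids")
  dims_list <- lapply(roi_specs, function(r) cuboid_dims(r$base_voxel_count))
  dmax <- Reduce(pmax, dims_list)
  cell <- dmax + gap
  k <- length(roi_specs)
  ng <- ceiling(k^(1 / 3))
  gx <- ((seq_len(k) - 1L) %% ng)
  gy <- ((seq_len(k) - 1L) %/% ng) %% ng
  gz <- (seq_len(k) - 1L) %/% (ng * ng)
  full <- cell * c(ng, ng, max(gz) + 1L) + gap
  labels <- array(0L, dim = full)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    d <- dims_list[[i]]
    o <- c(gx[i], gy[i], gz[i]) * cell + gap + 1L
    labels[o[1]:(o[1] + d[1] - 1L),
           o[2]:(o[2] + d[2] - 1L),
           o[3]:(o[3] + d[3] - 1L)] <- roi_specs[[i]]$label_id
    rows[[i]] <- tibble::tibble(
      label_id = roi_specs[[i]]$label_id, name = roi_specs[[i]]$name,
      lobe = roi_specs[[i]]$lobe, n_voxels = prod(d),
      d1 = d[1], d2 = d[2], d3 = d[3], o1 = o[1], o2 = o[2], o3 = o[3]
    )
  }
  attr(labels, "roi_table") <- dplyr::bind_rows(rows)
  labels
}

gaussian_kernel_matrix <- function(n, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])  # renormalize truncated edge rows
  }
  K
}

gaussian_smooth3d <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  d <- dim(arr)
  K1 <- gaussian_kernel_matrix(d[1], fwhm)
  arr <- array(K1 %*% matrix(arr, d[1], d[2] * d[3]), dim = d)
  K2 <- gaussian_kernel_matrix(d[2], fwhm)
  a2 <- aperm(arr, c(2, 1, 3))
  a2 <- array(K2 %*% matrix(a2, d[2], d[1] * d[3]), dim = c(d[2], d[1], d[3]))
  arr <- aperm(a2, c(2, 1, 3))
  K3 <- gaussian_kernel_matrix(d[3], fwhm)
  a3 <- aperm(arr, c(3, 1, 2))
  a3 <- array(K3 %*% matrix(a3, d[3], d[1] * d[2]), dim = c(d[3], d[1], d[2]))
  aperm(a3, c(2, 3, 1))
}

#' Generate a phantom intensity volume over a label volume
#'
#' Each ROI's voxels are `base_mean_intensity`, plus a fixed broad anatomy
#' gradient (SD `anatomy_sigma`, identical construction in every group),
#' plus the fine-scale texture fluctuation field (SD
#' `texture_sigma * multiplier` with the group's per-ROI multiplier,
#' smoothed to `smooth_fwhm_vox`), plus i.i.d. noise of SD
#' `noise_floor_sigma`. Both random fields are mean-centred and rescaled to
#' their exact target SD over the ROI. Background remains 0. Because the
#' broad gradient anchors the quantization range, the texture SD maps
#' monotonically onto downstream GLCM contrast.
#'
#' @param labels integer 3D label array.
#' @param roi_specs list of [roi_spec()] covering every nonzero label.
#' @param group_effect optional [group_effect()] providing texture
#'   multipliers.
#' @param noise_floor_sigma i.i.d. noise SD (>= 0).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return numeric 3D intensity array.
#' @export
generate_intensity_volume <- function(labels, roi_specs, group_effect = NULL,
                                      noise_floor_sigma = 0, seed = NULL) {
  if (noise_floor_sigma < 0) stop("noise_floor_sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  present <- sort(unique(labels[labels != 0L]))
  ids <- vapply(roi_specs, function(r) r$label_id, integer(1))
  if (!all(present %in% ids)) stop("labels present without an ROI spec")
  intensity <- array(0, dim = dim(labels))
  smooth_component <- function(cr, fwhm, target_sd) {
    field <- array(rnorm(length(cr)), dim = dim(cr))
    field <- gaussian_smooth3d(field, fwhm)
    fv <- field[cr]
    s <- sd(fv)
    if (s > 0) (fv - mean(fv)) / s * target_sd else rep(0, sum(cr))
  }
  for (r in roi_specs) {
    if (r$texture_sigma < 0) stop("texture_sigma must be >= 0")
    mask <- labels == r$label_id
    nv <- sum(mask)
    if (nv == 0L) next
    vals <- rep(r$base_mean_intensity, nv)
    sig <- r$texture_sigma * effect_multiplier(group_effect, r$name)
    if (sig < 0) stop("negative effective texture sigma")
    cr <- NULL
    if (r$anatomy_sigma > 0 && nv > 1L) {
      cr <- crop_to_mask(list(mask = mask), mask)$mask
      vals <- vals + smooth_component(cr, r$anatomy_fwhm_vox, r$anatomy_sigma)
    }
    if (sig > 0 && nv > 1L) {
      if (is.null(cr)) cr <- crop_to_mask(list(mask = mask), mask)$mask
      vals <- vals + smooth_component(cr, r$smooth_fwhm_vox, sig)
    }
    if (noise_floor_sigma > 0) vals <- vals + rnorm(nv, 0, noise_floor_sigma)
    intensity[mask] <- vals
  }
  intensity
}

shift_mask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  sx <- seq.int(max(1L, 1L - off[1]), min(d[1], d[1] - off[1]))
  sy <- seq.int(max(1L, 1L - off[2]), min(d[2], d[2] - off[2]))
  sz <- seq.int(max(1L, 1L - off[3]), min(d[3], d[3] - off[3]))
  if (length(sx) && length(sy) && length(sz)) {
    out[sx, sy, sz] <- mask[sx + off[1], sy + off[2], sz + off[3]]
  }
  out
}

boundary_shell <- function(mask) {
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  outside <- array(FALSE, dim = dim(mask))
  for (i in seq_len(nrow(offs))) {
    outside <- outside | !shift_mask(mask, offs[i, ])
  }
  mask & outside
}

#' Shrink an ROI by boundary erosion
#'
#' Removes (reassigns to background) approximately
#' `round(atrophy_fraction * n)` boundary voxels of the ROI by iterative
#' 6-connected morphological erosion; the final partial shell is peeled in a
#' fixed lexicographic sweep so the realized count lands within one voxel of
#' the target and the ROI stays 6-connected. Emulates atrophic boundary loss
#' while keeping voxel accounting exact.
#'
#' @param labels integer 3D label array.
#' @param roi_label label id to erode.
#' @param atrophy_fraction fraction of voxels to remove, in `[0, 1)`.
#' @param seed accepted for interface symmetry; the peel order is
#'   deterministic.
#' @return the modified label array.
#' @export
apply_atrophy <- function(labels, roi_label, atrophy_fraction, seed = NULL) {
  if (atrophy_fraction < 0 || atrophy_fraction >= 1) {
    stop("atrophy_fraction must be in [0, 1)")
  }
  full_mask <- labels == roi_label
  n0 <- sum(full_mask)
  if (n0 == 0L) stop("ROI label absent")
  target <- round(atrophy_fraction * n0)
  if (target == 0L) return(labels)
  if (n0 - target < 1L) stop("erosion would empty the ROI")
  # erode inside the ROI bounding box only
  w0 <- which(full_mask, arr.ind = TRUE)
  rx <- range(w0[, 1]); ry <- range(w0[, 2]); rz <- range(w0[, 3])
  mask <- full_mask[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2], drop = FALSE]
  removed <- 0L
  while (removed < target) {
    shell <- boundary_shell(mask)
    ns <- sum(shell)
    if (ns == sum(mask) && removed + ns <= target) {
      stop("erosion would empty the ROI")
    }
    if (removed + ns <= target) {
      mask[shell] <- FALSE
      removed <- removed + ns
    } else {
      w <- which(shell, arr.ind = TRUE)
      ord <- order(w[, 1], w[, 2], w[, 3])
      take <- w[ord[seq_len(target - removed)], , drop = FALSE]
      mask[take] <- FALSE
      removed <- target
    }
  }
  sub <- labels[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2], drop = FALSE]
  sub[sub == roi_label & !mask] <- 0L
  labels[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2]] <- sub
  labels
}

truncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Generate a full phantom cohort
#'
#' Builds the shared label volume, then per subject: draws covariates from
#' the per-group distributions (age truncated at 60, education at 0, MMSE
#' clamped to 0-30, sex Bernoulli), applies subject-level plus group-level
#' boundary erosion to every grey-matter ROI, and synthesizes the intensity
#' volume with the group's texture multipliers. Fully reproducible from the
#' spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; when given, writes
#'   `<subject_id>_intensity.nii.gz`, `<subject_id>_labels.nii.gz`,
#'   `subjects.csv` and `roi_map.csv`.
#' @return list with `subjects` (tibble), `volumes` (named list of
#'   `list(intensity, labels)` per subject), `roi_table`, `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  base_labels <- generate_label_volume(spec$roi_specs)
  roi_table <- attr(base_labels, "roi_table")
  grey <- roi_table[roi_table$lobe != "csf", , drop = FALSE]
  subjects <- list()
  volumes <- list()
  sid <- 0L
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[gi]
    eff <- spec$group_effects[[g]]
    for (i in seq_len(spec$n_per_group[[gi]])) {
      sid <- sid + 1L
      subject_id <- sprintf("S%04d", sid)
      age <- truncated_normal(1, spec$age_mean[gi], spec$age_sd[gi], lower = 60)
      edu <- truncated_normal(1, spec$education_mean[gi],
                              spec$education_sd[gi], lower = 0)
      mmse <- min(30, max(0, rnorm(1, spec$mmse_mean[gi], spec$mmse_sd[gi])))
      sex <- if (runif(1) < spec$sex_female_prop[gi]) "F" else "M"
      labs <- base_labels
      for (ri in seq_len(nrow(grey))) {
        f <- effect_atrophy(eff, grey$name[ri]) + spec$baseline_atrophy +
          rnorm(1, 0, spec$atrophy_jitter_sd)
        f <- min(0.8, max(0, f))
        if (f > 0) labs <- apply_atrophy(labs, grey$label_id[ri], f)
      }
      intensity <- generate_intensity_volume(
        labs, spec$roi_specs, group_effect = eff,
        noise_floor_sigma = spec$noise_floor_sigma
      )
      subjects[[sid]] <- tibble::tibble(
        subject_id = subject_id, group = g, age = age, sex = sex,
        education = edu, mmse = mmse
      )
      volumes[[subject_id]] <- list(intensity = intensity, labels = labs)
    }
  }
  subjects <- dplyr::bind_rows(subjects)
  out <- list(subjects = subjects, volumes = volumes,
              roi_table = roi_table, spec = spec)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

#' Write a generated cohort to disk as NIfTI + CSV
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$volumes)) {
    v <- cohort$volumes[[sid]]
    RNifti::writeNifti(RNifti::asNifti(v$intensity, pixdim = c(1, 1, 1)),
                       file.path(out_dir, paste0(sid, "_intensity.nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(v$labels + 0L, pixdim = c(1, 1, 1)),
                       file.path(out_dir, paste0(sid, "_labels.nii.gz")))
  }
  write.csv(cohort$subjects, file.path(out_dir, "subjects.csv"),
            row.names = FALSE)
  write.csv(cohort$roi_table[, c("label_id", "name", "lobe")],
            file.path(out_dir, "roi_map.csv"), row.names = FALSE)
  invisible(out_dir)
}
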