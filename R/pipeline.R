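#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline with defaults that reproduce the
#' reference analysis settings: 32 grey levels, GLCM distance 1 over the 13
#' unique directions, 3-sigma partial-volume trimming, alpha 0.05 with a
#' 3-fold Bonferroni post hoc correction.
#'
#' @param mode one of `"simulate"`, `"extract"`, `"analyze"`, `"full"`.
#' @param grey_levels grey-level count L (default 32).
#' @param trim_sigma trimming half-width in SD units (default 3).
#' @param glcm_distance co-occurrence distance in voxels (only 1 supported).
#' @param alpha omnibus/post hoc significance level (default 0.05).
#' @param posthoc_m Bonferroni multiplier for the three pairwise
#'   comparisons (default 3).
#' @param csf_labels integer CSF label ids (`NULL`: taken from the ROI map).
#' @param texture_feature texture feature analysed (default `"contrast"`).
#' @param seed integer seed.
#' @param out_dir output directory or `NULL`.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = "full", grey_levels = 32L, trim_sigma = 3,
                       glcm_distance = 1L, alpha = 0.05, posthoc_m = 3L,
                       csf_labels = NULL, texture_feature = "contrast",
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode, c("simulate", "extract", "analyze", "full"))
  if (glcm_distance != 1L) stop("only glcm_distance = 1 is supported")
  structure(list(mode = mode, grey_levels = as.integer(grey_levels),
                 trim_sigma = trim_sigma, glcm_distance = 1L,
                 alpha = alpha, posthoc_m = as.integer(posthoc_m),
                 csf_labels = csf_labels, texture_feature = texture_feature,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `<id>_intensity.nii.gz`,
#'   `<id>_labels.nii.gz`, `subjects.csv`, `roi_map.csv`.
#' @return list with `subjects`, `volumes`, `roi_table`.
#' @export
read_cohort_dir <- function(dir) {
  subjects <- tibble::as_tibble(read.csv(file.path(dir, "subjects.csv")))
  roi_table <- tibble::as_tibble(read.csv(file.path(dir, "roi_map.csv")))
  volumes <- lapply(setNames(nm = subjects$subject_id), function(sid) {
    intensity <- file.path(dir, paste0(sid, "_intensity.nii.gz"))
    labs <- file.path(dir, paste0(sid, "_labels.nii.gz"))
    if (!file.exists(intensity) || !file.exists(labs)) {
      stop("missing NIfTI pair for subject ", sid)
    }
    list(intensity = array(as.numeric(RNifti::readNifti(intensity)),
                           dim = dim(RNifti::readNifti(intensity))),
         labels = array(as.integer(round(as.numeric(RNifti::readNifti(labs)))),
                        dim = dim(RNifti::readNifti(labs))))
  })
  list(subjects = subjects, volumes = volumes, roi_table = roi_table)
}

extract_one_subject <- function(sid, vol, roi_table, csf_labels, L,
                                trim_sigma, voxel_dims, lobe_rows) {
  intensity <- vol$intensity
  labs <- vol$labels
  tbv <- total_brain_volume(labs, voxel_dims)
  grey <- roi_table[roi_table$lobe != "csf", , drop = FALSE]
  rows <- vector("list", nrow(grey))
  for (ri in seq_len(nrow(grey))) {
    vr <- suppressWarnings(
      roi_volume_cc(labs, grey$label_id[ri], voxel_dims)
    )
    tx <- if (vr$n_voxels > 0L) {
      roi_texture_profile(intensity, labs, grey$label_id[ri], csf_labels,
                          L = L, trim_sigma = trim_sigma)
    } else {
      tibble::new_tibble(list(contrast = NA_real_, entropy = NA_real_,
                              autocorrelation = NA_real_,
                              n_directions_used = 0L, n_retained = 0L,
                              n_roi = 0L, flagged = TRUE), nrow = 1L)
    }
    rows[[ri]] <- tibble::new_tibble(list(
      subject_id = sid, roi = grey$name[ri], lobe = grey$lobe[ri],
      lobe_row = FALSE, n_voxels = vr$n_voxels, volume_cc = vr$volume_cc,
      volume_tbv_norm = normalize_to_tbv(vr$volume_cc, tbv),
      tbv_cc = tbv,
      contrast = tx$contrast, entropy = tx$entropy,
      autocorrelation = tx$autocorrelation,
      n_directions_used = tx$n_directions_used, flagged = tx$flagged),
      nrow = 1L)
  }
  out <- dplyr::bind_rows(rows)
  if (lobe_rows) {
    lrs <- lapply(unique(grey$lobe), function(lb) {
      ids <- grey$label_id[grey$lobe == lb]
      sub <- out[out$lobe == lb & !out$lobe_row, , drop = FALSE]
      tx <- roi_texture_profile(intensity, labs, ids, csf_labels,
                                L = L, trim_sigma = trim_sigma)
      tibble::tibble(
        subject_id = sid, roi = paste0(lb, "_lobe"), lobe = lb,
        lobe_row = TRUE, n_voxels = sum(sub$n_voxels),
        volume_cc = sum(sub$volume_cc),
        volume_tbv_norm = normalize_to_tbv(sum(sub$volume_cc), tbv),
        tbv_cc = tbv,
        contrast = tx$contrast, entropy = tx$entropy,
        autocorrelation = tx$autocorrelation,
        n_directions_used = tx$n_directions_used, flagged = tx$flagged
      )
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(lrs))
  }
  out
}

#' Extract volumetry and texture features for every subject
#'
#' Runs the per-ROI pipeline (count volumetry, TBV normalization, trimming,
#' CSF normalization, quantization, 13-direction averaged GLCM, Haralick
#' features) for every subject and grey-matter ROI, plus merged-mask lobe
#' aggregate rows. A subject whose volumes fail to process is recorded in
#' the `errors` attribute and skipped; the remaining subjects complete.
#'
#' @param cohort a [generate_cohort()] result, a [read_cohort_dir()] result,
#'   or a directory path.
#' @param config a [run_config()].
#' @param lobe_rows include merged-mask lobe aggregate rows (default TRUE).
#' @param voxel_dims voxel dimensions in mm (default 1 mm isotropic).
#' @return features tibble (one row per subject x ROI and per subject x
#'   lobe), with attribute `errors` (tibble of failed subjects).
#' @export
run_extract <- function(cohort, config = run_config(), lobe_rows = TRUE,
                        voxel_dims = c(1, 1, 1)) {
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  roi_table <- cohort$roi_table
  csf_labels <- config$csf_labels
  if (is.null(csf_labels)) {
    csf_labels <- roi_table$label_id[roi_table$lobe == "csf"]
  }
  if (length(csf_labels) == 0L) stop("no CSF labels available")
  feats <- list(); errs <- list()
  for (sid in names(cohort$volumes)) {
    res <- tryCatch(
      extract_one_subject(sid, cohort$volumes[[sid]], roi_table, csf_labels,
                          config$grey_levels, config$trim_sigma, voxel_dims,
                          lobe_rows),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errs[[sid]] <- tibble::tibble(subject_id = sid,
                                    error = conditionMessage(res))
    } else {
      feats[[sid]] <- res
    }
  }
  if (length(feats) == 0L) stop("feature extraction failed for all subjects")
  out <- dplyr::bind_rows(feats)
  attr(out, "errors") <- dplyr::bind_rows(errs)
  out
}

#' Run the group-comparison analysis and emit study-style tables
#'
#' Produces the demographics table, the regional-volume ANCOVA table
#' (covariates age, sex, education, TBV), the regional-texture ANCOVA table
#' (covariates age, sex, education, regional volume), a long-format stats
#' table with raw and Bonferroni-adjusted pairwise p-values, and a JSON run
#' manifest. Writes CSVs when `config$out_dir` is set.
#'
#' @param features tibble from [run_extract()].
#' @param subjects subject table.
#' @param config a [run_config()].
#' @return list with `table1`, `table2_volume`, `table3_texture`,
#'   `stats_long`, `manifest`.
#' @export
run_analyze <- function(features, subjects, config = run_config()) {
  orphans <- setdiff(unique(features$subject_id), subjects$subject_id)
  if (length(orphans) > 0L) {
    stop("subjects missing from the subject table: ",
         paste(head(orphans, 5L), collapse = ", "))
  }
  subj <- subjects
  tbv <- unique(features[, c("subject_id", "tbv_cc")])
  subj <- dplyr::left_join(subj, tbv, by = "subject_id")
  table1 <- demographics_table(subj, alpha = config$alpha)
  vol <- build_results_table(features, subj, kind = "volume",
                             alpha = config$alpha, m = config$posthoc_m)
  tex <- build_results_table(features, subj, kind = "texture",
                             feature = config$texture_feature,
                             alpha = config$alpha, m = config$posthoc_m)
  stats_long <- dplyr::bind_rows(vol$stats, tex$stats)
  manifest <- list(
    package = "braintex",
    version = as.character(utils::packageVersion("braintex")),
    config = unclass(config),
    n_subjects = nrow(subj),
    groups = as.list(table(subj$group)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  out <- list(table1 = table1, table2_volume = vol$table,
              table3_texture = tex$table, stats_long = stats_long,
              manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(table1, file.path(config$out_dir, "table1.csv"),
              row.names = FALSE)
    write.csv(vol$table, file.path(config$out_dir, "table2_volume.csv"),
              row.names = FALSE)
    write.csv(tex$table, file.path(config$out_dir, "table3_texture.csv"),
              row.names = FALSE)
    write.csv(stats_long, file.path(config$out_dir, "stats.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Simulate, extract and analyse in one call
#'
#' End-to-end run on a phantom cohort: generate, extract features, run the
#' group statistics. With a fixed seed the whole run is reproducible. The
#' default cohort is a demonstration-scale phantom (20 subjects per group,
#' regional voxel counts at 5% of study magnitude); pass
#' `spec = default_cohort_spec()` for the full study-scale recipe.
#'
#' @param seed integer seed (overrides the spec seed).
#' @param spec optional [cohort_spec()].
#' @param config a [run_config()].
#' @return list with `cohort`, `features`, `analysis`.
#' @export
run_full <- function(seed = 1L, spec = NULL, config = run_config(seed = seed)) {
  if (is.null(spec)) {
    spec <- default_cohort_spec(voxel_scale = 0.05, seed = seed)
    spec$n_per_group <- c("N-CN" = 20L, "N+CN" = 20L, "N+MCI" = 20L)
  } else {
    spec$seed <- as.integer(seed)
  }
  cohort <- generate_cohort(spec, out_dir = NULL)
  features <- run_extract(cohort, config)
  analysis <- run_analyze(features, cohort$subjects, config)
  list(cohort = cohort, features = features, analysis = analysis)
}
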