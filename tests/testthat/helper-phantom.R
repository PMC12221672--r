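# Shared fixtures: small phantom specs, a naive GLCM oracle, connectivity.

# Small three-group cohort spec: two grey-matter ROIs plus the CSF reference.
# Effects are supplied per group; defaults give a null cohort.
small_cohort_spec <- function(seed, n = c(20L, 20L, 20L),
                              effects = NULL, roi_voxels = 512L,
                              texture_sigma = 15, noise = 5,
                              baseline_atrophy = 0.05,
                              atrophy_jitter_sd = 0.02) {
  if (is.null(effects)) {
    effects <- list(
      "N-CN" = group_effect("N-CN", reference = TRUE),
      "N+CN" = group_effect("N+CN"),
      "N+MCI" = group_effect("N+MCI")
    )
  }
  cohort_spec(
    n_per_group = c("N-CN" = n[1], "N+CN" = n[2], "N+MCI" = n[3]),
    age_mean = c(74.4, 75.3, 74.8), age_sd = c(4.5, 4.4, 4.4),
    education_mean = c(12.0, 12.1, 10.9), education_sd = c(4.8, 5.0, 5.2),
    sex_female_prop = c(0.634, 0.514, 0.619),
    mmse_mean = c(27.6, 26.9, 24.1), mmse_sd = c(2.1, 2.8, 3.5),
    roi_specs = list(
      roi_spec(1, "hippocampus", "temporal", 400, roi_voxels,
               texture_sigma = texture_sigma, smooth_fwhm_vox = 2,
               anatomy_sigma = 20),
      roi_spec(2, "entorhinal", "temporal", 400, roi_voxels,
               texture_sigma = texture_sigma, smooth_fwhm_vox = 2,
               anatomy_sigma = 20),
      roi_spec(3, "lateral_ventricle", "csf", 100, 216)
    ),
    group_effects = effects,
    noise_floor_sigma = noise,
    baseline_atrophy = baseline_atrophy,
    atrophy_jitter_sd = atrophy_jitter_sd,
    seed = seed
  )
}

# Naive triple-loop pair enumerator: the independent co-occurrence oracle.
naive_glcm <- function(levels, offset, N) {
  d <- dim(levels)
  C <- matrix(0, N, N)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    x2 <- x + offset[1]; y2 <- y + offset[2]; z2 <- z + offset[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
    a <- levels[x, y, z]; b <- levels[x2, y2, z2]
    if (is.na(a) || is.na(b)) next
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1
  }
  C
}

# 6-connectivity check by flood fill.
is_connected6 <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) <= 1L) return(TRUE)
  d <- dim(mask)
  visited <- array(FALSE, dim = d)
  queue <- list(w[1, ])
  visited[w[1, 1], w[1, 2], w[1, 3]] <- TRUE
  count <- 1L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (length(queue) > 0L) {
    v <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (i in seq_len(6)) {
      nb <- v + offs[i, ]
      if (any(nb < 1) || any(nb > d)) next
      if (mask[nb[1], nb[2], nb[3]] && !visited[nb[1], nb[2], nb[3]]) {
        visited[nb[1], nb[2], nb[3]] <- TRUE
        count <- count + 1L
        queue[[length(queue) + 1L]] <- nb
      }
    }
  }
  count == nrow(w)
}

# Wrap a level vector as a 3D array with NA padding where excluded.
levels_array <- function(values, dims) {
  array(as.integer(values), dim = dims)
}
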