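#' Partial-volume trimming of an ROI intensity sample
#'
#' Retains voxels whose intensity lies inside \eqn{[\mu - k\sigma, \mu + k\sigma]}
#' (inclusive), where \eqn{\mu} and \eqn{\sigma} are the mean and population
#' standard deviation (divide by n) of the ROI's own voxels. Voxels at the
#' edge of an ROI mix tissue classes; trimming the intensity tails removes
#' most of that partial-volume contamination before texture quantization.
#'
#' With \eqn{\sigma = 0} (constant sample) every voxel is retained. By
#' Chebyshev's inequality the retained fraction is always at least
#' \eqn{1 - 1/k^2} (8/9 at the default k = 3).
#'
#' @param values numeric vector of in-mask voxel intensities.
#' @param n_sigma half-width of the retention window in SD units (default 3).
#' @return logical vector, `TRUE` for retained voxels.
#' @examples
#' trim_partial_volume(c(rep(0, 10), 100))  # the outlier is dropped
#' @export
trim_partial_volume <- function(values, n_sigma = 3) {
  if (length(values) == 0L) stop("empty intensity sample")
  if (anyNA(values)) stop("intensity sample contains NA")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))  # population SD
  if (sigma == 0) return(rep(TRUE, length(values)))
  values >= mu - n_sigma * sigma & values <= mu + n_sigma * sigma
}

#' Mean CSF reference intensity from the lateral ventricles
#'
#' Arithmetic mean of the intensity volume over all voxels whose label is in
#' `csf_labels`. Used as the per-subject denominator that removes global
#' scanner/receive-gain scale before quantization.
#'
#' @param intensity 3D numeric array.
#' @param labels integer 3D array of the same dimensions.
#' @param csf_labels integer vector of CSF label ids.
#' @return scalar mean CSF intensity (> 0).
#' @export
csf_reference_mean <- function(intensity, labels, csf_labels) {
  stopifnot(identical(dim(intensity), dim(labels)))
  sel <- labels %in% csf_labels
  if (!any(sel)) stop("no voxels carry a CSF label")
  m <- mean(intensity[sel])
  if (!is.finite(m) || m <= 0) {
    stop("CSF reference mean is not positive; cannot normalize")
  }
  m
}

#' Normalize intensities to the CSF reference
#'
#' @param values numeric vector or array of intensities.
#' @param csf_mean positive scalar CSF reference mean.
#' @return `values / csf_mean` (dimensionless ratios).
#' @export
normalize_to_csf <- function(values, csf_mean) {
  if (!is.finite(csf_mean) || csf_mean <= 0) stop("csf_mean must be > 0")
  values / csf_mean
}

#' Linear min-max quantization to L grey levels
#'
#' Maps retained voxel values to integer levels `1..L` by equal-width binning
#' over the retained range:
#' `level(v) = min(L, floor((v - vmin) / (vmax - vmin) * L) + 1)`.
#' A degenerate range (`vmax == vmin`) maps every voxel to level 1. Binning is
#' per ROI over retained voxels only (fixed-bin-number convention), so levels
#' are invariant to any affine intensity transform with positive slope.
#'
#' @param values numeric vector of (normalized) retained-voxel intensities.
#' @param L integer number of grey levels (>= 2, default 32).
#' @return integer vector of levels in `1..L`.
#' @export
quantize_to_levels <- function(values, L = 32L) {
  if (length(values) == 0L) stop("no retained voxels to quantize")
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  vmin <- min(values)
  vmax <- max(values)
  if (vmax == vmin) return(rep(1L, length(values)))
  pmin(L, as.integer(floor((values - vmin) / (vmax - vmin) * L)) + 1L)
}

#' Run the full pre-texture intensity chain for one ROI
#'
#' Composes, in order: partial-volume trimming (per-ROI by default),
#' CSF-referenced normalization, and min-max re-quantization to `L` grey
#' levels. Returns a quantized ROI ready for co-occurrence counting.
#'
#' @param intensity 3D numeric array.
#' @param mask logical 3D array selecting the ROI.
#' @param csf_mean positive scalar from [csf_reference_mean()].
#' @param L grey-level count (default 32).
#' @param trim_sigma trimming half-width in SD units (default 3).
#' @param trim_stats optional list with elements `mu`, `sigma` to trim against
#'   precomputed (e.g. whole-brain) statistics instead of the ROI's own.
#' @return an object of class `quantized_roi`: list with `levels` (3D integer
#'   array, `NA` outside the retained mask), `retained_mask`, `L`,
#'   `n_retained`, `n_roi`.
#' @export
quantize_roi <- function(intensity, mask, csf_mean, L = 32L, trim_sigma = 3,
                         trim_stats = NULL) {
  stopifnot(identical(dim(intensity), dim(mask)))
  vals <- intensity[mask]
  if (length(vals) == 0L) stop("empty ROI mask")
  if (is.null(trim_stats)) {
    keep <- trim_partial_volume(vals, n_sigma = trim_sigma)
  } else {
    if (trim_stats$sigma == 0) {
      keep <- rep(TRUE, length(vals))
    } else {
      lo <- trim_stats$mu - trim_sigma * trim_stats$sigma
      hi <- trim_stats$mu + trim_sigma * trim_stats$sigma
      keep <- vals >= lo & vals <= hi
    }
  }
  retained_mask <- mask
  retained_mask[mask] <- keep
  norm <- normalize_to_csf(vals[keep], csf_mean)
  lev <- quantize_to_levels(norm, L = L)
  levels_arr <- array(NA_integer_, dim = dim(intensity))
  levels_arr[retained_mask] <- lev
  structure(
    list(levels = levels_arr, retained_mask = retained_mask, L = as.integer(L),
         n_retained = sum(keep), n_roi = length(vals)),
    class = "quantized_roi"
  )
}
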