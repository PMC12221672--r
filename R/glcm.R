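#' The 13 unique 3D co-occurrence directions at distance 1
#'
#' The 26-neighborhood of a voxel splits into 13 antipodal offset pairs; with
#' symmetric co-occurrence counting one member of each pair suffices. The
#' canonical member is the lexicographically greater of `(dx, dy, dz)` and its
#' negation, so e.g. `(0, 0, 1)` is canonical and `(0, 0, -1)` is not.
#'
#' @return a 13 x 3 integer matrix with columns `dx`, `dy`, `dz`, fixed order.
#' @export
glcm_directions <- function() {
  .glcm_dirs
}

.glcm_dirs <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[, c("dx", "dy", "dz")]
  keep <- g$dx > 0 | (g$dx == 0 & g$dy > 0) | (g$dx == 0 & g$dy == 0 & g$dz > 0)
  m <- as.matrix(g[keep, , drop = FALSE])
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
})

#' Build a symmetric GLCM for one direction
#'
#' Counts every ordered pair of retained voxels `(v, v + offset)` inside the
#' level array, accumulating both orientations (`C[i,j]` and `C[j,i]`), then
#' normalizes to probabilities. Voxels outside the retained mask carry `NA`
#' and never pair. No padding or wraparound: pairs must have both ends inside
#' the array and the retained mask.
#'
#' @param levels 3D integer array of grey levels in `1..N`, `NA` elsewhere,
#'   or a `quantized_roi` object.
#' @param offset length-3 integer offset (one row of [glcm_directions()]).
#' @param N number of grey levels; defaults to the `L` of a `quantized_roi`
#'   input or `max(levels, na.rm = TRUE)`.
#' @return object of class `glcm`: list with `P` (N x N matrix summing to 1
#'   when any pair exists), `N`, `pair_count` (raw symmetric pair count).
#' @export
build_glcm <- function(levels, offset, N = NULL) {
  if (inherits(levels, "quantized_roi")) {
    if (is.null(N)) N <- levels$L
    levels <- levels$levels
  }
  stopifnot(length(dim(levels)) == 3L, length(offset) == 3L)
  if (is.null(N)) N <- max(levels, na.rm = TRUE)
  N <- as.integer(N)
  rng <- range(levels, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 1L || rng[2] > N)) {
    stop("levels outside 1..N")
  }
  d <- dim(levels)
  off <- as.integer(offset)
  lo <- pmax(1L, 1L - off)
  hi <- pmin(d, d - off)
  C <- matrix(0, N, N)
  pair_count <- 0L
  if (all(lo <= hi)) {
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    a <- levels[ix, iy, iz, drop = FALSE]
    b <- levels[ix + off[1], iy + off[2], iz + off[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      ai <- a[ok]; bi <- b[ok]
      tab <- tabulate((ai - 1L) * N + bi, nbins = N * N)
      C <- matrix(tab, N, N, byrow = TRUE)
      C <- C + t(C)  # symmetric accumulation: each ordered pair both ways
      pair_count <- as.integer(sum(C))
    }
  }
  P <- if (pair_count > 0L) C / sum(C) else C
  structure(list(P = P, N = N, pair_count = pair_count), class = "glcm")
}

#' Average normalized GLCMs over directions
#'
#' Elementwise mean of the normalized matrices over directions that produced
#' at least one pair; empty directions are excluded, not averaged as zero
#' matrices. The result is renormalized to sum exactly 1 to guard against
#' floating-point drift. Per-direction normalization before averaging weights
#' all directions equally even when their pair counts differ at mask
#' boundaries.
#'
#' @param glcms list of `glcm` objects with a common `N`.
#' @return a `glcm` object; `pair_count` is the total over used directions and
#'   attribute `n_directions_used` records how many contributed.
#' @export
average_glcms <- function(glcms) {
  stopifnot(length(glcms) >= 1L)
  Ns <- vapply(glcms, function(g) g$N, integer(1))
  if (length(unique(Ns)) != 1L) stop("GLCMs have differing N")
  used <- Filter(function(g) g$pair_count > 0L, glcms)
  if (length(used) == 0L) stop("all directions produced zero pairs")
  P <- Reduce(`+`, lapply(used, function(g) g$P)) / length(used)
  P <- P / sum(P)
  out <- structure(
    list(P = P, N = Ns[1], pair_count = sum(vapply(used, function(g) g$pair_count, integer(1)))),
    class = "glcm"
  )
  attr(out, "n_directions_used") <- length(used)
  out
}

check_normalized <- function(glcm, tol = 1e-6) {
  if (!inherits(glcm, "glcm")) stop("not a glcm object")
  if (glcm$pair_count == 0L) stop("GLCM has no pairs; features undefined")
  if (abs(sum(glcm$P) - 1) > tol) stop("GLCM is not normalized")
  invisible(glcm)
}

#' Haralick contrast of a normalized GLCM
#'
#' \eqn{\sum_{i=1}^{N}\sum_{j=1}^{N} (i-j)^2 P_{ij}}: grows with the
#' grey-level difference between adjacent voxel pairs, so higher values mean
#' more local intensity heterogeneity. Bounded by \eqn{(N-1)^2}.
#'
#' @param glcm a normalized `glcm` object.
#' @return scalar contrast, in `[0, (N-1)^2]`.
#' @export
glcm_contrast <- function(glcm) {
  check_normalized(glcm)
  idx <- seq_len(glcm$N)
  sum(outer(idx, idx, function(i, j) (i - j)^2) * glcm$P)
}

#' Haralick entropy of a normalized GLCM
#'
#' \eqn{-\sum P_{ij} \ln P_{ij}} in nats, with \eqn{0 \ln 0 = 0}. Measures
#' the disorder of the co-occurrence distribution; 0 for a single nonzero
#' cell, at most \eqn{\ln N^2}.
#'
#' @inheritParams glcm_contrast
#' @return scalar entropy (nats).
#' @export
glcm_entropy <- function(glcm) {
  check_normalized(glcm)
  p <- glcm$P[glcm$P > 0]
  -sum(p * log(p))
}

#' GLCM autocorrelation
#'
#' \eqn{\sum_{i,j} i \, j \, P_{ij}}: co-occurrence probability weighted by
#' the product of the paired grey levels. In `[1, N^2]` for 1-based levels.
#'
#' @inheritParams glcm_contrast
#' @return scalar autocorrelation.
#' @export
glcm_autocorrelation <- function(glcm) {
  check_normalized(glcm)
  idx <- seq_len(glcm$N)
  sum(outer(idx, idx) * glcm$P)
}

crop_to_mask <- function(arrs, mask) {
  w <- which(mask, arr.ind = TRUE)
  rx <- range(w[, 1]); ry <- range(w[, 2]); rz <- range(w[, 3])
  lapply(arrs, function(a) a[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2], drop = FALSE])
}

#' Full texture profile for one ROI (or a merged set of ROIs)
#'
#' Runs the complete chain for the voxels labelled `roi_label`:
#' trim to \eqn{\mu \pm 3\sigma}, normalize to the lateral-ventricle CSF mean,
#' quantize to `L` levels, build the 13 distance-1 symmetric GLCMs, average
#' the normalized matrices, and evaluate contrast, entropy and
#' autocorrelation. `roi_label` may contain several label ids, in which case
#' the chain runs once on the merged mask (used for lobe-level rows).
#'
#' @param intensity 3D numeric array.
#' @param labels integer 3D array of the same dimensions.
#' @param roi_label integer label id(s) defining the ROI mask.
#' @param csf_labels integer CSF label id(s) for the reference mean.
#' @param L grey levels (default 32).
#' @param trim_sigma trimming half-width (default 3).
#' @return a tibble row with `contrast`, `entropy`, `autocorrelation`,
#'   `n_directions_used`, `n_retained`, `n_roi`, and a logical `flagged`
#'   (TRUE, with NA features, when no direction yields an adjacent retained
#'   pair).
#' @export
roi_texture_profile <- function(intensity, labels, roi_label, csf_labels,
                                L = 32L, trim_sigma = 3) {
  mask <- labels %in% roi_label & labels != 0L
  dim(mask) <- dim(labels)
  if (!any(mask)) stop("ROI label(s) absent from label volume")
  csf_mean <- csf_reference_mean(intensity, labels, csf_labels)
  cr <- crop_to_mask(list(intensity = intensity, mask = mask), mask)
  q <- quantize_roi(cr$intensity, cr$mask, csf_mean, L = L,
                    trim_sigma = trim_sigma)
  dirs <- glcm_directions()
  glcms <- lapply(seq_len(nrow(dirs)), function(k) build_glcm(q, dirs[k, ]))
  any_pairs <- any(vapply(glcms, function(g) g$pair_count > 0L, logical(1)))
  if (!any_pairs) {
    return(tibble::new_tibble(list(
      contrast = NA_real_, entropy = NA_real_, autocorrelation = NA_real_,
      n_directions_used = 0L, n_retained = q$n_retained, n_roi = q$n_roi,
      flagged = TRUE), nrow = 1L))
  }
  avg <- average_glcms(glcms)
  tibble::new_tibble(list(
    contrast = glcm_contrast(avg),
    entropy = glcm_entropy(avg),
    autocorrelation = glcm_autocorrelation(avg),
    n_directions_used = attr(avg, "n_directions_used"),
    n_retained = q$n_retained,
    n_roi = q$n_roi,
    flagged = FALSE), nrow = 1L)
}
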