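test_that("the 13 canonical directions cover the 26-neighborhood without antipodes", {
  d <- glcm_directions()
  expect_equal(nrow(d), 13)
  expect_true(all(abs(d) <= 1))
  expect_false(any(rowSums(abs(d)) == 0))
  key <- apply(d, 1, paste, collapse = ",")
  neg <- apply(-d, 1, paste, collapse = ",")
  expect_length(intersect(key, neg), 0)
  expect_equal(length(unique(c(key, neg))), 26)
  expect_true("0,0,1" %in% key)
  expect_false("0,0,-1" %in% key)
})

test_that("build_glcm counts symmetric pairs on hand-enumerable ROIs", {
  lev <- levels_array(c(1, 2), c(1, 1, 2))
  g <- build_glcm(lev, c(0, 0, 1), N = 2)
  expect_equal(g$pair_count, 2L)
  expect_equal(g$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  lev3 <- levels_array(rep(3, 8), c(2, 2, 2))
  g3 <- build_glcm(lev3, c(1, 0, 0), N = 5)
  expect_equal(g3$P[3, 3], 1)
  expect_equal(sum(g3$P), 1)

  lev121 <- levels_array(c(1, 2, 1), c(1, 1, 3))
  g121 <- build_glcm(lev121, c(0, 0, 1), N = 2)
  expect_equal(g121$P[1, 2], 0.5)
  expect_equal(g121$P[2, 1], 0.5)

  expect_error(build_glcm(levels_array(c(0, 1), c(1, 1, 2)), c(0, 0, 1), N = 2),
               "outside 1..N")
})

test_that("averaging GLCMs is an elementwise mean over non-empty directions", {
  lev <- levels_array(c(1, 2), c(1, 1, 2))
  g <- build_glcm(lev, c(0, 0, 1), N = 2)
  avg13 <- average_glcms(rep(list(g), 13))
  expect_equal(avg13$P, g$P)
  expect_equal(attr(avg13, "n_directions_used"), 13)

  g2 <- build_glcm(levels_array(c(1, 1), c(1, 1, 2)), c(0, 0, 1), N = 2)
  avg <- average_glcms(list(g, g2))
  expect_equal(avg$P, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))

  # a 1-voxel-thick ROI has pairs only along its axis; other directions are
  # skipped rather than averaged in as zeros
  thin <- levels_array(c(1, 2, 1, 2), c(1, 1, 4))
  dirs <- glcm_directions()
  gl <- lapply(seq_len(nrow(dirs)), function(k) build_glcm(thin, dirs[k, ], N = 2))
  avg_thin <- average_glcms(gl)
  expect_equal(attr(avg_thin, "n_directions_used"), 1)
  expect_equal(avg_thin$P[1, 2] + avg_thin$P[2, 1], 1)

  empty <- build_glcm(levels_array(c(1, 2), c(1, 1, 2)), c(1, 0, 0), N = 2)
  expect_error(average_glcms(list(empty)), "zero pairs")
})

test_that("contrast, entropy and autocorrelation match closed forms", {
  mk <- function(P, N) structure(list(P = P, N = N, pair_count = 10L),
                                 class = "glcm")
  Pgg <- matrix(0, 4, 4); Pgg[3, 3] <- 1
  expect_equal(glcm_contrast(mk(Pgg, 4)), 0)
  expect_equal(glcm_entropy(mk(Pgg, 4)), 0)
  expect_equal(glcm_autocorrelation(mk(Pgg, 4)), 9)

  P12 <- matrix(0, 2, 2); P12[1, 2] <- 0.5; P12[2, 1] <- 0.5
  expect_equal(glcm_contrast(mk(P12, 2)), 1)
  expect_equal(glcm_entropy(mk(P12, 2)), log(2))
  expect_equal(glcm_autocorrelation(mk(P12, 2)), 2)

  Pext <- matrix(0, 32, 32); Pext[1, 32] <- 0.5; Pext[32, 1] <- 0.5
  expect_equal(glcm_contrast(mk(Pext, 32)), 961)

  P23 <- matrix(0, 3, 3); P23[2, 3] <- 0.5; P23[3, 2] <- 0.5
  expect_equal(glcm_autocorrelation(mk(P23, 3)), 6)

  Pu <- matrix(0, 2, 2); Pu[1, 1] <- Pu[1, 2] <- Pu[2, 1] <- Pu[2, 2] <- 0.25
  expect_equal(glcm_entropy(mk(Pu, 2)), log(4))

  bad <- mk(P12 * 2, 2)
  expect_error(glcm_contrast(bad), "not normalized")
})

test_that("build_glcm matches the naive pair-enumeration oracle exactly", {
  set.seed(99)
  dirs <- glcm_directions()
  for (rep in 1:30) {
    d <- sample(2:12, 3, replace = TRUE)
    N <- sample(2:8, 1)
    lev <- array(sample(N, prod(d), replace = TRUE), dim = d)
    lev[array(runif(prod(d)) < 0.3, dim = d)] <- NA  # random exclusions
    off <- dirs[sample(13, 1), ]
    g <- build_glcm(lev, off, N = N)
    C <- naive_glcm(lev, off, N)
    expect_equal(g$pair_count, sum(C))
    if (sum(C) > 0) expect_equal(g$P, C / sum(C)) else expect_equal(sum(g$P), 0)
  }
})

test_that("grey-level inversion preserves contrast and entropy; autocorrelation transforms predictably", {
  set.seed(7)
  N <- 6
  lev <- array(sample(N, 8^3, replace = TRUE), dim = c(8, 8, 8))
  dirs <- glcm_directions()
  gl <- lapply(seq_len(nrow(dirs)), function(k) build_glcm(lev, dirs[k, ], N = N))
  avg <- average_glcms(gl)
  inv <- array(N + 1L - lev, dim = dim(lev))
  gli <- lapply(seq_len(nrow(dirs)), function(k) build_glcm(inv, dirs[k, ], N = N))
  avgi <- average_glcms(gli)
  expect_equal(glcm_contrast(avgi), glcm_contrast(avg), tolerance = 1e-12)
  expect_equal(glcm_entropy(avgi), glcm_entropy(avg), tolerance = 1e-12)
  # i -> N+1-i maps autocorrelation to (N+1)^2 - 2(N+1) mu + A, with mu the
  # marginal level mean (symmetric GLCM)
  mu <- sum(seq_len(N) * rowSums(avg$P))
  expect_equal(glcm_autocorrelation(avgi),
               (N + 1)^2 - 2 * (N + 1) * mu + glcm_autocorrelation(avg),
               tolerance = 1e-12)
})

test_that("averaged GLCMs stay normalized on random masked ROIs", {
  set.seed(123)
  dirs <- glcm_directions()
  for (rep in 1:10) {
    d <- sample(3:10, 3, replace = TRUE)
    lev <- array(sample(5, prod(d), replace = TRUE), dim = d)
    lev[array(runif(prod(d)) < 0.4, dim = d)] <- NA
    gl <- lapply(seq_len(nrow(dirs)), function(k) build_glcm(lev, dirs[k, ], N = 5))
    if (all(vapply(gl, function(g) g$pair_count == 0L, logical(1)))) next
    avg <- average_glcms(gl)
    expect_lt(abs(sum(avg$P) - 1), 1e-9)
    expect_equal(avg$P, t(avg$P))
  }
})

test_that("roi_texture_profile composes the chain and matches brute force on a checkerboard", {
  # constant ROI: zero contrast and entropy
  labs <- array(0L, c(8, 8, 8))
  labs[2:5, 2:5, 2:5] <- 1L
  labs[7, 7, 7] <- 2L
  img <- array(0, c(8, 8, 8))
  img[labs == 1L] <- 400
  img[labs == 2L] <- 100
  prof <- roi_texture_profile(img, labs, 1L, 2L)
  expect_equal(prof$contrast, 0)
  expect_equal(prof$entropy, 0)
  expect_false(prof$flagged)

  # checkerboard of two extreme intensities: equals the naive oracle on the
  # quantization the chain produces (levels 1 and 32 by parity)
  img2 <- img
  w <- which(labs == 1L, arr.ind = TRUE)
  parity <- (w[, 1] + w[, 2] + w[, 3]) %% 2
  img2[labs == 1L] <- ifelse(parity == 0, 450, 150)
  prof2 <- roi_texture_profile(img2, labs, 1L, 2L)
  lev <- array(NA_integer_, c(4, 4, 4))
  w2 <- which(array(TRUE, c(4, 4, 4)), arr.ind = TRUE)
  # same parity pattern on the cropped 4^3 block (offset by 1 in each axis)
  lev[] <- ifelse((w2[, 1] + w2[, 2] + w2[, 3]) %% 2 == 1, 32L, 1L)
  dirs <- glcm_directions()
  Ps <- list(); used <- 0
  contrast_naive <- 0
  acc <- matrix(0, 32, 32)
  for (k in seq_len(nrow(dirs))) {
    C <- naive_glcm(lev, dirs[k, ], 32)
    if (sum(C) == 0) next
    used <- used + 1
    acc <- acc + C / sum(C)
  }
  Pavg <- acc / used
  idx <- seq_len(32)
  contrast_naive <- sum(outer(idx, idx, function(i, j) (i - j)^2) * Pavg)
  expect_equal(prof2$contrast, contrast_naive, tolerance = 1e-12)
  # axis directions alone hit the (N-1)^2 bound
  gax <- build_glcm(lev, c(0, 0, 1), N = 32)
  expect_equal(glcm_contrast(gax), 961)
})

test_that("texture features depend only on voxels inside the ROI mask", {
  set.seed(17)
  labs <- array(0L, c(9, 9, 9))
  labs[2:6, 2:6, 2:6] <- 1L
  labs[8, 8, 8] <- 2L
  img <- array(rnorm(9^3, 300, 25), c(9, 9, 9))
  img[labs == 2L] <- 100
  p1 <- roi_texture_profile(img, labs, 1L, 2L)
  img_mod <- img
  img_mod[labs == 0L] <- img_mod[labs == 0L] + rnorm(sum(labs == 0L), 0, 500)
  p2 <- roi_texture_profile(img_mod, labs, 1L, 2L)
  expect_equal(p1, p2)
})

test_that("an ROI with no adjacent retained pair is flagged, not silently zero", {
  labs <- array(0L, c(5, 5, 5))
  labs[1, 1, 1] <- 1L  # single-voxel ROI: no pairs in any direction
  labs[3, 3, 3] <- 2L
  img <- array(0, c(5, 5, 5))
  img[labs == 1L] <- 400; img[labs == 2L] <- 100
  prof <- roi_texture_profile(img, labs, 1L, 2L)
  expect_true(prof$flagged)
  expect_true(is.na(prof$contrast))
  expect_equal(prof$n_directions_used, 0L)
})
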