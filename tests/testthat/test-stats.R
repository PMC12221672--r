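test_that("one-way ANOVA matches hand computation and the lm route", {
  res <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(res$F, 1.5)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 4L)

  same <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(same$F, 0)

  set.seed(5)
  y <- rnorm(30); g <- sample(c("a", "b", "c"), 30, replace = TRUE)
  res2 <- one_way_anova(y, g)
  ref <- anova(lm(y ~ factor(g)))
  expect_equal(res2$F, ref$`F value`[1])
  expect_equal(res2$p, ref$`Pr(>F)`[1])

  expect_error(one_way_anova(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3)),
               "zero within-group")
})

test_that("chi-square test reproduces hand-computed statistics", {
  expect_equal(chi_square_test(rbind(c(10, 10), c(10, 10)))$chi2, 0)
  res <- chi_square_test(rbind(c(20, 10), c(10, 20)))
  expect_equal(res$chi2, 20 / 3)
  expect_equal(res$df, 1L)
  expect_error(chi_square_test(rbind(c(0, 0), c(10, 20))), "marginal")
})

test_that("partial eta squared follows the F identity", {
  expect_equal(partial_eta_squared(0, 2, 442), 0)
  set.seed(2)
  F <- rexp(20); df1 <- sample(1:4, 20, TRUE); df2 <- sample(10:500, 20)
  expect_equal(partial_eta_squared(F, df1, df2),
               (F * df1) / (F * df1 + df2), tolerance = 1e-15)
})

test_that("ANCOVA with zero covariates reproduces one-way ANOVA exactly", {
  set.seed(9)
  y <- rnorm(45); g <- rep(c("a", "b", "c"), each = 15)
  a1 <- ancova_group_test(y, g)
  a2 <- one_way_anova(y, g)
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  expect_equal(a1$p, a2$p, tolerance = 1e-10)
  expect_equal(a1$df2, a2$df2)
  expect_equal(unname(a1$adjusted_means),
               as.numeric(tapply(y, g, mean)), tolerance = 1e-10)
})

test_that("a covariate orthogonal to groups and response only costs one df", {
  y <- c(1, 2, 3, 2, 3, 4)
  g <- rep(c("g1", "g2"), each = 3)
  cov <- data.frame(z = c(1, -2, 1, 1, -2, 1))  # orthogonal to dummies and y
  fit <- ancova_group_test(y, g, cov)
  # hand computation: SSB = 1.5, RSS = 4 unchanged, df2 = 6 - 2 - 1 = 3
  expect_equal(fit$F, (1.5 / 1) / (4 / 3), tolerance = 1e-12)
  expect_equal(fit$df2, 3L)
})

test_that("ANCOVA group F agrees with the Type-III route in car", {
  set.seed(33)
  n <- 60
  g <- factor(rep(c("a", "b", "c"), each = n / 3))
  covs <- data.frame(age = rnorm(n, 74, 4), sex = factor(sample(c("F", "M"), n, TRUE)),
                     education = rnorm(n, 12, 5))
  y <- rnorm(n) + 0.05 * covs$age + 0.4 * (g == "c")
  fit <- ancova_group_test(y, g, covs)
  m <- lm(y ~ g + age + sex + education, data = cbind(covs, g = g, y = y),
          contrasts = list(g = "contr.sum", sex = "contr.sum"))
  a3 <- car::Anova(m, type = 3)
  expect_equal(fit$F, a3["g", "F value"], tolerance = 1e-10)
  expect_equal(fit$p, a3["g", "Pr(>F)"], tolerance = 1e-10)
})

test_that("adjusted means and pairwise contrasts agree with emmeans", {
  set.seed(44)
  n <- 48
  g <- factor(rep(c("a", "b", "c"), each = n / 3))
  covs <- data.frame(age = rnorm(n, 74, 4), education = rnorm(n, 12, 5))
  y <- rnorm(n) + 0.1 * covs$age + 0.5 * (g == "b")
  fit <- ancova_group_test(y, g, covs)
  ph <- bonferroni_posthoc(fit, m = 3)
  dat <- cbind(covs, g = g, y = y)
  m <- lm(y ~ g + age + education, data = dat)
  em <- emmeans::emmeans(m, "g")
  expect_equal(unname(fit$adjusted_means),
               summary(em)$emmean, tolerance = 1e-10)
  prs <- summary(emmeans::contrast(em, "pairwise"), adjust = "bonferroni")
  expect_equal(abs(ph$pairs$estimate), abs(prs$estimate), tolerance = 1e-10)
  expect_equal(ph$pairs$p_adj, pmin(1, prs$p.value), tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly naming the collinear column", {
  y <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  covs <- data.frame(x1 = rnorm(30))
  covs$x2 <- 2 * covs$x1
  expect_error(ancova_group_test(y, g, covs), "x2")
})

test_that("Bonferroni adjustment triples and caps pairwise p-values", {
  set.seed(55)
  y <- rnorm(36); g <- rep(c("a", "b", "c"), each = 12)
  fit <- ancova_group_test(y, g)
  ph <- bonferroni_posthoc(fit, m = 3)
  expect_equal(ph$pairs$p_adj, pmin(1, 3 * ph$pairs$p_raw))
  expect_equal(nrow(ph$pairs), 3L)
})

test_that("post hoc p-values are invariant to group relabeling", {
  set.seed(66)
  y <- rnorm(36) + rep(c(0, 0.5, 1.5), each = 12)
  g <- rep(c("a", "b", "c"), each = 12)
  ph1 <- bonferroni_posthoc(ancova_group_test(y, g))
  # relabel a<->c; the same unordered pairs must carry the same p-values
  g2 <- c(a = "c", b = "b", c = "a")[g]
  ph2 <- bonferroni_posthoc(ancova_group_test(y, factor(g2, levels = c("a", "b", "c"))))
  key1 <- apply(ph1$pairs[, c("group1", "group2")], 1, function(r)
    paste(sort(c(c(a = "c", b = "b", c = "a")[r[1]],
                 c(a = "c", b = "b", c = "a")[r[2]])), collapse = "-"))
  key2 <- apply(ph2$pairs[, c("group1", "group2")], 1, function(r)
    paste(sort(r), collapse = "-"))
  expect_equal(ph1$pairs$p_raw[order(key1)], ph2$pairs$p_raw[order(key2)],
               tolerance = 1e-12)
})

test_that("pattern strings follow the compact a/b/c convention", {
  sig_all <- matrix(TRUE, 3, 3); diag(sig_all) <- FALSE
  expect_equal(pattern_string(c(a = 3, b = 2, c = 1), sig_all), "a > b > c")
  expect_equal(pattern_string(c(a = 1, b = 2, c = 3), sig_all), "a < b < c")

  # a-c and b-c significant, a-b not, c lowest
  sig <- matrix(FALSE, 3, 3)
  sig[1, 3] <- sig[3, 1] <- TRUE
  sig[2, 3] <- sig[3, 2] <- TRUE
  expect_equal(pattern_string(c(a = 3, b = 2.9, c = 1), sig), "a, b > c")
  expect_equal(pattern_string(c(a = 1, b = 1.1, c = 3), sig), "a, b < c")

  # only a-c significant: b is omitted
  sig_ac <- matrix(FALSE, 3, 3)
  sig_ac[1, 3] <- sig_ac[3, 1] <- TRUE
  expect_equal(pattern_string(c(a = 1, b = 2, c = 3), sig_ac), "a < c")
  expect_equal(pattern_string(c(a = 3, b = 2, c = 1), sig_ac), "a > c")

  # a lowest, b and c tied above
  sig_a <- matrix(FALSE, 3, 3)
  sig_a[1, 2] <- sig_a[2, 1] <- TRUE
  sig_a[1, 3] <- sig_a[3, 1] <- TRUE
  expect_equal(pattern_string(c(a = 1, b = 2, c = 2.1), sig_a), "a < b, c")

  expect_equal(pattern_string(c(a = 1, b = 2, c = 3),
                              matrix(FALSE, 3, 3)), "")
})

test_that("ICC(2,1) matches perfect agreement, a mean-squares oracle, and aov", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_equal(icc_two_rater(a, a)$icc, 1)

  # small table; oracle from the two-way ANOVA mean squares via aov()
  r1 <- c(9, 6, 8, 7, 10, 6)
  r2 <- c(2, 1, 4, 1, 5, 2)
  res <- icc_two_rater(r1, r2)
  d <- data.frame(y = c(r1, r2),
                  subj = factor(rep(1:6, 2)),
                  rater = factor(rep(1:2, each = 6)))
  ms <- anova(lm(y ~ subj + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, oracle, tolerance = 1e-12)
  expect_lte(res$ci_low, res$icc)
  expect_gte(res$ci_high, res$icc)

  # independent ratings: ICC near zero
  set.seed(77)
  hits <- 0L
  for (r in 1:20) {
    x <- rnorm(200); z <- rnorm(200)
    if (abs(icc_two_rater(x, z)$icc) < 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 19L)

  flat <- icc_two_rater(rep(1, 6), rep(1, 6))
  expect_true(flat$flagged)
})

test_that("ANCOVA omnibus p-values are uniform under a phantom null", {
  # 500 null replicates of the volumetric model the phantom generates:
  # counts = 512 - round(512 f) with truncated-normal subject erosion f,
  # TBV the sum of two such ROIs plus a fixed CSF compartment.
  set.seed(123)
  nrep <- 500L
  ps <- numeric(nrep)
  for (r in seq_len(nrep)) {
    n <- 60L
    g <- factor(rep(c("N-CN", "N+CN", "N+MCI"), each = 20),
                levels = c("N-CN", "N+CN", "N+MCI"))
    f1 <- pmin(0.8, pmax(0, rnorm(n, 0.05, 0.02)))
    f2 <- pmin(0.8, pmax(0, rnorm(n, 0.05, 0.02)))
    v1 <- (512 - round(512 * f1)) / 1000
    v2 <- (512 - round(512 * f2)) / 1000
    covs <- data.frame(age = rnorm(n, 74.4, 4.5),
                       sex = factor(sample(c("F", "M"), n, TRUE)),
                       education = pmax(0, rnorm(n, 12, 5)),
                       volcov = v1 + v2 + 0.216)
    ps[r] <- ancova_group_test(v1, g, covs)$p
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 1.96 * sqrt(0.05 * 0.95 / nrep))
})
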