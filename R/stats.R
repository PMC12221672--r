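#' Partial eta squared from an F statistic
#'
#' \eqn{\eta^2_p = F \cdot df_1 / (F \cdot df_1 + df_2)}, algebraically equal
#' to \eqn{SS_{effect} / (SS_{effect} + SS_{error})}.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 numerator / denominator degrees of freedom.
#' @return effect size in `[0, 1]`.
#' @export
partial_eta_squared <- function(F, df1, df2) {
  stopifnot(all(F >= 0), all(df1 > 0), all(df2 > 0))
  F * df1 / (F * df1 + df2)
}

#' Classical one-way ANOVA
#'
#' Between/within F test for a difference in group means.
#'
#' @param y numeric response.
#' @param group grouping vector (>= 2 groups, each n >= 2).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(y, group) {
  group <- factor(group)
  k <- nlevels(group)
  stopifnot(k >= 2L, all(table(group) >= 2L))
  n <- length(y)
  gm <- mean(y)
  means <- tapply(y, group, mean)
  ns <- tapply(y, group, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((y - means[group])^2)
  if (ssw == 0) stop("zero within-group variance everywhere")
  df1 <- k - 1L
  df2 <- n - k
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction, df = (r-1)(k-1).
#'
#' @param contingency matrix of counts.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("zero marginal in contingency table")
  }
  res <- suppressWarnings(chisq.test(contingency, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  covariates <- as.data.frame(covariates)
  X <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  X
}

#' ANCOVA group test with covariate adjustment
#'
#' Fits `y ~ group + covariates` by least squares (group dummy-coded against
#' the first level; two-level categorical covariates such as sex become 0/1
#' dummies) and tests the group effect with the partial (Type III) F — the
#' full-versus-reduced comparison, which for a single factor plus covariates
#' coincides with Type II. Also returns covariate-adjusted group means
#' (predictions at the covariate means) and partial eta squared.
#'
#' @param y numeric response.
#' @param group grouping vector; level order is kept if already a factor.
#' @param covariates data frame of covariates (may be `NULL`).
#' @return object of class `ancova_result`: `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq`, `adjusted_means` (named), plus the pieces post hoc
#'   contrasts need (`coef`, `vcov`, `Lrows`, `df_residual`, `groups`).
#' @export
ancova_group_test <- function(y, group, covariates = NULL) {
  group <- if (is.factor(group)) droplevels(group) else factor(group)
  k <- nlevels(group)
  n <- length(y)
  Xc <- covariate_matrix(covariates, n)
  stopifnot(k >= 2L, n > k + ncol(Xc) + 1L)
  G <- model.matrix(~ group)
  X <- cbind(G, Xc)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- lm.fit(X, y)
  rss_full <- sum(fit$residuals^2)
  Xr <- cbind(`(Intercept)` = rep(1, n), Xc)
  rss_red <- sum(lm.fit(Xr, y)$residuals^2)
  df1 <- k - 1L
  df2 <- n - ncol(X)
  F <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  p <- pf(F, df1, df2, lower.tail = FALSE)
  sigma2 <- rss_full / df2
  XtXinv <- chol2inv(qr.R(qrX))
  V <- sigma2 * XtXinv
  dimnames(V) <- list(colnames(X), colnames(X))
  cov_means <- if (ncol(Xc) > 0) colMeans(Xc) else numeric(0)
  Lrows <- matrix(0, k, ncol(X), dimnames = list(levels(group), colnames(X)))
  Lrows[, 1] <- 1
  for (g in 2:k) Lrows[g, g] <- 1
  if (ncol(Xc) > 0) Lrows[, colnames(Xc)] <- matrix(cov_means, k,
                                                    ncol(Xc), byrow = TRUE)
  beta <- fit$coefficients
  adjusted_means <- drop(Lrows %*% beta)
  structure(list(
    F = F, df1 = df1, df2 = df2, p = p,
    partial_eta_sq = partial_eta_squared(F, df1, df2),
    adjusted_means = adjusted_means,
    coef = beta, vcov = V, Lrows = Lrows, df_residual = df2,
    groups = levels(group), n = n
  ), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA group test: F(%d, %d) = %.3f, p = %.4g, eta^2_p = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$partial_eta_sq))
  cat("Adjusted means:\n")
  print(round(x$adjusted_means, 4))
  invisible(x)
}

cluster_components <- function(keep, nonsig) {
  comp <- seq_along(keep)
  repeat {
    changed <- FALSE
    for (i in seq_along(keep)) for (j in seq_along(keep)) {
      if (nonsig[i, j] && comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Assemble a post hoc pattern string
#'
#' Compact notation for which groups differ: groups with no significant
#' pairwise difference to any other are omitted; mutually non-different
#' groups are joined with a comma; ordered clusters are joined with `<` or
#' `>` by their adjusted means, written so the earliest group label comes
#' first (e.g. `"a, b > c"`, `"a < b < c"`, `"a < c"`).
#'
#' @param means named adjusted means (names = group labels in label order).
#' @param sig k x k logical matrix of pairwise significance.
#' @param labels display labels, default letters.
#' @return pattern string, `""` when no pair is significant.
#' @export
pattern_string <- function(means, sig, labels = letters[seq_along(means)]) {
  k <- length(means)
  any_sig <- vapply(seq_len(k), function(i) any(sig[i, -i]), logical(1))
  keep <- which(any_sig)
  if (length(keep) == 0L) return("")
  nonsig <- !sig[keep, keep, drop = FALSE]
  comp <- cluster_components(keep, nonsig)
  clusters <- split(keep, comp)
  cmeans <- vapply(clusters, function(ix) mean(means[ix]), numeric(1))
  asc <- clusters[order(cmeans)]
  first <- min(keep)
  in_first_asc <- first %in% asc[[1]]
  in_first_desc <- first %in% asc[[length(asc)]]
  if (!in_first_asc && in_first_desc) {
    ordered <- rev(asc); sep <- " > "
  } else {
    ordered <- asc; sep <- " < "
  }
  paste(vapply(ordered, function(ix) {
    paste(labels[sort(ix)], collapse = ", ")
  }, character(1)), collapse = sep)
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' Pairwise contrasts of covariate-adjusted group means using the ANCOVA's
#' pooled error variance (estimated-marginal-means style t tests on the
#' model degrees of freedom), Bonferroni-adjusted (`p_adj = min(1, m p)`).
#' The pattern string is empty when the omnibus p is at or above `alpha`.
#'
#' @param result an [ancova_group_test()] result.
#' @param alpha significance level (default 0.05).
#' @param m number of comparisons for the correction (default: all pairs).
#' @return list with `pairs` (tibble: groups, estimate, se, t, df, p_raw,
#'   p_adj, significant) and `pattern`.
#' @export
bonferroni_posthoc <- function(result, alpha = 0.05, m = NULL) {
  stopifnot(inherits(result, "ancova_result"))
  k <- length(result$groups)
  pairs <- utils::combn(k, 2)
  if (is.null(m)) m <- ncol(pairs)
  rows <- vector("list", ncol(pairs))
  sig <- matrix(FALSE, k, k)
  for (p_i in seq_len(ncol(pairs))) {
    i <- pairs[1, p_i]; j <- pairs[2, p_i]
    L <- result$Lrows[i, ] - result$Lrows[j, ]
    est <- sum(L * result$coef)
    se <- sqrt(drop(t(L) %*% result$vcov %*% L))
    tval <- est / se
    p_raw <- 2 * pt(-abs(tval), df = result$df_residual)
    p_adj <- min(1, m * p_raw)
    s <- p_adj < alpha
    sig[i, j] <- sig[j, i] <- s
    rows[[p_i]] <- tibble::tibble(
      group1 = result$groups[i], group2 = result$groups[j],
      estimate = est, se = se, t = tval, df = result$df_residual,
      p_raw = p_raw, p_adj = p_adj, significant = s
    )
  }
  pattern <- if (result$p >= alpha) "" else {
    pattern_string(result$adjusted_means, sig)
  }
  list(pairs = dplyr::bind_rows(rows), pattern = pattern)
}

#' Two-way random-effects single-measure ICC with absolute agreement
#'
#' ICC(2,1): both raters and subjects are random effects and systematic
#' rater differences count against agreement. Computed from the two-way
#' ANOVA mean squares with the F-based 95% confidence interval.
#'
#' @param ratings_a,ratings_b equal-length paired ratings (n >= 5).
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @return list with `icc`, `ci_low`, `ci_high`, `flagged` (TRUE when
#'   between-subject variance is zero and the ICC is undefined).
#' @export
icc_two_rater <- function(ratings_a, ratings_b, alpha = 0.05) {
  stopifnot(length(ratings_a) == length(ratings_b), length(ratings_a) >= 5L)
  x <- cbind(ratings_a, ratings_b)
  n <- nrow(x); k <- 2L
  grand <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  if (all(rm_ == rm_[1])) {
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                flagged = TRUE))
  }
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # McGraw & Wong F-based CI for ICC(A,1)
  if (mse == 0 && msc == 0) {
    return(list(icc = icc, ci_low = icc, ci_high = icc, flagged = FALSE))
  }
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  Fl <- qf(1 - alpha / 2, n - 1, v)
  Fu <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - Fl * mse) /
    (Fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (Fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * Fu * msr)
  list(icc = icc, ci_low = lo, ci_high = hi, flagged = FALSE)
}
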