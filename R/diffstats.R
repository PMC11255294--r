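#' Wilcoxon rank-sum test with AUC effect size
#'
#' Computes the Mann-Whitney U statistic with midranks for ties,
#' `U = R_a - n_a(n_a+1)/2`, and the AUC `U / (n_a n_b)`, the probability
#' that a random value of group A exceeds one of group B (ties counted
#' half). The p-value is exact (full enumeration of all group assignments)
#' when `n_a + n_b <= 12`, otherwise a normal approximation with tie
#' correction and 0.5 continuity correction.
#'
#' @param a,b numeric values of the two groups (each non-empty).
#' @param alternative `"two.sided"`, `"greater"` (A tends larger) or
#'   `"less"`.
#' @param exact_max largest pooled size for which the exact permutation
#'   p-value is enumerated.
#' @return list with `U`, `auc`, `p`.
#' @export
rank_sum_auc <- function(a, b, alternative = c("two.sided", "greater", "less"),
                         exact_max = 12) {
  alternative <- match.arg(alternative)
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  n_a <- length(a)
  n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  auc <- U / (n_a * n_b)
  mu <- n_a * n_b / 2
  n <- n_a + n_b

  if (n <= exact_max) {
    # exact permutation null: U over all C(n, n_a) group assignments
    assignments <- utils::combn(n, n_a)
    u_null <- apply(assignments, 2, function(idx) {
      sum(r[idx]) - n_a * (n_a + 1) / 2
    })
    eps <- 1e-9
    p <- switch(alternative,
                two.sided = mean(abs(u_null - mu) >= abs(U - mu) - eps),
                greater = mean(u_null >= U - eps),
                less = mean(u_null <= U + eps))
  } else {
    ties <- table(r)
    sigma2 <- (n_a * n_b / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      p <- switch(alternative,
                  two.sided = {
                    z <- (abs(U - mu) - 0.5) / sigma
                    min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
                  },
                  greater = stats::pnorm((U - mu - 0.5) / sigma,
                                         lower.tail = FALSE),
                  less = stats::pnorm((U - mu + 0.5) / sigma))
      p <- min(max(p, .Machine$double.xmin), 1)
    }
  }
  list(U = U, auc = auc, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `padj_(i) = min_(j >= i) m p_(j) / j` clipped at 1, returned in input
#' order.
#'
#' @param pvals numeric p-values in `(0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' One-vs-rest differential features with AUC
#'
#' Tests every feature of a normalized matrix for difference between a
#' target cell group and all remaining cells with the two-sided Wilcoxon
#' rank-sum test, reporting the AUC and an average log2 fold change of the
#' de-logged normalized values,
#' `log2((mean_target + eps) / (mean_rest + eps))`. P-values are BH-adjusted
#' across all tested features; filtering by `padj` and sign is the caller's
#' choice. With `delog = FALSE` the values are taken as-is (e.g. motif
#' deviation z-scores, which may be negative) and `avg_log2fc` holds the
#' difference of group means instead of a log ratio.
#'
#' @param norm_matrix features x cells normalized matrix (log scale unless
#'   `delog = FALSE`).
#' @param labels group label per cell (length `ncol`).
#' @param target_group label of the group of interest.
#' @param eps pseudocount added to both means in the fold change.
#' @param delog exponentiate (`expm1`) values before computing group means;
#'   set `FALSE` for matrices that are not log-scaled (e.g. motif z-scores).
#' @param min_cells_expressed when > 0, only features detected (value != 0)
#'   in at least this many cells are tested.
#' @return data.frame with `feature_id`, `avg_log2fc`, `auc`, `p`, `padj`,
#'   `group`, ordered as the input features.
#' @export
differential_features <- function(norm_matrix, labels, target_group,
                                  eps = 1e-9, delog = TRUE,
                                  min_cells_expressed = 0) {
  if (length(labels) != ncol(norm_matrix)) {
    stop("labels length must equal number of cells")
  }
  in_target <- labels == target_group
  if (sum(in_target) < 2 || sum(!in_target) < 2) {
    stop("each side of the comparison needs >= 2 cells")
  }
  m <- as.matrix(norm_matrix)
  if (min_cells_expressed > 0) {
    m <- m[rowSums(m != 0) >= min_cells_expressed, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no features to test")
  res <- t(apply(m, 1, function(x) {
    rs <- rank_sum_auc(x[in_target], x[!in_target])
    lfc <- if (delog) {
      vals <- expm1(x)
      log2((mean(vals[in_target]) + eps) / (mean(vals[!in_target]) + eps))
    } else {
      mean(x[in_target]) - mean(x[!in_target])
    }
    c(lfc, rs$auc, rs$p)
  }))
  data.frame(feature_id = rownames(m),
             avg_log2fc = res[, 1], auc = res[, 2], p = res[, 3],
             padj = bh_adjust(res[, 3]),
             group = target_group, row.names = NULL)
}

#' Simplified negative-binomial Wald test for replicated bulk counts
#'
#' Two-group differential test for replicate-level count data (e.g. bulk
#' ATAC on a union peak set): median-of-ratios size factors, per-region
#' method-of-moments dispersion `alpha = (s^2 - mu)/mu^2` on
#' size-factor-normalized counts with `s^2` taken within condition groups
#' (group-centered residuals, so real differences do not inflate the
#' dispersion), then a two-group NB GLM with log link and
#' size-factor offsets fit by Newton/IRLS per group. The Wald statistic is
#' `z = (log-mean difference) / SE` with `SE` from the Fisher information;
#' two-sided normal p-values are BH-adjusted.
#'
#' With a handful of replicates the per-region moment estimate is far too
#' noisy to test against, so by default the regression
#' `alpha(mu) = a0 + a1/mu` is fit across all regions and its fitted value
#' is used per region (a trended dispersion). This shares information
#' through the mean-dispersion trend only; there is no per-region
#' empirical-Bayes blending. `dispersion = "per_region"` uses the raw
#' per-region estimates instead.
#'
#' @param bulk_counts regions x samples integer matrix.
#' @param condition_labels two-level factor/character, length `ncol`.
#' @param size_factors optional precomputed per-sample factors.
#' @param dispersion `"trended"` (default) or `"per_region"`.
#' @return data.frame with `feature_id`, `log2fc` (second level vs first),
#'   `base_mean`, `dispersion`, `se`, `stat`, `p`, `padj`; all-zero regions
#'   carry `NA` statistics.
#' @export
nb_wald_differential <- function(bulk_counts, condition_labels,
                                 size_factors = NULL,
                                 dispersion = c("trended", "per_region")) {
  dispersion <- match.arg(dispersion)
  m <- as.matrix(bulk_counts)
  cond <- as.factor(condition_labels)
  if (nlevels(cond) != 2) stop("exactly two conditions are required")
  if (any(table(cond) < 2)) stop("each condition needs >= 2 replicates")
  if (length(cond) != ncol(m)) stop("condition labels must match samples")
  sf <- if (is.null(size_factors)) median_ratio_size_factors(m) else size_factors
  norm <- sweep(m, 2, sf, `/`)
  mu_bar <- rowMeans(norm)
  # within-group moments: sum_g (n_g-1) s2_g = sum_g (n_g-1)(mu_g + a mu_g^2)
  num <- 0
  den <- 0
  for (lv in levels(cond)) {
    idx <- which(cond == lv)
    mu_g <- rowMeans(norm[, idx, drop = FALSE])
    s2_g <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    w <- length(idx) - 1
    num <- num + w * (s2_g - mu_g)
    den <- den + w * mu_g^2
  }
  alpha_raw <- num / den
  nonzero <- rowSums(m) > 0
  if (dispersion == "trended") {
    use <- nonzero & is.finite(alpha_raw)
    x <- 1 / mu_bar[use]
    tr <- stats::coef(stats::lm(alpha_raw[use] ~ x))
    tr <- pmax(tr, 0)
    alpha <- pmax(tr[1] + tr[2] / mu_bar, 1e-8)
  } else {
    alpha <- pmax(alpha_raw, 1e-8)
  }
  alpha[!nonzero] <- NA_real_

  # per-group NB log-mean by Newton iteration, vectorized over regions
  fit_group <- function(idx) {
    y <- m[nonzero, idx, drop = FALSE]
    s <- sf[idx]
    a <- alpha[nonzero]
    tot <- rowSums(y)
    eta <- log(pmax(tot, 0.5) / sum(s))
    for (it in 1:50) {
      mu <- exp(eta) %o% s
      denom <- 1 + a * mu
      f <- rowSums((y - mu) / denom)
      fp <- -rowSums(mu * (1 + a * y) / denom^2)
      step <- f / fp
      step[!is.finite(step)] <- 0
      step <- pmax(pmin(step, 5), -5)
      eta <- eta - step
      if (max(abs(step)) < 1e-10) break
    }
    mu <- exp(eta) %o% s
    info <- rowSums(mu / (1 + a * mu))
    list(eta = eta, info = info)
  }
  ga <- fit_group(which(cond == levels(cond)[1]))
  gb <- fit_group(which(cond == levels(cond)[2]))
  beta <- gb$eta - ga$eta
  se <- sqrt(1 / ga$info + 1 / gb$info)
  z <- beta / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- data.frame(feature_id = rownames(m),
                    log2fc = NA_real_, base_mean = mu_bar,
                    dispersion = alpha, se = NA_real_, stat = NA_real_,
                    p = NA_real_, padj = NA_real_, row.names = NULL)
  out$log2fc[nonzero] <- beta / log(2)
  out$se[nonzero] <- se / log(2)
  out$stat[nonzero] <- z
  out$p[nonzero] <- p
  out$padj[nonzero] <- bh_adjust(p)
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; errors on constant input where the
#' coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Linear model of scores on a categorical condition
#'
#' Ordinary least squares of per-observation scores on dummy-coded
#' condition levels, with two-sided t-tests on each non-reference
#' coefficient and the overall F test.
#'
#' @param scores numeric outcomes.
#' @param condition condition label per observation.
#' @param reference reference level (default: first factor level).
#' @return list: `coefficients` data.frame (level, estimate, se, t, p),
#'   `reference`, `f_statistic`, `f_p`, and the fitted `lm` object.
#' @export
ols_condition_test <- function(scores, condition, reference = NULL) {
  cond <- factor(condition)
  if (nlevels(cond) < 2) stop("need >= 2 condition levels")
  if (any(table(cond) < 2)) stop("each level needs >= 2 observations")
  if (!is.null(reference)) cond <- stats::relevel(cond, ref = reference)
  fit <- stats::lm(scores ~ cond)
  sm <- summary(fit)
  ct <- sm$coefficients[-1, , drop = FALSE]
  levels_tested <- sub("^cond", "", rownames(ct))
  fstat <- sm$fstatistic
  list(coefficients = data.frame(level = levels_tested,
                                 estimate = ct[, 1], se = ct[, 2],
                                 t = ct[, 3], p = ct[, 4],
                                 row.names = NULL),
       reference = levels(cond)[1],
       f_statistic = unname(fstat[1]),
       f_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                              lower.tail = FALSE)),
       fit = fit)
}
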