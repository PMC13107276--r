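#' Mann-Whitney test with a Hodges-Lehmann effect estimate
#'
#' The p-value is exact (full permutation enumeration, tie-aware, computed
#' by a rank-sum counting recursion) when `length(x) * length(y) <= 400`,
#' otherwise the normal approximation with tie correction is used. The
#' effect size is the Hodges-Lehmann median of pairwise differences with
#' its distribution-free confidence interval; with `log = TRUE` the test
#' statistic is unchanged (ranks are monotone-invariant) but the effect is
#' computed on logs and exponentiated, giving a ratio-type effect.
#'
#' @param x,y Numeric samples (each of size >= 3).
#' @param conf.level Confidence level for the effect CI.
#' @param log Compute the effect on the log scale (ratio effect)?
#' @return List: estimate, ci95, p_value, method, n.
#' @export
mann_whitney_effect <- function(x, y, conf.level = 0.95, log = FALSE) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  m <- length(x); n <- length(y)
  if (length(unique(c(x, y))) == 1L) {
    warning("all observations tied; effect 0, p = 1")
    est <- if (log) 1 else 0
    return(list(estimate = est, ci95 = c(est, est), p_value = 1,
                method = "degenerate", n = c(m, n)))
  }
  exact <- m * n <= 400
  p <- if (exact) mw_exact_p(x, y) else mw_normal_p(x, y)
  xe <- if (log) base::log(x) else x
  ye <- if (log) base::log(y) else y
  wt <- suppressWarnings(stats::wilcox.test(xe, ye, conf.int = TRUE,
                                            conf.level = conf.level))
  est <- unname(wt$estimate)
  ci <- unname(wt$conf.int)
  if (log) { est <- exp(est); ci <- exp(ci) }
  list(estimate = est, ci95 = ci, p_value = p,
       method = if (exact) "exact enumeration" else "normal approximation",
       n = c(m, n))
}

## Exact two-sided Mann-Whitney p by counting rank-sum attainments over all
## choose(m+n, m) group labelings (ties handled through midranks doubled to
## integers). Equivalent to full permutation enumeration.
mw_exact_p <- function(x, y) {
  m <- length(x)
  all_v <- c(x, y)
  r2 <- as.integer(round(2 * rank(all_v)))  # midranks doubled -> integers
  obs <- sum(r2[seq_len(m)])
  mu <- m * sum(r2) / length(r2)
  dev <- abs(obs - mu)
  # f[k+1, s+1] = number of k-subsets with doubled-rank sum s
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
  f <- matrix(0, nrow = m + 1, ncol = smax + 1)
  f[1, 1] <- 1
  for (v in r2) {
    kmax <- m
    for (k in kmax:1) {
      src <- f[k, ]
      if (all(src == 0)) next
      shifted <- c(rep(0, v), src)[seq_len(smax + 1)]
      f[k + 1, ] <- f[k + 1, ] + shifted
    }
  }
  cnt <- f[m + 1, ]
  sums <- 0:smax
  hit <- abs(sums - mu) >= dev - 1e-9
  min(1, sum(cnt[hit]) / sum(cnt))
}

## Normal approximation with tie correction (two-sided, no continuity
## correction so large-sample results track the exact enumeration mean).
mw_normal_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  nties <- table(r)
  sigma2 <- m * n / 12 * ((m + n + 1) -
                            sum(nties^3 - nties) / ((m + n) * (m + n - 1)))
  z <- (U - mu) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' One-way ANOVA with protected LSD post hoc letters
#'
#' Standard one-way F test; when the omnibus test is significant at
#' `alpha`, least-significant-difference pairwise t tests on the pooled
#' within-group mean square follow (protected LSD), summarised as a compact
#' letter display (groups sharing a letter are not significantly
#' different; letters assigned by a greedy insert-absorb pass over groups
#' ordered by decreasing mean). Normality (Shapiro-Wilk per group) and
#' homogeneity of variance (Levene) diagnostics are attached.
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 3 groups, >= 2 observations each; >= 3
#'   for the normality diagnostic).
#' @param alpha Significance level.
#' @return List: f_statistic, df, p_value, means, lsd (pairwise table or
#'   NULL), letters (named), shapiro_p, levene_p.
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 3) stop("need at least 3 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 observations")
  fit <- aov(values ~ groups)
  sm <- summary(fit)[[1]]
  Fv <- sm$`F value`[1]; p <- sm$`Pr(>F)`[1]
  mse <- sm$`Mean Sq`[2]; dfe <- sm$Df[2]
  means <- tapply(values, groups, mean)
  shapiro_p <- vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(v) < 3 || length(unique(v)) == 1) NA_real_
    else shapiro.test(v)$p.value
  }, numeric(1))
  levene_p <- tryCatch(
    car::leveneTest(values ~ groups)[1, "Pr(>F)"],
    error = function(e) NA_real_)
  lsd <- NULL
  letters_out <- setNames(rep("a", nlevels(groups)), levels(groups))
  if (!is.na(p) && p < alpha) {
    cmb <- combn(levels(groups), 2)
    lsd <- data.frame(g1 = cmb[1, ], g2 = cmb[2, ])
    lsd$diff <- means[lsd$g1] - means[lsd$g2]
    se <- sqrt(mse * (1 / sizes[lsd$g1] + 1 / sizes[lsd$g2]))
    lsd$t <- as.numeric(lsd$diff / se)
    lsd$p_value <- 2 * pt(-abs(lsd$t), dfe)
    lsd$significant <- lsd$p_value < alpha
    rownames(lsd) <- NULL
    letters_out <- compact_letters(levels(groups)[order(-means)], lsd, alpha)
  }
  list(f_statistic = unname(Fv), df = c(sm$Df[1], dfe), p_value = unname(p),
       means = means, lsd = lsd, letters = letters_out,
       shapiro_p = shapiro_p, levene_p = unname(levene_p))
}

## Greedy insert-absorb compact letter display. `order` gives groups by
## decreasing mean; `lsd` the pairwise table with `significant`.
compact_letters <- function(order, lsd, alpha) {
  differ <- function(a, b) {
    hit <- (lsd$g1 == a & lsd$g2 == b) | (lsd$g1 == b & lsd$g2 == a)
    any(lsd$significant[hit])
  }
  sets <- list()
  for (g in order) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (!any(vapply(sets[[k]], function(h) differ(g, h), logical(1)))) {
        sets[[k]] <- c(sets[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  # absorb sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (k in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (j != k && keep[k] && keep[j] && all(sets[[k]] %in% sets[[j]]))
        keep[k] <- FALSE
    }
  }
  sets <- sets[keep]
  out <- setNames(rep("", length(order)), order)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out[order]
}

#' Correlation with automatic method selection
#'
#' Pearson when both variables pass the Shapiro-Wilk normality test at
#' `alpha_normal`, Spearman otherwise; the method used is recorded.
#' Correlation significance is judged at `alpha_sig` (0.01 by convention
#' for correlation screens). Spearman confidence intervals use the Fisher
#' z approximation with the 1.03/sqrt(n-3) standard error.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param alpha_normal Normality test level for method selection.
#' @param alpha_sig Significance level for the correlation.
#' @return List: estimate, ci95, p_value, method, significant, n.
#' @export
correlate <- function(x, y, alpha_normal = 0.05, alpha_sig = 0.01) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("correlation undefined for constant input")
  normal <- function(v) {
    if (length(v) > 4999) v <- sample(v, 4999)
    shapiro.test(v)$p.value >= alpha_normal
  }
  use_pearson <- normal(x) && normal(y)
  method <- if (use_pearson) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  est <- unname(ct$estimate)
  n <- length(x)
  ci <- if (use_pearson && !is.null(ct$conf.int)) {
    unname(ct$conf.int)
  } else {
    z <- atanh(min(max(est, -0.999999), 0.999999))
    se <- 1.03 / sqrt(n - 3)
    tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  list(estimate = est, ci95 = ci, p_value = ct$p.value, method = method,
       significant = ct$p.value < alpha_sig, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (order-preserving, monotone).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
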