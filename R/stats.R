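#' Group-comparison results
#'
#' All statistical tests in the package return a `group_comparison`
#' object holding the test name, per-group summaries (n, mean, SEM with
#' the sample standard deviation), the test statistic(s), degrees of
#' freedom and p-value(s). The significance level is fixed at 0.05 but
#' p-values are always reported, never only thresholded.
#'
#' @name group_comparison
#' @aliases group_comparison-class
NULL

new_group_comparison <- function(test, groups, effects, alpha = 0.05) {
  structure(list(test = test, groups = groups, effects = effects,
                 alpha = alpha),
            class = "group_comparison")
}

group_summary <- function(values, labels) {
  parts <- split(values, as.character(labels))
  tibble(
    label = names(parts),
    n = unname(lengths(parts)),
    mean = unname(vapply(parts, mean, numeric(1))),
    sem = unname(vapply(parts, function(v) {
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)))
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s>\n", x$test))
  print(as.data.frame(x$groups), row.names = FALSE)
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' @describeIn group_comparison One row per effect: `term`, `statistic`,
#'   `df`, `df2` (residual df where applicable), `p.value`.
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$effects

#' @describeIn group_comparison One-row summary: test name, first
#'   statistic and p-value, alpha, number of groups.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test = x$test,
         statistic = x$effects$statistic[nrow(x$effects)],
         p.value = x$effects$p.value[nrow(x$effects)],
         alpha = x$alpha, n_groups = nrow(x$groups))
}

#' Two-sample t-test (pooled or Welch)
#'
#' Two-sided two-sample t-test; with `equal_var = TRUE` the classic
#' pooled-variance test, otherwise Welch's test with
#' Welch-Satterthwaite degrees of freedom (the variant used for unequal
#' variances in cell-count comparisons). When both groups have zero
#' variance and equal means, `t = 0`, `p = 1` by convention.
#'
#' @param a,b Numeric vectors, each of length `>= 2`.
#' @param equal_var Assume equal variances (pooled test)?
#' @param labels Group labels for the summary table.
#' @return A [group_comparison].
#' @export
t_test_groups <- function(a, b, equal_var = FALSE, labels = c("a", "b")) {
  if (length(a) < 2L || length(b) < 2L) abort("each group needs n >= 2")
  groups <- group_summary(c(a, b), rep(labels, c(length(a), length(b))))
  if (sd(a) == 0 && sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    eff <- tibble(term = "t", statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, df2 = NA_real_,
                  p.value = if (equal) 1 else 0)
  } else {
    ht <- stats::t.test(a, b, var.equal = equal_var)
    eff <- tibble(term = "t", statistic = unname(ht$statistic),
                  df = unname(ht$parameter), df2 = NA_real_,
                  p.value = ht$p.value)
  }
  new_group_comparison(
    if (equal_var) "two-sample t-test (pooled)" else "Welch two-sample t-test",
    groups, eff)
}

#' One-way ANOVA and Tukey HSD post hoc comparisons
#'
#' `one_way_anova()` compares `>= 2` groups with the one-way F-test;
#' `tukey_hsd()` follows up with all pairwise comparisons adjusted by the
#' studentized-range distribution (the "ANOVA of four groups followed by
#' Tukey posthoc test" design).
#'
#' @param values Numeric response vector.
#' @param group Group labels, same length as `values`; each group needs
#'   `n >= 2`.
#' @return `one_way_anova()`: a [group_comparison]. `tukey_hsd()`: a
#'   tibble of pairwise contrasts with `diff`, confidence bounds and
#'   `p.adj`.
#' @export
one_way_anova <- function(values, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) abort("need >= 2 groups")
  if (any(table(group) < 2L)) abort("every group needs n >= 2")
  groups <- group_summary(values, group)
  if (sd(values) == 0) {
    eff <- tibble(term = "group", statistic = 0,
                  df = nlevels(group) - 1,
                  df2 = length(values) - nlevels(group), p.value = 1)
  } else {
    fit <- aov(values ~ group)
    tab <- summary(fit)[[1]]
    eff <- tibble(term = "group", statistic = tab[1, "F value"],
                  df = tab[1, "Df"], df2 = tab[2, "Df"],
                  p.value = tab[1, "Pr(>F)"])
  }
  new_group_comparison("one-way ANOVA", groups, eff)
}

#' @rdname one_way_anova
#' @export
tukey_hsd <- function(values, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) abort("need >= 2 groups")
  if (any(table(group) < 2L)) abort("every group needs n >= 2")
  tk <- TukeyHSD(aov(values ~ group))$group
  tibble(contrast = rownames(tk), diff = tk[, "diff"],
         conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
         p.adj = tk[, "p adj"])
}

#' Two-way ANOVA with interaction (Type II sums of squares)
#'
#' Fits `response ~ A * B` on a complete crossed design and reports F and
#' p for both main effects and the interaction. Type II sums of squares
#' are used so that unbalanced designs (e.g. 17 vs 20 ROIs per
#' phenotype) are handled; with balanced data Type II coincides with the
#' classical decomposition.
#'
#' @param response Numeric response vector.
#' @param factor_a,factor_b Factors (coerced), same length as `response`.
#' @param names Length-2 character vector naming the two factors in the
#'   output.
#' @return A [group_comparison] whose effects are the two main effects
#'   and the `A:B` interaction.
#' @export
two_way_anova <- function(response, factor_a, factor_b,
                          names = c("A", "B")) {
  fa <- as.factor(factor_a)
  fb <- as.factor(factor_b)
  stopifnot(length(response) == length(fa), length(fa) == length(fb))
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("empty design cell: %s = '%s', %s = '%s'",
                  names[1], levels(fa)[empty[1]],
                  names[2], levels(fb)[empty[2]]))
  }
  terms <- c(names[1], names[2], paste0(names[1], ":", names[2]))
  if (sd(response) == 0) {
    eff <- tibble(term = terms, statistic = 0,
                  df = c(nlevels(fa) - 1, nlevels(fb) - 1,
                         (nlevels(fa) - 1) * (nlevels(fb) - 1)),
                  df2 = length(response) - nlevels(fa) * nlevels(fb),
                  p.value = 1)
  } else {
    fit <- lm(response ~ fa * fb)
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((response - mean(response))^2)
    if (rss <= 1e-12 * tss) {
      # saturated fit: effect F is 0 (no SS) or unbounded (positive SS)
      rss_of <- function(f) sum(stats::residuals(lm(f))^2)
      ss <- c(rss_of(response ~ fb) - rss_of(response ~ fa + fb),
              rss_of(response ~ fa) - rss_of(response ~ fa + fb),
              rss_of(response ~ fa + fb) - rss)
      pos <- ss > 1e-12 * tss
      eff <- tibble(term = terms,
                    statistic = ifelse(pos, Inf, 0),
                    df = c(nlevels(fa) - 1, nlevels(fb) - 1,
                           (nlevels(fa) - 1) * (nlevels(fb) - 1)),
                    df2 = length(response) - nlevels(fa) * nlevels(fb),
                    p.value = ifelse(pos, 0, 1))
    } else {
      tab <- car::Anova(fit, type = 2)
      eff <- tibble(term = terms,
                    statistic = tab[1:3, "F value"],
                    df = tab[1:3, "Df"],
                    df2 = tab["Residuals", "Df"],
                    p.value = tab[1:3, "Pr(>F)"])
    }
  }
  groups <- group_summary(response, fa)
  new_group_comparison("two-way ANOVA (Type II)", groups, eff)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares the empirical CDFs of two samples: `D` is the supremum of
#' their absolute difference over the merged sample grid; the p-value
#' uses the asymptotic Kolmogorov distribution with effective sample
#' size `n_a * n_b / (n_a + n_b)`. The asymptotic p is conservative for
#' very small samples (roughly n < 20 per group).
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param labels Group labels.
#' @return A [group_comparison] with effect `D`.
#' @export
ks_two_sample <- function(a, b, labels = c("a", "b")) {
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  groups <- group_summary(c(a, b), rep(labels, c(length(a), length(b))))
  eff <- tibble(term = "D", statistic = unname(ht$statistic),
                df = NA_real_, df2 = NA_real_, p.value = ht$p.value)
  new_group_comparison("two-sample Kolmogorov-Smirnov test", groups, eff)
}

#' Mean and standard error of the mean
#'
#' SEM uses the sample standard deviation (n - 1 denominator), the
#' "mean +/- SEM" summary used throughout.
#'
#' @param values Numeric vector, `n >= 2`.
#' @return Named numeric vector `c(mean = , sem = )`.
#' @export
mean_sem <- function(values) {
  if (length(values) < 2L) abort("SEM needs n >= 2")
  c(mean = mean(values), sem = sd(values) / sqrt(length(values)))
}
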