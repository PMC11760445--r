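# Gated group comparison pipeline: normality/variance gating into
# ANOVA + Holm-Sidak or Kruskal-Wallis + Dunn-Bonferroni, variability
# comparison, per-group Pearson correlation and observed power.

#' Holm-Sidak step-down adjusted p values
#'
#' Step-down Sidak adjustment: with the raw p values in increasing order,
#' `p_adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, made monotone by cumulative
#' maxima. Less conservative than Holm's Bonferroni variant while
#' controlling the family-wise error rate.
#'
#' @param p Numeric vector of raw p values.
#' @return Adjusted p values in the original order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  if (m == 0L) return(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise pooled-variance t tests from a one-way layout
#' @noRd
pairwise_pooled_t <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g)
  ns <- lengths(g)
  means <- vapply(g, mean, numeric(1L))
  df <- sum(ns) - k
  mse <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1L))) / df
  pairs <- utils::combn(names(g), 2L)
  p <- apply(pairs, 2L, function(pr) {
    se <- sqrt(mse * (1 / ns[[pr[1L]]] + 1 / ns[[pr[2L]]]))
    if (se == 0) return(if (means[[pr[1L]]] == means[[pr[2L]]]) 1 else 0)
    2 * stats::pt(-abs((means[[pr[1L]]] - means[[pr[2L]]]) / se), df)
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], p_raw = p,
             stringsAsFactors = FALSE)
}

#' Pairwise Dunn rank tests (z statistics on mean ranks, tie-corrected)
#' @noRd
pairwise_dunn <- function(values, groups) {
  r <- rank(values)
  g <- split(r, groups)
  n <- length(values)
  ns <- lengths(g)
  rbar <- vapply(g, mean, numeric(1L))
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(names(g), 2L)
  p <- apply(pairs, 2L, function(pr) {
    se <- sqrt(v0 * (1 / ns[[pr[1L]]] + 1 / ns[[pr[2L]]]))
    if (se == 0) return(1)
    2 * stats::pnorm(-abs((rbar[[pr[1L]]] - rbar[[pr[2L]]]) / se))
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], p_raw = p,
             stringsAsFactors = FALSE)
}

check_groups <- function(values, groups) {
  if (length(values) != length(groups))
    stop("`values` and `groups` must have equal length", call. = FALSE)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  list(values = values, groups = droplevels(groups))
}

#' Gated omnibus comparison with post hoc tests
#'
#' Implements the parametric/non-parametric gate used throughout the
#' package: Shapiro-Wilk normality per group and a Brown-Forsythe
#' (median-centred Levene) equal-variance check at `alpha` decide between
#' a one-way ANOVA with Holm-Sidak-adjusted pairwise pooled-variance t
#' tests and a Kruskal-Wallis test with Bonferroni-adjusted Dunn post hoc
#' tests. Observed power (noncentral F at the sample effect size) is
#' reported for the parametric branch.
#'
#' Groups too small for Shapiro-Wilk (n < 3) or with zero spread do not
#' fail the normality gate on their own; a zero-spread group does force the
#' non-parametric branch since its normality is undecidable.
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels (coerced to factor), >= 2 values per group.
#' @param alpha Gate and test level (default 0.05).
#' @return A list of class `comparison_result`: `test_used`
#'   (`"anova"`/`"kruskal"`), `omnibus_p`, `shapiro_p` (per group),
#'   `variance_p`, `pairwise` (data.frame with `p_raw`, `p_adj`,
#'   `method`), `observed_power` (NA for the non-parametric branch).
#' @export
gate_and_compare <- function(values, groups, alpha = 0.05) {
  gg <- check_groups(values, groups)
  values <- gg$values; groups <- gg$groups
  by_group <- split(values, groups)

  shapiro_p <- vapply(by_group, function(x) {
    if (length(x) < 3L) return(NA_real_)
    if (stats::sd(x) == 0) return(0)     # degenerate: not testably normal
    stats::shapiro.test(x)$p.value
  }, numeric(1L))
  variance_p <- car::leveneTest(values ~ groups, center = stats::median)[
    1L, "Pr(>F)"]

  normal_ok <- all(is.na(shapiro_p) | shapiro_p > alpha)
  var_ok <- is.na(variance_p) || variance_p > alpha

  if (normal_ok && var_ok) {
    fit <- stats::aov(values ~ groups)
    omnibus_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    pw <- pairwise_pooled_t(values, groups)
    pw$p_adj <- holm_sidak(pw$p_raw)
    pw$method <- "holm-sidak"
    power <- observed_power(values, groups, alpha = alpha)
    test_used <- "anova"
  } else {
    omnibus_p <- stats::kruskal.test(values, groups)$p.value
    pw <- pairwise_dunn(values, groups)
    pw$p_adj <- pmin(1, nrow(pw) * pw$p_raw)
    pw$method <- "dunn-bonferroni"
    power <- NA_real_
    test_used <- "kruskal"
  }
  structure(list(test_used = test_used, omnibus_p = omnibus_p,
                 shapiro_p = shapiro_p, variance_p = variance_p,
                 pairwise = pw, observed_power = power, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: omnibus p = %.4g\n",
              x$test_used, x$omnibus_p))
  cat(sprintf("  variance (Brown-Forsythe) p = %.4g; observed power %s\n",
              x$variance_p,
              if (is.na(x$observed_power)) "n/a"
              else sprintf("%.3f", x$observed_power)))
  print(x$pairwise, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare group variability (spread) rather than location
#'
#' Brown-Forsythe construction: the analysis is run on absolute deviations
#' from each group's median, giving an omnibus F test for unequal spread
#' plus Holm-adjusted pairwise pooled-variance t tests on the deviations.
#' Constant groups throughout make the comparison degenerate; p = 1 is
#' returned with a warning.
#'
#' @inheritParams gate_and_compare
#' @return A list of class `variability_result`: `omnibus_p`, `pairwise`
#'   (Holm-adjusted), `method`.
#' @export
compare_variability <- function(values, groups, alpha = 0.05) {
  gg <- check_groups(values, groups)
  dev <- unsplit(lapply(split(gg$values, gg$groups),
                        function(x) abs(x - stats::median(x))), gg$groups)
  if (all(dev == 0)) {
    warning("all groups constant; variability comparison is degenerate")
    pairs <- utils::combn(levels(gg$groups), 2L)
    return(structure(list(
      omnibus_p = 1,
      pairwise = data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                            p_raw = 1, p_adj = 1, method = "holm",
                            stringsAsFactors = FALSE),
      method = "brown-forsythe"), class = "variability_result"))
  }
  fit <- stats::aov(dev ~ gg$groups)
  omnibus_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  pw <- pairwise_pooled_t(dev, gg$groups)
  pw$p_adj <- stats::p.adjust(pw$p_raw, "holm")
  pw$method <- "holm"
  structure(list(omnibus_p = omnibus_p, pairwise = pw,
                 method = "brown-forsythe"),
            class = "variability_result")
}

#' Per-group Pearson correlation
#'
#' Pearson's r with a two-sided test, computed within each group (or once
#' overall when `groups` is NULL). Zero variance in either variable makes
#' the correlation undefined and raises an error.
#'
#' @param x,y Numeric vectors (e.g. a density metric and an outcome
#'   metric).
#' @param groups Optional group labels.
#' @return data.frame with columns `group`, `n`, `r`, `p`.
#' @export
correlate <- function(x, y, groups = NULL) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (is.null(groups)) groups <- rep("all", length(x))
  groups <- factor(groups)
  out <- lapply(levels(groups), function(g) {
    xi <- x[groups == g]; yi <- y[groups == g]
    if (length(xi) < 3L)
      stop(sprintf("group '%s' has fewer than 3 pairs", g), call. = FALSE)
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0)
      stop(sprintf("zero variance in group '%s': correlation undefined", g),
           call. = FALSE)
    ct <- stats::cor.test(xi, yi, method = "pearson")
    data.frame(group = g, n = length(xi), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Observed (post hoc) power of a one-way ANOVA
#'
#' Noncentral-F power at level `alpha` using the sample effect as the
#' noncentrality basis: `ncp = SS_between / MS_within`, with the study's
#' group sizes and degrees of freedom. Zero residual variance yields power
#' 1 with a warning.
#'
#' @inheritParams gate_and_compare
#' @return Power in \[0, 1\].
#' @export
observed_power <- function(values, groups, alpha = 0.05) {
  gg <- check_groups(values, groups)
  by_group <- split(gg$values, gg$groups)
  k <- length(by_group)
  n <- length(gg$values)
  grand <- mean(gg$values)
  ssb <- sum(lengths(by_group) *
               (vapply(by_group, mean, numeric(1L)) - grand)^2)
  ssw <- sum(vapply(by_group, function(x) sum((x - mean(x))^2), numeric(1L)))
  df1 <- k - 1L; df2 <- n - k
  msw <- ssw / df2
  if (msw == 0) {
    warning("zero residual variance; observed power is 1")
    return(1)
  }
  ncp <- ssb / msw
  fcrit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(fcrit, df1, df2, ncp = ncp)
}
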