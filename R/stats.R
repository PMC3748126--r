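#' Two-sample t-test
#'
#' Classical two-sided Student t-test with pooled variance (the convention
#' of this assay's reporting); Welch's unequal-variance form by flag.
#'
#' @param group1,group2 numeric vectors, each with n >= 2.
#' @param welch use the Welch correction instead of pooling.
#' @return list with `t`, `p`, `df`, `estimate` (difference of means).
#' @export
two_sample_t <- function(group1, group2, welch = FALSE) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs n >= 2")
  if (sd(group1) == 0 && sd(group2) == 0)
    stop("both groups are constant: t-test undefined")
  ht <- stats::t.test(group1, group2, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       estimate = unname(diff(rev(ht$estimate))))
}

#' One-way ANOVA with Tukey HSD comparisons
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor), >= 2 levels, each n >= 2.
#' @return list with `F`, `p`, `df` (c(between, within)), and `tukey`, a
#'   data.frame of pairwise comparisons (difference, confidence bounds,
#'   studentized-range adjusted p).
#' @export
oneway_anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  tk <- TukeyHSD(fit)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = c(between = tab$Df[1], within = tab$Df[2]), tukey = tukey)
}

#' Two-way factorial ANOVA with interaction
#'
#' Fits `response ~ A * B` on a well-level table and reports F and p for
#' both main effects and the interaction, cell means with standard errors,
#' and corrected pairwise cell comparisons. For balanced designs the sums
#' of squares are the classical ones; for unbalanced designs type-II sums
#' of squares are used.
#'
#' @param data data.frame of one row per replication unit (well).
#' @param response name of the response column.
#' @param factor_a,factor_b names of the two factor columns (e.g.
#'   `"ethanol"`, `"gsi"`); coerced to factors, each >= 2 levels, and every
#'   factorial cell must hold n >= 2 (an empty cell leaves the interaction
#'   non-estimable).
#' @param correction pairwise-comparison correction: `"bonferroni"`,
#'   `"bh_fdr"`, or `"tukey"`.
#' @param alpha significance level recorded in the result.
#' @param pairwise compute corrected pairwise cell comparisons (skippable
#'   for speed in simulation studies).
#' @return object of class `factorial_result`: `anova` table (term, df, F,
#'   p), `cell_means`, `pairwise`, `correction`, `alpha`.
#' @export
twoway_anova <- function(data, response, factor_a = "ethanol",
                         factor_b = "gsi",
                         correction = c("bonferroni", "bh_fdr", "tukey"),
                         alpha = 0.05, pairwise = TRUE) {
  correction <- match.arg(correction)
  for (v in c(response, factor_a, factor_b))
    if (is.null(data[[v]])) stop("no such column: ", v)
  d <- data.frame(y = data[[response]],
                  A = factor(data[[factor_a]]), B = factor(data[[factor_b]]))
  d <- d[complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$A)) < 2 || nlevels(droplevels(d$B)) < 2)
    stop("both factors need >= 2 observed levels")
  cells <- table(d$A, d$B)
  if (any(cells == 0))
    stop("empty factorial cell: interaction is not estimable")
  if (any(cells < 2)) stop("every cell needs n >= 2")
  fit <- lm(y ~ A * B, data = d)
  a2 <- car::Anova(fit, type = 2)
  terms <- c("A", "B", "A:B")
  atab <- data.frame(
    term = c(factor_a, factor_b, paste(factor_a, factor_b, sep = ":")),
    df = a2[terms, "Df"], sum_sq = a2[terms, "Sum Sq"],
    F = a2[terms, "F value"], p = a2[terms, "Pr(>F)"], row.names = NULL)
  agg <- aggregate(y ~ A + B, d, function(x) c(mean(x), sd(x) / sqrt(length(x)),
                                               length(x)))
  cell_means <- data.frame(setNames(list(agg$A, agg$B), c(factor_a, factor_b)),
                           mean = agg$y[, 1], se = agg$y[, 2], n = agg$y[, 3])
  pw_tab <- NULL
  if (pairwise) {
    emm <- emmeans::emmeans(fit, ~ A * B)
    adj <- switch(correction, bonferroni = "bonferroni", bh_fdr = "fdr",
                  tukey = "tukey")
    pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = adj))
    pw_tab <- data.frame(comparison = pw$contrast, estimate = pw$estimate,
                         se = pw$SE, df = pw$df, t = pw$t.ratio,
                         p_adj = pw$p.value)
  }
  structure(list(response = response, anova = atab, cell_means = cell_means,
                 pairwise = pw_tab, correction = correction, alpha = alpha),
            class = "factorial_result")
}

#' @export
print.factorial_result <- function(x, ...) {
  cat("Two-way factorial ANOVA on '", x$response, "'\n", sep = "")
  tab <- x$anova
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-16s F(%d) = %8.3f   p = %.3g%s\n", tab$term[i],
                tab$df[i], tab$F[i], tab$p[i],
                ifelse(tab$p[i] <= x$alpha, " *", "")))
  cat("Cell means:\n")
  print(x$cell_means, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Pairwise comparisons (", x$correction, "):\n", sep = "")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m*p)`) or Benjamini-Hochberg step-up false-discovery
#' control.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @return adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = if (method == "bonferroni") "bonferroni" else "BH")
}
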