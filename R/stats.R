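## Group-comparison decision tree and significance conventions.

#' Significance stars for a p value
#'
#' Nested thresholds: `""` for p >= 0.05, `"*"` for p < 0.05, `"**"` for
#' p < 0.005, `"***"` for p < 0.0005.
#'
#' @param p A p value in `[0, 1]`.
#' @return Character string of stars (possibly empty).
#' @examples
#' starLabel(0.03)    # "*"
#' starLabel(0.0004)  # "***"
#' @export
starLabel <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p < 0.0005) "***" else if (p < 0.005) "**" else
    if (p < 0.05) "*" else ""
}

#' Dunn-Sidak adjustment
#'
#' Family-wise adjusted p value `1 - (1 - p)^m` for `m` comparisons,
#' monotone in p and bounded by 1.
#'
#' @param p Numeric p values.
#' @param m Number of comparisons in the family.
#' @return Adjusted p values.
#' @export
sidakAdjust <- function(p, m) pmin(1, 1 - (1 - p)^m)

## Dunn's rank-based pairwise z tests after Kruskal-Wallis, with the
## standard tie correction, Sidak-adjusted.
dunnPairwise <- function(values, groups) {
  g <- factor(groups)
  r <- rank(values)
  N <- length(values)
  tie <- table(r)
  tieTerm <- sum(tie^3 - tie) / (12 * (N - 1))
  meanR <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sigma <- sqrt((N * (N + 1) / 12 - tieTerm) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (meanR[[i]] - meanR[[j]]) / sigma
    res$p[k] <- 2 * stats::pnorm(-abs(z))
  }
  res$pAdjusted <- sidakAdjust(res$p, m)
  res
}

## Pairwise two-sided t tests (pooled s.d.), Bonferroni-adjusted.
bonferroniPairwise <- function(values, groups) {
  g <- factor(groups)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    a <- values[g == pairs[1, k]]; b <- values[g == pairs[2, k]]
    res$p[k] <- if (stats::sd(c(a - mean(a), b - mean(b))) == 0) 1 else
      stats::t.test(a, b, var.equal = TRUE)$p.value
  }
  res$pAdjusted <- stats::p.adjust(res$p, method = "bonferroni", n = m)
  res
}

#' Normality-gated group comparison
#'
#' The comparison decision tree used throughout the package: Shapiro-Wilk
#' normality per group at `alpha`; when every group passes, a one-way
#' ANOVA with Bonferroni-adjusted pairwise pooled t tests (a plain
#' two-sided t test when there are exactly two groups); when any group
#' fails, a Kruskal-Wallis test (with tie correction) followed by
#' Dunn-Sidak pairwise z tests.  Group summaries are mean +/- s.e.m.
#' Groups whose values are all identical cannot be tested for normality
#' and are routed to the nonparametric branch.
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @return A [ComparisonResult].
#' @export
compareGroups <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  ns <- tapply(values, g, length)
  if (any(ns < 3L)) stop("each group needs n >= 3")

  shap <- vapply(levels(g), function(l) {
    x <- values[g == l]
    if (stats::sd(x) == 0) return(0)  # degenerate: cannot be normal
    stats::shapiro.test(x)$p.value
  }, numeric(1))

  parametric <- all(shap > alpha)
  if (parametric) {
    if (nlevels(g) == 2L) {
      tt <- stats::t.test(values[g == levels(g)[1]],
                          values[g == levels(g)[2]], var.equal = TRUE)
      omnibus <- list(name = "two-sided t test",
                      stat = unname(tt$statistic), p = tt$p.value)
      pw <- data.frame(group1 = levels(g)[1], group2 = levels(g)[2],
                       p = tt$p.value, pAdjusted = tt$p.value,
                       stringsAsFactors = FALSE)
    } else {
      fit <- stats::aov(values ~ g)
      an <- summary(fit)[[1]]
      omnibus <- list(name = "one-way ANOVA", stat = an[["F value"]][1],
                      p = an[["Pr(>F)"]][1])
      pw <- bonferroniPairwise(values, g)
    }
  } else {
    kw <- stats::kruskal.test(values, g)
    omnibus <- list(name = "Kruskal-Wallis", stat = unname(kw$statistic),
                    p = kw$p.value)
    pw <- dunnPairwise(values, g)
  }
  pw$stars <- vapply(pw$pAdjusted, starLabel, character(1))

  summ <- data.frame(
    group = levels(g),
    mean = as.numeric(tapply(values, g, mean)),
    sem = as.numeric(tapply(values, g,
                            function(x) stats::sd(x) / sqrt(length(x)))),
    n = as.integer(ns), stringsAsFactors = FALSE)

  new("ComparisonResult",
      branch = if (parametric) "parametric" else "nonparametric",
      omnibusTest = omnibus$name, omnibusStatistic = omnibus$stat,
      omnibusP = omnibus$p, shapiroP = shap, pairwise = pw,
      groupSummary = summ)
}
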