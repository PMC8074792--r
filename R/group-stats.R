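#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA over a named list of replicate-value groups; the
#' p value comes from the F distribution with (k - 1, N - k) degrees of
#' freedom. The degenerate all-identical case returns `F = 0`, `p = 1`
#' flagged as degenerate; zero within-group variance with differing means
#' returns `F = Inf`, `p = 0`.
#'
#' @param groups named list of >= 2 numeric vectors (replicate values).
#' @return list with `F`, `p`, `df` (numerator, denominator), `degenerate`.
#' @export
one_way_anova <- function(groups) {
  groups <- validate_groups(groups, min_groups = 2L, min_per_group = 1L)
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), lengths(groups)))
  df_num <- nlevels(group) - 1L
  df_den <- length(value) - nlevels(group)
  if (df_den < 1L) stopf("ANOVA needs at least one residual degree of freedom")
  fit <- stats::aov(value ~ group)
  tab <- suppressWarnings(stats::anova(fit))  # degeneracy is handled below
  ss_between <- tab[["Sum Sq"]][1]
  ss_within <- tab[["Sum Sq"]][2]
  if (ss_within <= 1e-14 * max(ss_between, 1)) {
    if (ss_between <= 1e-14) {
      warnf("all values identical: ANOVA is degenerate")
      return(list(F = 0, p = 1, df = c(df_num, df_den), degenerate = TRUE))
    }
    return(list(F = Inf, p = 0, df = c(df_num, df_den), degenerate = TRUE))
  }
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df = c(df_num, df_den), degenerate = FALSE)
}

#' Tukey's honestly significant difference test
#'
#' All-pairs comparison after one-way ANOVA using the studentized-range
#' distribution; unbalanced designs use the Tukey-Kramer form (this is what
#' [stats::TukeyHSD()] computes). A pair is flagged significant when its
#' adjusted p falls below `alpha`.
#'
#' @param groups named list of >= 2 numeric vectors, each with >= 2 values.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per pair: `pair`, `diff` (difference of
#'   means), `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- validate_groups(groups, min_groups = 2L, min_per_group = 2L)
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), lengths(groups)))
  fit <- stats::aov(value ~ group)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  if (mse <= 1e-14 * max(abs(value), 1)^2) {
    # zero residual variance: identical groups get p = 1, differing means p = 0
    combs <- utils::combn(names(groups), 2)
    means <- vapply(groups, mean, 0)
    diffs <- means[combs[2, ]] - means[combs[1, ]]
    p <- ifelse(abs(diffs) <= 1e-12 * max(abs(value), 1), 1, 0)
    return(data.frame(pair = paste(combs[2, ], combs[1, ], sep = "-"),
                      diff = unname(diffs), p_adj = p,
                      significant = p < alpha, stringsAsFactors = FALSE))
  }
  tk <- stats::TukeyHSD(fit)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ordinary least-squares regression with correlation report
#'
#' Simple linear regression `y ~ x`; `r_squared` is the squared Pearson
#' correlation and the p value tests slope != 0 against the t distribution
#' with n - 2 degrees of freedom. A constant response yields slope 0,
#' `r_squared` 0 and p = 1 (flagged degenerate).
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` must vary.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n`,
#'   `degenerate`.
#' @export
linear_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) < 3L) stopf("regression needs n >= 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("x and y must be finite")
  if (stats::var(x) == 0) stopf("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # silence the perfect-fit warning
  slope <- unname(stats::coef(fit)[2])
  degenerate <- stats::var(y) == 0
  p <- if (degenerate) 1 else unname(s$coefficients[2, 4])
  list(slope = if (degenerate) 0 else slope,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (degenerate) 0 else unname(s$r.squared),
       p = p, n = length(x), degenerate = degenerate)
}

validate_groups <- function(groups, min_groups, min_per_group) {
  if (!is.list(groups) || length(groups) < min_groups)
    stopf("need a list of at least %d groups", min_groups)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stopf("groups must be named")
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes < min_per_group))
    stopf("every group needs >= %d values (got %s)", min_per_group,
          paste(sizes, collapse = ", "))
  if (any(!vapply(groups, function(g) all(is.finite(g)), TRUE)))
    stopf("group values must be finite")
  groups
}
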