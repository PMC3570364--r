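## Statistical layer: descriptives, group comparisons, univariate and
## multivariate ordinary least squares with log transforms, variance
## partitioning of the airflow-limitation outcome, and Bland-Altman
## agreement. No multiple-testing correction is applied (two-sided
## p < 0.05 is the significance convention); missing values are dropped
## listwise per analysis. Logs are natural logs.

#' Cohort descriptives
#'
#' Mean +/- SD for near-normal columns, median (25th-75th percentile,
#' quantile type 7) for columns flagged as skewed, percentage for
#' logicals.
#'
#' @param table Data.frame of subjects.
#' @param skewed Character vector of columns to summarize by median/IQR.
#' @return Data.frame with variable, type and summary statistics.
#' @export
describe_cohort <- function(table, skewed = character(0)) {
  if (nrow(table) == 0) stop_domain("empty cohort table")
  rows <- lapply(names(table), function(v) {
    x <- table[[v]]
    if (all(is.na(x))) {
      return(data.frame(variable = v, type = "all_missing", value1 = NA_real_,
                        value2 = NA_real_, value3 = NA_real_,
                        summary = NA_character_, stringsAsFactors = FALSE))
    }
    x <- x[!is.na(x)]
    if (is.logical(x)) {
      pct <- 100 * mean(x)
      data.frame(variable = v, type = "percent", value1 = pct,
                 value2 = NA_real_, value3 = NA_real_,
                 summary = sprintf("%.1f", pct), stringsAsFactors = FALSE)
    } else if (is.numeric(x) && v %in% skewed) {
      q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(variable = v, type = "median_iqr", value1 = q[2],
                 value2 = q[1], value3 = q[3],
                 summary = sprintf("%.1f (%.1f - %.1f)", q[2], q[1], q[3]),
                 stringsAsFactors = FALSE)
    } else if (is.numeric(x)) {
      data.frame(variable = v, type = "mean_sd", value1 = mean(x),
                 value2 = sd(x), value3 = NA_real_,
                 summary = sprintf("%.1f ± %.1f", mean(x), sd(x)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variable = v, type = "other", value1 = NA_real_,
                 value2 = NA_real_, value3 = NA_real_,
                 summary = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Two-group and paired comparisons
#'
#' Mann-Whitney U for non-normal continuous data (exact p for small
#' samples without ties, normal approximation with continuity correction
#' otherwise), Student's t for normal data, chi-square for dichotomous
#' data, Wilcoxon signed rank for paired data. All p-values two-sided.
#'
#' @param values Numeric (or logical, for chi-square) outcome vector.
#' @param group Logical or two-level factor; for the signed-rank test,
#'   `values` and `values2` are the paired measurements instead.
#' @param kind One of `"mann_whitney"`, `"t_test"`, `"chi_square"`,
#'   `"wilcoxon_signed_rank"`.
#' @param values2 Second paired sample (signed-rank only).
#' @return List with `statistic`, `p_value`, `kind`, `n`.
#' @export
compare_groups <- function(values, group = NULL,
                           kind = c("mann_whitney", "t_test", "chi_square",
                                    "wilcoxon_signed_rank"),
                           values2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "wilcoxon_signed_rank") {
    if (is.null(values2) || length(values) != length(values2)) {
      stop_domain("signed-rank test needs paired samples of equal length")
    }
    ok <- complete.cases(values, values2)
    if (sum(ok) < 3) stop_domain("need at least 3 pairs")
    wt <- wilcox.test(values[ok], values2[ok], paired = TRUE,
                      correct = TRUE)
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                kind = kind, n = sum(ok)))
  }
  group <- as.logical(group)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- group[ok]
  if (min(table(group)) < 3) stop_domain("need at least 3 per group")
  a <- values[group]; b <- values[!group]
  if (kind == "mann_whitney") {
    exact <- length(a) <= 20 && length(b) <= 20 &&
      !any(duplicated(values))
    wt <- wilcox.test(a, b, exact = exact, correct = TRUE)
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         kind = kind, n = length(values))
  } else if (kind == "t_test") {
    if (sd(a) == 0 && sd(b) == 0) stop_domain("zero variance in both groups")
    tt <- t.test(a, b)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         kind = kind, n = length(values))
  } else {
    tab <- table(factor(as.logical(values), levels = c(FALSE, TRUE)),
                 factor(group, levels = c(FALSE, TRUE)))
    ct <- suppressWarnings(chisq.test(tab))
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         kind = kind, n = length(values))
  }
}

apply_transforms <- function(df, transform_map) {
  for (v in names(transform_map)) {
    f <- transform_map[[v]]
    if (is.character(f)) f <- match.fun(f)
    df[[v]] <- f(df[[v]])
  }
  df
}

#' Univariate linear regression
#'
#' OLS of `y` on a single predictor, with optional transforms (e.g.
#' `list(awt35_mm = log)`) applied first.
#'
#' @param data Data.frame.
#' @param y,x Column names of outcome and predictor.
#' @param transform_map Named list of transforms applied to columns
#'   before fitting.
#' @return A `regression_result`: data.frame of terms (coefficient,
#'   standard error, p-value) plus `r_squared` and `n`.
#' @export
univariate_ols <- function(data, y, x, transform_map = list()) {
  multivariate_ols(data, y, x, transform_map)
}

#' Multivariate linear regression
#'
#' OLS of `y` on the named predictors after transforms. Errors on rank
#' deficiency, naming the collinear columns.
#'
#' @inheritParams univariate_ols
#' @param x Character vector of predictor columns.
#' @return A `regression_result` (see [univariate_ols()]).
#' @export
multivariate_ols <- function(data, y, x, transform_map = list()) {
  data <- apply_transforms(data, transform_map)
  keep <- complete.cases(data[, c(y, x), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  if (n <= length(x) + 1) stop_domain("not enough observations (n = ", n, ")")
  for (v in x) {
    if (is.logical(data[[v]])) data[[v]] <- as.numeric(data[[v]])
    if (is.numeric(data[[v]]) && sd(data[[v]]) == 0) {
      stop_domain("constant predictor: ", v)
    }
  }
  fml <- as.formula(paste(y, "~", paste(x, collapse = " + ")))
  fit <- lm(fml, data = data)
  if (any(is.na(coef(fit)))) {
    stop_domain("rank-deficient design; collinear terms: ",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- data.frame(term = rownames(co), coefficient = co[, 1],
                      std_error = co[, 2], p_value = co[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(outcome = y, terms = terms, r_squared = sm$r.squared, n = n,
         n_dropped = sum(!keep), fit = fit, log_base = "natural"),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: %s ~ %s  (n = %d, R^2 = %.3f)\n", x$outcome,
              paste(setdiff(x$terms$term, "(Intercept)"), collapse = " + "),
              x$n, x$r_squared))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Significance-gated term selection for the multivariate model
#'
#' Reproduces the entry rule: only predictors univariately associated
#' with the outcome at p < 0.05 enter the multivariate model.
#'
#' @inheritParams multivariate_ols
#' @param candidates Character vector of candidate predictors.
#' @param alpha Entry threshold.
#' @return Character vector of selected predictors.
#' @export
select_terms_univariate <- function(data, y, candidates, alpha = 0.05,
                                    transform_map = list()) {
  sel <- vapply(candidates, function(v) {
    fit <- univariate_ols(data, y, v, transform_map)
    fit$terms$p_value[fit$terms$term != "(Intercept)"][1] < alpha
  }, logical(1))
  candidates[sel]
}

#' Variance of the outcome explained per term
#'
#' Reports both decompositions: (a) sequential R-squared increments in
#' the stated term order (these sum exactly to the full-model R-squared)
#' and (b) squared semi-partial correlations from the full model. The
#' two coincide for orthogonal predictors.
#'
#' @inheritParams multivariate_ols
#' @param ordered_terms Predictors in entry order.
#' @return Data.frame with term, `sequential_r2` and `semipartial_r2`,
#'   plus attributes `r_squared` and `method`.
#' @export
variance_explained <- function(data, y, ordered_terms,
                               transform_map = list()) {
  data <- apply_transforms(data, transform_map)
  keep <- complete.cases(data[, c(y, ordered_terms), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  full <- multivariate_ols(data, y, ordered_terms)
  r2_full <- full$r_squared
  seq_r2 <- numeric(length(ordered_terms))
  prev <- 0
  for (i in seq_along(ordered_terms)) {
    fit <- multivariate_ols(data, y, ordered_terms[seq_len(i)])
    seq_r2[i] <- fit$r_squared - prev
    prev <- fit$r_squared
  }
  tv <- full$terms[match(ordered_terms, full$terms$term), ]
  tstat <- tv$coefficient / tv$std_error
  df_res <- full$n - length(ordered_terms) - 1
  semi <- tstat^2 * (1 - r2_full) / df_res
  out <- data.frame(term = ordered_terms, sequential_r2 = seq_r2,
                    semipartial_r2 = semi, stringsAsFactors = FALSE)
  attr(out, "r_squared") <- r2_full
  attr(out, "method") <- c(headline = "sequential",
                           alternative = "semipartial")
  out
}

#' Bland-Altman agreement between paired measurements
#'
#' @param a,b Paired measurements (e.g. low- and high-dose AWT).
#' @return List with `bias` (mean difference a - b), `loa_low`,
#'   `loa_high` (bias -/+ 1.96 SD of differences), `sd_diff`,
#'   `bias_ci_low`/`bias_ci_high` (95% CI of the bias), `p_value`
#'   (one-sample t on the differences) and `n_pairs`.
#' @export
bland_altman <- function(a, b) {
  ok <- complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop_domain("need at least 3 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  se <- s / sqrt(n)
  tq <- qt(0.975, n - 1)
  p <- if (s == 0) {
    if (bias == 0) 1 else 0
  } else {
    2 * pt(-abs(bias / se), n - 1)
  }
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, bias_ci_low = bias - tq * se,
       bias_ci_high = bias + tq * se, p_value = p, n_pairs = n)
}
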