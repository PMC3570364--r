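test_that("cohort descriptives follow the mean/median/percent conventions", {
  tab <- data.frame(const = rep(5, 100), v = 1:100,
                    flag = rep(c(TRUE, FALSE), c(59, 41)))
  d <- describe_cohort(tab, skewed = "v")
  cc <- d[d$variable == "const", ]
  expect_equal(cc$value1, 5)
  expect_equal(cc$value2, 0)
  ## quantile type 7 on 1..100
  vv <- d[d$variable == "v", ]
  expect_equal(vv$value1, 50.5)
  expect_equal(vv$value2, 25.75)
  expect_equal(vv$value3, 75.25)
  ff <- d[d$variable == "flag", ]
  expect_equal(ff$summary, "59.0")
  ## all-missing columns are flagged, not summarized
  tab$gone <- NA_real_
  d2 <- describe_cohort(tab)
  expect_equal(d2$type[d2$variable == "gone"], "all_missing")
})

test_that("Mann-Whitney p-values agree with exhaustive enumeration", {
  ## fully separated groups: minimal two-sided p for 3 vs 3 is 0.1
  a <- c(1, 2, 3); b <- c(101, 102, 103)
  cmp <- compare_groups(c(a, b), rep(c(TRUE, FALSE), each = 3),
                        "mann_whitney")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, mw_exact_oracle(a, b), tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 / choose(6, 3), tolerance = 1e-12)
  ## random small samples up to n = 7 per group
  set.seed(31)
  for (rep in 1:8) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- sample(1:1000, n1 + n2)  # distinct values: no ties
    g <- rep(c(TRUE, FALSE), c(n1, n2))
    cmp <- compare_groups(x, g, "mann_whitney")
    expect_equal(cmp$p_value, mw_exact_oracle(x[g], x[!g]),
                 tolerance = 1e-9)
  }
})

test_that("group comparisons handle null, paired and dichotomous data", {
  ## identical groups: p near 1
  x <- c(1, 5, 9, 2, 6, 10)
  cmp <- compare_groups(x, rep(c(TRUE, FALSE), 3), "t_test")
  expect_gt(cmp$p_value, 0.8)
  ## paired signed rank
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  cmp2 <- compare_groups(a, kind = "wilcoxon_signed_rank",
                         values2 = a + c(1.1, 1.3, 0.9, 1.2, 1.4, 1.05,
                                         0.95, -0.5))
  expect_lt(cmp2$p_value, 0.05)
  ## chi-square on booleans
  v <- rep(c(TRUE, FALSE, TRUE, TRUE), 25)
  g <- rep(c(TRUE, TRUE, FALSE, FALSE), 25)
  cmp3 <- compare_groups(v, g, "chi_square")
  expect_true(cmp3$p_value >= 0 && cmp3$p_value <= 1)
  ## degenerate inputs
  expect_error(compare_groups(rep(1, 6), rep(c(TRUE, FALSE), 3), "t_test"),
               "variance")
  expect_error(compare_groups(1:4, c(TRUE, TRUE, TRUE, FALSE)), "at least 3")
})

test_that("symptomatic subjects have thicker walls in simulated cohorts", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(default_params(seed = 1000 + s))
    cmp <- compare_groups(co$awt35_mm, co$dyspnea, "mann_whitney")
    md <- median(co$awt35_mm[co$dyspnea]) > median(co$awt35_mm[!co$dyspnea])
    cmp$p_value < 0.05 && md
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("OLS matches the noise-free line and the null", {
  d <- data.frame(x = 1:30, y = 2 * (1:30))
  fit <- suppressWarnings(univariate_ols(d, "y", "x"))
  expect_equal(fit$terms$coefficient[2], 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  set.seed(8)
  d2 <- data.frame(x = rnorm(200), y = rnorm(200))
  fit2 <- univariate_ols(d2, "y", "x")
  b <- fit2$terms[fit2$terms$term == "x", ]
  expect_lt(abs(b$coefficient), 2 * b$std_error)
  expect_error(univariate_ols(data.frame(x = rep(1, 20), y = rnorm(20)),
                              "y", "x"), "constant")
})

test_that("OLS agrees with normal-equations brute force", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(20:50, 1); k <- sample(2:4, 1)
    X <- matrix(rnorm(n * k), n)
    d <- as.data.frame(X)
    names(d) <- paste0("x", seq_len(k))
    d$y <- rnorm(n)
    fit <- multivariate_ols(d, "y", names(d)[seq_len(k)])
    Xd <- cbind(1, X)
    beta <- solve(t(Xd) %*% Xd, t(Xd) %*% d$y)
    expect_equal(fit$terms$coefficient, as.vector(beta), tolerance = 1e-8)
  }
})

test_that("collinear designs are rejected with the offending column", {
  d <- data.frame(x1 = 1:20, x2 = 2 * (1:20), y = rnorm(20))
  expect_error(multivariate_ols(d, "y", c("x1", "x2")), "x2")
})

test_that("orthogonal predictors give equal uni- and multivariate betas", {
  x1 <- rep(c(-1, 1), 50)
  x2 <- rep(c(-1, -1, 1, 1), 25)
  set.seed(5)
  d <- data.frame(x1 = x1, x2 = x2, y = 1.5 * x1 - 2 * x2 + rnorm(100))
  uni <- univariate_ols(d, "y", "x1")$terms$coefficient[2]
  multi <- multivariate_ols(d, "y", c("x1", "x2"))
  expect_equal(uni, multi$terms$coefficient[multi$terms$term == "x1"],
               tolerance = 1e-10)
})

test_that("confounding shifts the univariate beta by the omitted-variable term", {
  p <- default_params(n = 400, seed = 13)
  p$resid_sd <- 1e-9
  co <- simulate_cohort(p)
  uni <- univariate_ols(co, "fev1_pct_pred", "log_awt35")
  b_uni <- uni$terms$coefficient[2]
  ## analytic omitted-variable formula
  expected <- p$beta_logawt + p$beta_perc15 *
    stats::cov(co$perc15_hu, co$log_awt35) / stats::var(co$log_awt35)
  expect_equal(b_uni, expected, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(b_uni, p$beta_logawt, tolerance = 0.01)))
})

test_that("variance decompositions behave and sum to the model R-squared", {
  co <- cached("cohort", simulate_cohort(default_params(seed = 7)))
  ## single predictor: share equals r-squared under both methods
  v1 <- variance_explained(co, "fev1_pct_pred", "log_awt35")
  r2 <- univariate_ols(co, "fev1_pct_pred", "log_awt35")$r_squared
  expect_equal(v1$sequential_r2, r2, tolerance = 1e-12)
  expect_equal(v1$semipartial_r2, r2, tolerance = 1e-12)
  ## orthogonal predictors: the two decompositions coincide
  set.seed(6)
  d <- data.frame(x1 = rep(c(-1, 1), 50), x2 = rep(c(-1, -1, 1, 1), 25))
  d$y <- d$x1 + 0.5 * d$x2 + rnorm(100)
  vo <- variance_explained(d, "y", c("x1", "x2"))
  expect_equal(vo$sequential_r2, vo$semipartial_r2, tolerance = 1e-10)
  ## sequential shares always sum to the full R-squared, any order
  for (terms in list(c("log_awt35", "perc15_hu"),
                     c("perc15_hu", "log_awt35"))) {
    vv <- variance_explained(co, "fev1_pct_pred", terms)
    expect_equal(sum(vv$sequential_r2), attr(vv, "r_squared"),
                 tolerance = 1e-12)
    expect_true(all(vv$sequential_r2 >= -1e-12))
    ## semipartials are non-negative but need not sum below R^2 when
    ## predictors suppress each other (as log-AWT and Perc15 do here)
    expect_true(all(vv$semipartial_r2 >= -1e-12))
  }
})

test_that("Bland-Altman reports bias and limits of agreement", {
  ba <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)
  ba2 <- bland_altman(c(1, 2, 3, 4) + 0.1, c(1, 2, 3, 4))
  expect_equal(ba2$bias, 0.1)
  expect_equal(ba2$sd_diff, 0)
  set.seed(2)
  a <- rnorm(30); b <- a + rnorm(30, 0.2, 0.1)
  ba3 <- bland_altman(a, b)
  expect_equal(ba3$loa_high - ba3$loa_low, 2 * 1.96 * ba3$sd_diff)
  expect_true(ba3$loa_low <= ba3$bias && ba3$bias <= ba3$loa_high)
  expect_error(bland_altman(1:2, 2:3), "3 pairs")
})

test_that("the univariate significance gate selects the generating terms", {
  co <- cached("cohort", simulate_cohort(default_params(seed = 7)))
  set.seed(123)
  co$noise_var <- rnorm(nrow(co))
  sel <- select_terms_univariate(co, "fev1_pct_pred",
                                 c("log_awt35", "perc15_hu", "noise_var"))
  expect_true(all(c("log_awt35", "perc15_hu") %in% sel))
  expect_false("noise_var" %in% sel)
})
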