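test_that("Bonferroni family levels are literal base/m", {
  a3 <- bonferroni_alpha(3)
  expect_equal(a3$alpha, 0.05 / 3)
  expect_equal(a3$alpha_reported, 0.017)
  expect_equal(bonferroni_alpha(7)$alpha, 0.05 / 7)
  expect_equal(bonferroni_alpha(9)$alpha, 0.05 / 9)
})

test_that("group comparison gates on normality and respects the family level", {
  set.seed(123)
  co <- data.frame(group = rep(c("control", "PAH"), c(50, 50)),
                   gaussian = rnorm(100, 10, 2),
                   skewed = rlnorm(100, 2, 0.8))
  g <- group_compare(co, "gaussian", family_size = 3)
  expect_equal(g$test, "t")
  expect_equal(g$alpha_reported, 0.017)
  s <- group_compare(co, "skewed", family_size = 3)
  expect_equal(s$test, "mann_whitney")

  # planted 1 SD shift at n = 45/51 is detected essentially always
  set.seed(102)
  hits <- replicate(200, {
    d <- data.frame(group = rep(c("a", "b"), c(51, 45)),
                    x = c(rnorm(51, 0, 1), rnorm(45, 1, 1)))
    group_compare(d, "x")$p_value < 0.05
  })
  expect_gt(mean(hits), 0.99)
})

test_that("label-permuted group comparisons keep the nominal type-I rate", {
  set.seed(103)
  p <- replicate(400, {
    d <- data.frame(group = sample(rep(c("a", "b"), 50)), x = rnorm(100))
    group_compare(d, "x")$p_value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("Pearson correlation handles exact, orthogonal and planted cases", {
  x <- rnorm(30)
  expect_equal(correlate(data.frame(x = x, y = 2 * x), "x", "y")$r, 1)
  y <- rnorm(30)
  y_perp <- residuals(lm(y ~ x))
  expect_equal(correlate(data.frame(x = x, y = y_perp), "x", "y")$r, 0,
               tolerance = 1e-12)
  expect_error(correlate(data.frame(x = x, y = rep(1, 30)), "x", "y"),
               "zero variance")
  set.seed(104)
  ok <- replicate(100, {
    z <- matrix(rnorm(96 * 2), ncol = 2) %*% chol(matrix(c(1, -0.6, -0.6, 1), 2))
    abs(correlate(data.frame(x = z[, 1], y = z[, 2]), "x", "y")$r + 0.6) < 0.15
  })
  expect_gt(mean(ok), 0.9)
})

test_that("stepwise regression recovers planted signals and screens decoys", {
  set.seed(105)
  n <- 96
  X <- matrix(rnorm(n * 7), n, 7)
  colnames(X) <- paste0("x", 1:7)
  y <- 0.6 * X[, 1] + 0.2 * X[, 2] + rnorm(n, 0, 0.25)
  df <- data.frame(y = y, X)
  rep <- stepwise_model(df, "y", paste0("x", 1:7))
  expect_true(all(c("x1", "x2") %in% rep$selected))
  expect_true(all(rep$multivariable$ci_low <= rep$multivariable$estimate &
                  rep$multivariable$estimate <= rep$multivariable$ci_high))
  # every selected variable passed the univariate screen
  surv <- rep$univariate$variable[rep$univariate$p_value < 0.05]
  expect_true(all(rep$selected %in% surv))

  # single candidate equal to the outcome: R^2 = 1, coefficient 1
  ident <- suppressWarnings(stepwise_model(data.frame(y = y, x1 = y), "y", "x1"))
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$multivariable$estimate, 1)

  # no survivors: multivariable stage is empty but the report stands
  noise <- data.frame(y = rnorm(40), a = rnorm(40) * 0 + 1e-8 * rnorm(40))
  r0 <- stepwise_model(noise, "y", "a")
  expect_true(is.null(r0$multivariable) || nrow(r0$multivariable) == 0 ||
              length(r0$selected) %in% 0:1)

  # ln outcome reproduces a log-linear relationship
  z <- exp(0.5 * X[, 1] + rnorm(n, 0, 0.1))
  rln <- stepwise_model(data.frame(y = z, X), "y", paste0("x", 1:7),
                        ln_outcome = TRUE)
  expect_true("x1" %in% rln$selected)
  expect_equal(rln$multivariable$estimate[rln$multivariable$variable == "x1"],
               0.5, tolerance = 0.1)
  expect_error(stepwise_model(data.frame(y = c(-1, 2, 3), x = 1:3), "y", "x",
                              ln_outcome = TRUE), "positive")
})

test_that("pure-noise candidates enter at about the screen rate", {
  set.seed(106)
  sel <- replicate(300, {
    d <- data.frame(y = rnorm(50), x1 = rnorm(50))
    length(stepwise_model(d, "y", "x1")$selected)
  })
  expect_lt(abs(mean(sel) - 0.05), 0.035)
})

test_that("the empirical AUC equals the scaled Mann-Whitney U statistic", {
  set.seed(107)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    x <- sample(1:6, n1 + n0, replace = TRUE)  # heavy ties
    y <- rep(c(TRUE, FALSE), c(n1, n0))
    d <- data.frame(x = x, y = y)
    r <- roc_youden(d, "x", "y", direction = ">")
    w <- suppressWarnings(wilcox.test(x[y], x[!y])$statistic)
    expect_equal(r$auc, unname(w) / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("Youden thresholds match brute-force enumeration on 6-observation tables", {
  set.seed(108)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  combos <- combos[rowSums(combos) %in% 1:5, ]
  for (i in seq_len(nrow(combos))) {
    y <- unlist(combos[i, ])
    for (rep_ in 1:3) {
      x <- sample(1:4, 6, replace = TRUE)
      d <- data.frame(x = x, y = y)
      r <- roc_youden(d, "x", "y", direction = ">")
      bf <- brute_force_youden(x, y)
      expect_equal(r$youden, bf$j, tolerance = 1e-12)
      expect_equal(r$threshold, bf$threshold)
      expect_equal(r$sensitivity, bf$sens)
      expect_equal(r$specificity, bf$spec)
    }
  }
})

test_that("ROC extremes and direction handling behave", {
  d <- data.frame(x = c(1, 2, 3, 10, 11, 12),
                  y = rep(c(FALSE, TRUE), each = 3))
  r <- roc_youden(d, "x", "y")
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  flip <- roc_youden(data.frame(x = -d$x, y = d$y), "x", "y", direction = "auto")
  expect_equal(flip$auc, 1)
  expect_equal(flip$direction, "<")
  expect_error(roc_youden(data.frame(x = 1:3, y = rep(TRUE, 3)), "x", "y"),
               "both classes")
})

test_that("the DeLong test agrees with an established implementation", {
  set.seed(109)
  n <- 40
  y <- rep(c(TRUE, FALSE), each = n / 2)
  a <- rnorm(n) + y; b <- rnorm(n) + 0.5 * y
  d <- data.frame(a = a, b = b, y = y)
  ours <- delong_compare(d, "a", "b", "y")
  ref <- pROC::roc.test(pROC::roc(y, a, direction = "<", quiet = TRUE),
                        pROC::roc(y, b, direction = "<", quiet = TRUE),
                        method = "delong")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(ours$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)

  same <- delong_compare(data.frame(a = a, b = a, y = y), "a", "b", "y")
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)

  # identical predictors reduce the covariance to the single-AUC variance
  v <- delong_auc_variance(d, "a", "y")
  expect_equal(v$auc, ours$auc_a)
  expect_error(delong_compare(data.frame(a = rep(1, n), b = rep(1, n), y = y),
                              "a", "b", "y"), "degenerate")
})

test_that("nested logistic increments behave like a likelihood-ratio test", {
  set.seed(110)
  n <- 96
  y <- rep(c(0, 1), each = n / 2)
  base <- rnorm(n) + y
  d <- data.frame(y = y, base = base, dup = base, info = rnorm(n) + 2 * y,
                  noise = rnorm(n))
  dup <- nested_logistic(d, "y", "base", "dup")
  expect_lt(abs(dup$delta_chi2), 1e-6)
  info <- nested_logistic(d, "y", "base", "info")
  expect_gt(info$delta_chi2, 10)
  expect_lt(info$p_value, 0.01)
  expect_equal(info$chi2_full - info$chi2_base, info$delta_chi2,
               tolerance = 1e-9)
  expect_equal(info$df, 1)

  # invariance under affine rescaling of predictors
  d2 <- transform(d, base = 100 * base - 7, info = 0.01 * info + 3)
  info2 <- nested_logistic(d2, "y", "base", "info")
  expect_equal(info2$delta_chi2, info$delta_chi2, tolerance = 1e-6)

  sep <- data.frame(y = y, base = y * 10 - 5, x = rnorm(n))
  expect_true(nested_logistic(sep, "y", "base", "x")$separation)
})

test_that("Bland-Altman agreement follows its closed forms", {
  a <- c(10, 12, 14, 16)
  ident <- bland_altman(a, a)
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_lower, ident$loa_upper), c(0, 0))
  expect_equal(ident$cov_pct, 0)

  off <- bland_altman(a + 2, a)
  expect_equal(off$bias, 2)
  expect_equal(off$sd_diff, 0)

  set.seed(111)
  sigma <- 0.7
  x <- rnorm(5000, 50, 5)
  ba <- bland_altman(x + rnorm(5000, 0, sigma), x + rnorm(5000, 0, sigma))
  expect_equal(ba$sd_diff, sigma * sqrt(2), tolerance = 0.05)
  expect_error(bland_altman(1, 1), ">= 2")
})
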