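# Cohort statistics: two-group comparisons with Bonferroni families,
# Pearson correlation, univariate screening + stepwise multivariable linear
# regression, empirical ROC with Youden thresholds, DeLong comparison of
# correlated AUCs, nested logistic likelihood-ratio tests and Bland-Altman
# reproducibility.

#' Bonferroni-corrected significance level for a comparison family
#'
#' Computed as the literal `base / family_size`; the displayed value is
#' rounded to 3 decimals.
#'
#' @param family_size Number of comparisons in the family.
#' @param base Family-wise level (default 0.05).
#' @return List with exact `alpha` and `alpha_reported` (3 decimals).
#' @export
bonferroni_alpha <- function(family_size, base = 0.05) {
  if (family_size < 1) stop("family_size must be >= 1")
  a <- base / family_size
  list(alpha = a, alpha_reported = round(a, 3))
}

#' Two-group comparison with a normality gate
#'
#' Shapiro-Wilk at 0.05 per group decides the test: two-sample t test when
#' both groups look normal, Mann-Whitney U otherwise (groups of fewer than 3
#' observations take the nonparametric path). The Bonferroni level for the
#' comparison's family is reported alongside the raw P value.
#'
#' @param cohort A [read_cohort()] table (or data frame with a `group`
#'   column).
#' @param variable Name of the numeric column to compare.
#' @param family_size Size of the Bonferroni family this comparison belongs
#'   to (default 1 = no correction).
#' @param group_col Name of the two-level grouping column.
#' @return List with `test`, `statistic`, `p_value`, `alpha_bonferroni`,
#'   `alpha_reported` and `significant` (raw P below the family level).
#' @export
group_compare <- function(cohort, variable, family_size = 1,
                          group_col = "group") {
  g <- factor(cohort[[group_col]])
  if (nlevels(g) != 2L) stop("grouping column must have exactly two levels")
  x <- cohort[[variable]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  ns <- table(g)
  if (any(ns < 2L)) stop("need >= 2 observations per group")
  normal <- vapply(levels(g), function(lv) {
    xs <- x[g == lv]
    if (length(xs) < 3L || stats::sd(xs) == 0) return(FALSE)
    stats::shapiro.test(xs)$p.value >= 0.05
  }, TRUE)
  if (all(normal)) {
    if (any(tapply(x, g, stats::sd) == 0))
      stop("degenerate variance for the t-test path")
    ht <- stats::t.test(x ~ g)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x ~ g))
    test <- "mann_whitney"
  }
  alpha <- bonferroni_alpha(family_size)
  list(variable = variable, test = test,
       statistic = unname(ht$statistic), p_value = ht$p.value,
       alpha_bonferroni = alpha$alpha, alpha_reported = alpha$alpha_reported,
       significant = ht$p.value < alpha$alpha)
}

#' Pearson correlation between two cohort variables
#'
#' @param cohort Data frame.
#' @param x,y Column names.
#' @return List with `r`, `p_value` and `n` (complete pairs).
#' @export
correlate <- function(cohort, x, y) {
  xv <- cohort[[x]]; yv <- cohort[[y]]
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3L) stop("need >= 3 complete pairs")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) stop("zero variance")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(xv))
}

# p-value of the last coefficient of a linear model
.last_coef_p <- function(fit) {
  cf <- stats::summary.lm(fit)$coefficients
  cf[nrow(cf), 4]
}

#' Univariate screen plus stepwise multivariable linear regression
#'
#' Stage 1 fits one univariate linear model per candidate and keeps those
#' with P < `screen_p`. Stage 2 runs forward selection with backward
#' elimination among the survivors (entry when the partial P is below
#' `entry_p`, removal when an included variable's partial P rises above
#' `removal_p`). Outcomes flagged `ln_outcome` are natural-log transformed
#' before fitting, as is conventional for right-skewed outcomes.
#'
#' @param cohort Data frame.
#' @param outcome Name of the outcome column.
#' @param candidates Character vector of candidate predictor columns.
#' @param ln_outcome Model `log(outcome)` instead of the raw outcome.
#' @param screen_p,entry_p,removal_p Selection thresholds (defaults 0.05,
#'   0.05, 0.10).
#' @return An object of class `regression_report`: `univariate` and
#'   `multivariable` coefficient tables (estimate, 95% CI, P), `excluded`
#'   variable names, `selected`, and the final model `r_squared`.
#' @export
stepwise_model <- function(cohort, outcome, candidates, ln_outcome = FALSE,
                           screen_p = 0.05, entry_p = 0.05, removal_p = 0.10) {
  df <- as.data.frame(cohort)[, c(outcome, candidates)]
  df <- df[stats::complete.cases(df), ]
  y <- df[[outcome]]
  if (ln_outcome) {
    if (any(y <= 0)) stop("ln outcome requires positive values")
    y <- log(y)
  }
  df$.y <- y
  uni <- do.call(rbind, lapply(candidates, function(v) {
    fit <- stats::lm(stats::reformulate(v, ".y"), df)
    cf <- stats::summary.lm(fit)$coefficients
    ci <- stats::confint(fit)[2, ]
    data.frame(variable = v, estimate = cf[2, 1],
               ci_low = ci[1], ci_high = ci[2], p_value = cf[2, 4])
  }))
  rownames(uni) <- NULL
  survivors <- uni$variable[uni$p_value < screen_p]
  included <- character(0)
  if (length(survivors) > 0) {
    repeat {
      changed <- FALSE
      pool <- setdiff(survivors, included)
      if (length(pool) > 0) {
        entry <- vapply(pool, function(v) {
          fit <- stats::lm(stats::reformulate(c(included, v), ".y"), df)
          cf <- stats::coef(fit)
          if (anyNA(cf)) {
            warning("dropping collinear candidate: ", v)
            return(Inf)
          }
          .last_coef_p(fit)
        }, 1.0)
        if (min(entry) < entry_p) {
          included <- c(included, pool[which.min(entry)])
          changed <- TRUE
        }
      }
      if (length(included) > 1) {
        fit <- stats::lm(stats::reformulate(included, ".y"), df)
        pv <- stats::summary.lm(fit)$coefficients[-1, 4]
        if (max(pv) > removal_p) {
          included <- setdiff(included, included[which.max(pv)])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  multi <- NULL
  r2 <- NA_real_
  if (length(included) > 0) {
    fit <- stats::lm(stats::reformulate(included, ".y"), df)
    sm <- stats::summary.lm(fit)
    ci <- stats::confint(fit)
    multi <- data.frame(variable = included,
                        estimate = sm$coefficients[included, 1],
                        ci_low = ci[included, 1],
                        ci_high = ci[included, 2],
                        p_value = sm$coefficients[included, 4])
    rownames(multi) <- NULL
    r2 <- sm$r.squared
  }
  structure(list(outcome = outcome, ln_outcome = ln_outcome,
                 univariate = uni, multivariable = multi,
                 selected = included,
                 excluded = setdiff(candidates, included),
                 r_squared = r2),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("stepwise regression for %s%s\n",
              if (x$ln_outcome) "Ln " else "", x$outcome))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("R-squared (multivariable): %s\n", format(x$r_squared)))
  invisible(x)
}

# Empirical AUC with midrank tie handling; equals the Mann-Whitney U
# statistic scaled by n_pos * n_neg.
.auc_rank <- function(values, positive) {
  r <- rank(values)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC analysis with Youden-optimal threshold
#'
#' Builds the empirical ROC over all observed cut-points (classification
#' rule: positive when the predictor is at or beyond the threshold in the
#' stated direction), takes the AUC by the rank (Mann-Whitney) formula, and
#' selects the threshold maximizing Youden's index (sensitivity +
#' specificity - 1); ties are broken toward higher specificity.
#'
#' @param cohort Data frame.
#' @param predictor Name of the predictor column.
#' @param label Name of the class column (logical, 0/1, or two-level).
#' @param direction `">"` if larger predictor values indicate the positive
#'   class, `"<"` for smaller, `"auto"` to pick the direction with
#'   AUC >= 0.5.
#' @return An object of class `roc_report` with `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `youden`, `direction` and the full
#'   `curve` data frame.
#' @export
roc_youden <- function(cohort, predictor, label, direction = ">") {
  x <- cohort[[predictor]]
  y <- .as_binary(cohort[[label]])
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!any(y) || all(y)) stop("both classes must be present")
  if (direction == "auto")
    direction <- if (.auc_rank(x, y) >= 0.5) ">" else "<"
  s <- if (direction == ">") x else -x
  auc <- .auc_rank(s, y)
  cuts <- sort(unique(s))
  sens <- vapply(cuts, function(c_) mean(s[y] >= c_), 1.0)
  spec <- vapply(cuts, function(c_) mean(s[!y] < c_), 1.0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]  # ties -> higher specificity
  structure(list(predictor = predictor, auc = auc,
                 threshold = if (direction == ">") cuts[best] else -cuts[best],
                 sensitivity = sens[best], specificity = spec[best],
                 youden = j[best], direction = direction,
                 curve = data.frame(
                   threshold = if (direction == ">") cuts else -cuts,
                   sensitivity = sens, specificity = spec, youden = j)),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("ROC for %s (direction %s): AUC %.3f\n",
              x$predictor, x$direction, x$auc))
  cat(sprintf("  Youden threshold %.4g -> sens %.3f, spec %.3f (J = %.3f)\n",
              x$threshold, x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

.as_binary <- function(y) {
  if (is.logical(y)) return(y)
  if (is.numeric(y)) {
    if (!all(y %in% 0:1 | is.na(y))) stop("numeric labels must be 0/1")
    return(y == 1)
  }
  f <- factor(y)
  if (nlevels(f) != 2L) stop("label must have exactly two levels")
  f == levels(f)[2]
}

# DeLong structural components for one predictor: list(auc, v10, v01)
.delong_components <- function(x, positive) {
  xp <- x[positive]; xn <- x[!positive]
  m <- length(xp); n <- length(xn)
  psi <- outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two predictors measured on the same subjects using
#' the structural-components covariance estimator, with a two-sided normal
#' test on the AUC difference. Identical predictors give a zero difference
#' and P = 1.
#'
#' @param cohort Data frame.
#' @param predictor_a,predictor_b Predictor column names.
#' @param label Class column name (see [roc_youden()]).
#' @param direction Length-2 directions for the two predictors (`">"` or
#'   `"<"`, recycled); `"auto"` picks per predictor.
#' @return List with `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_compare <- function(cohort, predictor_a, predictor_b, label,
                           direction = ">") {
  xa <- cohort[[predictor_a]]; xb <- cohort[[predictor_b]]
  y <- .as_binary(cohort[[label]])
  keep <- !is.na(xa) & !is.na(xb) & !is.na(y)
  xa <- xa[keep]; xb <- xb[keep]; y <- y[keep]
  if (!any(y) || all(y)) stop("both classes must be present")
  direction <- rep(direction, length.out = 2L)
  orient <- function(x, d) {
    if (d == "auto") d <- if (.auc_rank(x, y) >= 0.5) ">" else "<"
    if (d == ">") x else -x
  }
  ca <- .delong_components(orient(xa, direction[1]), y)
  cb <- .delong_components(orient(xb, direction[2]), y)
  m <- sum(y); n <- sum(!y)
  if (stats::var(c(ca$v10, ca$v01)) == 0 && stats::var(c(cb$v10, cb$v01)) == 0)
    stop("degenerate AUC variance (constant predictor)")
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
               (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- ca$auc - cb$auc
  if (var_delta <= .Machine$double.eps) {
    z <- 0; p <- 1
    if (abs(delta) > 1e-12) stop("degenerate AUC variance with nonzero difference")
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = z, p_value = p)
}

#' Variance of a single AUC by the DeLong estimator
#'
#' @param cohort Data frame.
#' @param predictor,label Column names.
#' @param direction As in [roc_youden()].
#' @return List with `auc` and `variance`.
#' @export
delong_auc_variance <- function(cohort, predictor, label, direction = ">") {
  x <- cohort[[predictor]]
  y <- .as_binary(cohort[[label]])
  if (direction == "auto")
    direction <- if (.auc_rank(x, y) >= 0.5) ">" else "<"
  cc <- .delong_components(if (direction == ">") x else -x, y)
  list(auc = cc$auc,
       variance = stats::var(cc$v10) / sum(y) + stats::var(cc$v01) / sum(!y))
}

#' Nested binary logistic regression: incremental chi-square
#'
#' Fits the base and the augmented logistic model by maximum likelihood;
#' each model's chi-square is twice its log-likelihood gain over the
#' intercept-only model, and the increment `chi2_full - chi2_base` is tested
#' against a chi-square distribution with one degree of freedom per added
#' column.
#'
#' @param cohort Data frame.
#' @param label Binary outcome column.
#' @param base_vars Character vector of base-model predictors.
#' @param added_var Predictor whose incremental value is tested.
#' @return List with `chi2_base`, `chi2_full`, `delta_chi2`, `df`,
#'   `p_value` and a `separation` flag (fitted probabilities at the 0/1
#'   boundary; estimates unreliable).
#' @export
nested_logistic <- function(cohort, label, base_vars, added_var) {
  df <- as.data.frame(cohort)
  df$.y <- as.integer(.as_binary(df[[label]]))
  keep <- stats::complete.cases(df[, c(".y", base_vars, added_var)])
  df <- df[keep, ]
  sep <- FALSE
  fit_glm <- function(vars) {
    fit <- withCallingHandlers(
      stats::glm(stats::reformulate(vars, ".y"), stats::binomial(), df),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (!fit$converged ||
        any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8))
      sep <<- TRUE
    fit
  }
  base <- fit_glm(base_vars)
  full <- fit_glm(c(base_vars, added_var))
  chi2_base <- base$null.deviance - base$deviance
  chi2_full <- full$null.deviance - full$deviance
  delta <- base$deviance - full$deviance
  dfree <- base$df.residual - full$df.residual
  list(chi2_base = chi2_base, chi2_full = chi2_full,
       delta_chi2 = delta, df = dfree,
       p_value = stats::pchisq(delta, dfree, lower.tail = FALSE),
       separation = sep)
}

#' Bland-Altman agreement and coefficient of variation
#'
#' Bias is the mean paired difference, the limits of agreement are
#' `bias +/- 1.96 * SD(differences)`, and the coefficient of variation is
#' `100 * SD(differences) / grand mean` of all measurements.
#'
#' @param a,b Paired measurement vectors (e.g., two observers).
#' @return List with `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `cov_pct`
#'   and `n`.
#' @export
bland_altman <- function(a, b) {
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("need >= 2 pairs")
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  list(bias = bias, sd_diff = sd_d,
       loa_lower = bias - 1.96 * sd_d, loa_upper = bias + 1.96 * sd_d,
       cov_pct = 100 * sd_d / mean(c(a, b)), n = length(a))
}
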