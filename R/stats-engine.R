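#' Effect-size r from a t statistic
#'
#' Converts a t statistic with its residual degrees of freedom to the
#' point-biserial-style effect size r = t / sqrt(t^2 + df). The sign of r
#' follows the sign of t.
#'
#' @param t t statistic.
#' @param df Residual degrees of freedom (n - p - 1 for a regression with p
#'   predictors).
#' @return Effect-size r in [-1, 1].
#' @export
effect_r_from_t <- function(t, df) {
  stopifnot(df > 0)
  t / sqrt(t^2 + df)
}

#' Standardized ordinary least squares regression
#'
#' Fits an OLS regression after (optionally) Z-scoring the response and all
#' predictors, so coefficients are standardized betas. Each predictor's
#' effect-size r is derived from its t statistic and the residual df. All
#' p-values are two-sided.
#'
#' @param response Numeric response vector.
#' @param predictors Data frame or matrix of numeric predictors (named
#'   columns).
#' @param zscore Standardize response and predictors first (default TRUE).
#' @param cond_tol Condition-number threshold above which the predictor
#'   matrix is declared collinear (default 1e8).
#' @return An object of class \code{std_ols}: list with \code{coef} (data
#'   frame term/beta/se/t/df/p/effect_r), \code{n}, \code{r_squared},
#'   \code{df_resid}, \code{two_sided = TRUE}, and the underlying \code{lm}
#'   fit.
#' @export
fit_ols_standardized <- function(response, predictors, zscore = TRUE,
                                 cond_tol = 1e8) {
  y <- as.numeric(response)
  X <- as.data.frame(predictors)
  stopifnot(all(vapply(X, is.numeric, logical(1))))
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  if (zscore) {
    y <- as.numeric(scale(y))
    X[] <- lapply(X, function(col) as.numeric(scale(col)))
  }
  kappa_x <- kappa(cbind(1, as.matrix(X)), exact = TRUE)
  if (!is.finite(kappa_x) || kappa_x > cond_tol) {
    cors <- stats::cor(as.matrix(X))
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop("collinear predictors (condition number ", format(kappa_x), "): ",
         paste(colnames(X)[worst], collapse = ", "))
  }
  dat <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  ct <- sm$coefficients
  df_resid <- fit$df.residual
  terms <- rownames(ct)[-1]
  coef_tab <- data.frame(
    term = terms,
    beta = ct[-1, 1], se = ct[-1, 2], t = ct[-1, 3],
    df = df_resid, p = ct[-1, 4],
    effect_r = effect_r_from_t(ct[-1, 3], df_resid),
    row.names = NULL, stringsAsFactors = FALSE
  )
  stopifnot(all(sign(coef_tab$effect_r) == sign(coef_tab$t) |
                  coef_tab$t == 0))
  structure(
    list(coef = coef_tab, n = n, r_squared = sm$r.squared,
         df_resid = df_resid, two_sided = TRUE, fit = fit),
    class = "std_ols"
  )
}

#' @export
print.std_ols <- function(x, digits = 3, ...) {
  cat(sprintf("Standardized OLS: n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  tab <- x$coef
  tab[-1] <- lapply(tab[-1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Linear mixed model with Satterthwaite degrees of freedom
#'
#' Fits a linear mixed-effects model by REML and reports fixed-effect tests
#' with Satterthwaite denominator degrees of freedom (generally fractional).
#' Convergence problems and singular fits are surfaced as flags on the
#' result, never hidden.
#'
#' @param formula An lme4-style formula with random-effect terms, e.g.
#'   \code{y ~ x + age + (1 + x | participant)}.
#' @param data Data frame.
#' @param zscore Optional character vector of numeric columns to Z-score
#'   before fitting.
#' @return An object of class \code{lmm_result}: list with \code{fixed}
#'   (data frame term/estimate/se/t/df/p), \code{ranef_var} (random-effect
#'   variances), \code{converged}, \code{singular}, \code{two_sided = TRUE},
#'   and the underlying fit.
#' @export
fit_lmm <- function(formula, data, zscore = NULL) {
  data <- as.data.frame(data)
  if (!is.null(zscore)) {
    for (v in zscore) data[[v]] <- as.numeric(scale(data[[v]]))
  }
  fit <- suppressMessages(
    lmerTest::lmer(formula, data = data, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 lme4::.makeCC("ignore", tol = 1e-4)))
  )
  ct <- stats::coef(summary(fit))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  vc <- as.data.frame(lme4::VarCorr(fit))
  fixed <- data.frame(
    term = rownames(ct),
    estimate = ct[, "Estimate"], se = ct[, "Std. Error"],
    t = ct[, "t value"], df = ct[, "df"], p = ct[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(fixed = fixed,
         ranef_var = vc[, c("grp", "var1", "var2", "vcov")],
         converged = conv,
         singular = lme4::isSingular(fit, tol = 1e-4),
         two_sided = TRUE, fit = fit),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, digits = 3, ...) {
  cat("Linear mixed model (REML, Satterthwaite df)\n")
  tab <- x$fixed
  tab[-1] <- lapply(tab[-1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  if (x$singular) cat("note: singular fit\n")
  if (!x$converged) cat("warning: convergence problems reported\n")
  invisible(x)
}

#' Welch two-sample t test with Cohen's d
#'
#' Welch's unequal-variance t test (fractional Satterthwaite df), two-sided,
#' with the pooled-s.d. form of Cohen's d. The sign convention follows
#' \code{t.test(a, b)}: positive t means group a exceeds group b.
#'
#' @param a,b Numeric vectors for the two independent groups.
#' @return An object of class \code{ttest_result}.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  ht <- stats::t.test(a, b, var.equal = FALSE)
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
         sd_a = stats::sd(a), sd_b = stats::sd(b),
         cohen_d = (mean(a) - mean(b)) / sp,
         type = "welch", two_sided = TRUE),
    class = "ttest_result"
  )
}

#' Paired t test with Cohen's d
#'
#' Two-sided paired t test; Cohen's d is the mean difference divided by the
#' s.d. of the differences.
#'
#' @param pre,post Paired numeric vectors (same length, same order).
#' @return An object of class \code{ttest_result}. Positive t means
#'   \code{pre} exceeds \code{post}.
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  ok <- stats::complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  d <- pre - post
  ht <- stats::t.test(d)
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_a = mean(pre), mean_b = mean(post),
         sd_a = stats::sd(pre), sd_b = stats::sd(post),
         cohen_d = mean(d) / stats::sd(d),
         type = "paired", two_sided = TRUE),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s t test: t(%.2f) = %.3f, p = %.3g, d = %.3f\n",
              if (x$type == "welch") "Welch" else "Paired",
              x$df, x$t, x$p, x$cohen_d))
  cat(sprintf("  means: %.4f vs %.4f (sd %.4f, %.4f)\n",
              x$mean_a, x$mean_b, x$sd_a, x$sd_b))
  invisible(x)
}

#' Estimated marginal means per factor level
#'
#' Adjusted group means at the covariate means, from a linear model with one
#' factor and optional numeric covariates. With no covariates (or perfectly
#' balanced ones) these equal the raw group means.
#'
#' @param response Numeric response.
#' @param factor_var Factor (or coercible) giving group membership.
#' @param covariates Optional data frame of numeric covariates.
#' @return Data frame with columns \code{level}, \code{emmean}, \code{se}.
#' @export
estimated_marginal_means <- function(response, factor_var, covariates = NULL) {
  dat <- data.frame(.y = as.numeric(response),
                    .g = factor(factor_var))
  rhs <- ".g"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    rhs <- paste(c(".g", names(covariates)), collapse = " + ")
  }
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  em <- as.data.frame(emmeans::emmeans(fit, ".g"))
  data.frame(level = as.character(em$.g), emmean = em$emmean, se = em$SE,
             stringsAsFactors = FALSE)
}
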