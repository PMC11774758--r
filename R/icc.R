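#' Intraclass correlation coefficient with F-based confidence interval
#'
#' Computes the ICC of a subjects x measurements matrix under one of three
#' standard variance-components forms:
#' \describe{
#'   \item{\code{oneway}}{ICC(1,1): one-way random effects, single
#'     measurement.}
#'   \item{\code{twoway_consistency_single}}{ICC(3,1): two-way mixed effects,
#'     consistency, single measurement. The default for day-to-day stability
#'     and method agreement, where the "raters" (days, scoring methods) are
#'     fixed.}
#'   \item{\code{twoway_consistency_average}}{ICC(3,k): as above but for the
#'     reliability of the k-measurement average.}
#' }
#' Confidence intervals and the p-value (upper tail of the F statistic for
#' the null of zero ICC) follow the classical mean-squares construction.
#' Rows with missing cells are dropped listwise with a message.
#'
#' @param x Numeric matrix or data frame, subjects in rows, repeated
#'   measurements (days, methods, raters) in columns.
#' @param form ICC form; see above.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class \code{icc_result}: list with \code{icc},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{form}, \code{n_subjects},
#'   \code{n_raters}, and the mean squares used.
#' @export
icc <- function(x, form = c("twoway_consistency_single", "oneway",
                            "twoway_consistency_average"),
                conf_level = 0.95) {
  form <- match.arg(form)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    message("dropping ", sum(!complete), " subject(s) with missing cells")
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 measurements")

  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols      # two-way residual
  ss_within <- ss_total - ss_rows             # one-way within

  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  msw <- ss_within / (n * (k - 1))
  if (ss_total <= 0) stop("zero total variance; ICC undefined")

  alpha <- 1 - conf_level
  if (form == "oneway") {
    est <- (msr - msw) / (msr + (k - 1) * msw)
    fstat <- msr / msw
    df1 <- n - 1; df2 <- n * (k - 1)
    fl <- fstat / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fstat * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    fstat <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- fstat / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fstat * stats::qf(1 - alpha / 2, df2, df1)
    if (form == "twoway_consistency_single") {
      est <- (msr - mse) / (msr + (k - 1) * mse)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else {
      est <- (msr - mse) / msr
      ci <- c(1 - 1 / fl, 1 - 1 / fu)
    }
  }
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)

  structure(
    list(icc = est, ci_low = ci[1], ci_high = ci[2], p = p, form = form,
         n_subjects = n, n_raters = k, conf_level = conf_level,
         msr = msr, msc = msc, mse = mse, msw = msw, f = fstat,
         df1 = df1, df2 = df2),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s) = %.3f, %d%% CI [%.3f, %.3f], F(%d, %d) = %.2f, p = %.3g\n",
              x$form, x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$df1, x$df2, x$f, x$p))
  cat(sprintf("  %d subjects x %d measurements\n", x$n_subjects, x$n_raters))
  invisible(x)
}
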