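#' Repeated-measures ANCOVA with participant-level covariates
#'
#' Mixed ANOVA for designs with one within-subject factor (e.g. the three
#' psychopathology dimensions) and one or more continuous participant-level
#' covariates (e.g. the browsing negativity score, age, gender). Implemented
#' as the equivalent two-stage GLM:
#' \itemize{
#'   \item Between-subject tests (each covariate's main effect on the
#'     response) come from an OLS fit of the participant-mean response on all
#'     covariates; for single-df terms F = t^2.
#'   \item Within-subject tests (the within-factor main effect and each
#'     covariate x factor interaction) come from regressions of the
#'     orthonormalized within-subject contrasts on the covariates, with sums
#'     of squares pooled across contrasts.
#' }
#' Greenhouse-Geisser correction is applied to within-subject tests when
#' Mauchly's sphericity test rejects at p < 0.05. Partial eta squared is
#' SS_effect / (SS_effect + SS_error) per term. All p-values two-sided.
#'
#' @param data Long data frame with columns \code{participant},
#'   \code{dimension} (within-subject factor), \code{score} (response).
#'   Every participant must have exactly one row per factor level.
#' @param covariates Data frame of numeric covariates, one row per
#'   participant, with a \code{participant} column.
#' @return An object of class \code{mixed_anova}: list with \code{table}
#'   (term, F, df1, df2, p, partial_eta_sq, stratum), \code{sphericity}
#'   (Mauchly W, p, Greenhouse-Geisser epsilon, whether applied), \code{n}.
#' @export
mixed_anova_covariate <- function(data, covariates) {
  stopifnot(all(c("participant", "dimension", "score") %in% names(data)),
            "participant" %in% names(covariates))
  data$participant <- as.character(data$participant)
  covariates$participant <- as.character(covariates$participant)
  levs <- sort(unique(as.character(data$dimension)))
  k <- length(levs)
  if (k < 2) stop("within-subject factor needs at least 2 levels")

  wide <- stats::reshape(
    data[, c("participant", "dimension", "score")],
    idvar = "participant", timevar = "dimension", direction = "wide"
  )
  score_cols <- paste0("score.", levs)
  if (!all(score_cols %in% names(wide)) || anyNA(wide[score_cols])) {
    stop("unbalanced design: every participant needs one score per level")
  }
  wide <- merge(wide, covariates, by = "participant")
  n <- nrow(wide)
  Y <- as.matrix(wide[score_cols])
  cov_names <- setdiff(names(covariates), "participant")
  stopifnot(length(cov_names) >= 1,
            all(vapply(wide[cov_names], is.numeric, logical(1))))
  X <- scale(as.matrix(wide[cov_names]), center = TRUE, scale = FALSE)

  # --- between stratum: participant-mean response on covariates
  ybar <- rowMeans(Y)
  bet <- stats::lm(ybar ~ X)
  sm <- summary(bet)$coefficients
  df2_b <- bet$df.residual
  between <- do.call(rbind, lapply(seq_along(cov_names), function(j) {
    tval <- sm[j + 1, 3]
    data.frame(term = cov_names[j], F = tval^2, df1 = 1, df2 = df2_b,
               p = sm[j + 1, 4],
               partial_eta_sq = tval^2 / (tval^2 + df2_b),
               stratum = "between", stringsAsFactors = FALSE)
  }))

  # --- within stratum: orthonormal contrasts of the factor levels
  C <- stats::contr.helmert(k)
  C <- apply(C, 2, function(v) v / sqrt(sum(v^2)))  # orthonormal columns
  Yc <- Y %*% C                                      # n x (k-1)
  wfit <- stats::lm(Yc ~ X)
  dfe_w <- wfit$df.residual
  R <- stats::residuals(wfit)                        # n x (k-1)
  S <- crossprod(R) / dfe_w

  # Mauchly sphericity on the orthonormalized residual covariance
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, .Machine$double.eps)
  pprime <- k - 1
  W <- prod(lam) / (mean(lam))^pprime
  gg_eps <- sum(lam)^2 / (pprime * sum(lam^2))
  if (pprime > 1) {
    f <- 1 - (2 * pprime^2 + pprime + 2) / (6 * pprime * dfe_w)
    chi2 <- -f * dfe_w * log(W)
    df_m <- pprime * (pprime + 1) / 2 - 1
    mauchly_p <- stats::pchisq(chi2, df_m, lower.tail = FALSE)
  } else {
    mauchly_p <- NA_real_  # sphericity trivially holds with 2 levels
  }
  apply_gg <- is.finite(mauchly_p) && !is.na(mauchly_p) && mauchly_p < 0.05

  ss_err_w <- sum(R^2)
  within_term <- function(term_name, ss_eff) {
    df1 <- pprime; df2 <- pprime * dfe_w
    eps <- if (apply_gg) gg_eps else 1
    if (ss_err_w / df2 < .Machine$double.eps) {
      # degenerate within stratum (e.g. identical level scores): no error
      # variance, so any non-zero effect is infinite, a zero effect is null
      Fv <- if (ss_eff < .Machine$double.eps) 0 else Inf
      return(data.frame(term = term_name, F = Fv, df1 = df1 * eps,
                        df2 = df2 * eps, p = if (is.infinite(Fv)) 0 else 1,
                        partial_eta_sq = if (is.infinite(Fv)) 1 else 0,
                        stratum = "within", stringsAsFactors = FALSE))
    }
    Fv <- (ss_eff / df1) / (ss_err_w / df2)
    data.frame(term = term_name, F = Fv, df1 = df1 * eps, df2 = df2 * eps,
               p = stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
               partial_eta_sq = ss_eff / (ss_eff + ss_err_w),
               stratum = "within", stringsAsFactors = FALSE)
  }
  # factor main effect at covariate means (covariates are centered in wfit,
  # so the contrast-regression intercepts are the adjusted level contrasts)
  ss_main <- n * sum(colMeans(Yc)^2)
  rows <- list(within_term("dimension", ss_main))
  # covariate x factor interactions: type-III SS per covariate
  for (j in seq_along(cov_names)) {
    Xr <- X[, -j, drop = FALSE]
    rfit <- if (ncol(Xr) == 0) stats::lm(Yc ~ 1) else stats::lm(Yc ~ Xr)
    ss_eff <- sum(stats::residuals(rfit)^2) - ss_err_w
    rows <- c(rows, list(within_term(paste0(cov_names[j], ":dimension"),
                                     max(ss_eff, 0))))
  }
  tab <- rbind(between, do.call(rbind, rows))
  rownames(tab) <- NULL
  structure(
    list(table = tab,
         sphericity = list(W = W, mauchly_p = mauchly_p,
                           gg_epsilon = gg_eps, gg_applied = apply_gg),
         n = n, levels = levs, two_sided = TRUE),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, digits = 3, ...) {
  cat(sprintf("Repeated-measures ANCOVA: n = %d, within factor with %d levels\n",
              x$n, length(x$levels)))
  tab <- x$table
  tab[c("F", "df1", "df2", "p", "partial_eta_sq")] <-
    lapply(tab[c("F", "df1", "df2", "p", "partial_eta_sq")],
           function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  if (isTRUE(x$sphericity$gg_applied)) {
    cat(sprintf("Greenhouse-Geisser applied (Mauchly p = %.3g, eps = %.3f)\n",
                x$sphericity$mauchly_p, x$sphericity$gg_epsilon))
  }
  invisible(x)
}
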