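# Fit an LMM trying progressively simpler random-effect structures; the
# first non-singular fit wins, and the structure used is recorded.
fit_lmm_backoff <- function(formulas, data, zscore = NULL) {
  last <- NULL
  for (f in formulas) {
    # convergence status of each attempt is carried on the result; the
    # optimizer's warning text is not re-emitted for structures we back away from
    res <- tryCatch(suppressWarnings(fit_lmm(f, data, zscore = zscore)),
                    error = function(e) NULL)
    if (is.null(res)) next
    last <- res
    last$formula <- f
    if (!res$singular && res$converged) break
  }
  if (is.null(last)) {
    # final backoff: fixed-effects-only least squares (e.g. when residual
    # variance is exactly zero and the mixed fit cannot be computed)
    f0 <- stats::as.formula(paste(deparse(formulas[[length(formulas)]][[2]]),
                                  "~",
                                  deparse(lme4::nobars(formulas[[length(formulas)]][[3]]))))
    fit0 <- stats::lm(f0, data = data)
    ct <- suppressWarnings(summary(fit0))$coefficients
    last <- structure(
      list(fixed = data.frame(term = rownames(ct), estimate = ct[, 1],
                              se = ct[, 2], t = ct[, 3],
                              df = fit0$df.residual, p = ct[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
           ranef_var = NULL, converged = TRUE, singular = TRUE,
           two_sided = TRUE, fit = fit0, formula = f0,
           note = "fixed-effects fallback"),
      class = "lmm_result")
  }
  last
}

z <- function(x) as.numeric(scale(x))

#' Relate browsing valence to psychopathology dimensions
#'
#' The core observational analysis: given participant-level affect profiles
#' and psychopathology dimension scores, computes (a) the day-to-day
#' stability ICC of the negative and positive scores (multi-day data only),
#' (b) a repeated-measures ANCOVA of the three dimension scores with the
#' valence score (negative, then positive) plus age and gender as
#' participant-level covariates, and (c) the simplified standardized
#' regression of the composite psychopathology score on valence, age and
#' gender. All variables are Z-scored for (b) and (c).
#'
#' @param profile Output of [aggregate_participant()] (needs \code{pos} and
#'   \code{neg} columns).
#' @param dims Dimension scores from [score_dimensions()].
#' @param demographics Data frame with \code{participant}, \code{age},
#'   \code{gender} (numeric coding).
#' @return List of class \code{study_results} with elements
#'   \code{icc_neg}, \code{icc_pos} (NULL for single-day data),
#'   \code{anova_neg}, \code{anova_pos}, \code{ols_neg}, \code{ols_pos},
#'   \code{n}.
#' @export
run_valence_psychopathology <- function(profile, dims, demographics) {
  dat <- merge(merge(profile$overall, dims, by = "participant"),
               demographics, by = "participant")
  n <- nrow(dat)

  icc_neg <- icc_pos <- NULL
  days_per <- table(profile$daily$participant)
  if (max(days_per) >= 2) {
    for (v in c("neg", "pos")) {
      wide <- stats::reshape(
        profile$daily[c("participant", "day", v)],
        idvar = "participant", timevar = "day", direction = "wide"
      )
      m <- as.matrix(wide[-1])
      m <- m[stats::complete.cases(m), , drop = FALSE]
      res <- icc(m, form = "twoway_consistency_single")
      if (v == "neg") icc_neg <- res else icc_pos <- res
    }
  }

  long <- stats::reshape(
    dat[c("participant", "AD", "SW", "CIT")],
    varying = list(c("AD", "SW", "CIT")), v.names = "score",
    timevar = "dimension", times = c("AD", "SW", "CIT"),
    idvar = "participant", direction = "long"
  )
  results <- list(icc_neg = icc_neg, icc_pos = icc_pos)
  for (v in c("neg", "pos")) {
    covs <- data.frame(participant = dat$participant,
                       valence = z(dat[[v]]),
                       age = z(dat$age), gender = z(dat$gender))
    names(covs)[2] <- v
    results[[paste0("anova_", v)]] <- mixed_anova_covariate(long, covs)
    results[[paste0("ols_", v)]] <- fit_ols_standardized(
      dat$mean_psych, dat[c(v, "age", "gender")]
    )
  }
  results$n <- n
  structure(results, class = "study_results")
}

#' Relate browsing valence to pre- and post-browsing mood
#'
#' Four models linking mood to the valence of pages browsed. With repeated
#' daily observations these are linear mixed-effects models with participant
#' random intercepts and a random slope of the focal predictor (backing off
#' to intercept-only on singular fit); with a single observation per
#' participant they are the OLS analogues:
#' \enumerate{
#'   \item pre-mood predicting the daily negative score,
#'   \item pre-mood predicting the daily positive score,
#'   \item the negative score predicting post-mood, controlling pre-mood,
#'   \item the positive score predicting post-mood, controlling pre-mood,
#' }
#' all controlling for age and gender (fixed effects) and with all variables
#' Z-scored, so estimates are standardized coefficients.
#'
#' @param profile Output of [aggregate_participant()].
#' @param moods Data frame \code{participant}, \code{day}, \code{pre},
#'   \code{post} (mood on the -50..+50 scale).
#' @param demographics Data frame \code{participant}, \code{age},
#'   \code{gender}.
#' @return List of class \code{study_results} with \code{pre_neg},
#'   \code{pre_pos}, \code{post_neg}, \code{post_pos} (each an
#'   \code{lmm_result} or \code{std_ols}), \code{design} ("multi_day" or
#'   "single_day"), \code{n}.
#' @export
run_mood_valence <- function(profile, moods, demographics) {
  dat <- merge(merge(profile$daily, moods, by = c("participant", "day")),
               demographics, by = "participant")
  multi_day <- max(table(dat$participant)) >= 2
  for (v in c("neg", "pos", "pre", "post", "age", "gender")) {
    dat[[v]] <- z(dat[[v]])
  }
  out <- list(design = if (multi_day) "multi_day" else "single_day",
              n = length(unique(dat$participant)))
  if (multi_day) {
    out$pre_neg <- fit_lmm_backoff(
      list(neg ~ pre + age + gender + (1 + pre | participant),
           neg ~ pre + age + gender + (1 | participant)), dat)
    out$pre_pos <- fit_lmm_backoff(
      list(pos ~ pre + age + gender + (1 + pre | participant),
           pos ~ pre + age + gender + (1 | participant)), dat)
    out$post_neg <- fit_lmm_backoff(
      list(post ~ neg + pre + age + gender + (1 + neg + pre | participant),
           post ~ neg + pre + age + gender + (1 + neg | participant),
           post ~ neg + pre + age + gender + (1 | participant)), dat)
    out$post_pos <- fit_lmm_backoff(
      list(post ~ pos + pre + age + gender + (1 + pos + pre | participant),
           post ~ pos + pre + age + gender + (1 + pos | participant),
           post ~ pos + pre + age + gender + (1 | participant)), dat)
  } else {
    out$pre_neg <- fit_ols_standardized(dat$neg, dat[c("pre", "age", "gender")],
                                        zscore = FALSE)
    out$pre_pos <- fit_ols_standardized(dat$pos, dat[c("pre", "age", "gender")],
                                        zscore = FALSE)
    out$post_neg <- fit_ols_standardized(dat$post,
                                         dat[c("neg", "pre", "age", "gender")],
                                         zscore = FALSE)
    out$post_pos <- fit_ols_standardized(dat$post,
                                         dat[c("pos", "pre", "age", "gender")],
                                         zscore = FALSE)
  }
  structure(out, class = "study_results")
}

#' Analyse a mood-manipulation experiment
#'
#' (a) Standardized OLS predicting post-exposure mood from condition
#' (0 control, 1 negative), controlling for pre-exposure mood, age and
#' gender; (b) estimated marginal mean mood per condition at covariate means
#' (on the raw mood scale); (c) Welch t test comparing free-browse
#' negativity between conditions (control minus negative, so a more negative
#' t means the negative condition browsed more negatively), with Cohen's d.
#'
#' @param exposure Data frame from [simulate_manipulation()] or equivalent:
#'   \code{condition}, \code{pre}, \code{post}, \code{free_neg}, \code{age},
#'   \code{gender}.
#' @return List of class \code{study_results}: \code{mood_model}
#'   (\code{std_ols}), \code{emmeans} (per-condition adjusted means),
#'   \code{free_browse_t} (\code{ttest_result}), \code{n}.
#' @export
run_manipulation_study <- function(exposure) {
  stopifnot(all(c("condition", "pre", "post", "free_neg", "age", "gender")
                %in% names(exposure)))
  mood_model <- fit_ols_standardized(
    exposure$post, exposure[c("condition", "pre", "age", "gender")]
  )
  em <- estimated_marginal_means(exposure$post, exposure$condition,
                                 exposure[c("pre", "age", "gender")])
  ft <- welch_t(exposure$free_neg[exposure$condition == 0],
                exposure$free_neg[exposure$condition == 1])
  structure(list(mood_model = mood_model, emmeans = em, free_browse_t = ft,
                 n = nrow(exposure)),
            class = "study_results")
}

#' Analyse an affective-label choice experiment
#'
#' Counts each participant's positive, neutral and negative selections and
#' fits three standardized OLS models predicting each count from the label
#' condition (0 no-label, 1 label), controlling for age and gender.
#'
#' @param trials Trial table: \code{participant}, \code{choice}
#'   (-1 negative, 0 neutral, 1 positive).
#' @param participants Participant table: \code{participant},
#'   \code{condition}, \code{age}, \code{gender}.
#' @return List of class \code{study_results}: \code{counts} (per-participant
#'   selection counts), \code{model_positive}, \code{model_neutral},
#'   \code{model_negative} (each \code{std_ols}), \code{n}.
#' @export
run_label_choice <- function(trials, participants) {
  counts <- do.call(rbind, lapply(split(trials, trials$participant),
    function(d) data.frame(participant = d$participant[1],
                           n_pos = sum(d$choice == 1),
                           n_neu = sum(d$choice == 0),
                           n_neg = sum(d$choice == -1),
                           stringsAsFactors = FALSE)))
  stopifnot(all(counts$n_pos + counts$n_neu + counts$n_neg ==
                  as.vector(table(trials$participant)[counts$participant])))
  dat <- merge(counts, participants, by = "participant")
  models <- lapply(c(n_pos = "n_pos", n_neu = "n_neu", n_neg = "n_neg"),
                   function(v) fit_ols_standardized(
                     dat[[v]], dat[c("condition", "age", "gender")]))
  structure(list(counts = counts,
                 model_positive = models$n_pos,
                 model_neutral = models$n_neu,
                 model_negative = models$n_neg,
                 n = nrow(dat)),
            class = "study_results")
}

#' Analyse trial-level mood under the label intervention
#'
#' (a) Paired t tests comparing the percentage of positive selections with
#' the percentage of negative and neutral selections; (b) a linear
#' mixed-effects model predicting post-trial mood from the valence of the
#' chosen page (-1, 0, +1; fixed and random slope by participant),
#' controlling for baseline mood, age and gender (fixed effects). Mood is
#' Z-scored; choice valence stays on its -1..+1 coding, so the choice
#' coefficient is the standardized mood change per valence step.
#'
#' @param trials Trial table: \code{participant}, \code{trial},
#'   \code{choice}, \code{mood}.
#' @param participants Participant table: \code{participant},
#'   \code{baseline}, \code{age}, \code{gender}.
#' @return List of class \code{study_results}: \code{choice_pcts},
#'   \code{t_pos_vs_neg}, \code{t_pos_vs_neu}, \code{mood_model}
#'   (\code{lmm_result}), \code{degenerate} flag, \code{n}.
#' @export
run_label_mood <- function(trials, participants) {
  pct <- do.call(rbind, lapply(split(trials, trials$participant),
    function(d) data.frame(participant = d$participant[1],
                           pct_pos = 100 * mean(d$choice == 1),
                           pct_neu = 100 * mean(d$choice == 0),
                           pct_neg = 100 * mean(d$choice == -1),
                           stringsAsFactors = FALSE)))
  stopifnot(all(abs(pct$pct_pos + pct$pct_neu + pct$pct_neg - 100) < 1e-9))
  dat <- merge(trials, participants, by = "participant")
  degenerate <- stats::var(dat$choice) == 0
  t_pn <- t_pu <- NULL
  if (!degenerate) {
    t_pn <- paired_t(pct$pct_pos, pct$pct_neg)
    t_pu <- paired_t(pct$pct_pos, pct$pct_neu)
  }
  mood_model <- NULL
  if (!degenerate) {
    dat$mood <- z(dat$mood)
    dat$baseline <- z(dat$baseline)
    dat$age <- z(dat$age)
    dat$gender <- z(dat$gender)
    mood_model <- fit_lmm_backoff(
      list(mood ~ choice + baseline + age + gender + (1 + choice | participant),
           mood ~ choice + baseline + age + gender + (1 | participant)), dat)
  }
  structure(list(choice_pcts = pct, t_pos_vs_neg = t_pn, t_pos_vs_neu = t_pu,
                 mood_model = mood_model, degenerate = degenerate,
                 n = nrow(pct)),
            class = "study_results")
}

#' Validate whole-page scoring against attended-region scoring
#'
#' Two mixed-effects models (negative and positive), each predicting the
#' whole-page valence score from the score of the text regions that received
#' the most attention, with participant random intercepts and slopes
#' (backing off on singular fits).
#'
#' @param page_pairs Data frame: \code{participant}, \code{whole_neg},
#'   \code{region_neg}, \code{whole_pos}, \code{region_pos}, one row per
#'   page.
#' @return List of class \code{study_results}: \code{model_neg},
#'   \code{model_pos} (each \code{lmm_result}), \code{n_pages}.
#' @export
run_attention_validation <- function(page_pairs) {
  stopifnot(all(c("participant", "whole_neg", "region_neg",
                  "whole_pos", "region_pos") %in% names(page_pairs)))
  m_neg <- fit_lmm_backoff(
    list(whole_neg ~ region_neg + (1 + region_neg | participant),
         whole_neg ~ region_neg + (1 | participant)), page_pairs)
  m_pos <- fit_lmm_backoff(
    list(whole_pos ~ region_pos + (1 + region_pos | participant),
         whole_pos ~ region_pos + (1 | participant)), page_pairs)
  structure(list(model_neg = m_neg, model_pos = m_pos,
                 n_pages = nrow(page_pairs)),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat("Study results with elements:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
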