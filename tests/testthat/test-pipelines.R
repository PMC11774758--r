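make_profile <- function(co) {
  aggregate_participant(co$pages[c("participant", "day", "pos", "neg")])
}

test_that("valence-psychopathology pipeline runs end to end on a cohort", {
  co <- simulate_cohort(gen_params(n_participants = 150, n_days = 5, seed = 71))
  prof <- make_profile(co)
  dims <- score_dimensions(zscore_items(co$items), co$weights)
  res <- run_valence_psychopathology(prof, dims, co$demographics)
  expect_s3_class(res$icc_neg, "icc_result")
  expect_gt(res$icc_neg$icc, 0.2)           # stable browsing tendency
  expect_s3_class(res$ols_neg, "std_ols")
  expect_equal(res$n, 150)
  # effect-r identity holds on the fitted pipeline regression
  ct <- res$ols_neg$coef
  expect_equal(abs(ct$effect_r), abs(ct$t) / sqrt(ct$t^2 + ct$df))
  # single-day data: ICC is skipped, not fabricated
  co1 <- simulate_cohort(gen_params(n_participants = 120, n_days = 1, seed = 72))
  res1 <- run_valence_psychopathology(make_profile(co1),
                                      score_dimensions(zscore_items(co1$items),
                                                       co1$weights),
                                      co1$demographics)
  expect_null(res1$icc_neg)
})

test_that("identical dimension scores produce a null dimension interaction", {
  co <- simulate_cohort(gen_params(n_participants = 100, n_days = 1, seed = 73))
  prof <- make_profile(co)
  g <- co$ground_truth$latents$z_g
  dims <- data.frame(participant = co$ground_truth$latents$participant,
                     AD = g, SW = g, CIT = g)
  dims$mean_psych <- g
  res <- run_valence_psychopathology(prof, dims, co$demographics)
  tab <- res$anova_neg$table
  expect_lt(tab$F[tab$term == "neg:dimension"], 1e-20)
})

test_that("the single-day mood path equals a direct OLS oracle", {
  co <- simulate_cohort(gen_params(n_participants = 200, n_days = 5, seed = 74))
  prof <- make_profile(co)
  day1 <- prof$daily[prof$daily$day == 1, ]
  prof1 <- list(daily = day1,
                overall = day1[c("participant", "pos", "neg")])
  moods1 <- co$moods[co$moods$day == 1, ]
  res <- run_mood_valence(prof1, moods1, co$demographics)
  expect_equal(res$design, "single_day")
  dat <- merge(merge(day1, moods1, by = c("participant", "day")),
               co$demographics, by = "participant")
  oracle <- fit_ols_standardized(dat$neg, dat[c("pre", "age", "gender")])
  expect_equal(res$pre_neg$coef$beta, oracle$coef$beta, tolerance = 1e-12)
  expect_equal(res$pre_neg$coef$p, oracle$coef$p, tolerance = 1e-12)
})

test_that("multi-day mood models are mixed models with fractional df", {
  co <- simulate_cohort(gen_params(n_participants = 120, n_days = 5, seed = 75))
  res <- run_mood_valence(make_profile(co), co$moods, co$demographics)
  expect_equal(res$design, "multi_day")
  for (m in list(res$pre_neg, res$post_neg)) {
    expect_s3_class(m, "lmm_result")
    focal <- m$fixed[2, ]
    expect_gt(focal$df, 0)
  }
  # couplings are negative by construction; estimates should lean that way
  expect_lt(res$pre_neg$fixed$estimate[2], 0.05)
  expect_lt(res$post_neg$fixed$estimate[2], 0.05)
})

test_that("manipulation pipeline detects the mood effect and reports emmeans", {
  detected <- vapply(1:20, function(i) {
    sim <- simulate_manipulation(seed = 760 + i)
    res <- run_manipulation_study(sim)
    cond <- res$mood_model$coef[res$mood_model$coef$term == "condition", ]
    cond$beta < 0 && cond$p < 0.05
  }, logical(1))
  expect_gte(sum(detected), 16)   # -0.5 s.d. shift is reliably detected

  sim <- simulate_manipulation(seed = 76)
  res <- run_manipulation_study(sim)
  expect_equal(nrow(res$emmeans), 2)
  expect_s3_class(res$free_browse_t, "ttest_result")
  expect_gt(res$free_browse_t$df, 46)
  expect_lt(res$free_browse_t$df, 100)
  # null manipulation: adjusted means agree within their standard errors
  null_sim <- simulate_manipulation(n_negative = 300, n_control = 300,
                                    mood_effect_sd = 0,
                                    free_browse_gap_sd = 0, seed = 77)
  null_res <- run_manipulation_study(null_sim)
  gap <- abs(diff(null_res$emmeans$emmean))
  expect_lt(gap, 3 * sum(null_res$emmeans$se))
})

test_that("label-choice pipeline counts selections and recovers the shift", {
  lab <- simulate_label_study(n_label = 400, n_nolabel = 400, n_trials = 3,
                              seed = 78)
  res <- run_label_choice(lab$trials, lab$participants)
  expect_true(all(res$counts$n_pos + res$counts$n_neu + res$counts$n_neg == 3))
  neg_beta <- res$model_negative$coef$beta[1]
  pos_beta <- res$model_positive$coef$beta[1]
  expect_lt(neg_beta, 0)
  expect_gt(pos_beta, 0)
  expect_lt(res$model_negative$coef$p[1], 0.05)

  # no label effect: all three condition betas near zero
  null_lab <- simulate_label_study(n_label = 400, n_nolabel = 400,
                                   label_shift = c(pos = 0, neg = 0),
                                   seed = 79)
  null_res <- run_label_choice(null_lab$trials, null_lab$participants)
  for (m in list(null_res$model_positive, null_res$model_neutral,
                 null_res$model_negative)) {
    expect_lt(abs(m$coef$beta[1]), 3.5 * m$coef$se[1])
  }
})

test_that("label-mood pipeline pairs selections and models trial mood", {
  lab <- simulate_label_study(n_label = 200, n_nolabel = 0, n_trials = 6,
                              seed = 80)
  res <- run_label_mood(lab$trials, lab$participants)
  expect_equal(rowSums(res$choice_pcts[c("pct_pos", "pct_neu", "pct_neg")]),
               rep(100, 200), ignore_attr = TRUE)
  expect_gt(res$t_pos_vs_neg$t, 0)   # positive labels chosen more often
  expect_lt(res$t_pos_vs_neg$p, 0.001)
  choice_row <- res$mood_model$fixed[res$mood_model$fixed$term == "choice", ]
  expect_gt(choice_row$estimate, 0)
  # all-neutral choices cannot identify a valence effect
  allneu <- lab
  allneu$trials$choice <- 0
  res_n <- run_label_mood(allneu$trials, allneu$participants)
  expect_true(res_n$degenerate)
  expect_null(res_n$mood_model)
})

test_that("attention validation recovers identity, signal and null slopes", {
  lex <- make_fixture_lexicons(400, seed = 81)
  vlex <- load_valence_lexicon(lex$valence)
  set.seed(82)
  n_subj <- 19; pages_per <- 3
  rows <- list()
  for (s in seq_len(n_subj)) {
    for (pg in seq_len(pages_per)) {
      target_neg <- runif(1, 0.02, 0.12); target_pos <- runif(1, 0.05, 0.25)
      whole <- make_webpage(target_neg, target_pos, 600, lex)
      region <- sample(whole$tokens, 150)   # attended region: same token pool
      ws <- score_valence(whole$tokens, vlex)
      rs <- score_valence(region, vlex)
      rows[[length(rows) + 1]] <- data.frame(
        participant = sprintf("s%02d", s),
        whole_neg = ws["neg"], region_neg = rs["neg"],
        whole_pos = ws["pos"], region_pos = rs["pos"])
    }
  }
  pairs <- do.call(rbind, rows)
  res <- run_attention_validation(pairs)
  slope <- res$model_neg$fixed[res$model_neg$fixed$term == "region_neg", ]
  expect_gt(slope$estimate, 0)
  expect_lt(slope$p, 0.05)

  # identity: region text equal to whole text
  ident <- pairs
  ident$region_neg <- ident$whole_neg
  ident$region_pos <- ident$whole_pos
  res_i <- run_attention_validation(ident)
  s_i <- res_i$model_neg$fixed
  expect_equal(s_i$estimate[s_i$term == "region_neg"], 1, tolerance = 1e-8)
  expect_equal(s_i$estimate[s_i$term == "(Intercept)"], 0, tolerance = 1e-8)

  # null: regions unrelated to the page
  null_pairs <- pairs
  null_pairs$region_neg <- sample(null_pairs$region_neg)
  null_pairs$region_pos <- sample(null_pairs$region_pos)
  res_0 <- run_attention_validation(null_pairs)
  s_0 <- res_0$model_neg$fixed[res_0$model_neg$fixed$term == "region_neg", ]
  expect_lt(abs(s_0$estimate), 3.5 * s_0$se)
})
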