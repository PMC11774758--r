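#' Simulate a mood-manipulation experiment
#'
#' Emulates a between-subjects exposure design: participants are assigned to
#' a negative-content condition or a neutral control condition, report mood
#' before and after exposure, and then browse freely. The condition shifts
#' post-exposure mood by \code{mood_effect_sd} standard deviations
#' (negative = mood worsens) and shifts free-browse negativity by
#' \code{free_browse_gap_sd} pooled standard deviations.
#'
#' @param n_negative,n_control Group sizes.
#' @param mood_effect_sd Standardized effect of the negative condition on
#'   post mood (default -0.5).
#' @param free_browse_gap_sd Group gap in free-browse negativity, in pooled
#'   s.d. units (default 0.4).
#' @param rho_m Pre/post mood carry-over.
#' @param mu_neg,sigma_neg Free-browse negativity mean and s.d.
#' @param mood_sd Mood s.d. in slider units.
#' @param seed Integer seed.
#' @return Data frame, one row per participant: \code{participant},
#'   \code{condition} (0 control, 1 negative), \code{pre}, \code{post}
#'   (mood, -50..+50), \code{free_neg} (free-browse negativity score),
#'   \code{age}, \code{gender}.
#' @export
simulate_manipulation <- function(n_negative = 55, n_control = 47,
                                  mood_effect_sd = -0.5,
                                  free_browse_gap_sd = 0.4,
                                  rho_m = 0.7, mu_neg = 0.03,
                                  sigma_neg = 0.017, mood_sd = 15,
                                  seed = 1) {
  set.seed(seed)
  n <- n_negative + n_control
  condition <- c(rep(1L, n_negative), rep(0L, n_control))
  z_pre <- stats::rnorm(n)
  z_post <- rho_m * z_pre + mood_effect_sd * condition +
    sqrt(1 - rho_m^2) * stats::rnorm(n)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  data.frame(
    participant = sprintf("m%03d", seq_len(n)),
    condition = condition,
    pre = clamp(mood_sd * z_pre, -50, 50),
    post = clamp(mood_sd * z_post, -50, 50),
    free_neg = clamp(mu_neg + free_browse_gap_sd * sigma_neg * condition +
                       sigma_neg * stats::rnorm(n), 0, 1),
    age = round(clamp(stats::rnorm(n, 34, 11), 18, 80)),
    gender = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Simulate an affective-label choice experiment
#'
#' Emulates the search-result choice design: on each trial a participant
#' picks one of three result options (positive, neutral, negative page).
#' Choice follows a softmax whose utilities shift by \code{label_shift} when
#' affective labels are shown. Per-trial mood is generated from baseline mood
#' plus a standardized gain per unit of chosen-page valence
#' (\code{mood_gain}), so label-driven choices can improve mood.
#'
#' The default \code{label_shift} moves the choice distribution from uniform
#' (1/3 each) to approximately (0.45, 0.30, 0.25) for
#' (positive, neutral, negative).
#'
#' @param n_label,n_nolabel Participants per condition (set
#'   \code{n_nolabel = 0} for a labels-only mood study).
#' @param n_trials Trials per participant.
#' @param label_shift Named numeric utility shift applied in the label
#'   condition, \code{c(pos = ..., neg = ...)} (neutral fixed at 0; the
#'   \code{neg} shift is subtracted).
#' @param mood_gain Standardized mood gain per valence step of the chosen
#'   page (default 0.09).
#' @param rho_m Baseline-to-trial mood carry-over.
#' @param mood_sd Mood s.d. in slider units.
#' @param seed Integer seed.
#' @return List with \code{trials} (participant, condition, trial, choice in
#'   \{-1, 0, 1\}, mood after the trial) and \code{participants} (condition,
#'   baseline mood, age, gender).
#' @export
simulate_label_study <- function(n_label = 55, n_nolabel = 54, n_trials = 3,
                                 label_shift = c(pos = log(1.5),
                                                 neg = log(1.2)),
                                 mood_gain = 0.09, rho_m = 0.7,
                                 mood_sd = 15, seed = 1) {
  set.seed(seed)
  n <- n_label + n_nolabel
  condition <- c(rep(1L, n_label), rep(0L, n_nolabel))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  z_base <- stats::rnorm(n)
  participants <- data.frame(
    participant = sprintf("l%03d", seq_len(n)),
    condition = condition,
    baseline = clamp(mood_sd * z_base, -50, 50),
    age = round(clamp(stats::rnorm(n, 36, 12), 18, 80)),
    gender = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  )
  u_nolabel <- c(pos = 0, neu = 0, neg = 0)
  u_label <- c(pos = unname(label_shift["pos"]), neu = 0,
               neg = -unname(label_shift["neg"]))
  softmax <- function(u) exp(u) / sum(exp(u))
  valence_of <- c(pos = 1, neu = 0, neg = -1)

  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- softmax(if (condition[i] == 1L) u_label else u_nolabel)
    choice <- sample(names(p), n_trials, replace = TRUE, prob = p)
    v <- valence_of[choice]
    z_mood <- rho_m * z_base[i] + mood_gain * v +
      sqrt(1 - rho_m^2 - mood_gain^2) * stats::rnorm(n_trials)
    data.frame(
      participant = participants$participant[i],
      condition = condition[i], trial = seq_len(n_trials),
      choice = unname(v),
      mood = clamp(mood_sd * z_mood, -50, 50),
      stringsAsFactors = FALSE
    )
  }))
  rownames(trials) <- NULL
  list(trials = trials, participants = participants)
}
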