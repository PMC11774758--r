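#' Parameters for cohort simulation
#'
#' Assembles and validates the generator parameters for [simulate_cohort()].
#' Couplings are standardized path coefficients among unit-variance latent
#' variables (see the methods vignette); observation scales are set by
#' \code{mu_neg}/\code{sigma_neg} (page negativity target), \code{mu_pos}/
#' \code{sigma_pos}, and \code{mood_sd} (mood on the -50..+50 scale).
#'
#' @param n_participants Number of participants.
#' @param n_days Browsing days per participant (1 or 5 in the designs
#'   emulated).
#' @param pages_per_day Integer range (min, max) of pages per day.
#' @param words_per_page Integer range (min, max) of tokens per page.
#' @param rho Latent factor correlation (3x3 compound-symmetric covariance).
#' @param n_items_per_dim Questionnaire items per dimension.
#' @param loading_range Range of item factor weights.
#' @param item_noise_sd Item-level noise s.d. (items have unit-variance
#'   latent signal before weighting).
#' @param gamma_g Standardized latent-psychopathology -> negativity coupling.
#' @param b2 Standardized pre-mood -> negativity coupling (negative
#'   expected: worse mood, more negative browsing).
#' @param lambda Standardized latent -> pre-mood coupling (enters with a
#'   negative sign: higher psychopathology, worse mood).
#' @param delta Standardized negativity -> post-mood coupling (negative
#'   expected).
#' @param rho_m Mood carry-over (pre -> post) standardized coupling.
#' @param kappa_mood Fraction of residual pre-mood variance that is
#'   participant-level (the rest fluctuates daily).
#' @param icc_neg Target participant-level share of latent negativity
#'   variance (day-to-day stability before measurement noise).
#' @param mu_neg,sigma_neg Mean and s.d. of the daily negativity target.
#' @param mu_pos,sigma_pos Mean and s.d. of the daily positivity target.
#' @param mood_sd Mood s.d. in slider units (scale -50..+50).
#' @param seed Integer seed.
#' @return A validated list of class \code{gen_params}.
#' @export
gen_params <- function(n_participants = 450, n_days = 1,
                       pages_per_day = c(4, 8), words_per_page = c(200, 600),
                       rho = 0.4, n_items_per_dim = 10,
                       loading_range = c(0.4, 0.9), item_noise_sd = 0.5,
                       gamma_g = 0.09, b2 = -0.08, lambda = 0.30,
                       delta = -0.05, rho_m = 0.70, kappa_mood = 0.5,
                       icc_neg = 0.55,
                       mu_neg = 0.03, sigma_neg = 0.01,
                       mu_pos = 0.15, sigma_pos = 0.02,
                       mood_sd = 15, seed = 1) {
  p <- as.list(environment())
  stopifnot(n_participants >= 2, n_days >= 1,
            length(pages_per_day) == 2, pages_per_day[1] >= 1,
            pages_per_day[1] <= pages_per_day[2],
            length(words_per_page) == 2, words_per_page[1] >= 1,
            words_per_page[1] <= words_per_page[2],
            rho > -0.5, rho < 1,          # keeps Sigma positive-definite
            mu_neg >= 0, mu_pos >= 0, mu_neg + mu_pos < 1,
            sigma_neg > 0, sigma_pos > 0, mood_sd > 0,
            kappa_mood >= 0, kappa_mood <= 1,
            icc_neg >= 0, icc_neg <= 1,
            all(is.finite(c(gamma_g, b2, lambda, delta, rho_m))))
  structural_var <- gamma_g^2 + b2^2 + 2 * gamma_g * b2 * (-lambda)
  if (structural_var >= 1) stop("negativity couplings explain > 100% variance")
  if (lambda^2 >= 1) stop("|lambda| must be < 1")
  class(p) <- "gen_params"
  p
}

# Draw correlated latent factors and z-standardized composite
draw_latents <- function(n, rho) {
  L <- chol(matrix(rho, 3, 3) + diag(1 - rho, 3))
  f <- matrix(stats::rnorm(n * 3), n, 3) %*% L
  colnames(f) <- c("AD", "SW", "CIT")
  g <- rowMeans(f)
  list(f = f, z_g = g / sqrt((3 + 6 * rho) / 9))
}

#' Simulate a complete browsing cohort with known ground truth
#'
#' Generates a full synthetic study: correlated latent psychopathology
#' factors, questionnaire items produced through factor weights, daily pre-
#' and post-browsing moods, and per-page affect scores, all linked by the
#' configured standardized couplings. The structural model is, per
#' participant i and day d (all z-variables unit-variance):
#' \preformatted{
#'   z_mood_pre  = -lambda * z_g + residual (participant + day parts)
#'   z_negativity = gamma_g * z_g + b2 * z_mood_pre + residual
#'   z_mood_post = rho_m * z_mood_pre + delta * z_negativity + residual
#' }
#' Page-level lexicon-hit counts are drawn from the exact multinomial law
#' implied by i.i.d. token draws at the day's target proportions; with
#' \code{materialize = "html"} the tokens and HTML documents themselves are
#' generated instead (identical in distribution, much slower).
#'
#' @param params A \code{gen_params} object.
#' @param materialize \code{"scores"} (default) or \code{"html"}.
#' @param lexicons Fixture lexicons (required for \code{materialize =
#'   "html"}); defaults to \code{make_fixture_lexicons(seed = params$seed)}.
#' @return A list with \code{pages} (per-page scores; with html also
#'   \code{html} and \code{url}), \code{items} (participants x items matrix),
#'   \code{weights} (item/dimension/weight), \code{moods} (participant, day,
#'   pre, post on the -50..+50 scale), \code{demographics} (participant, age,
#'   gender), \code{ground_truth} (latents and true daily targets; never
#'   consumed by pipelines), and \code{params}.
#' @export
simulate_cohort <- function(params = gen_params(),
                            materialize = c("scores", "html"),
                            lexicons = NULL) {
  stopifnot(inherits(params, "gen_params"))
  materialize <- match.arg(materialize)
  set.seed(params$seed)
  n <- params$n_participants
  D <- params$n_days
  ids <- sprintf("p%04d", seq_len(n))

  lat <- draw_latents(n, params$rho)

  # questionnaire items through the factor weights
  k <- params$n_items_per_dim
  dims <- c("AD", "SW", "CIT")
  weights <- data.frame(
    item = sprintf("item_%02d", seq_len(3 * k)),
    dimension = rep(dims, each = k),
    weight = round(stats::runif(3 * k, params$loading_range[1],
                                params$loading_range[2]), 3),
    stringsAsFactors = FALSE
  )
  items <- sapply(seq_len(3 * k), function(j) {
    d <- weights$dimension[j]
    weights$weight[j] * lat$f[, d] +
      stats::rnorm(n, 0, params$item_noise_sd)
  })
  colnames(items) <- weights$item
  rownames(items) <- ids

  # daily structural layer
  z_g_day <- rep(lat$z_g, each = D)
  v_i <- rep(stats::rnorm(n), each = D)          # participant mood residual
  w_id <- stats::rnorm(n * D)                    # daily mood residual
  lam <- params$lambda
  z_pre <- -lam * z_g_day + sqrt(1 - lam^2) *
    (sqrt(params$kappa_mood) * v_i + sqrt(1 - params$kappa_mood) * w_id)

  struct_var <- params$gamma_g^2 + params$b2^2 -
    2 * params$gamma_g * params$b2 * lam
  rem <- 1 - struct_var
  c_i <- sqrt(params$icc_neg * rem)
  c_d <- sqrt((1 - params$icc_neg) * rem)
  eta_i <- rep(stats::rnorm(n), each = D)
  u_id <- stats::rnorm(n * D)
  z_nu <- params$gamma_g * z_g_day + params$b2 * z_pre +
    c_i * eta_i + c_d * u_id

  cov_pre_nu <- params$b2 - params$gamma_g * lam   # Cov(z_pre, z_nu)
  post_expl <- params$rho_m^2 + params$delta^2 +
    2 * params$rho_m * params$delta * cov_pre_nu
  if (post_expl >= 1) stop("post-mood couplings explain > 100% variance")
  z_post <- params$rho_m * z_pre + params$delta * z_nu +
    sqrt(1 - post_expl) * stats::rnorm(n * D)

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  moods <- data.frame(
    participant = rep(ids, each = D), day = rep(seq_len(D), n),
    pre = clamp(params$mood_sd * z_pre, -50, 50),
    post = clamp(params$mood_sd * z_post, -50, 50),
    stringsAsFactors = FALSE
  )

  nu <- clamp(params$mu_neg + params$sigma_neg * z_nu, 0, 0.5)
  z_pi <- sqrt(0.5) * rep(stats::rnorm(n), each = D) +
    sqrt(0.5) * stats::rnorm(n * D)
  pi_pos <- clamp(params$mu_pos + params$sigma_pos * z_pi, 0, 0.5)

  # per-page scores
  n_pages <- sample(params$pages_per_day[1]:params$pages_per_day[2],
                    n * D, replace = TRUE)
  row_idx <- rep(seq_len(n * D), n_pages)
  n_words <- sample(params$words_per_page[1]:params$words_per_page[2],
                    length(row_idx), replace = TRUE)
  if (materialize == "scores") {
    neg_hits <- stats::rbinom(length(row_idx), n_words, nu[row_idx])
    # positive draws from the remaining tokens: exact multinomial factorization
    pos_hits <- stats::rbinom(length(row_idx), n_words - neg_hits,
                              pi_pos[row_idx] / (1 - nu[row_idx]))
    pages <- data.frame(
      participant = moods$participant[row_idx],
      day = moods$day[row_idx],
      order = unlist(lapply(n_pages, seq_len)) - 1L,
      n_tokens = n_words,
      pos = pos_hits / n_words,
      neg = neg_hits / n_words,
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(lexicons)) lexicons <- make_fixture_lexicons(seed = params$seed)
    vlex <- load_valence_lexicon(lexicons$valence)
    rows <- lapply(seq_along(row_idx), function(j) {
      i <- row_idx[j]
      pg <- make_webpage(nu[i], pi_pos[i], n_words[j], lexicons)
      list(participant = moods$participant[i], day = moods$day[i],
           html = pg$html, n_tokens = n_words[j],
           pos = pg$true_pos, neg = pg$true_neg)
    })
    pages <- data.frame(
      participant = vapply(rows, `[[`, character(1), "participant"),
      day = vapply(rows, `[[`, numeric(1), "day"),
      order = unlist(lapply(n_pages, seq_len)) - 1L,
      n_tokens = vapply(rows, `[[`, numeric(1), "n_tokens"),
      pos = vapply(rows, `[[`, numeric(1), "pos"),
      neg = vapply(rows, `[[`, numeric(1), "neg"),
      url = sprintf("https://example.test/page%06d", seq_along(rows)),
      stringsAsFactors = FALSE
    )
    attr(pages, "html_by_url") <- stats::setNames(
      lapply(rows, `[[`, "html"), pages$url)
  }

  demographics <- data.frame(
    participant = ids,
    age = round(clamp(stats::rnorm(n, 34, 12), 18, 80)),
    gender = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  )

  ground_truth <- list(
    latents = data.frame(participant = ids, lat$f, z_g = lat$z_g),
    daily = data.frame(participant = moods$participant, day = moods$day,
                       true_neg_target = nu, true_pos_target = pi_pos,
                       z_pre = z_pre, z_nu = z_nu, z_post = z_post)
  )

  list(pages = pages, items = items, weights = weights, moods = moods,
       demographics = demographics, ground_truth = ground_truth,
       params = params)
}
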