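# Synthetic multi-rater ratings with known latent structure.

#' Configuration for the synthetic ratings generator
#'
#' Defaults emulate the three-site wild macaque design: 150/101/77 subjects
#' rated by 5/4/5 site-specific observers on the 51-item general catalog,
#' five oblique latent factors, strong primary loadings, additive per
#' (rater, item) bias (the structure consistency ICCs are designed to
#' ignore), independent rater noise, occasional skipped (rater, subject)
#' pairs, and scores discretised to a 1-7 scale.
#'
#' @param groups Tibble with columns `group`, `n_subjects`, `n_raters`.
#' @param items Character vector of item names (default: general catalog).
#' @param true_k Number of latent factors.
#' @param loading Primary loading magnitude, recycled over items; each item
#'   loads on exactly one factor (round-robin assignment).
#' @param phi_offdiag Common inter-factor correlation of `Phi_true`.
#' @param rater_bias_sd SD of the per (rater, item) additive bias.
#' @param rater_noise_sd SD of the per-observation rater noise.
#' @param missing_rater_prob Probability a (rater, subject) pair is skipped.
#' @param discretise Map scores to the 1-7 scale by fixed rounding
#'   thresholds (attenuates correlations); `FALSE` keeps continuous scores.
#' @param center_raters Subtract each rater's per-item mean (emulates raters
#'   mean-centering their own ratings).
#' @param cross_situation_rho Latent correlation between matched factors of
#'   the paired situations.
#' @param human_excluded_items Items omitted from the paired human-situation
#'   form; defaults to the catalog's eight exclusions when the items are the
#'   survey catalog, otherwise none.
#' @param seed RNG seed used by the generator.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(groups = tibble(
                               group = c("rhesus", "longtailed", "bonnet"),
                               n_subjects = c(150L, 101L, 77L),
                               n_raters = c(5L, 4L, 5L)),
                             items = GENERAL_ITEMS,
                             true_k = 5,
                             loading = 0.75,
                             phi_offdiag = 0.3,
                             rater_bias_sd = 0.5,
                             rater_noise_sd = 1.0,
                             missing_rater_prob = 0.1,
                             discretise = TRUE,
                             center_raters = FALSE,
                             cross_situation_rho = 0.7,
                             human_excluded_items = NULL,
                             seed = 1L) {
  p <- length(items)
  stopifnot(true_k >= 1, p >= true_k,
            missing_rater_prob >= 0, missing_rater_prob < 1,
            abs(cross_situation_rho) <= 1)
  lambda_mag <- rep_len(loading, p)
  primary <- rep_len(seq_len(true_k), p)
  Lambda <- matrix(0, p, true_k, dimnames = list(items, paste0("F", seq_len(true_k))))
  Lambda[cbind(seq_len(p), primary)] <- lambda_mag
  Phi <- matrix(phi_offdiag, true_k, true_k)
  diag(Phi) <- 1
  u2 <- 1 - lambda_mag^2   # simple structure: diag(Lambda Phi Lambda') = lambda^2
  if (any(u2 <= 0)) {
    stopf("ratefa_validation_error", "loading magnitude must be < 1 in the correlation metric")
  }
  if (is.null(human_excluded_items)) {
    human_excluded_items <-
      if (all(HUMAN_EXCLUDED_ITEMS %in% items)) HUMAN_EXCLUDED_ITEMS else character(0)
  }
  structure(list(groups = as_tibble(groups), items = items, true_k = true_k,
                 Lambda = Lambda, Phi = Phi, u2 = setNames(u2, items),
                 primary = setNames(primary, items),
                 rater_bias_sd = rater_bias_sd,
                 rater_noise_sd = rater_noise_sd,
                 missing_rater_prob = missing_rater_prob,
                 discretise = discretise, center_raters = center_raters,
                 cross_situation_rho = cross_situation_rho,
                 human_excluded_items = human_excluded_items,
                 seed = seed),
            class = "generator_config")
}

# latents: n x k matrix with correlation Phi
draw_latents <- function(n, Phi) {
  Chol <- chol(Phi)
  matrix(rnorm(n * nrow(Phi)), n, nrow(Phi)) %*% Chol
}

discretise_scores <- function(x) pmin(7, pmax(1, round(4 + x)))

# One site's ratings in long format, given subject latents.
simulate_site <- function(cfg, group, n_subjects, n_raters, latents,
                          situation = "general", items = cfg$items) {
  keep <- match(items, cfg$items)
  Lambda <- cfg$Lambda[keep, , drop = FALSE]
  u2 <- cfg$u2[keep]
  p <- length(items)
  subjects <- sprintf("%s_s%03d", group, seq_len(n_subjects))
  raters <- sprintf("%s_r%d", group, seq_len(n_raters))

  true_vals <- latents %*% t(Lambda) +
    matrix(rnorm(n_subjects * p), n_subjects, p) %*% diag(sqrt(u2), p)
  colnames(true_vals) <- items
  rownames(true_vals) <- subjects

  bias <- matrix(rnorm(n_raters * p, sd = cfg$rater_bias_sd), n_raters, p)
  skip <- matrix(stats::runif(n_raters * n_subjects) < cfg$missing_rater_prob,
                 n_subjects, n_raters)
  # keep every subject rated by at least one rater
  none <- rowSums(!skip) == 0
  skip[none, 1] <- FALSE

  recs <- vector("list", n_raters)
  for (r in seq_len(n_raters)) {
    rated <- which(!skip[, r])
    noise <- matrix(rnorm(length(rated) * p, sd = cfg$rater_noise_sd),
                    length(rated), p)
    scores <- true_vals[rated, , drop = FALSE] +
      matrix(bias[r, ], length(rated), p, byrow = TRUE) + noise
    if (cfg$discretise) scores <- discretise_scores(scores)
    if (cfg$center_raters) {
      scores <- sweep(scores, 2, colMeans(scores))
    }
    recs[[r]] <- tibble(
      site = group, situation = situation,
      rater = raters[r],
      subject = rep(subjects[rated], times = p),
      item = rep(items, each = length(rated)),
      score = as.vector(scores))
  }
  list(ratings = dplyr::bind_rows(recs), true_values = true_vals)
}

#' Generate a synthetic multi-group ratings dataset
#'
#' Subject latent factor scores are drawn with correlation `Phi_true`; each
#' item's true value is its loading times the latents plus a unique part
#' (unit total variance). Each rater's score adds a per (rater, item) bias
#' constant over subjects and independent noise, is optionally discretised
#' to the 1-7 scale, and (rater, subject) pairs are skipped at random.
#'
#' @param cfg A [generator_config()].
#' @return List with `ratings` (long tibble across all groups) and `truth`
#'   (per-group latents and true item values, the generating `Lambda`,
#'   `Phi`, `u2`, the expected single-rater ICC
#'   \eqn{1/(1+\sigma_n^2)}, and per-group item attenuation factors
#'   \eqn{\lambda_i^2/(1+\sigma_n^2/k)} for the continuous scale).
#' @export
generate_ratings_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(cfg$seed)
  }
  sims <- purrr::pmap(cfg$groups, function(group, n_subjects, n_raters) {
    latents <- draw_latents(n_subjects, cfg$Phi)
    rownames(latents) <- sprintf("%s_s%03d", group, seq_len(n_subjects))
    site <- simulate_site(cfg, group, n_subjects, n_raters, latents)
    list(group = group, latents = latents, true_values = site$true_values,
         ratings = site$ratings, n_raters = n_raters)
  })
  lambda_mag <- cfg$Lambda[cbind(seq_along(cfg$items), cfg$primary)]
  attenuation <- lapply(sims, function(s)
    setNames(lambda_mag^2 / (1 + cfg$rater_noise_sd^2 / s$n_raters), cfg$items))
  names(attenuation) <- cfg$groups$group
  truth <- list(
    Lambda = cfg$Lambda, Phi = cfg$Phi, u2 = cfg$u2,
    latents = setNames(lapply(sims, `[[`, "latents"), cfg$groups$group),
    true_values = setNames(lapply(sims, `[[`, "true_values"), cfg$groups$group),
    icc31_expected = 1 / (1 + cfg$rater_noise_sd^2),
    item_attenuation = attenuation,
    seed = cfg$seed)
  list(ratings = dplyr::bind_rows(lapply(sims, `[[`, "ratings")), truth = truth)
}

#' Generate paired general and human-situation datasets
#'
#' The two situations share subjects and raters; their latent factor scores
#' are drawn jointly so that matched factors correlate at
#' `cross_situation_rho` while each situation's factors keep correlation
#' `Phi_true`. Item unique parts are drawn independently per situation, and
#' the human form omits the configured excluded items.
#'
#' @param cfg A [generator_config()].
#' @return List with `general`, `human` (ratings tibbles) and `truth`
#'   (latents for both situations per group, generator parameters, and the
#'   per-item cross-situation correlation expected for mean ratings on the
#'   continuous scale,
#'   \eqn{\rho \lambda_i^2 / (1 + \sigma_n^2 / k)} per group).
#' @export
generate_paired_situation_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(cfg$seed)
  }
  rho <- cfg$cross_situation_rho
  human_items <- setdiff(cfg$items, cfg$human_excluded_items)
  sims <- purrr::pmap(cfg$groups, function(group, n_subjects, n_raters) {
    f_g <- draw_latents(n_subjects, cfg$Phi)
    f_h <- rho * f_g + sqrt(1 - rho^2) * draw_latents(n_subjects, cfg$Phi)
    subjects <- sprintf("%s_s%03d", group, seq_len(n_subjects))
    rownames(f_g) <- rownames(f_h) <- subjects
    gen <- simulate_site(cfg, group, n_subjects, n_raters, f_g,
                         situation = "general")
    hum <- simulate_site(cfg, group, n_subjects, n_raters, f_h,
                         situation = "human", items = human_items)
    list(group = group, f_general = f_g, f_human = f_h,
         general = gen$ratings, human = hum$ratings, n_raters = n_raters)
  })
  lambda_mag <- cfg$Lambda[cbind(seq_along(cfg$items), cfg$primary)]
  attenuated_r <- lapply(sims, function(s)
    setNames(rho * lambda_mag^2 / (1 + cfg$rater_noise_sd^2 / s$n_raters),
             cfg$items))
  names(attenuated_r) <- cfg$groups$group
  truth <- list(
    Lambda = cfg$Lambda, Phi = cfg$Phi, u2 = cfg$u2,
    cross_situation_rho = rho,
    latents_general = setNames(lapply(sims, `[[`, "f_general"), cfg$groups$group),
    latents_human = setNames(lapply(sims, `[[`, "f_human"), cfg$groups$group),
    expected_item_r = attenuated_r,
    seed = cfg$seed)
  list(general = dplyr::bind_rows(lapply(sims, `[[`, "general")),
       human = dplyr::bind_rows(lapply(sims, `[[`, "human")),
       truth = truth)
}
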