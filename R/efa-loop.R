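# The item-exclusion loop: MSA screen, factor-count vote, fit, communality
# screen, iterated to a fixed point.

#' Configuration for the factor-model fitting loop
#'
#' @param msa_threshold Items with MSA below this are dropped (default 0.50).
#' @param communality_bounds Items with communality at or below the first
#'   value, or at or above the second, are dropped (defaults 0.4 and 0.99).
#' @param residual_threshold Final-model adequacy check on
#'   \eqn{\sqrt{\sum_{i<j} \tilde r_{ij}^2}} (default 0.10); failing it
#'   warns rather than fails, since it is a confirmation.
#' @param k_max Largest candidate factor count for the vote.
#' @param n_parallel_iter Simulated datasets for parallel analysis.
#' @param freeze_k Keep the factor count from the first vote across loop
#'   iterations instead of re-voting after item drops.
#' @param k_override Fix the factor count, skipping the vote entirely.
#' @param max_iterations Cap on exclusion-loop passes.
#' @param seed Seed for the parallel-analysis simulations.
#' @return A list of class `efa_config`.
#' @export
efa_config <- function(msa_threshold = 0.50, communality_bounds = c(0.4, 0.99),
                       residual_threshold = 0.10, k_max = 8,
                       n_parallel_iter = 20, freeze_k = FALSE,
                       k_override = NULL, max_iterations = 10, seed = NULL) {
  stopifnot(msa_threshold >= 0, msa_threshold <= 1,
            length(communality_bounds) == 2,
            communality_bounds[1] < communality_bounds[2])
  structure(list(msa_threshold = msa_threshold,
                 communality_bounds = communality_bounds,
                 residual_threshold = residual_threshold,
                 k_max = k_max, n_parallel_iter = n_parallel_iter,
                 freeze_k = freeze_k, k_override = k_override,
                 max_iterations = max_iterations, seed = seed),
            class = "efa_config")
}

#' Fit a factor model with the item-exclusion loop
#'
#' Runs the full model-selection recipe on reliability-screened mean
#' ratings: (1) drop items with MSA below the threshold; (2) vote the factor
#' count by the median of parallel analysis, empirical BIC and VSS;
#' (3) fit minres + oblimin; (4) drop items with out-of-bounds communality;
#' (5) repeat until no item is dropped (or the iteration cap). The final
#' model is confirmed to have per-item MSA at or above the threshold and a
#' root mean square residual correlation below `residual_threshold`;
#' failures set `adequate = FALSE` with a warning (the checks are
#' confirmations, not hard failures).
#'
#' @param m Subjects-by-items matrix or aggregated ratings tibble, already
#'   reliability-screened.
#' @param config An [efa_config()].
#' @return A `factor_solution` whose `exclusions` log carries stages
#'   `"Low MSA"`, `"Low Communality"`, `"High Communality"`, and whose
#'   `vote` records the (last) factor-count vote.
#' @export
fit_rating_model <- function(m, config = efa_config()) {
  if (is.data.frame(m) && all(c("subject", "item", "score") %in% names(m))) {
    m <- ratings_matrix(m)
  }
  m <- as.matrix(m)
  exclusions <- tibble(item = character(), stage = character(),
                       statistic = numeric(), threshold = numeric())
  vote <- NULL
  frozen_k <- config$k_override
  solution <- NULL

  for (pass in seq_len(config$max_iterations)) {
    dropped <- FALSE
    cm <- correlation_model(m)

    adequacy <- kmo(cm)
    low_msa <- adequacy$msa[!is.na(adequacy$msa$msa) &
                            adequacy$msa$msa < config$msa_threshold, ]
    if (nrow(low_msa) > 0) {
      exclusions <- dplyr::bind_rows(exclusions, tibble(
        item = low_msa$item, stage = "Low MSA", statistic = low_msa$msa,
        threshold = config$msa_threshold))
      m <- m[, setdiff(colnames(m), low_msa$item), drop = FALSE]
      cm <- correlation_model(m)
      dropped <- TRUE
    }

    if (is.null(frozen_k) || (!config$freeze_k && is.null(config$k_override))) {
      k_max <- min(config$k_max, floor((ncol(m) - 1) / 2))
      kp <- n_factors_parallel(m, n_iter = config$n_parallel_iter,
                               seed = config$seed)$k
      kp <- max(1L, min(kp, k_max))
      survey <- survey_factor_counts(cm, k_max)
      eligible <- which(survey$df > 0)
      ke <- survey$k[eligible[which.min(survey$ebic[eligible])]]
      kv <- survey$k[which.max(survey$vss)]
      vote <- choose_n_factors(kp, ke, kv)
      k <- vote$k_chosen
      if (config$freeze_k && is.null(frozen_k)) frozen_k <- k
    } else {
      k <- frozen_k
      if (is.null(vote)) {
        vote <- tibble(k_parallel = NA_integer_, k_ebic = NA_integer_,
                       k_vss = NA_integer_, k_chosen = as.integer(k))
      }
    }

    if (ncol(m) < 3 * k) {
      stopf("ratefa_validation_error",
            "under-identified: %d items remaining for k = %d factors",
            ncol(m), k)
    }

    solution <- fit_efa(cm, k, vote = vote)

    h2 <- solution$h2
    low <- h2 <= config$communality_bounds[1]
    high <- h2 >= config$communality_bounds[2]
    if (any(low | high)) {
      exclusions <- dplyr::bind_rows(
        exclusions,
        tibble(item = names(h2)[low], stage = "Low Communality",
               statistic = unname(h2[low]),
               threshold = config$communality_bounds[1]),
        tibble(item = names(h2)[high], stage = "High Communality",
               statistic = unname(h2[high]),
               threshold = config$communality_bounds[2]))
      m <- m[, names(h2)[!(low | high)], drop = FALSE]
      dropped <- TRUE
      next
    }
    if (!dropped) break
  }

  final_msa <- solution$msa$msa
  adequate <- all(final_msa >= config$msa_threshold, na.rm = TRUE) &&
    solution$fit$rmsr < config$residual_threshold
  if (!adequate) {
    warn(sprintf(
      "final model adequacy check failed (min MSA %.3f, RMSR %.3f)",
      min(final_msa, na.rm = TRUE), solution$fit$rmsr))
  }
  solution$adequate <- adequate
  solution$exclusions <- exclusions
  solution$vote <- vote
  solution
}
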