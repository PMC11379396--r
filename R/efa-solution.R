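# Rotated factor solutions and their fit statistics.

#' Model fit statistics for a rotated solution
#'
#' Residuals are taken against the oblique reproduced matrix
#' \eqn{\Lambda \Phi \Lambda' + diag(u^2)}; both the plain RMSR (mean square
#' over the p(p-1)/2 off-diagonal cells) and the degrees-of-freedom
#' corrected version (dividing by the model df) are reported, along with
#' standardised alpha, total omega
#' (\eqn{1 - \sum u^2_i / \sum_{ij} R_{ij}}) and per-factor explained
#' variance from \eqn{diag(\Phi \Lambda' \Lambda)}.
#'
#' @param cm A `cor_model`.
#' @param loadings Pattern matrix.
#' @param Phi Factor correlation matrix.
#' @param u2 Uniquenesses.
#' @return List: `rmsr`, `rmsr_df_corrected` (`NA` with a flag when
#'   `df <= 0`), `root_sum_squares` (the square root of the summed squared
#'   off-diagonal residuals), `echisq`, `df`, `alpha`, `omega_total`, and a
#'   `variance` tibble (`factor`, `ss`, `proportion`, `cumulative`).
#' @export
model_fit_stats <- function(cm, loadings, Phi, u2) {
  cm <- as_cor_model(cm)
  R <- cm$R
  p <- nrow(R)
  k <- ncol(loadings)
  model <- loadings %*% Phi %*% t(loadings) + diag(u2, p)
  resid <- R - model
  ss_resid <- sum(resid[lower.tri(resid)]^2)
  n_off <- p * (p - 1) / 2
  df <- p * (p - 1) / 2 - p * k + k * (k - 1) / 2
  rmsr <- sqrt(ss_resid / n_off)
  rmsr_df <- if (df > 0) sqrt(ss_resid / df) else NA_real_
  alpha <- (p / (p - 1)) * (1 - p / sum(R))
  omega_total <- 1 - sum(u2) / sum(R)
  ss <- diag(Phi %*% crossprod(loadings))
  variance <- tibble(
    factor = colnames(loadings) %||% paste0("F", seq_len(k)),
    ss = unname(ss),
    proportion = unname(ss) / p)
  variance$cumulative <- cumsum(variance$proportion)
  list(rmsr = rmsr, rmsr_df_corrected = rmsr_df,
       root_sum_squares = sqrt(ss_resid),
       echisq = cm$n * ss_resid, df = df,
       alpha = alpha, omega_total = omega_total, variance = variance)
}

#' Fit a rotated exploratory factor model
#'
#' Minres extraction followed by oblimin rotation, packaged with
#' communalities, sampling adequacy and fit statistics.
#'
#' @param cm A `cor_model`.
#' @param k Number of factors.
#' @param vote Optional factor-count vote tibble to carry in the result.
#' @param ... Passed to [rotate_oblimin()].
#' @return A `factor_solution` object.
#' @export
fit_efa <- function(cm, k, vote = NULL, ...) {
  cm <- as_cor_model(cm)
  mr <- fit_minres(cm, k)
  rot <- rotate_oblimin(mr$loadings, ...)
  h2 <- 1 - mr$u2
  stats <- model_fit_stats(cm, rot$loadings, rot$Phi, mr$u2)
  msa_tbl <- kmo(cm)
  structure(list(
    items = cm$items, k = as.integer(k),
    loadings = rot$loadings, Phi = rot$Phi,
    h2 = h2, u2 = mr$u2,
    msa = msa_tbl$msa, kmo_overall = msa_tbl$overall,
    fit = stats, objective = mr$objective, heywood = mr$heywood,
    vote = vote, n = cm$n, R = cm$R,
    exclusions = tibble(item = character(), stage = character(),
                        statistic = numeric(), threshold = numeric()),
    adequate = NA), class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> %d items, %d factors, n = %d\n",
              length(x$items), x$k, x$n))
  cat(sprintf("  cumulative variance %.2f | RMSR %.3f (df-corrected %s) | alpha %.2f | omega_total %.2f\n",
              max(x$fit$variance$cumulative), x$fit$rmsr,
              ifelse(is.na(x$fit$rmsr_df_corrected), "NA",
                     sprintf("%.3f", x$fit$rmsr_df_corrected)),
              x$fit$alpha, x$fit$omega_total))
  if (nrow(x$exclusions) > 0) {
    cat(sprintf("  %d item(s) excluded during fitting\n", nrow(x$exclusions)))
  }
  invisible(x)
}

#' Tidy a factor solution into long loadings
#'
#' @param x A `factor_solution`.
#' @param ... Unused.
#' @return A tibble `item`, `factor`, `loading`, `h2`, `u2`, `msa`.
#' @export
tidy.factor_solution <- function(x, ...) {
  long <- as_tibble(x$loadings, rownames = "item") |>
    tidyr::pivot_longer(-"item", names_to = "factor", values_to = "loading")
  meta <- tibble(item = x$items, h2 = unname(x$h2), u2 = unname(x$u2)) |>
    dplyr::left_join(x$msa, by = "item")
  dplyr::left_join(long, meta, by = "item")
}

#' One-row fit summary of a factor solution
#'
#' @param x A `factor_solution`.
#' @param ... Unused.
#' @export
glance.factor_solution <- function(x, ...) {
  tibble(n_items = length(x$items), k = x$k, n = x$n,
         cumulative_variance = max(x$fit$variance$cumulative),
         rmsr = x$fit$rmsr, rmsr_df_corrected = x$fit$rmsr_df_corrected,
         root_sum_squares = x$fit$root_sum_squares,
         alpha = x$fit$alpha, omega_total = x$fit$omega_total,
         mean_h2 = mean(x$h2), kmo = x$kmo_overall,
         heywood = x$heywood, adequate = x$adequate)
}

#' Loading heatmap for a factor solution
#'
#' @param object A `factor_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.factor_solution <- function(object, ...) {
  df <- tidy(object)
  df$item <- factor(df$item, levels = rev(object$items))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$item,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal(base_size = 9)
}
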