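# ten Berge correlation-preserving factor scores and cross-situation
# score correlations.

#' ten Berge factor scores
#'
#' Correlation-preserving factor score estimates: with standardised data
#' `Z`, pattern matrix \eqn{\Lambda}, factor correlations \eqn{\Phi} and
#' item correlations `R`,
#' \deqn{L = \Lambda \Phi^{1/2}, \quad
#'       C = R^{-1/2} L (L' R^{-1} L)^{-1/2}, \quad
#'       W = R^{-1/2} C \Phi^{1/2}, \quad S = Z W.}
#' The correlation matrix of the score columns equals \eqn{\Phi} (the
#' method's defining property). Subjects with any missing item value are
#' excluded and listed in the `dropped_subjects` attribute.
#'
#' @param m Subjects-by-items matrix or aggregated ratings tibble covering
#'   the solution's items.
#' @param solution A `factor_solution` fitted on these items.
#' @param ridge Regularisation added to a non-positive-definite `R`
#'   (flagged via the `ridged` attribute).
#' @return A `score_matrix` tibble: `subject` plus one column per factor.
#' @export
tenberge_scores <- function(m, solution, ridge = 1e-8) {
  if (is.data.frame(m) && all(c("subject", "item", "score") %in% names(m))) {
    m <- ratings_matrix(m)
  }
  m <- as.matrix(m)
  key_cols <- item_key(colnames(m))
  idx <- match(item_key(solution$items), key_cols)
  if (anyNA(idx)) {
    stopf("ratefa_validation_error", "ratings lack solution item(s): %s",
          paste(solution$items[is.na(idx)], collapse = ", "))
  }
  m <- m[, idx, drop = FALSE]
  complete <- stats::complete.cases(m)
  dropped <- rownames(m)[!complete]
  if (length(dropped) > 0) {
    inform(sprintf("%d subject(s) dropped for missing item values: %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  m <- m[complete, , drop = FALSE]
  Z <- scale(m)
  R <- cor(m)
  ridged <- FALSE
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10) {
    R <- R + diag(ridge + abs(ev_min), nrow(R))
    R <- stats::cov2cor(R)
    ridged <- TRUE
  }
  Lambda <- solution$loadings
  Phi <- solution$Phi
  Phi_half <- mat_power(Phi, 0.5)
  R_inv_half <- mat_power(R, -0.5)
  R_inv <- mat_power(R, -1)
  L <- Lambda %*% Phi_half
  C <- R_inv_half %*% L %*% mat_power(crossprod(L, R_inv %*% L), -0.5)
  W <- R_inv_half %*% C %*% Phi_half
  S <- Z %*% W
  colnames(S) <- colnames(Lambda)
  out <- as_tibble(S)
  out <- dplyr::bind_cols(tibble(subject = rownames(m) %||%
                                   as.character(seq_len(nrow(m)))), out)
  attr(out, "method") <- "tenberge"
  attr(out, "weights") <- W
  attr(out, "dropped_subjects") <- dropped
  attr(out, "ridged") <- ridged
  class(out) <- c("score_matrix", class(out))
  out
}

#' Correlate factor scores across two solutions
#'
#' Pearson correlations between every pair of score columns on the shared
#' subjects, with two-sided p-values (uncorrected) and conventional star
#' annotations.
#'
#' @param a,b `score_matrix` tibbles sharing subject ids (e.g. general and
#'   human-situation scores).
#' @return A tibble `factor_a`, `factor_b`, `r`, `p`, `n`, `stars`.
#'   Zero-variance columns give `NA` with a note.
#' @export
score_correlations <- function(a, b) {
  shared <- dplyr::inner_join(as_tibble(a), as_tibble(b), by = "subject",
                              suffix = c("_a", "_b"))
  if (nrow(shared) < 3) {
    stopf("ratefa_validation_error", "fewer than 3 shared subjects")
  }
  fac_a <- setdiff(names(a), "subject")
  fac_b <- setdiff(names(b), "subject")
  col_a <- ifelse(fac_a %in% fac_b, paste0(fac_a, "_a"), fac_a)
  col_b <- ifelse(fac_b %in% fac_a, paste0(fac_b, "_b"), fac_b)
  grid <- tidyr::expand_grid(ia = seq_along(fac_a), ib = seq_along(fac_b))
  n <- nrow(shared)
  purrr::pmap_dfr(grid, function(ia, ib) {
    x <- shared[[col_a[ia]]]
    y <- shared[[col_b[ib]]]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(factor_a = fac_a[ia], factor_b = fac_b[ib], r = NA_real_,
                    p = NA_real_, n = n, stars = "",
                    note = "zero variance"))
    }
    r <- cor(x, y)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    tibble(factor_a = fac_a[ia], factor_b = fac_b[ib], r = r, p = p, n = n,
           stars = dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                                    p < 0.05 ~ "*", TRUE ~ ""),
           note = NA_character_)
  })
}
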