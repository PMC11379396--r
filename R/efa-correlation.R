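# Correlation model and sampling adequacy.

#' Pearson correlation model of aggregated ratings
#'
#' Pairwise-complete Pearson correlations of the item columns, with the
#' effective sample size recorded as the minimum pairwise count.
#'
#' @param m Subjects-by-items numeric matrix (see [ratings_matrix()]) or an
#'   aggregated ratings tibble (see [aggregate_ratings()]).
#' @return A `cor_model` object: list with `R` (correlation matrix), `n`
#'   (minimum pairwise n), `items`.
#' @export
correlation_model <- function(m) {
  if (is.data.frame(m) && all(c("subject", "item", "score") %in% names(m))) {
    m <- ratings_matrix(m)
  }
  m <- as.matrix(m)
  if (nrow(m) < 3) {
    stopf("ratefa_validation_error", "need >= 3 subjects, got %d", nrow(m))
  }
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    stopf("ratefa_validation_error", "constant or empty item column(s): %s",
          paste(colnames(m)[sds == 0 | is.na(sds)], collapse = ", "))
  }
  R <- cor(m, use = "pairwise.complete.obs")
  n_pair <- crossprod(!is.na(m))
  structure(list(R = R, n = min(n_pair[lower.tri(n_pair, diag = TRUE)]),
                 items = colnames(m)),
            class = "cor_model")
}

#' @export
print.cor_model <- function(x, ...) {
  cat(sprintf("<cor_model> %d items, n = %d\n", length(x$items), x$n))
  invisible(x)
}

as_cor_model <- function(x) {
  if (inherits(x, "cor_model")) return(x)
  if (is.matrix(x) && isSymmetric(unname(x)) &&
      all(abs(diag(x) - 1) < 1e-8)) {
    stopf("ratefa_validation_error",
          "pass a cor_model (with its n); a bare correlation matrix has no sample size")
  }
  correlation_model(x)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Per-item MSA and the overall KMO index, from the anti-image partial
#' correlations \eqn{q_{jk}} obtained from the inverse correlation matrix:
#' \deqn{MSA_j = \sum_{k \ne j} r_{jk}^2 / (\sum_{k \ne j} r_{jk}^2 +
#'   \sum_{k \ne j} q_{jk}^2)}
#'
#' @param cm A `cor_model`.
#' @param ridge_fallback Ridge-regularise a singular correlation matrix
#'   (flagged in the result) instead of failing.
#' @return List with `msa` (tibble `item`, `msa`), `overall`, `ridged`.
#'   An identity correlation matrix yields `NaN` (0/0) MSAs, reported as is.
#' @export
kmo <- function(cm, ridge_fallback = TRUE) {
  cm <- as_cor_model(cm)
  R <- cm$R
  inv <- tryCatch(solve(R), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(inv)) {
    if (!ridge_fallback) {
      stopf("ratefa_validation_error", "singular correlation matrix")
    }
    inv <- solve(R + diag(1e-4, nrow(R)))
    ridged <- TRUE
  }
  # anti-image partial correlations
  q <- -inv / sqrt(outer(diag(inv), diag(inv)))
  diag(q) <- 0
  r2 <- R^2; diag(r2) <- 0
  q2 <- q^2
  msa <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  overall <- sum(r2) / (sum(r2) + sum(q2))
  list(msa = tibble(item = cm$items, msa = unname(msa)),
       overall = overall, ridged = ridged)
}
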