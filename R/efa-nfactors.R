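# Factor-count diagnostics: parallel analysis, very simple structure,
# empirical BIC, and the median vote.

reduced_eigenvalues <- function(R) {
  Rr <- R
  diag(Rr) <- smc(R)
  eigen(Rr, symmetric = TRUE, only.values = TRUE)$values
}

#' Horn parallel analysis (common-factor form)
#'
#' Counts the leading eigenvalues of the reduced correlation matrix (squared
#' multiple correlations on the diagonal) that exceed the mean of eigenvalues
#' obtained from `n_iter` random standard-normal datasets of the same shape,
#' processed identically.
#'
#' @param m Subjects-by-items data matrix or aggregated ratings tibble.
#' @param n_iter Number of simulated datasets.
#' @param seed Optional RNG seed.
#' @return List: `k` and an `eigen` tibble (`index`, `observed`,
#'   `random_mean`).
#' @export
n_factors_parallel <- function(m, n_iter = 20, seed = NULL) {
  if (is.data.frame(m) && all(c("subject", "item", "score") %in% names(m))) {
    m <- ratings_matrix(m)
  }
  m <- as.matrix(m)
  n <- nrow(m)
  p <- ncol(m)
  if (n < 20) {
    stopf("ratefa_validation_error", "parallel analysis needs n >= 20, got %d", n)
  }
  obs <- reduced_eigenvalues(cor(m, use = "pairwise.complete.obs"))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  sims <- vapply(seq_len(n_iter), function(i) {
    reduced_eigenvalues(cor(matrix(rnorm(n * p), n, p)))
  }, numeric(p))
  rand_mean <- rowMeans(sims)
  above <- obs > rand_mean
  first_fail <- which(!above)
  k <- if (length(first_fail) == 0) p else first_fail[1] - 1L
  list(k = as.integer(k),
       eigen = tibble(index = seq_len(p), observed = obs, random_mean = rand_mean))
}

#' Very simple structure criterion (complexity 1)
#'
#' For each candidate k, fits a minres + oblimin model, simplifies the
#' pattern matrix to its largest-absolute loading per item (all others set
#' to zero), and measures how well the simplified model reproduces the
#' off-diagonal correlations:
#' \deqn{VSS_k = 1 - \sum_{i<j} \tilde r_{ij}^2 / \sum_{i<j} r_{ij}^2}
#'
#' @param cm A `cor_model`.
#' @param k_max Largest k to evaluate (must be `< p / 2`).
#' @return List: `k` (argmax) and `table` (`k`, `vss`).
#' @export
n_factors_vss <- function(cm, k_max) {
  cm <- as_cor_model(cm)
  R <- cm$R
  p <- nrow(R)
  if (k_max >= p / 2) {
    stopf("ratefa_validation_error", "k_max must be < items/2")
  }
  denom <- sum(R[lower.tri(R)]^2)
  vss <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    fit <- tryCatch({
      mr <- fit_minres(cm, k)
      rot <- rotate_oblimin(mr$loadings)
      list(L = rot$loadings, Phi = rot$Phi)
    }, ratefa_convergence_error = function(e) NULL)
    if (is.null(fit)) {
      warn(sprintf("VSS: fit at k = %d did not converge; skipped", k))
      next
    }
    keep <- max.col(abs(fit$L), ties.method = "first")
    Ls <- matrix(0, p, ncol(fit$L))
    Ls[cbind(seq_len(p), keep)] <- fit$L[cbind(seq_len(p), keep)]
    model <- Ls %*% fit$Phi %*% t(Ls)
    resid <- R - model
    vss[k] <- 1 - sum(resid[lower.tri(resid)]^2) / denom
  }
  list(k = as.integer(which.max(vss)), table = tibble(k = seq_len(k_max), vss = vss))
}

#' Empirical BIC for the factor count
#'
#' Scores each candidate k by a residual-correlation chi-square with a BIC
#' penalty: \eqn{eBIC_k = n \sum_{i<j} \tilde r_{ij}^2 - df_k \ln n}, with
#' \eqn{df_k = p(p-1)/2 - pk + k(k-1)/2}. The minimiser over k with
#' positive degrees of freedom is returned. Residuals come from the
#' unrotated minres fit (rotation leaves them unchanged).
#'
#' @param cm A `cor_model`.
#' @param k_max Largest k to evaluate.
#' @return List: `k` (argmin) and `table` (`k`, `echisq`, `df`, `ebic`).
#' @export
n_factors_ebic <- function(cm, k_max) {
  cm <- as_cor_model(cm)
  R <- cm$R
  n <- cm$n
  p <- nrow(R)
  ks <- seq_len(k_max)
  df <- p * (p - 1) / 2 - p * ks + ks * (ks - 1) / 2
  if (all(df <= 0)) {
    stopf("ratefa_validation_error", "all candidate k have non-positive degrees of freedom")
  }
  echisq <- vapply(ks, function(k) {
    fit <- fit_minres(cm, k)
    resid <- R - tcrossprod(fit$loadings)
    n * sum(resid[lower.tri(resid)]^2)
  }, numeric(1))
  ebic <- echisq - df * log(n)
  eligible <- which(df > 0)
  k <- eligible[which.min(ebic[eligible])]
  list(k = as.integer(k),
       table = tibble(k = ks, echisq = echisq, df = df, ebic = ebic))
}

# Shared survey over candidate k: one minres (+ oblimin for VSS) fit per k,
# feeding both the empirical BIC and the VSS criteria.
survey_factor_counts <- function(cm, k_max) {
  cm <- as_cor_model(cm)
  R <- cm$R
  n <- cm$n
  p <- nrow(R)
  denom <- sum(R[lower.tri(R)]^2)
  ks <- seq_len(k_max)
  df <- p * (p - 1) / 2 - p * ks + ks * (ks - 1) / 2
  echisq <- vss <- rep(NA_real_, k_max)
  for (k in ks) {
    mr <- fit_minres(cm, k)
    resid <- R - tcrossprod(mr$loadings)
    echisq[k] <- n * sum(resid[lower.tri(resid)]^2)
    rot <- tryCatch(rotate_oblimin(mr$loadings),
                    ratefa_convergence_error = function(e) NULL)
    if (is.null(rot)) {
      warn(sprintf("VSS: rotation at k = %d did not converge; skipped", k))
      next
    }
    keep <- max.col(abs(rot$loadings), ties.method = "first")
    Ls <- matrix(0, p, k)
    Ls[cbind(seq_len(p), keep)] <- rot$loadings[cbind(seq_len(p), keep)]
    model <- Ls %*% rot$Phi %*% t(Ls)
    resid_s <- R - model
    vss[k] <- 1 - sum(resid_s[lower.tri(resid_s)]^2) / denom
  }
  tibble(k = ks, echisq = echisq, df = df, ebic = echisq - df * log(n),
         vss = vss)
}

#' Median vote over the three factor-count diagnostics
#'
#' @param k_parallel,k_ebic,k_vss Integer estimates from the three
#'   diagnostics.
#' @return A one-row tibble `k_parallel`, `k_ebic`, `k_vss`, `k_chosen`
#'   (the median of the three).
#' @export
choose_n_factors <- function(k_parallel, k_ebic, k_vss) {
  ks <- c(k_parallel, k_ebic, k_vss)
  stopifnot(length(ks) == 3, all(ks == round(ks)))
  tibble(k_parallel = as.integer(k_parallel), k_ebic = as.integer(k_ebic),
         k_vss = as.integer(k_vss), k_chosen = as.integer(median(ks)))
}
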