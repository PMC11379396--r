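# Minimum-residual factor extraction and quartimin (oblimin, gamma = 0)
# rotation by gradient projection.

# Loadings from a reduced correlation matrix given uniquenesses:
# leading-k eigenpairs of R - diag(u2), negative eigenvalues clipped.
minres_loadings <- function(R, u2, k) {
  Rr <- R
  diag(Rr) <- 1 - u2
  e <- eigen(Rr, symmetric = TRUE)
  vals <- pmax(e$values[seq_len(k)], 0)
  L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
  rownames(L) <- rownames(R)
  L
}

minres_objective <- function(u2, R, k) {
  L <- minres_loadings(R, u2, k)
  resid <- R - tcrossprod(L)
  sum(resid[lower.tri(resid)]^2)
}

# Profile ULS criterion: sum of squared eigenvalues beyond k of
# R - diag(u2). Its gradient in u2 is -2 * diag of the truncated residual;
# at an interior optimum the diagonal residual vanishes, making this equal
# to the off-diagonal-only criterion.
minres_fn <- function(u2, R, k) {
  p <- nrow(R)
  Rr <- R
  diag(Rr) <- 1 - u2
  d <- eigen(Rr, symmetric = TRUE, only.values = TRUE)$values
  sum(d[(k + 1):p]^2)
}

minres_gr <- function(u2, R, k) {
  p <- nrow(R)
  Rr <- R
  diag(Rr) <- 1 - u2
  e <- eigen(Rr, symmetric = TRUE)
  idx <- (k + 1):p
  -2 * as.vector((e$vectors[, idx, drop = FALSE]^2) %*% e$values[idx])
}

# Deterministic column convention: order by explained sum of squares
# (descending), sign so that each column sums to a non-negative value.
normalise_columns <- function(L, Phi = NULL) {
  ss <- if (is.null(Phi)) colSums(L^2) else diag(Phi %*% crossprod(L))
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  if (!is.null(Phi)) Phi <- Phi[ord, ord, drop = FALSE]
  signs <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, signs, `*`)
  if (!is.null(Phi)) Phi <- diag(signs, ncol(L)) %*% Phi %*% diag(signs, ncol(L))
  list(loadings = L, Phi = Phi, order = ord, signs = signs)
}

#' Minimum-residual factor extraction
#'
#' Fits an unrotated k-factor model by minimising the sum of squared
#' off-diagonal residuals of \eqn{R - \Lambda\Lambda'} over the
#' uniquenesses (minres / ULS). Given uniquenesses, the loadings are the
#' leading eigenpairs of the reduced correlation matrix; the profile
#' objective is minimised with box-constrained quasi-Newton iterations from
#' a squared-multiple-correlation start.
#'
#' @param cm A `cor_model`.
#' @param k Number of factors, `>= 1`.
#' @param heywood_floor Lower bound for uniquenesses; solutions touching it
#'   are flagged as Heywood cases.
#' @return List: `loadings` (columns ordered by explained variance, signs
#'   normalised to non-negative column sums), `u2`, `objective`, `heywood`,
#'   `converged`, `iterations`.
#' @export
fit_minres <- function(cm, k, heywood_floor = 0.001) {
  cm <- as_cor_model(cm)
  R <- cm$R
  p <- nrow(R)
  stopifnot(k >= 1, k < p)
  df_k <- p * (p - 1) / 2 - p * k + k * (k - 1) / 2
  if (df_k < 0) {
    stopf("ratefa_validation_error", "k = %d gives negative degrees of freedom for p = %d", k, p)
  }
  start <- pmin(pmax(1 - smc(R), heywood_floor), 1)
  opt <- stats::optim(start, minres_fn, gr = minres_gr, R = R, k = k,
                      method = "L-BFGS-B", lower = heywood_floor, upper = 1,
                      control = list(maxit = 1000, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 52) {
    stopf("ratefa_convergence_error",
          "minres did not converge (code %d: %s) after %d evaluations",
          opt$convergence, opt$message %||% "", opt$counts[1])
  }
  u2 <- opt$par
  heywood <- any(u2 <= heywood_floor + 1e-8)
  if (heywood) {
    warn("Heywood case: uniqueness clamped at the lower bound")
  }
  L <- minres_loadings(R, u2, k)
  L <- normalise_columns(L)$loadings
  colnames(L) <- paste0("F", seq_len(k))
  resid <- R - tcrossprod(L)
  list(loadings = L, u2 = setNames(u2, cm$items),
       objective = sum(resid[lower.tri(resid)]^2),
       heywood = heywood, converged = TRUE, iterations = unname(opt$counts[1]))
}

vgq_quartimin <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  M <- matrix(1, k, k) - diag(k)
  X <- L2 %*% M
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

random_orthogonal <- function(k) {
  qr_d <- qr(matrix(rnorm(k * k), k, k))
  Q <- qr.Q(qr_d)
  Q %*% diag(sign(diag(qr.R(qr_d))), k)
}

gpa_oblq <- function(A, Tmat, eps = 1e-6, maxit = 1000) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- vgq_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    trace <- c(trace, f)
    if (s < eps) {
      converged <- TRUE
      break
    }
    al <- 2 * al
    for (i in 0:10) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vg <- vgq_quartimin(L)
      if (vg$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vg$f
    G <- -t(t(L) %*% vg$Gq %*% Ti)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, criterion = f,
       converged = converged, trace = trace)
}

#' Oblimin (quartimin) rotation
#'
#' Oblique rotation of an unrotated loading matrix by gradient projection on
#' the quartimin criterion (oblimin with gamma = 0), started from the
#' identity. Optional seeded random orthogonal restarts keep the best
#' criterion value. Column order and signs follow the same convention as
#' [fit_minres()].
#'
#' @param loadings Unrotated items-by-k loading matrix.
#' @param n_starts Number of starts; the first is always the identity.
#' @param seed Optional seed for the random restarts.
#' @param maxit,eps Iteration cap and gradient-norm tolerance.
#' @return List: `loadings` (pattern matrix), `Phi` (factor correlations),
#'   `criterion`, `converged`. For `k = 1` the input is returned with
#'   `Phi = 1`.
#' @export
rotate_oblimin <- function(loadings, n_starts = 1, seed = NULL,
                           maxit = 1000, eps = 1e-5) {
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (k == 1) {
    nc <- normalise_columns(A, matrix(1, 1, 1))
    return(list(loadings = nc$loadings, Phi = matrix(1, 1, 1,
                dimnames = list(colnames(A), colnames(A))),
                criterion = 0, converged = TRUE))
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    Tmat <- if (s == 1) diag(k) else random_orthogonal(k)
    res <- gpa_oblq(A, Tmat, eps = eps, maxit = maxit)
    if (is.null(best) || res$criterion < best$criterion) best <- res
  }
  if (!best$converged) {
    stopf("ratefa_convergence_error",
          "oblimin rotation did not converge in %d iterations (criterion trace tail: %s)",
          maxit, paste(signif(utils::tail(best$trace, 3), 6), collapse = ", "))
  }
  nc <- normalise_columns(best$loadings, best$Phi)
  L <- nc$loadings
  Phi <- nc$Phi
  colnames(L) <- paste0("F", seq_len(k))
  dimnames(Phi) <- list(colnames(L), colnames(L))
  rownames(L) <- rownames(A)
  list(loadings = L, Phi = Phi, criterion = best$criterion, converged = TRUE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
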