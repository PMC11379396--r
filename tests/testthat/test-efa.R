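test_that("correlation model matches a direct-sum oracle", {
  withr::local_seed(31)
  m <- matrix(rnorm(20), 4, 5)
  colnames(m) <- paste0("i", 1:5)
  cm <- correlation_model(m)
  # hand-coded covariance / sd oracle
  for (a in 1:4) for (b in 1:5) {
    xa <- m[, a]; xb <- m[, b]
    num <- sum((xa - mean(xa)) * (xb - mean(xb)))
    den <- sqrt(sum((xa - mean(xa))^2) * sum((xb - mean(xb))^2))
    expect_equal(cm$R[a, b], num / den, tolerance = 1e-12)
  }
  m2 <- cbind(m, dup = m[, 1], neg = -m[, 1])
  cm2 <- correlation_model(m2)
  expect_equal(cm2$R["i1", "dup"], 1)
  expect_equal(cm2$R["i1", "neg"], -1)
  m3 <- cbind(m, const = 1)
  expect_error(correlation_model(m3), class = "ratefa_validation_error")
})

test_that("MSA reduces to 0.5 for two items and matches a partials oracle", {
  R2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2, dimnames = list(NULL, c("a", "b")))
  cm2 <- structure(list(R = R2, n = 50L, items = c("a", "b")),
                   class = "cor_model")
  expect_equal(kmo(cm2)$msa$msa, c(0.5, 0.5))

  # identity correlations: MSA is 0/0
  RI <- diag(3); dimnames(RI) <- list(NULL, c("a", "b", "c"))
  cmI <- structure(list(R = RI, n = 50L, items = c("a", "b", "c")),
                   class = "cor_model")
  expect_true(all(is.nan(kmo(cmI)$msa$msa)))

  # partial-correlation oracle via regression residuals
  withr::local_seed(37)
  x <- latent_item_matrix(200, 6, 2)$x
  cm <- correlation_model(x)
  res <- kmo(cm)
  p <- ncol(x)
  for (j in 1:p) {
    r2 <- q2 <- 0
    for (k in setdiff(1:p, j)) {
      others <- setdiff(1:p, c(j, k))
      rj <- stats::lm.fit(cbind(1, x[, others]), x[, j])$residuals
      rk <- stats::lm.fit(cbind(1, x[, others]), x[, k])$residuals
      q2 <- q2 + cor(rj, rk)^2
      r2 <- r2 + cm$R[j, k]^2
    }
    expect_equal(res$msa$msa[j], r2 / (r2 + q2), tolerance = 1e-10)
  }
})

test_that("minres recovers closed-form and degenerate solutions", {
  R <- matrix(0.49, 3, 3); diag(R) <- 1
  colnames(R) <- rownames(R) <- paste0("i", 1:3)
  cm <- structure(list(R = R, n = 100L, items = colnames(R)),
                  class = "cor_model")
  fit <- fit_minres(cm, 1)
  expect_equal(unname(fit$loadings[, 1]), rep(0.7, 3), tolerance = 1e-6)

  RI <- diag(4); colnames(RI) <- rownames(RI) <- paste0("i", 1:4)
  cmI <- structure(list(R = RI, n = 100L, items = colnames(RI)),
                   class = "cor_model")
  fitI <- fit_minres(cmI, 1)
  expect_lt(max(abs(fitI$loadings)), 1e-4)
  expect_lt(fitI$objective, 1e-8)
})

test_that("minres objective matches a derivative-free oracle", {
  withr::local_seed(41)
  oracle_obj <- function(u2, R, k) {
    # independent implementation: eigen truncation + explicit loops
    Rr <- R; diag(Rr) <- 1 - u2
    e <- eigen(Rr, symmetric = TRUE)
    ev <- pmax(e$values[1:k], 0)
    L <- e$vectors[, 1:k, drop = FALSE] %*% diag(sqrt(ev), k)
    tot <- 0
    for (i in 2:nrow(R)) for (j in 1:(i - 1)) {
      tot <- tot + (R[i, j] - sum(L[i, ] * L[j, ]))^2
    }
    tot
  }
  for (rep in 1:3) {
    x <- latent_item_matrix(150, 8, 2)$x
    cm <- correlation_model(x)
    fit <- fit_minres(cm, 2)
    # random multi-start + Nelder-Mead polish, derivative-free
    best <- Inf
    for (s in 1:20) {
      start <- pmin(pmax(stats::runif(8, 0.05, 0.95), 0.001), 1)
      o <- stats::optim(start, oracle_obj, R = cm$R, k = 2,
                        method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
      best <- min(best, o$value)
    }
    polish <- stats::optim(fit$u2, oracle_obj, R = cm$R, k = 2,
                           method = "Nelder-Mead",
                           control = list(maxit = 3000, reltol = 1e-12))
    best <- min(best, polish$value)
    expect_equal(fit$objective, best, tolerance = 1e-6)
  }
})

test_that("oblimin preserves simple structure and descends", {
  # perfect cluster structure is a fixed point (Phi ~ identity)
  L <- rbind(matrix(c(0.8, 0), 4, 2, byrow = TRUE),
             matrix(c(0, 0.8), 4, 2, byrow = TRUE))
  rot <- rotate_oblimin(L)
  expect_equal(abs(rot$loadings), abs(L), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(rot$Phi, diag(2), tolerance = 1e-3, ignore_attr = TRUE)

  withr::local_seed(43)
  for (i in 1:5) {
    # premix a simple structure by a random orthogonal matrix; rotation
    # must recover it up to column permutation and sign
    L0 <- matrix(0, 12, 3)
    L0[cbind(1:12, rep(1:3, each = 4))] <- runif(12, 0.6, 0.9)
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    rot <- rotate_oblimin(L0 %*% Q)
    cong <- abs(tucker_congruence(rot$loadings, L0))
    expect_true(all(apply(cong, 2, max) >= 0.99))
    # descent: criterion at convergence is no worse than at the start
    start_f <- sum((L0 %*% Q)^2 * ((L0 %*% Q)^2 %*% (matrix(1, 3, 3) - diag(3)))) / 4
    expect_lte(rot$criterion, start_f + 1e-12)
  }
})

test_that("fit statistics behave at the boundary cases", {
  # exact model: zero residuals
  p <- 6
  L <- matrix(0, p, 2)
  L[cbind(1:p, rep(1:2, each = 3))] <- 0.8
  Phi <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  u2 <- 1 - diag(L %*% Phi %*% t(L))
  R0 <- L %*% Phi %*% t(L) + diag(u2)
  colnames(R0) <- rownames(R0) <- paste0("i", 1:p)
  cm0 <- structure(list(R = R0, n = 100L, items = colnames(R0)),
                   class = "cor_model")
  st <- model_fit_stats(cm0, L, Phi, u2)
  expect_equal(st$rmsr, 0, tolerance = 1e-12)
  expect_equal(st$echisq, 0, tolerance = 1e-8)
  expect_equal(max(st$variance$cumulative),
               sum(st$variance$proportion), tolerance = 1e-8)

  # perfectly redundant items: standardised alpha reaches 1
  R1 <- matrix(1, 4, 4)
  cm1 <- structure(list(R = R1, n = 100L, items = paste0("i", 1:4)),
                   class = "cor_model")
  st1 <- model_fit_stats(cm1, matrix(1, 4, 1), matrix(1, 1, 1), rep(0, 4))
  expect_equal(st1$alpha, 1)
})

test_that("omega_total tracks the generator's closed form", {
  withr::local_seed(47)
  diffs <- replicate(20, {
    lat <- latent_item_matrix(400, 10, 2, loading = 0.75)
    R0 <- lat$Lambda %*% lat$Phi %*% t(lat$Lambda) + diag(lat$u2)
    omega_true <- 1 - sum(lat$u2) / sum(R0)
    cm <- correlation_model(lat$x)
    sol <- fit_efa(cm, 2)
    sol$fit$omega_total - omega_true
  })
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("rotation leaves fit statistics and communalities unchanged", {
  withr::local_seed(53)
  lat <- latent_item_matrix(200, 12, 3)
  cm <- correlation_model(lat$x)
  mr <- fit_minres(cm, 3)
  rot <- rotate_oblimin(mr$loadings)
  st_unrot <- model_fit_stats(cm, mr$loadings, diag(3), mr$u2)
  st_rot <- model_fit_stats(cm, rot$loadings, rot$Phi, mr$u2)
  expect_equal(st_rot$rmsr, st_unrot$rmsr, tolerance = 1e-8)
  expect_equal(st_rot$echisq, st_unrot$echisq, tolerance = 1e-6)
  h2_unrot <- rowSums(mr$loadings^2)
  h2_rot <- diag(rot$loadings %*% rot$Phi %*% t(rot$loadings))
  expect_equal(h2_rot, h2_unrot, tolerance = 1e-8)
  # reconstruction identity: off-diagonal residual equals the objective
  resid <- cm$R - (rot$loadings %*% rot$Phi %*% t(rot$loadings) + diag(mr$u2))
  expect_equal(sum(resid[lower.tri(resid)]^2), mr$objective,
               tolerance = 1e-8)
})
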