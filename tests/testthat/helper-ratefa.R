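# Shared test helpers: small programmatic fixtures.

# Long ratings tibble from a subjects x raters matrix for a single item.
one_item_ratings <- function(m, item = "bold", site = "s1",
                             situation = "general") {
  tibble::tibble(
    site = site, situation = situation,
    rater = rep(paste0("r", seq_len(ncol(m))), each = nrow(m)),
    subject = rep(paste0("sub", seq_len(nrow(m))), times = ncol(m)),
    item = item, score = as.vector(m))
}

# Fully crossed ratings for several items with independent rater noise.
# Items in `null_items` carry no subject-level signal (true reliability 0).
crossed_ratings <- function(n_subjects, n_raters, items, null_items = character(0),
                            subject_sd = 1, noise_sd = 1) {
  recs <- lapply(items, function(it) {
    signal <- if (it %in% null_items) rep(0, n_subjects) else
      rnorm(n_subjects, sd = subject_sd)
    m <- matrix(signal, n_subjects, n_raters) +
      matrix(rnorm(n_subjects * n_raters, sd = noise_sd), n_subjects, n_raters)
    one_item_ratings(m, item = it)
  })
  dplyr::bind_rows(recs)
}

# Subject-level data matrix with a clean oblique factor structure
# (no rater layer): n x p with population correlation
# Lambda Phi Lambda' + diag(u2).
latent_item_matrix <- function(n, p, k, loading = 0.7, phi = 0.3) {
  Phi <- matrix(phi, k, k); diag(Phi) <- 1
  primary <- rep_len(seq_len(k), p)
  Lambda <- matrix(0, p, k)
  Lambda[cbind(seq_len(p), primary)] <- loading
  f <- matrix(rnorm(n * k), n, k) %*% chol(Phi)
  x <- f %*% t(Lambda) +
    matrix(rnorm(n * p), n, p) %*% diag(sqrt(1 - loading^2), p)
  colnames(x) <- sprintf("item%02d", seq_len(p))
  list(x = x, Lambda = Lambda, Phi = Phi, u2 = rep(1 - loading^2, p), f = f)
}

# Independent double-loop ANOVA ICC oracle (no matrix shortcuts).
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) grand <- grand + m[i, j]
  grand <- grand / (n * k)
  ss_sub <- 0
  for (i in seq_len(n)) {
    rm_ <- 0
    for (j in seq_len(k)) rm_ <- rm_ + m[i, j]
    ss_sub <- ss_sub + k * (rm_ / k - grand)^2
  }
  ss_rat <- 0
  for (j in seq_len(k)) {
    cm_ <- 0
    for (i in seq_len(n)) cm_ <- cm_ + m[i, j]
    ss_rat <- ss_rat + n * (cm_ / n - grand)^2
  }
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - grand)^2
  msb <- ss_sub / (n - 1)
  mse <- (ss_tot - ss_sub - ss_rat) / ((n - 1) * (k - 1))
  list(icc31 = (msb - mse) / (msb + (k - 1) * mse),
       icc3k = (msb - mse) / msb)
}

expect_tbl_equal_num <- function(x, y, tol = 1e-8) {
  expect_equal(as.numeric(x), as.numeric(y), tolerance = tol)
}
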