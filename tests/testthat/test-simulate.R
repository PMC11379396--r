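test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- generator_config(groups = tibble::tibble(group = "g", n_subjects = 20L,
                                                  n_raters = 3L),
                          items = sprintf("i%02d", 1:6), true_k = 2, seed = 99)
  d1 <- generate_ratings_dataset(cfg)
  d2 <- generate_ratings_dataset(cfg)
  expect_identical(d1$ratings, d2$ratings)
  expect_identical(d1$truth$latents, d2$truth$latents)
})

test_that("noise-free raters agree perfectly", {
  cfg <- generator_config(groups = tibble::tibble(group = "g", n_subjects = 25L,
                                                  n_raters = 3L),
                          items = sprintf("i%02d", 1:5), true_k = 2,
                          rater_noise_sd = 0, rater_bias_sd = 0,
                          discretise = FALSE, missing_rater_prob = 0,
                          seed = 5)
  d <- generate_ratings_dataset(cfg)
  icc <- item_reliability(d$ratings)
  expect_true(all(abs(icc$icc31 - 1) < 1e-10))
})

test_that("a 1:1 variance ratio yields ICC(3,1) near one half", {
  # true item variance is 1, so rater_noise_sd = 1 puts the expected
  # single-rater consistency at 0.5
  vals <- c()
  for (s in 1:10) {
    cfg <- generator_config(groups = tibble::tibble(group = "g",
                                                    n_subjects = 60L,
                                                    n_raters = 4L),
                            items = sprintf("i%02d", 1:20), true_k = 2,
                            rater_noise_sd = 1, rater_bias_sd = 0.5,
                            discretise = FALSE, missing_rater_prob = 0,
                            seed = 200 + s)
    d <- generate_ratings_dataset(cfg)
    vals <- c(vals, item_reliability(d$ratings)$icc31)
  }
  expect_equal(d$truth$icc31_expected, 0.5)
  expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("the empirical correlation matrix converges to the model", {
  cfg <- generator_config(groups = tibble::tibble(group = "g",
                                                  n_subjects = 5000L,
                                                  n_raters = 1L),
                          items = sprintf("i%02d", 1:10), true_k = 2,
                          rater_noise_sd = 0, rater_bias_sd = 0,
                          discretise = FALSE, missing_rater_prob = 0,
                          seed = 31)
  d <- generate_ratings_dataset(cfg)
  m <- ratings_matrix(aggregate_ratings(d$ratings))
  R_emp <- cor(m)
  R_true <- cfg$Lambda %*% cfg$Phi %*% t(cfg$Lambda) + diag(cfg$u2)
  expect_lt(max(abs(R_emp - R_true[colnames(m), colnames(m)])), 0.05)
})

test_that("missing raters are dropped but every subject stays rated", {
  cfg <- generator_config(groups = tibble::tibble(group = "g",
                                                  n_subjects = 40L,
                                                  n_raters = 4L),
                          items = sprintf("i%02d", 1:5), true_k = 1,
                          missing_rater_prob = 0.5, seed = 17)
  d <- generate_ratings_dataset(cfg)
  per_cell <- dplyr::count(d$ratings, subject, item)
  expect_true(all(per_cell$n >= 1))
  expect_lt(mean(per_cell$n), 4)
  expect_equal(dplyr::n_distinct(d$ratings$subject), 40)
})

test_that("paired situations share subjects and omit the human exclusions", {
  cfg <- generator_config(seed = 23)
  d <- generate_paired_situation_dataset(cfg)
  expect_setequal(unique(d$general$item), item_catalog("general")$item)
  expect_setequal(unique(d$human$item), item_catalog("human")$item)
  expect_setequal(unique(d$general$subject), unique(d$human$subject))
})

test_that("extreme cross-situation correlations propagate to the latents", {
  base <- list(groups = tibble::tibble(group = "g", n_subjects = 200L,
                                       n_raters = 2L),
               items = sprintf("i%02d", 1:6), true_k = 2)
  cfg1 <- do.call(generator_config,
                  c(base, list(cross_situation_rho = 1, seed = 41)))
  d1 <- generate_paired_situation_dataset(cfg1)
  expect_equal(d1$truth$latents_general$g, d1$truth$latents_human$g,
               tolerance = 1e-12)
  cfg0 <- do.call(generator_config,
                  c(base, list(cross_situation_rho = 0, seed = 43)))
  d0 <- generate_paired_situation_dataset(cfg0)
  matched <- diag(cor(d0$truth$latents_general$g, d0$truth$latents_human$g))
  expect_lt(max(abs(matched)), 0.2)
})

test_that("invalid configurations are refused before sampling", {
  expect_error(generator_config(missing_rater_prob = 1), "missing_rater_prob")
  expect_error(generator_config(cross_situation_rho = 1.2))
  expect_error(generator_config(loading = 1.1),
               class = "ratefa_validation_error")
})
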