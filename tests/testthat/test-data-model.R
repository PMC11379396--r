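test_that("item catalogs have the survey structure", {
  gen <- item_catalog("general")
  hum <- item_catalog("human")
  expect_equal(nrow(gen), 51)
  expect_equal(nrow(hum), 43)
  expect_setequal(setdiff(gen$item, hum$item),
                  c("Jealous", "Manipulative", "Nurturant", "Playful",
                    "Popular", "Protective", "Stingy/greedy",
                    "Warm/affectionate"))
  expect_false(any(duplicated(tolower(gen$item))))
})

test_that("read_ratings validates structure, items and duplicates", {
  df <- tidyr::expand_grid(rater = c("r1", "r2"), subject = c("a", "b"),
                           item = c("Bold", "Timid", "Lazy"))
  df <- dplyr::mutate(df, site = "s1", situation = "general",
                      score = seq_len(nrow(df)))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  ratings <- read_ratings(path)
  expect_equal(nrow(ratings), 12)

  # an item dropped from the survey is rejected against the catalog
  bad <- df
  bad$item[1] <- "flexible"
  readr::write_csv(bad, path)
  expect_error(read_ratings(path), class = "ratefa_validation_error")

  dup <- dplyr::bind_rows(df, df[1, ])
  readr::write_csv(dup, path)
  expect_error(read_ratings(path), regexp = "duplicated",
               class = "ratefa_validation_error")

  readr::write_csv(df[setdiff(names(df), "score")], path)
  expect_error(read_ratings(path), class = "ratefa_format_error")

  nonnum <- df
  nonnum$score <- as.character(nonnum$score)
  nonnum$score[2] <- "high"
  readr::write_csv(nonnum, path)
  expect_error(read_ratings(path), regexp = "non-numeric",
               class = "ratefa_validation_error")

  # matching is case-insensitive and canonicalises display names
  lower <- df
  lower$item <- tolower(lower$item)
  readr::write_csv(lower, path)
  expect_setequal(unique(read_ratings(path)$item), c("Bold", "Timid", "Lazy"))
})

test_that("ratings round-trip through CSV bit-identically", {
  withr::local_seed(1)
  df <- crossed_ratings(4, 3, c("Bold", "Lazy"))
  df$score <- round(df$score, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings(df, path)
  back <- read_ratings(path)
  expect_identical(back$score, df$score)
  expect_identical(back[c("rater", "subject", "item")],
                   df[c("rater", "subject", "item")])
})

test_that("rater aggregation averages available raters only", {
  ratings <- tibble::tibble(
    site = "s1", situation = "general",
    rater = c("r1", "r2", "r1", "r2", "r3"),
    subject = c("a", "a", "b", "b", "b"),
    item = "Bold",
    score = c(2, 4, 5, NA, 3))
  agg <- suppressMessages(aggregate_ratings(ratings))
  expect_equal(agg$score[agg$subject == "a"], 3)     # mean of 2 and 4
  expect_equal(agg$n_raters[agg$subject == "a"], 2L)
  # rater r2 skipped subject b (NA) -> mean over the two who rated
  expect_equal(agg$score[agg$subject == "b"], 4)
  expect_equal(agg$n_raters[agg$subject == "b"], 2L)
})

test_that("aggregation is the identity on single-rater data", {
  withr::local_seed(2)
  df <- crossed_ratings(5, 1, c("Bold", "Lazy", "Timid"))
  agg <- aggregate_ratings(df)
  merged <- dplyr::inner_join(df, agg, by = c("subject", "item"))
  expect_equal(merged$score.y, merged$score.x)
  expect_true(all(agg$n_raters == 1L))
})

test_that("cells with no rater at all are reported, not invented", {
  df <- crossed_ratings(3, 2, c("Bold", "Lazy"))
  df <- df[!(df$subject == "sub1" & df$item == "Lazy"), ]
  expect_message(agg <- aggregate_ratings(df), "1 \\(subject, item\\)")
  miss <- attr(agg, "missing_cells")
  expect_equal(miss$subject, "sub1")
  expect_equal(miss$item, "Lazy")
})

test_that("cross-situation item correlations hit the closed-form cases", {
  withr::local_seed(3)
  g <- aggregate_ratings(crossed_ratings(10, 1, c("Bold", "Lazy")))
  h <- g
  res <- item_cross_situation_correlation(g, h)
  expect_equal(res$r, c(1, 1))
  h_neg <- dplyr::mutate(g, score = -score)
  res_neg <- item_cross_situation_correlation(g, h_neg)
  expect_equal(res_neg$r, c(-1, -1))
  # zero variance is reported as undefined, not 0
  h_const <- dplyr::mutate(g, score = ifelse(item == "Bold", 1, score))
  res_const <- item_cross_situation_correlation(g, h_const)
  expect_true(is.na(res_const$r[res_const$item == "Bold"]))
  expect_equal(res_const$note[res_const$item == "Bold"], "zero variance")
})

test_that("paired generator attenuation predicts mean item correlation", {
  # Monte-Carlo check against the generator's closed-form attenuated
  # correlation rho * lambda^2 / (1 + sigma_n^2 / k)
  rs <- c()
  expected <- c()
  for (s in 1:20) {
    cfg <- generator_config(
      groups = tibble::tibble(group = "g", n_subjects = 100L, n_raters = 4L),
      items = sprintf("item%02d", 1:12), true_k = 3,
      cross_situation_rho = 0.7, discretise = FALSE,
      missing_rater_prob = 0, seed = 500 + s)
    d <- generate_paired_situation_dataset(cfg)
    res <- item_cross_situation_correlation(
      aggregate_ratings(d$general), aggregate_ratings(d$human))
    rs <- c(rs, mean(res$r))
    expected <- c(expected, mean(d$truth$expected_item_r$g))
  }
  expect_lt(abs(mean(rs) - mean(expected)), 0.15)
})
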