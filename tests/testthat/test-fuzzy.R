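three_group_loadings <- function(vals, item = "sociable") {
  out <- lapply(vals, function(v) {
    m <- matrix(v, 1, 1, dimnames = list(item, "F1"))
    m
  })
  setNames(out, paste0("g", seq_along(vals)))
}

simple_mapping <- function(groups, reversed = rep(FALSE, length(groups)),
                           set = "S") {
  fuzzy_mapping(tibble::tibble(set = set, species = groups,
                               factor = "F1", reversed = reversed))
}

test_that("intersection is the minimum absolute loading with its sign", {
  l <- three_group_loadings(c(0.12, 0.25, 0.76))
  fs <- fuzzy_intersections(l, simple_mapping(names(l)))
  expect_equal(fs$value, 0.12)

  single <- three_group_loadings(-0.63)
  fs1 <- fuzzy_intersections(single, simple_mapping("g1"))
  expect_equal(fs1$value, -0.63)
  expect_equal(fs1$n_groups, 1L)
})

test_that("reversal flips signs before intersection", {
  l <- three_group_loadings(c(-0.5, 0.7))
  fs <- fuzzy_intersections(l, simple_mapping(c("g1", "g2"),
                                              reversed = c(TRUE, FALSE)))
  expect_equal(fs$value, 0.5)
  expect_false(fs$sign_conflict)
})

test_that("sign conflicts are flagged, not silently resolved", {
  l <- three_group_loadings(c(0.3, -0.6))
  fs <- fuzzy_intersections(l, simple_mapping(c("g1", "g2")))
  expect_equal(fs$value, 0.3)  # sign of the minimum-|loading| group
  expect_true(fs$sign_conflict)
})

test_that("min-stability: a larger new loading never changes the value", {
  withr::local_seed(131)
  for (i in 1:20) {
    vals <- runif(3, -1, 1)
    l <- three_group_loadings(vals)
    fs <- fuzzy_intersections(l, simple_mapping(names(l)))
    bigger <- sign(runif(1, -1, 1)) * (max(abs(vals)) + runif(1, 0.01, 0.2))
    l4 <- three_group_loadings(c(vals, min(bigger, 1)))
    fs4 <- fuzzy_intersections(l4, simple_mapping(names(l4)))
    expect_equal(fs4$value, fs$value)
  }
})

test_that("items use known information from the groups that retain them", {
  la <- matrix(c(0.8, 0.5), 2, 1, dimnames = list(c("a", "b"), "F1"))
  lb <- matrix(0.6, 1, 1, dimnames = list("a", "F1"))
  fs <- fuzzy_intersections(list(g1 = la, g2 = lb),
                            simple_mapping(c("g1", "g2")))
  expect_equal(fs$value[fs$item == "a"], 0.6)
  expect_equal(fs$value[fs$item == "b"], 0.5)   # only g1 contributes
  expect_equal(fs$n_groups[fs$item == "b"], 1L)
})

test_that("the salience rule is inclusive at the threshold", {
  fs <- tibble::tibble(set = "S", item = c("a", "b", "c"),
                       value = c(0.40, -0.41, 0.39))
  marked <- salient_items(fs, 0.40)
  expect_equal(marked$salient, c(TRUE, TRUE, FALSE))
})

test_that("degenerate permutation distributions give an exact threshold", {
  l <- lapply(1:3, function(i)
    matrix(c(0.5, -0.5), 2, 2, dimnames = list(c("a", "b"), c("F1", "F2"))))
  names(l) <- paste0("g", 1:3)
  th <- fuzzy_salience_threshold(l, n_perm = 50, seed = 1)
  expect_equal(unname(th$threshold), rep(0.5, 2))
})

test_that("single-group single-factor threshold equals a quantile oracle", {
  withr::local_seed(137)
  load <- matrix(runif(30, -1, 1), 30, 1,
                 dimnames = list(paste0("i", 1:30), "F1"))
  th <- fuzzy_salience_threshold(list(g1 = load), n_perm = 100,
                                 percentile = 95, seed = 2)
  # with one factor every iteration pools the same |loadings|
  oracle <- unname(quantile(rep(abs(load[, 1]), 100), 0.95))
  expect_equal(unname(th$threshold[th$family == "family"]), oracle)
})

test_that("the permutation threshold ignores factor sign flips", {
  withr::local_seed(139)
  l <- lapply(1:3, function(i)
    matrix(rnorm(20), 10, 2,
           dimnames = list(paste0("i", 1:10), c("F1", "F2"))))
  names(l) <- paste0("g", 1:3)
  flipped <- l
  flipped$g2[, 1] <- -flipped$g2[, 1]
  t1 <- fuzzy_salience_threshold(l, n_perm = 200, seed = 3)
  t2 <- fuzzy_salience_threshold(flipped, n_perm = 200, seed = 3)
  expect_equal(t1$threshold, t2$threshold)
})

test_that("mappings are validated", {
  expect_error(fuzzy_mapping(tibble::tibble(set = "S", species = "g1")),
               class = "ratefa_format_error")
  expect_error(fuzzy_mapping(tibble::tibble(
    set = c("S", "S"), species = c("g1", "g1"),
    factor = c("F1", "F2"), reversed = FALSE)),
    class = "ratefa_validation_error")
  l <- three_group_loadings(0.5)
  bad <- fuzzy_mapping(tibble::tibble(set = "S", species = "g1",
                                      factor = "F9", reversed = FALSE))
  expect_error(fuzzy_intersections(l, bad), class = "ratefa_validation_error")
})
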