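# Inter-rater reliability: two-way consistency intraclass correlations and
# the item-retention screen.

#' Two-way consistency intraclass correlations
#'
#' Computes ICC(3,1) and ICC(3,k) for one item from a subjects-by-raters
#' score matrix, using the two-way (subject + rater) ANOVA without
#' interaction. Raters are treated as fixed and rater main effects are
#' removed, so adding a constant to any rater's column leaves both
#' coefficients unchanged (the defining property of the consistency form):
#' \deqn{ICC(3,1) = (MS_B - MS_E) / (MS_B + (k-1) MS_E)}
#' \deqn{ICC(3,k) = (MS_B - MS_E) / MS_B}
#' with \eqn{MS_B} the between-subjects and \eqn{MS_E} the residual mean
#' square. Rows with any missing value are dropped (complete-case).
#'
#' @param x Numeric matrix, subjects in rows, raters in columns.
#' @return A one-row tibble: `icc31`, `icc3k`, `k`, `n`, `ms_subject`,
#'   `ms_error`, `degenerate`. A constant matrix (no between-subject and no
#'   error variance) is degenerate: both ICCs are `NA`.
#' @export
icc_consistency <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) {
    stopf("ratefa_validation_error",
          "ICC needs >= 2 subjects and >= 2 raters after complete-case reduction (got %d x %d)",
          n, k)
  }
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_subject <- k * sum((row_means - grand)^2)
  ss_rater <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_error <- ss_total - ss_subject - ss_rater
  ms_subject <- ss_subject / (n - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))

  eps <- 1e-12 * max(1, abs(grand))
  degenerate <- ms_subject < eps && ms_error < eps
  if (degenerate) {
    icc31 <- icc3k <- NA_real_
  } else {
    icc31 <- (ms_subject - ms_error) / (ms_subject + (k - 1) * ms_error)
    icc3k <- (ms_subject - ms_error) / ms_subject
  }
  tibble(icc31 = icc31, icc3k = icc3k, k = k, n = n,
         ms_subject = ms_subject, ms_error = ms_error, degenerate = degenerate)
}

#' Per-item inter-rater reliability for a ratings table
#'
#' Builds, for each item, the subjects-by-raters matrix (restricted to raters
#' who rated at least one subject at the site) and applies
#' [icc_consistency()] on its complete-case rows.
#'
#' @param ratings A validated ratings tibble for one site and situation.
#' @return A tibble with one row per item: `item`, `icc31`, `icc3k`, `k`,
#'   `n`, `ms_subject`, `ms_error`, `degenerate`.
#' @export
item_reliability <- function(ratings) {
  items <- unique(ratings$item)
  purrr::map_dfr(items, function(it) {
    sub <- ratings[ratings$item == it, c("rater", "subject", "score")]
    wide <- tidyr::pivot_wider(sub, names_from = "rater", values_from = "score")
    m <- as.matrix(wide[-1])
    res <- tryCatch(icc_consistency(m), ratefa_error = function(e) {
      tibble(icc31 = NA_real_, icc3k = NA_real_, k = ncol(m),
             n = sum(stats::complete.cases(m)), ms_subject = NA_real_,
             ms_error = NA_real_, degenerate = TRUE)
    })
    dplyr::bind_cols(tibble(item = it), res)
  })
}

#' Reliability screen for survey items
#'
#' Retains an item if and only if its ICC(3,k) strictly exceeds `threshold`
#' (items at or below the cut-off are dropped). Degenerate items (no
#' between-subject variance) are always dropped. The default cut-off of 0.40
#' follows published scale recommendations; 0.10 and 0.00 support
#' sensitivity replications.
#'
#' @param ratings A validated ratings tibble for one site and situation.
#' @param threshold ICC(3,k) retention cut-off in `[0, 1]`.
#' @return A `reliability_screen` object: list with `items` (per-item ICC
#'   table plus `retained`), `exclusions` (exclusion-log tibble with stage
#'   `"Low ICC"`), `summary` (mean and sd of both ICC forms over retained
#'   items) and `threshold`.
#' @export
screen_reliability <- function(ratings, threshold = 0.40) {
  stopifnot(is_scalar_number(threshold))
  icc <- item_reliability(ratings)
  icc$retained <- !icc$degenerate & !is.na(icc$icc3k) & icc$icc3k > threshold
  exclusions <- icc |>
    dplyr::filter(!.data$retained) |>
    dplyr::transmute(item = .data$item, stage = "Low ICC",
                     statistic = .data$icc3k, threshold = threshold,
                     degenerate = .data$degenerate)
  retained <- icc[icc$retained, ]
  summary <- tibble(
    mean_icc31 = mean(retained$icc31), sd_icc31 = sd(retained$icc31),
    mean_icc3k = mean(retained$icc3k), sd_icc3k = sd(retained$icc3k),
    n_retained = nrow(retained), n_dropped = nrow(exclusions))
  structure(list(items = icc, exclusions = exclusions, summary = summary,
                 threshold = threshold),
            class = "reliability_screen")
}

#' @export
tidy.reliability_screen <- function(x, ...) x$items

#' @export
glance.reliability_screen <- function(x, ...) x$summary

#' @export
print.reliability_screen <- function(x, ...) {
  cat(sprintf("<reliability_screen> ICC(3,k) > %.2f: %d retained, %d dropped\n",
              x$threshold, x$summary$n_retained, x$summary$n_dropped))
  if (x$summary$n_retained > 0) {
    cat(sprintf("  retained ICC(3,k) %.2f +/- %.2f, ICC(3,1) %.2f +/- %.2f\n",
                x$summary$mean_icc3k, x$summary$sd_icc3k,
                x$summary$mean_icc31, x$summary$sd_icc31))
  }
  invisible(x)
}
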