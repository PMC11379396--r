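# Long-format ratings tables: I/O, validation, rater aggregation.

RATINGS_COLUMNS <- c("site", "situation", "rater", "subject", "item", "score")

#' Read a long-format ratings table
#'
#' Reads a CSV with one row per (rater, subject, item) score and validates it
#' against an item catalog: unknown items, duplicated (rater, subject, item)
#' triples and non-numeric scores are rejected. Item names are matched after
#' trimming and case-folding and rewritten to the catalog's canonical display
#' names.
#'
#' @param path Path to a UTF-8, comma-separated file with header columns
#'   `site`, `situation`, `rater`, `subject`, `item`, `score`.
#' @param catalog An item catalog tibble, see [item_catalog()].
#' @return A validated ratings tibble with the columns above.
#' @export
read_ratings <- function(path, catalog = item_catalog("general")) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  validate_ratings(df, catalog)
}

#' Validate a ratings tibble against a catalog
#'
#' @param ratings A data frame with columns `site`, `situation`, `rater`,
#'   `subject`, `item`, `score`.
#' @inheritParams read_ratings
#' @return The validated tibble with canonical item names and numeric scores.
#' @export
validate_ratings <- function(ratings, catalog = item_catalog("general")) {
  missing_cols <- setdiff(RATINGS_COLUMNS, names(ratings))
  if (length(missing_cols) > 0) {
    stopf("ratefa_format_error", "ratings table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df <- as_tibble(ratings)[RATINGS_COLUMNS]
  score_num <- suppressWarnings(as.numeric(df$score))
  bad_score <- !is.na(df$score) & is.na(score_num)
  if (any(bad_score)) {
    stopf("ratefa_validation_error", "non-numeric score value(s): %s",
          paste(unique(df$score[bad_score])[1:min(5, sum(bad_score))], collapse = ", "))
  }
  df$score <- score_num

  canon <- setNames(catalog$item, item_key(catalog$item))
  keys <- item_key(df$item)
  unknown <- setdiff(unique(keys), names(canon))
  if (length(unknown) > 0) {
    stopf("ratefa_validation_error", "item(s) not in the %s catalog: %s",
          catalog$situation[1], paste(unknown, collapse = ", "))
  }
  df$item <- unname(canon[keys])

  dup <- duplicated(df[c("rater", "subject", "item")])
  if (any(dup)) {
    first <- df[which(dup)[1], ]
    stopf("ratefa_validation_error",
          "duplicated (rater, subject, item) triple(s), e.g. (%s, %s, %s)",
          first$rater, first$subject, first$item)
  }
  df
}

#' Write a ratings table to CSV
#'
#' Inverse of [read_ratings()]; finite decimal scores round-trip exactly.
#'
#' @param ratings A ratings tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  readr::write_csv(ratings[RATINGS_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Average ratings over raters
#'
#' Collapses a multi-rater ratings table to one mean score per
#' (subject, item), so that every animal carries a single rating per item.
#' Missing (rater, subject) cells are simply excluded from the mean, never
#' imputed. Cells for which no rater is available are reported in the
#' `missing_cells` attribute; downstream callers decide the drop policy.
#'
#' @param ratings A validated ratings tibble for one site and situation.
#' @return A tibble with columns `subject`, `item`, `score` (mean over
#'   available raters) and `n_raters`. The attribute `missing_cells` lists
#'   (subject, item) pairs with zero raters.
#' @export
aggregate_ratings <- function(ratings) {
  agg <- ratings |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$subject, .data$item) |>
    dplyr::summarise(score = mean(.data$score), n_raters = dplyr::n(),
                     .groups = "drop")
  grid <- tidyr::expand_grid(subject = unique(ratings$subject),
                             item = unique(ratings$item))
  missing <- dplyr::anti_join(grid, agg, by = c("subject", "item"))
  if (nrow(missing) > 0) {
    inform(sprintf("%d (subject, item) cell(s) have no rating from any rater",
                   nrow(missing)))
  }
  attr(agg, "missing_cells") <- missing
  agg
}

#' Spread aggregated ratings to a subjects-by-items matrix
#'
#' @param aggregated Output of [aggregate_ratings()].
#' @param items Optional item order for the columns; defaults to first
#'   appearance order.
#' @return A numeric matrix with subject ids as row names; cells with no
#'   rating are `NA`.
#' @export
ratings_matrix <- function(aggregated, items = NULL) {
  wide <- tidyr::pivot_wider(aggregated[c("subject", "item", "score")],
                             names_from = "item", values_from = "score")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$subject
  if (!is.null(items)) {
    missing <- setdiff(items, colnames(m))
    if (length(missing) > 0) {
      stopf("ratefa_validation_error", "item(s) absent from ratings: %s",
            paste(missing, collapse = ", "))
    }
    m <- m[, items, drop = FALSE]
  }
  m
}

#' Per-item correlation of mean ratings across two situations
#'
#' For every item present in both situations, computes the Pearson
#' correlation of subjects' mean ratings between the two forms, dropping
#' subjects missing in either situation pairwise per item.
#'
#' @param general,human Aggregated ratings (see [aggregate_ratings()]) for
#'   the two situations, sharing subject ids.
#' @return A tibble with columns `item`, `r`, `n` and `note` (`NA` or
#'   `"zero variance"`); the `summary` attribute holds the mean and sd of
#'   the defined correlations.
#' @export
item_cross_situation_correlation <- function(general, human) {
  shared <- dplyr::inner_join(
    general[c("subject", "item", "score")],
    human[c("subject", "item", "score")],
    by = c("subject", "item"), suffix = c("_general", "_human"))
  if (length(unique(shared$subject)) < 3) {
    stopf("ratefa_validation_error",
          "fewer than 3 subjects shared between the two situations")
  }
  res <- shared |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (sd(.data$score_general) == 0 || sd(.data$score_human) == 0) {
        NA_real_
      } else {
        cor(.data$score_general, .data$score_human)
      },
      .groups = "drop") |>
    dplyr::mutate(note = ifelse(is.na(.data$r), "zero variance", NA_character_)) |>
    dplyr::select("item", "r", "n", "note")
  attr(res, "summary") <- tibble(
    mean_r = mean(res$r, na.rm = TRUE),
    sd_r = sd(res$r, na.rm = TRUE),
    n_items = sum(!is.na(res$r)))
  res
}
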