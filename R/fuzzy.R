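# Fuzzy-set intersections of factor loadings across groups, with the
# permutation salience threshold.

#' Construct a fuzzy-set factor mapping
#'
#' A mapping assigns, for each cross-group fuzzy set, at most one factor per
#' group, optionally sign-reversed so that the factors are directionally
#' consistent across groups before intersection.
#'
#' @param x A data frame with columns `set`, `species` (group id), `factor`,
#'   `reversed` (logical).
#' @return A validated `fuzzy_mapping` tibble.
#' @export
fuzzy_mapping <- function(x) {
  req <- c("set", "species", "factor", "reversed")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stopf("ratefa_format_error", "fuzzy mapping is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  x <- as_tibble(x)[req]
  x$reversed <- as.logical(x$reversed)
  dup <- duplicated(x[c("set", "species")])
  if (any(dup)) {
    stopf("ratefa_validation_error",
          "a group contributes more than one factor to set '%s'",
          x$set[which(dup)[1]])
  }
  class(x) <- c("fuzzy_mapping", class(x))
  x
}

# Aligned loading columns for every (set, group) of a mapping.
# loadings: named list of matrices (or factor_solutions) keyed by group id.
align_factor_directions <- function(loadings, mapping) {
  loadings <- lapply(loadings, get_loadings)
  purrr::pmap_dfr(mapping, function(set, species, factor, reversed) {
    if (!species %in% names(loadings)) {
      stopf("ratefa_validation_error", "mapping references unknown group '%s'", species)
    }
    L <- loadings[[species]]
    if (!factor %in% colnames(L)) {
      stopf("ratefa_validation_error",
            "mapping references missing factor '%s' for group '%s'", factor, species)
    }
    col <- L[, factor]
    if (reversed) col <- -col
    tibble(set = set, species = species, item = rownames(L),
           loading = unname(col))
  })
}

#' Fuzzy-set intersections of aligned loadings
#'
#' For every set and item, the intersection value is the loading of minimum
#' absolute value across the groups whose final model contains the item
#' ("known information" for items unreliable in some groups), keeping that
#' group's sign after directional alignment. A sign disagreement among the
#' contributing groups is flagged, not resolved. Ties on the minimum keep
#' the first contributing group in mapping order.
#'
#' @param loadings Named list of loading matrices or `factor_solution`s,
#'   keyed by group id.
#' @param mapping A [fuzzy_mapping()].
#' @param salience_threshold If non-`NULL`, adds a `salient` column marking
#'   items with `abs(value) >= salience_threshold`.
#' @return A `fuzzy_set` tibble: `set`, `item`, `value`, `n_groups`,
#'   `groups`, `sign_conflict` (and `salient`).
#' @export
fuzzy_intersections <- function(loadings, mapping,
                                salience_threshold = NULL) {
  aligned <- align_factor_directions(loadings, mapping)
  if (nrow(aligned) == 0) {
    stopf("ratefa_validation_error", "empty fuzzy mapping")
  }
  res <- aligned |>
    dplyr::group_by(.data$set, key = item_key(.data$item)) |>
    dplyr::summarise(
      item = .data$item[1],
      value = .data$loading[which.min(abs(.data$loading))],
      n_groups = dplyr::n(),
      groups = paste(.data$species, collapse = ","),
      sign_conflict = length(unique(sign(.data$loading[.data$loading != 0]))) > 1,
      .groups = "drop") |>
    dplyr::select(-"key")
  set_order <- unique(mapping$set)
  res <- res[order(match(res$set, set_order)), ]
  if (!is.null(salience_threshold)) {
    res$salient <- abs(res$value) >= salience_threshold
  }
  class(res) <- c("fuzzy_set", class(res))
  res
}

#' Mark salient fuzzy-set items
#'
#' An item is salient when the absolute intersection value reaches the
#' threshold (inclusive).
#'
#' @param fs A `fuzzy_set` tibble from [fuzzy_intersections()].
#' @param threshold Salience cut-off on `abs(value)` (default 0.40).
#' @return `fs` with a logical `salient` column.
#' @export
salient_items <- function(fs, threshold = 0.40) {
  fs$salient <- abs(fs$value) >= threshold
  fs
}

permute_family <- function(loadings, n_perm, seed_offset = 0) {
  loadings <- lapply(loadings, get_loadings)
  keys_by_group <- lapply(loadings, function(L) item_key(rownames(L)))
  universe <- unique(unlist(keys_by_group))
  n_groups <- length(loadings)
  # presence[i, g] and a per-group row index for each universe item
  presence <- vapply(keys_by_group, function(kk) universe %in% kk,
                     logical(length(universe)))
  row_idx <- vapply(keys_by_group, function(kk) match(universe, kk),
                    integer(length(universe)))
  out <- matrix(NA_real_, length(universe), n_perm)
  for (it in seq_len(n_perm)) {
    vals <- matrix(NA_real_, length(universe), n_groups)
    for (g in seq_len(n_groups)) {
      L <- loadings[[g]]
      f <- sample.int(ncol(L), 1)
      vals[presence[, g], g] <- abs(L[row_idx[presence[, g], g], f])
    }
    out[, it] <- apply(vals, 1, min, na.rm = TRUE)
  }
  as.vector(out)
}

#' Permutation salience threshold for fuzzy-set scores
#'
#' For each model family, repeatedly draws one factor per group uniformly at
#' random, forms the per-item minimum absolute loading over the groups whose
#' model contains the item, and pools the resulting scores over all
#' permutations. The threshold is the given percentile of the pooled
#' absolute scores, reported per family and aggregated across families.
#'
#' @param families A named list of model families, each a named list of
#'   loading matrices or `factor_solution`s keyed by group; a single family
#'   may be passed directly as a named list of matrices.
#' @param n_perm Permutations per family (default 1000).
#' @param percentile Percentile of the pooled absolute scores (default 95).
#' @param seed Optional RNG seed.
#' @return A tibble with one row per family plus an `"aggregate"` row:
#'   `family`, `threshold`, `n_scores`.
#' @export
fuzzy_salience_threshold <- function(families, n_perm = 1000, percentile = 95,
                                     seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  is_single <- all(vapply(families, function(x)
    is.matrix(x) || inherits(x, "factor_solution"), logical(1)))
  if (is_single) families <- list(family = families)
  pooled <- lapply(families, permute_family, n_perm = n_perm)
  per_family <- tibble(
    family = names(pooled),
    threshold = unname(vapply(pooled, function(v)
      unname(quantile(v, percentile / 100, type = 7)), numeric(1))),
    n_scores = unname(lengths(pooled)))
  all_scores <- unlist(pooled, use.names = FALSE)
  dplyr::bind_rows(per_family, tibble(
    family = "aggregate",
    threshold = unname(quantile(all_scores, percentile / 100, type = 7)),
    n_scores = length(all_scores)))
}

#' Items-by-sets matrix view of fuzzy intersections
#'
#' @param fs A `fuzzy_set` tibble.
#' @return A numeric matrix, items in rows, sets in columns; `NA` where an
#'   item contributes to no model of a set's groups.
#' @export
fuzzy_matrix <- function(fs) {
  wide <- tidyr::pivot_wider(fs[c("item", "set", "value")],
                             names_from = "set", values_from = "value")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$item
  m
}

#' Fuzzy-set profile plot
#'
#' @param object A `fuzzy_set` tibble.
#' @param threshold Salience line drawn at +/- this value.
#' @param ... Unused.
#' @export
autoplot.fuzzy_set <- function(object, threshold = 0.40, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   y = stats::reorder(.data$item, .data$value),
                                   colour = abs(.data$value) >= threshold)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold), linetype = 2) +
    ggplot2::facet_wrap(~set, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::labs(x = "fuzzy intersection", y = NULL) +
    ggplot2::theme_minimal(base_size = 8)
}
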