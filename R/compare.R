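# Cross-group structural comparison: shared items, Procrustes target
# rotation, Tucker congruence, and the congruence bins.

get_loadings <- function(x) {
  if (inherits(x, "factor_solution")) x$loadings else as.matrix(x)
}

#' Restrict two loading matrices to their shared items
#'
#' @param a,b `factor_solution` objects or loading matrices with item row
#'   names.
#' @return List of the two matrices row-aligned on the intersection of item
#'   sets, in `a`'s row order.
#' @export
restrict_to_shared_items <- function(a, b) {
  la <- get_loadings(a)
  lb <- get_loadings(b)
  shared_keys <- intersect(item_key(rownames(la)), item_key(rownames(lb)))
  if (length(shared_keys) < 2) {
    stopf("ratefa_validation_error", "fewer than 2 shared items")
  }
  ka <- item_key(rownames(la))
  kb <- item_key(rownames(lb))
  rows_a <- which(ka %in% shared_keys)
  la <- la[rows_a, , drop = FALSE]
  lb <- lb[match(ka[rows_a], kb), , drop = FALSE]
  list(a = la, b = lb)
}

#' Orthogonal Procrustes rotation toward a target
#'
#' Least-squares orthogonal rotation of `source` toward `target`: with
#' \eqn{M = \Lambda_s' \Lambda_t} and SVD \eqn{M = U D V'}, the rotation is
#' \eqn{T = U V'}. A source with fewer columns than the target is padded
#' with zero columns (flagged).
#'
#' @param source,target Row-aligned loading matrices.
#' @return List: `rotated` (source after rotation), `rotation` (the
#'   orthogonal matrix), `padded`, `rank_deficient`.
#' @export
procrustes_rotate <- function(source, target) {
  s <- get_loadings(source)
  t_ <- get_loadings(target)
  if (nrow(s) != nrow(t_)) {
    stopf("ratefa_validation_error", "matrices are not row-aligned (%d vs %d rows)",
          nrow(s), nrow(t_))
  }
  padded <- FALSE
  if (ncol(s) < ncol(t_)) {
    s <- cbind(s, matrix(0, nrow(s), ncol(t_) - ncol(s)))
    padded <- TRUE
  } else if (ncol(t_) < ncol(s)) {
    t_ <- cbind(t_, matrix(0, nrow(t_), ncol(s) - ncol(t_)))
    padded <- TRUE
  }
  M <- crossprod(s, t_)
  sv <- svd(M)
  rank_deficient <- any(sv$d < 1e-10 * max(sv$d, 1e-300))
  if (rank_deficient) {
    warn("Procrustes target cross-product is rank deficient; rotation tie resolved by SVD convention")
  }
  rotation <- sv$u %*% t(sv$v)
  rotated <- s %*% rotation
  colnames(rotated) <- colnames(get_loadings(source))[seq_len(ncol(rotated))] %||% NULL
  rownames(rotated) <- rownames(s)
  list(rotated = rotated, rotation = rotation, padded = padded,
       rank_deficient = rank_deficient)
}

#' Tucker's congruence coefficients between loading matrices
#'
#' \eqn{\phi(x, y) = \sum_i x_i y_i / \sqrt{\sum_i x_i^2 \sum_i y_i^2}} for
#' every column pair.
#'
#' @param x,y Row-aligned loading matrices.
#' @return Matrix of congruence coefficients, columns of `x` in rows.
#'   Zero-norm columns give `NA` with a warning.
#' @export
tucker_congruence <- function(x, y) {
  x <- get_loadings(x)
  y <- get_loadings(y)
  norms_x <- sqrt(colSums(x^2))
  norms_y <- sqrt(colSums(y^2))
  if (any(norms_x == 0) || any(norms_y == 0)) {
    warn("zero-norm loading column; congruence undefined for that pair")
    norms_x[norms_x == 0] <- NA_real_
    norms_y[norms_y == 0] <- NA_real_
  }
  crossprod(x, y) / outer(norms_x, norms_y)
}

congruence_bin <- function(phi) {
  a <- abs(as.vector(phi))
  dplyr::case_when(
    is.na(a) ~ NA_character_,
    a >= 0.95 ~ "good",
    a >= 0.85 ~ "fair",
    a >= 0.80 ~ "poor",
    TRUE ~ "incongruent")
}

#' Compare two factor structures
#'
#' Restricts both groups' loading matrices to shared items, Procrustes-
#' rotates the source group toward the target group, and reports Tucker's
#' congruence and Pearson correlations for every factor pair, with the
#' conventional congruence bins: good (>= 0.95), fair (0.85-0.94), poor
#' (0.80-0.84, just below fair but above the 0.80 hard cut-off), else
#' incongruent. Bins are descriptive labels, never decisions.
#'
#' @param target,source `factor_solution` objects or loading matrices; the
#'   source is rotated toward the target.
#' @param target_id,source_id Labels for reporting.
#' @return A `structure_comparison` object with `phi` and `r` matrices
#'   (source factors in rows, target factors in columns, matching the
#'   "source by target" table layout), `bins`, `shared_items`, and the
#'   rotation details.
#' @export
compare_structures <- function(target, source, target_id = "target",
                               source_id = "source") {
  shared <- restrict_to_shared_items(target, source)
  rot <- procrustes_rotate(shared$b, shared$a)
  phi <- tucker_congruence(rot$rotated, shared$a)
  r <- suppressWarnings(cor(rot$rotated, shared$a))
  # An orthogonal target rotation mixes the source columns, so each rotated
  # column is named after the original source factor it is most congruent
  # with (greedy, strongest matches first), and rows are reported in the
  # source's original factor order.
  orig_names <- colnames(shared$b)
  # The Procrustes alignment makes rotated column j correspond to target
  # factor j; each such column inherits the name of the source factor whose
  # unrotated loadings are most congruent with that target factor (greedy,
  # strongest pairings first). Target directions left without a source
  # factor arise only from zero-column padding and are reported separately.
  pre_cong <- abs(tucker_congruence(shared$b, shared$a))
  labels <- rep(NA_character_, nrow(phi))
  avail <- pre_cong
  for (step in seq_len(min(dim(pre_cong)))) {
    best <- arrayInd(which.max(avail), dim(avail))
    labels[best[2]] <- orig_names[best[1]]
    avail[best[1], ] <- -Inf
    avail[, best[2]] <- -Inf
  }
  leftover <- setdiff(orig_names, labels)
  labels[which(is.na(labels))[seq_along(leftover)]] <- leftover
  keep <- !is.na(labels)
  dimnames(phi) <- dimnames(r) <- list(labels, colnames(shared$a))
  dropped_columns <- phi[!keep, , drop = FALSE]
  rownames(dropped_columns) <- rep("padding", nrow(dropped_columns))
  phi <- phi[keep, , drop = FALSE]
  r <- r[keep, , drop = FALSE]
  ord <- order(match(rownames(phi), orig_names))
  phi <- phi[ord, , drop = FALSE]
  r <- r[ord, , drop = FALSE]
  colnames(rot$rotated) <- labels
  bins <- matrix(congruence_bin(phi), nrow(phi), ncol(phi), dimnames = dimnames(phi))
  structure(list(pair = c(target = target_id, source = source_id),
                 shared_items = rownames(shared$a),
                 phi = phi, r = r, bins = bins,
                 dropped_columns = dropped_columns,
                 padded = rot$padded, rank_deficient = rot$rank_deficient,
                 rotated_source = rot$rotated, target_loadings = shared$a),
            class = "structure_comparison")
}

#' @export
print.structure_comparison <- function(x, ...) {
  cat(sprintf("<structure_comparison> %s by %s, %d shared items\n",
              x$pair["source"], x$pair["target"], length(x$shared_items)))
  print(round(x$phi, 2))
  invisible(x)
}

#' Tidy a structure comparison
#'
#' @param x A `structure_comparison`.
#' @param ... Unused.
#' @return A tibble `source_factor`, `target_factor`, `phi`, `r`, `bin`.
#' @export
tidy.structure_comparison <- function(x, ...) {
  tibble(
    source_factor = rep(rownames(x$phi), times = ncol(x$phi)),
    target_factor = rep(colnames(x$phi), each = nrow(x$phi)),
    phi = as.vector(x$phi),
    r = as.vector(x$r),
    bin = as.vector(x$bins))
}

#' Congruence heatmap for a structure comparison
#'
#' @param object A `structure_comparison`.
#' @param ... Unused.
#' @export
autoplot.structure_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_factor,
                                   y = .data$source_factor,
                                   fill = .data$phi)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$phi)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = object$pair["target"], y = object$pair["source"],
                  fill = expression(phi)) +
    ggplot2::theme_minimal(base_size = 10)
}
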