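# End-to-end orchestration across groups and situations.

#' Pipeline configuration
#'
#' Collects the thresholds of every screening stage. The ICC cut-off
#' alternates (0.10, 0.00) support sensitivity replications.
#'
#' @param icc_threshold ICC(3,k) retention cut-off (strict `>`).
#' @param msa_threshold,communality_bounds,residual_threshold,k_max,freeze_k
#'   Passed to [efa_config()].
#' @param salience_threshold Fuzzy-set salience cut-off.
#' @param n_perm,percentile Permutation-null settings.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param k_override Named list `group -> k` fixing factor counts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(icc_threshold = 0.40, msa_threshold = 0.50,
                            communality_bounds = c(0.4, 0.99),
                            residual_threshold = 0.10,
                            salience_threshold = 0.40,
                            n_perm = 1000, percentile = 95,
                            seed = 1L, k_max = 8, freeze_k = FALSE,
                            k_override = list()) {
  stopifnot(icc_threshold >= 0, icc_threshold <= 1, n_perm >= 1)
  structure(list(icc_threshold = icc_threshold, msa_threshold = msa_threshold,
                 communality_bounds = communality_bounds,
                 residual_threshold = residual_threshold,
                 salience_threshold = salience_threshold,
                 n_perm = n_perm, percentile = percentile, seed = seed,
                 k_max = k_max, freeze_k = freeze_k, k_override = k_override),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' For every (site, situation) branch: reliability screen, rater averaging,
#' and the factor-model exclusion loop. Then, per situation, all pairwise
#' structure comparisons; optionally fuzzy-set intersections with the
#' permutation salience threshold; and, when both situations are present,
#' ten Berge factor scores and their cross-situation correlations. A stage
#' error aborts only its branch (logged); remaining branches continue.
#'
#' @param ratings Long ratings tibble with `site` and `situation` columns
#'   covering one or more groups and situations.
#' @param config A [pipeline_config()].
#' @param fuzzy_mappings Optional named list (by situation) of
#'   [fuzzy_mapping()] tables; fuzzy analyses are skipped when absent.
#' @return A `rating_pipeline` bundle: `solutions`, `screens`,
#'   `comparisons`, `fuzzy`, `salience`, `scores`, `score_correlations`,
#'   `log` (structured stage log), `config`.
#' @export
run_pipeline <- function(ratings, config = pipeline_config(),
                         fuzzy_mappings = NULL) {
  branches <- dplyr::distinct(ratings[c("site", "situation")])
  log <- list()
  note <- function(stage, branch, message) {
    log[[length(log) + 1]] <<- tibble(stage = stage, branch = branch,
                                      message = message)
  }
  solutions <- list()
  screens <- list()
  aggregated <- list()
  for (i in seq_len(nrow(branches))) {
    site <- branches$site[i]
    situation <- branches$situation[i]
    id <- paste(site, situation, sep = ".")
    branch_ratings <- ratings[ratings$site == site &
                                ratings$situation == situation, ]
    res <- tryCatch({
      screen <- screen_reliability(branch_ratings, config$icc_threshold)
      kept <- screen$items$item[screen$items$retained]
      note("reliability", id, sprintf("%d of %d items retained",
                                      length(kept), nrow(screen$items)))
      agg <- aggregate_ratings(
        branch_ratings[branch_ratings$item %in% kept, ])
      ecfg <- efa_config(
        msa_threshold = config$msa_threshold,
        communality_bounds = config$communality_bounds,
        residual_threshold = config$residual_threshold,
        k_max = config$k_max, freeze_k = config$freeze_k,
        k_override = config$k_override[[site]],
        seed = config$seed + i)
      solution <- fit_rating_model(agg, ecfg)
      solution$exclusions <- dplyr::bind_rows(
        screen$exclusions[c("item", "stage", "statistic", "threshold")],
        solution$exclusions)
      note("efa", id, sprintf("k = %d, %d items in final model",
                              solution$k, length(solution$items)))
      list(screen = screen, agg = agg, solution = solution)
    }, error = function(e) {
      note("error", id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    screens[[id]] <- res$screen
    aggregated[[id]] <- res$agg
    solutions[[id]] <- res$solution
  }

  comparisons <- list()
  for (situation in unique(branches$situation)) {
    ids <- names(solutions)[endsWith(names(solutions),
                                     paste0(".", situation))]
    if (length(ids) < 2) {
      note("compare", situation,
           "fewer than two fitted groups; comparisons skipped")
      next
    }
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    for (pr in pairs) {
      cid <- paste(pr[2], "by", pr[1])
      comparisons[[cid]] <- compare_structures(
        solutions[[pr[1]]], solutions[[pr[2]]],
        target_id = pr[1], source_id = pr[2])
    }
  }

  fuzzy <- list()
  salience <- NULL
  if (!is.null(fuzzy_mappings)) {
    families <- list()
    for (situation in names(fuzzy_mappings)) {
      ids <- names(solutions)[endsWith(names(solutions),
                                       paste0(".", situation))]
      loadings <- setNames(lapply(ids, function(id) solutions[[id]]$loadings),
                           sub(paste0("\\.", situation, "$"), "", ids))
      if (length(loadings) == 0) next
      families[[situation]] <- loadings
      fuzzy[[situation]] <- fuzzy_intersections(
        loadings, fuzzy_mappings[[situation]],
        salience_threshold = config$salience_threshold)
    }
    if (length(families) > 0) {
      salience <- fuzzy_salience_threshold(
        families, n_perm = config$n_perm, percentile = config$percentile,
        seed = config$seed)
    }
  } else {
    note("fuzzy", "all", "no fuzzy mapping supplied; fuzzy analyses skipped")
  }

  scores <- list()
  score_correlations <- list()
  for (site in unique(branches$site)) {
    gid <- paste(site, "general", sep = ".")
    hid <- paste(site, "human", sep = ".")
    if (!gid %in% names(solutions) || !hid %in% names(solutions)) next
    sc <- tryCatch({
      sg <- tenberge_scores(aggregated[[gid]], solutions[[gid]])
      sh <- tenberge_scores(aggregated[[hid]], solutions[[hid]])
      list(general = sg, human = sh,
           correlations = score_correlations(sg, sh))
    }, error = function(e) {
      note("scores", site, conditionMessage(e))
      NULL
    })
    if (is.null(sc)) next
    scores[[site]] <- sc[c("general", "human")]
    score_correlations[[site]] <- sc$correlations
  }

  structure(list(solutions = solutions, screens = screens,
                 aggregated = aggregated, comparisons = comparisons,
                 fuzzy = fuzzy, salience = salience, scores = scores,
                 score_correlations = score_correlations,
                 log = dplyr::bind_rows(log), config = config),
            class = "rating_pipeline")
}

#' @export
print.rating_pipeline <- function(x, ...) {
  cat(sprintf("<rating_pipeline> %d solution(s), %d comparison(s), %d fuzzy famil(ies)\n",
              length(x$solutions), length(x$comparisons), length(x$fuzzy)))
  print(x$log)
  invisible(x)
}

solution_table <- function(solution, exclusions = NULL) {
  tab <- as_tibble(solution$loadings, rownames = "item")
  tab$h2 <- unname(solution$h2)
  tab$u2 <- unname(solution$u2)
  tab <- dplyr::left_join(tab, solution$msa, by = "item")
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    tab <- dplyr::bind_rows(tab, tibble(item = exclusions$item,
                                        exclusion = exclusions$stage))
  }
  tab
}

#' Write pipeline report artifacts
#'
#' Serialises every bundle component: per-solution loading tables (with
#' exclusion annotations inline), factor-correlation/fit JSON sidecars,
#' comparison matrices, fuzzy-set tables, score matrices and correlations,
#' the stage log and a config echo (with seed). Output is deterministic
#' given the bundle.
#'
#' @param bundle A `rating_pipeline`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stopf("ratefa_format_error", "cannot create output directory '%s'", out_dir)
  }
  paths <- character(0)
  emit_csv <- function(df, file) {
    path <- file.path(out_dir, file)
    readr::write_csv(df, path, progress = FALSE, na = "")
    paths <<- c(paths, path)
  }
  emit_json <- function(x, file) {
    path <- file.path(out_dir, file)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, path)
  }
  safe <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

  for (id in names(bundle$solutions)) {
    s <- bundle$solutions[[id]]
    emit_csv(solution_table(s, s$exclusions), sprintf("solution_%s.csv", safe(id)))
    emit_json(list(Phi = s$Phi, fit = s$fit[c("rmsr", "rmsr_df_corrected",
                                              "root_sum_squares", "alpha",
                                              "omega_total", "df")],
                   variance = s$fit$variance, vote = s$vote,
                   adequate = s$adequate, n = s$n, k = s$k),
              sprintf("solution_%s.json", safe(id)))
  }
  for (cid in names(bundle$comparisons)) {
    cmp <- bundle$comparisons[[cid]]
    emit_csv(tidy(cmp), sprintf("comparison_%s.csv", safe(cid)))
  }
  if (length(bundle$fuzzy) > 0) {
    for (situation in names(bundle$fuzzy)) {
      emit_csv(as_tibble(bundle$fuzzy[[situation]]),
               sprintf("fuzzy_%s.csv", safe(situation)))
    }
    if (!is.null(bundle$salience)) emit_csv(bundle$salience, "salience_thresholds.csv")
  } else {
    readr::write_lines("fuzzy analyses skipped: no mapping supplied",
                       file.path(out_dir, "fuzzy_SKIPPED.txt"))
    paths <- c(paths, file.path(out_dir, "fuzzy_SKIPPED.txt"))
  }
  for (site in names(bundle$scores)) {
    emit_csv(as_tibble(bundle$scores[[site]]$general),
             sprintf("scores_%s_general.csv", safe(site)))
    emit_csv(as_tibble(bundle$scores[[site]]$human),
             sprintf("scores_%s_human.csv", safe(site)))
    emit_csv(bundle$score_correlations[[site]],
             sprintf("score_correlations_%s.csv", safe(site)))
  }
  if (nrow(bundle$log) > 0) emit_csv(bundle$log, "stage_log.csv")
  emit_json(unclass(bundle$config), "config_echo.json")
  invisible(paths)
}
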