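# Item catalogs and packaged reference loading matrices.

# The 51 adjective items of the general-situation survey, in the row order of
# the published general loading table.
GENERAL_ITEMS <- c(
  "Irritable", "Bullying", "Excitable", "Jealous", "Stingy/greedy", "Feisty",
  "Unpredictable", "Aggressive", "Persistent", "Defiant", "Impulsive",
  "Opportunistic", "Fearful", "Apprehensive", "Nervous/anxious/not calm",
  "Insecure", "Submissive/subordinate", "Timid", "Cautious", "Protective",
  "Intelligent", "Bold", "Direct/forceful/gets own way", "Confident", "Strong",
  "Effective", "Sociable", "Affiliative/Companionable", "Warm/affectionate",
  "Nurturant", "Popular", "Manipulative", "Independent", "Depressed",
  "Solitary", "Lazy", "Slow", "Curious/exploratory/inquisitive",
  "Active/Energetic", "Tolerant", "Equable", "Understanding", "Calm/Equable",
  "Playful", "Gentle", "Reckless", "Tense", "Unemotional", "Eccentric",
  "Sensitive", "Vigilant"
)

# Items dropped from the human-situation form during rater training.
HUMAN_EXCLUDED_ITEMS <- c(
  "Jealous", "Manipulative", "Nurturant", "Playful", "Popular", "Protective",
  "Stingy/greedy", "Warm/affectionate"
)

#' Survey item catalog
#'
#' Returns the adjective-item catalog for one rating situation. The general
#' form has 51 items; the human-situation form omits eight items for which
#' raters could not anchor behavioural examples, leaving 43.
#'
#' @param situation `"general"` or `"human"`.
#' @return A tibble with columns `item` (canonical display name) and
#'   `situation`. Row order is the canonical item order.
#' @export
#' @examples
#' item_catalog("general")
#' nrow(item_catalog("human"))
item_catalog <- function(situation = c("general", "human")) {
  situation <- match.arg(situation)
  items <- GENERAL_ITEMS
  if (situation == "human") {
    items <- setdiff(items, HUMAN_EXCLUDED_ITEMS)
  }
  tibble(item = items, situation = situation)
}

ratefa_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ratefa")
  if (!nzchar(path)) {
    stopf("ratefa_format_error", "packaged data file '%s' not found", file)
  }
  path
}

#' Published macaque loading matrices
#'
#' Rotated pattern matrices for the three wild macaque populations (rhesus,
#' long-tailed, bonnet), transcribed from the published factor tables at two
#' printed decimals. Only items retained in each final model appear.
#'
#' @param situation `"general"` (conspecific context) or `"human"`
#'   (human-interaction context).
#' @return A named list of numeric matrices (items in rows, factors in
#'   columns), one per species.
#' @seealso [published_exclusions()], [published_fuzzy_mapping()]
#' @export
#' @examples
#' lapply(published_loadings("general"), dim)
published_loadings <- function(situation = c("general", "human")) {
  situation <- match.arg(situation)
  species <- c("rhesus", "longtailed", "bonnet")
  out <- lapply(species, function(sp) {
    path <- ratefa_extdata(sprintf("loadings_%s_%s.csv", situation, sp))
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df[-1])
    rownames(m) <- df$item
    storage.mode(m) <- "double"
    m
  })
  setNames(out, species)
}

#' Published item-exclusion annotations
#'
#' The per-species reasons each catalog item was dropped before the final
#' published models: `"Low ICC"` (inter-rater reliability screen),
#' `"Low MSA"` (sampling adequacy), or `"Low Communality"`.
#'
#' @inheritParams published_loadings
#' @return A tibble with columns `species`, `item`, `stage`.
#' @export
published_exclusions <- function(situation = c("general", "human")) {
  situation <- match.arg(situation)
  readr::read_csv(ratefa_extdata(sprintf("exclusions_%s.csv", situation)),
                  show_col_types = FALSE, progress = FALSE)
}

#' Published fuzzy-set factor mapping
#'
#' The assignment of each species' factor (possibly sign-reversed) to the
#' cross-species fuzzy sets, as used for the published intersection tables.
#' Reversals make factors directionally consistent across species before the
#' minimum-absolute-loading intersection is taken.
#'
#' @inheritParams published_loadings
#' @return A `fuzzy_mapping` tibble with columns `set`, `species`, `factor`,
#'   `reversed`.
#' @export
published_fuzzy_mapping <- function(situation = c("general", "human")) {
  situation <- match.arg(situation)
  df <- readr::read_csv(ratefa_extdata(sprintf("fuzzy_mapping_%s.csv", situation)),
                        show_col_types = FALSE, progress = FALSE)
  fuzzy_mapping(df)
}
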