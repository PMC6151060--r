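#' The seven metabolite categories and their default score weights
#'
#' Matched food compounds are grouped into seven categories. The prebiotic
#' food score weights vitamins and amino acids most heavily (essential
#' growth factors usually present at very low concentrations), rewards
#' oligosaccharides, bioactive substances and organic nitrogen compounds,
#' barely counts monosaccharides, and strongly penalizes non-standard
#' nutritive compounds (NSN: trace metals, ethanol-like small organics).
#'
#' @param vitamins,amino_acids,oligosaccharides,bioactive_substances,nitrogenous_compounds,monosaccharides,NSN
#'   Per-category weights; defaults 10, 8, 6, 4, 2, 1 and -100.
#' @return Named numeric vector over exactly the seven categories.
#' @export
category_weights <- function(vitamins = 10, amino_acids = 8,
                             oligosaccharides = 6, bioactive_substances = 4,
                             nitrogenous_compounds = 2, monosaccharides = 1,
                             NSN = -100) {
  c(
    vitamins = vitamins,
    amino_acids = amino_acids,
    oligosaccharides = oligosaccharides,
    bioactive_substances = bioactive_substances,
    nitrogenous_compounds = nitrogenous_compounds,
    monosaccharides = monosaccharides,
    NSN = NSN
  )
}

#' @rdname category_weights
#' @format NULL
#' @export
FOOD_CATEGORIES <- c(
  "oligosaccharides", "monosaccharides", "amino_acids", "vitamins",
  "nitrogenous_compounds", "bioactive_substances", "NSN"
)

#' Growth-factor categories used by the food filter cascade
#' @rdname category_weights
#' @format NULL
#' @export
GROWTH_FACTOR_CATEGORIES <- c(
  "amino_acids", "vitamins", "oligosaccharides", "monosaccharides"
)

DETECTION_LEVELS <- c("quantified", "below_LOQ", "detected_below_LOQ",
                      "not_detected")

#' Normalize a compound name for exact matching
#'
#' Unicode NFC normalization, case folding and whitespace collapse; no
#' fuzzy matching. Nomenclature mismatches between model metabolite names
#' and food-compound names are surfaced in the unmatched report rather
#' than papered over.
#'
#' @param x Character vector of compound names.
#' @return Normalized names.
#' @export
normalize_name <- function(x) {
  x <- stringi::stri_trans_nfc(x)
  x <- stringr::str_to_lower(x)
  stringr::str_squish(x)
}

#' Read a food-composition table
#'
#' @param path TSV with columns `food_id`, `food_name`, `food_class`,
#'   `compound_name`, `concentration_mg_per_100g`, `detection`; or a data
#'   frame with those columns.
#' @return Validated tibble. `detection` must be one of `quantified`,
#'   `below_LOQ`, `detected_below_LOQ`, `not_detected`.
#' @export
read_food_table <- function(path) {
  tbl <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(
      concentration_mg_per_100g = "d", .default = "c"
    ), progress = FALSE)
  }
  need <- c("food_id", "food_name", "food_class", "compound_name",
            "concentration_mg_per_100g", "detection")
  if (!all(need %in% names(tbl))) {
    rlang::abort(paste0("Food table must have columns: ",
                        paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$detection), DETECTION_LEVELS)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown detection status: ",
                        paste(bad, collapse = ", ")))
  }
  tbl$concentration_mg_per_100g <- as.numeric(tbl$concentration_mg_per_100g)
  tbl
}

#' Read a compound-to-category map
#'
#' @param path TSV with columns `compound_name`, `category`; or a data
#'   frame. Categories must be among the seven of [FOOD_CATEGORIES].
#' @return Tibble with normalized `compound_name` plus `category`.
#' @export
read_category_map <- function(path) {
  tbl <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  if (!all(c("compound_name", "category") %in% names(tbl))) {
    rlang::abort("Category map must have columns `compound_name`, `category`.")
  }
  bad <- setdiff(unique(tbl$category), FOOD_CATEGORIES)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown categories: ", paste(bad, collapse = ", ")))
  }
  dplyr::mutate(tbl, compound_name = normalize_name(.data$compound_name)) |>
    dplyr::distinct(.data$compound_name, .keep_all = TRUE)
}

#' Match seed metabolite names into a food-composition table
#'
#' Exact name equality after [normalize_name()]; no fuzzy matching.
#'
#' @param seed_names Character vector of metabolite names to source.
#' @param food_table A [read_food_table()] tibble.
#' @return List with `matched` (sorted character vector of normalized names
#'   found in the table), `unmatched` (names not found), and `table`
#'   (the food table restricted to matched compounds, with a
#'   `compound_norm` column added).
#' @export
match_compounds <- function(seed_names, food_table) {
  stopifnot(length(seed_names) >= 1)
  seeds_norm <- unique(normalize_name(seed_names))
  tbl <- dplyr::mutate(food_table,
                       compound_norm = normalize_name(.data$compound_name))
  present <- unique(tbl$compound_norm)
  matched <- sort(intersect(seeds_norm, present))
  list(
    matched = matched,
    unmatched = sort(setdiff(seeds_norm, present)),
    table = dplyr::filter(tbl, .data$compound_norm %in% matched)
  )
}

is_detected <- function(detection) detection != "not_detected"
is_quantified <- function(detection) detection == "quantified"

#' Food filter cascade
#'
#' Applies the selection cascade to the food table, in order: (1) keep
#' foods containing at least one matched compound; (2) drop foods none of
#' whose matched compounds is quantified (all below the limit of
#' quantification); (3) drop processed foods, alcohol and not-clearly-
#' defined ("other") entries; (4) drop foods where any of the four
#' growth-factor categories (amino acids, vitamins, oligosaccharides,
#' monosaccharides) has no detected compound (limit of detection). Baby
#' foods are an annotated control class and are never dropped at stage 3.
#'
#' @param food_table A [read_food_table()] tibble (full table).
#' @param matched Result of [match_compounds()], or a character vector of
#'   normalized matched compound names.
#' @param category_map A [read_category_map()] tibble covering every
#'   matched compound.
#' @param drop_classes Food classes removed at stage 3.
#' @return List with `retained` (tibble `food_id`, `food_name`,
#'   `food_class` of surviving foods), `cascade` (tibble `stage`,
#'   `description`, `n_foods` of survivor counts after each stage) and
#'   `table` (matched rows of surviving foods with `category` attached).
#' @export
filter_foods <- function(food_table, matched, category_map,
                         drop_classes = c("processed", "alcohol",
                                          "other-undefined")) {
  matched_names <- if (is.list(matched) && !is.data.frame(matched)) {
    matched$matched
  } else {
    normalize_name(as.character(matched))
  }
  tbl <- dplyr::mutate(food_table,
                       compound_norm = normalize_name(.data$compound_name))
  mtbl <- dplyr::filter(tbl, .data$compound_norm %in% matched_names)
  missing_cat <- setdiff(unique(mtbl$compound_norm),
                         category_map$compound_name)
  if (length(missing_cat) > 0) {
    rlang::abort(paste0("Matched compounds without a category: ",
                        paste(missing_cat, collapse = ", ")))
  }
  mtbl <- dplyr::left_join(
    mtbl, dplyr::select(category_map, "compound_name", "category"),
    by = c(compound_norm = "compound_name")
  )

  # stage 1: foods containing >= 1 matched compound
  s1 <- sort(unique(mtbl$food_id))
  # stage 2: at least one matched compound above LOQ (quantified)
  s2 <- mtbl |>
    dplyr::filter(.data$food_id %in% s1) |>
    dplyr::group_by(.data$food_id) |>
    dplyr::summarise(any_q = any(is_quantified(.data$detection)),
                     .groups = "drop") |>
    dplyr::filter(.data$any_q) |>
    dplyr::pull("food_id") |>
    sort()
  # stage 3: remove processed / alcohol / undefined classes (baby foods kept)
  classes <- dplyr::distinct(tbl, .data$food_id, .data$food_class)
  s3 <- classes |>
    dplyr::filter(.data$food_id %in% s2,
                  !.data$food_class %in% drop_classes |
                    .data$food_class == "baby-food") |>
    dplyr::pull("food_id") |>
    sort()
  # stage 4: every growth-factor category has a detected matched compound
  s4 <- mtbl |>
    dplyr::filter(.data$food_id %in% s3,
                  .data$category %in% GROWTH_FACTOR_CATEGORIES,
                  is_detected(.data$detection)) |>
    dplyr::distinct(.data$food_id, .data$category) |>
    dplyr::count(.data$food_id) |>
    dplyr::filter(.data$n == length(GROWTH_FACTOR_CATEGORIES)) |>
    dplyr::pull("food_id") |>
    sort()

  cascade <- tibble::tibble(
    stage = 1:4,
    description = c(
      "contains >=1 matched compound",
      "matched compound above LOQ",
      "not processed/alcohol/undefined",
      "all growth-factor categories detected (LOD)"
    ),
    n_foods = c(length(s1), length(s2), length(s3), length(s4))
  )
  retained <- classes |>
    dplyr::filter(.data$food_id %in% s4) |>
    dplyr::left_join(dplyr::distinct(tbl, .data$food_id, .data$food_name),
                     by = "food_id") |>
    dplyr::select("food_id", "food_name", "food_class") |>
    dplyr::arrange(.data$food_id)
  list(
    retained = retained,
    cascade = cascade,
    table = dplyr::filter(mtbl, .data$food_id %in% s4)
  )
}

#' Per-category mean concentrations of one food
#'
#' For each of the seven categories, the mean concentration (mg/100 g) over
#' the food's matched, quantified compounds of that category; 0 when the
#' category has no quantified compound in the food.
#'
#' @param food_rows Rows of a matched food table (with `category` attached,
#'   as in the `table` element of [filter_foods()]) for one or more foods.
#' @return Tibble: one row per food, columns `food_id`, `food_name` and the
#'   seven category means.
#' @export
category_profile <- function(food_rows) {
  stopifnot(all(c("food_id", "category", "concentration_mg_per_100g",
                  "detection") %in% names(food_rows)))
  base <- dplyr::distinct(food_rows, .data$food_id, .data$food_name)
  means <- food_rows |>
    dplyr::filter(is_quantified(.data$detection),
                  !is.na(.data$concentration_mg_per_100g)) |>
    dplyr::group_by(.data$food_id, .data$category) |>
    dplyr::summarise(mean_conc = mean(.data$concentration_mg_per_100g),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "category", values_from = "mean_conc")
  for (cat in FOOD_CATEGORIES) {
    if (!cat %in% names(means)) means[[cat]] <- NA_real_
  }
  out <- dplyr::left_join(base, means, by = "food_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(FOOD_CATEGORIES),
                                ~ dplyr::coalesce(.x, 0))) |>
    dplyr::select("food_id", "food_name",
                  dplyr::all_of(c("vitamins", "amino_acids",
                                  "oligosaccharides", "bioactive_substances",
                                  "nitrogenous_compounds", "monosaccharides",
                                  "NSN"))) |>
    dplyr::arrange(.data$food_id)
  out
}

#' Normalize category profiles and rank foods by prebiotic score
#'
#' Each category is min-max normalized to [0, 1] across the retained
#' cohort (`(x - min) / (max - min)`; all zero when the category is
#' constant), and the food score is the weighted sum of normalized values.
#' Foods are ranked by descending score, ties broken by food name.
#'
#' @param profiles A [category_profile()] tibble over the retained foods.
#' @param weights A [category_weights()] vector.
#' @return Tibble of class `food_scores`: `rank`, `food_id`, `food_name`,
#'   `score`, the seven raw category means and the seven normalized values
#'   (`<category>_norm`). The normalization cohort is recorded in the
#'   `cohort` attribute.
#' @export
normalize_and_score <- function(profiles, weights = category_weights()) {
  stopifnot(nrow(profiles) >= 1,
            all(FOOD_CATEGORIES %in% names(profiles)),
            all(FOOD_CATEGORIES %in% names(weights)))
  out <- profiles
  for (cat in FOOD_CATEGORIES) {
    x <- out[[cat]]
    rng <- range(x)
    out[[paste0(cat, "_norm")]] <- if (rng[2] > rng[1]) {
      (x - rng[1]) / (rng[2] - rng[1])
    } else {
      rep(0, length(x))
    }
  }
  norm_cols <- paste0(names(weights), "_norm")
  out$score <- as.vector(
    as.matrix(out[, norm_cols, drop = FALSE]) %*% unname(weights)
  )
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$score), .data$food_name) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  attr(out, "cohort") <- sort(out$food_id)
  attr(out, "weights") <- weights
  class(out) <- c("food_scores", class(out))
  out
}

#' Rank prebiotic candidate foods end to end
#'
#' Convenience wrapper: match seed metabolite names, run the filter
#' cascade, profile the retained foods and score them.
#'
#' @param seed_names Metabolite names to source.
#' @param food_table A [read_food_table()] tibble.
#' @param category_map A [read_category_map()] tibble.
#' @param weights A [category_weights()] vector.
#' @return List with `scores` ([normalize_and_score()] result), `cascade`,
#'   `matched`, `unmatched`.
#' @export
rank_foods <- function(seed_names, food_table, category_map,
                       weights = category_weights()) {
  m <- match_compounds(seed_names, food_table)
  f <- filter_foods(food_table, m, category_map)
  if (nrow(f$retained) == 0) {
    return(list(scores = NULL, cascade = f$cascade,
                matched = m$matched, unmatched = m$unmatched))
  }
  prof <- category_profile(f$table)
  list(
    scores = normalize_and_score(prof, weights),
    cascade = f$cascade,
    matched = m$matched,
    unmatched = m$unmatched
  )
}

#' Long-format community/food relation tables
#'
#' Emits the metabolite-to-food and category-to-food relation tables behind
#' circular community/food plots, keeping only foods that cover at least
#' `coverage` of the community-shared metabolites.
#'
#' @param shared_compounds Character vector of (normalized) metabolite
#'   names shared across the community.
#' @param food_rows Matched rows of retained foods (with `category`), as in
#'   the `table` element of [filter_foods()].
#' @param coverage Minimum fraction of `shared_compounds` a food must
#'   contain (default 0.7).
#' @return List with `foods` (tibble `food_id`, `food_name`, `n_compounds`,
#'   `coverage`), `metabolite_food` (tibble `compound_norm`, `food_id`,
#'   `mean_concentration`) and `category_food` (tibble `category`,
#'   `food_id`, `mean_concentration`), all restricted to covering foods.
#' @export
community_food_tables <- function(shared_compounds, food_rows,
                                  coverage = 0.7) {
  stopifnot(length(shared_compounds) >= 1, coverage >= 0, coverage <= 1)
  shared <- unique(normalize_name(shared_compounds))
  rows <- dplyr::filter(food_rows, .data$compound_norm %in% shared)
  cov <- rows |>
    dplyr::distinct(.data$food_id, .data$food_name, .data$compound_norm) |>
    dplyr::group_by(.data$food_id, .data$food_name) |>
    dplyr::summarise(n_compounds = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(coverage = .data$n_compounds / length(shared)) |>
    dplyr::filter(.data$coverage >= !!coverage) |>
    dplyr::arrange(.data$food_id)
  rows <- dplyr::filter(rows, .data$food_id %in% cov$food_id)
  metabolite_food <- rows |>
    dplyr::filter(is_quantified(.data$detection)) |>
    dplyr::group_by(.data$compound_norm, .data$food_id) |>
    dplyr::summarise(
      mean_concentration = mean(.data$concentration_mg_per_100g),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$compound_norm, .data$food_id)
  category_food <- rows |>
    dplyr::filter(is_quantified(.data$detection)) |>
    dplyr::group_by(.data$category, .data$food_id) |>
    dplyr::summarise(
      mean_concentration = mean(.data$concentration_mg_per_100g),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category, .data$food_id)
  list(foods = cov, metabolite_food = metabolite_food,
       category_food = category_food)
}
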