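mini_table <- function() {
  tibble::tibble(
    food_id = c("F1", "F1", "F2"),
    food_name = c("apple", "apple", "beer"),
    food_class = c("regular", "regular", "alcohol"),
    compound_name = c("D-Glucose", "L-Alanine", "d-glucose"),
    concentration_mg_per_100g = c(100, 5, 50),
    detection = "quantified"
  )
}

test_that("compound matching is exact after normalization, never fuzzy", {
  m <- match_compounds(c("D-Glucose", "model-only-xyz"), mini_table())
  expect_equal(m$matched, "d-glucose")
  expect_equal(m$unmatched, c("model-only-xyz"))
  expect_equal(normalize_name("  L-Alanine  extra  "),
               normalize_name("l-alanine  extra"))
  expect_equal(normalize_name("A   B"), "a b")
})

test_that("the filter cascade drops foods for the documented reasons, in order", {
  cmap <- read_category_map(tibble::tibble(
    compound_name = c("glc", "ala", "vit", "oligo", "metal"),
    category = c("monosaccharides", "amino_acids", "vitamins",
                 "oligosaccharides", "NSN")
  ))
  full_food <- function(id, name, class, detection = "quantified") {
    tibble::tibble(
      food_id = id, food_name = name, food_class = class,
      compound_name = c("glc", "ala", "vit", "oligo"),
      concentration_mg_per_100g = c(10, 5, 1, 20),
      detection = detection
    )
  }
  tbl <- dplyr::bind_rows(
    full_food("OK", "good food", "regular"),
    full_food("ALC", "strong drink", "alcohol"),
    full_food("LOQ", "faint food", "regular", detection = "below_LOQ"),
    # only an NSN compound: growth-factor categories undetected
    tibble::tibble(food_id = "NSN", food_name = "metal food",
                   food_class = "regular", compound_name = "metal",
                   concentration_mg_per_100g = 3,
                   detection = "quantified"),
    full_food("BABY", "baby blend", "baby-food")
  )
  res <- filter_foods(tbl, c("glc", "ala", "vit", "oligo", "metal"), cmap)
  expect_equal(res$cascade$n_foods, c(5, 4, 3, 2))
  expect_setequal(res$retained$food_id, c("OK", "BABY"))
  # cascade counts never increase and the cascade is idempotent
  expect_true(all(diff(res$cascade$n_foods) <= 0))
  res2 <- filter_foods(dplyr::semi_join(tbl, res$retained, by = "food_id"),
                       c("glc", "ala", "vit", "oligo", "metal"), cmap)
  expect_setequal(res2$retained$food_id, res$retained$food_id)
  # a matched compound without category is an error, not a silent NA
  expect_error(
    filter_foods(tbl, c("glc", "ala", "vit", "oligo", "metal"),
                 cmap[cmap$compound_name != "metal", ]),
    "metal"
  )
})

test_that("category profiles average quantified compounds and default to zero", {
  rows <- tibble::tibble(
    food_id = "F", food_name = "f", food_class = "regular",
    compound_name = c("a", "b", "c"),
    compound_norm = c("a", "b", "c"),
    category = c("vitamins", "vitamins", "amino_acids"),
    concentration_mg_per_100g = c(2, 4, NA),
    detection = c("quantified", "quantified", "below_LOQ")
  )
  prof <- category_profile(rows)
  expect_equal(prof$vitamins, 3)          # mean of 2 and 4
  expect_equal(prof$amino_acids, 0)       # no quantified compound
  expect_equal(prof$NSN, 0)               # category absent entirely
})

test_that("the printed honey reference row round-trips verbatim", {
  prof <- category_profile(honey_food_rows())
  expect_equal(as.data.frame(prof), as.data.frame(honey_expected_profile()),
               tolerance = 1e-12)
})

test_that("scoring normalizes per category and ranks deterministically", {
  # a single food: every normalized value 0, score 0
  single <- category_profile(honey_food_rows())
  sc <- normalize_and_score(single)
  expect_equal(sc$score, 0)
  expect_true(all(as.matrix(sc[paste0(FOOD_CATEGORIES, "_norm")]) == 0))

  # dominance: a food leading every positive category with zero NSN wins
  prof2 <- tibble::tibble(
    food_id = c("A", "B"), food_name = c("alpha", "beta"),
    vitamins = c(10, 1), amino_acids = c(8, 2),
    oligosaccharides = c(5, 1), bioactive_substances = c(4, 1),
    nitrogenous_compounds = c(2, 1), monosaccharides = c(9, 3),
    NSN = c(0, 5)
  )
  sc2 <- normalize_and_score(prof2)
  expect_equal(sc2$food_id[1], "A")
  expect_true(all(sc2$score[1] > sc2$score[-1]))
})

test_that("generated food fixtures reproduce manifest cascade and ranking", {
  gen <- generate_food_table(n_foods = 50, rng_seed = 21)
  rf <- rank_foods(gen$seed_names, gen$food_table, gen$category_map)
  expect_equal(rf$cascade$n_foods, unname(gen$manifest$cascade_counts))
  expect_equal(rf$scores$food_id, gen$manifest$ranking$food_id)
  expect_equal(rf$scores$score, gen$manifest$ranking$score,
               tolerance = 1e-12)
  expect_setequal(rf$matched, gen$manifest$matched)
  expect_setequal(rf$unmatched, gen$manifest$unmatched)
})

test_that("ranking is invariant under positive per-category rescaling", {
  gen <- generate_food_table(n_foods = 25, rng_seed = 33)
  base <- rank_foods(gen$seed_names, gen$food_table, gen$category_map)
  scaled_tbl <- gen$food_table
  cmap <- gen$category_map
  cat_of <- stats::setNames(cmap$category, cmap$compound_name)
  cat_col <- unname(cat_of[normalize_name(scaled_tbl$compound_name)])
  factor_of <- c(vitamins = 1000, amino_acids = 0.01, oligosaccharides = 7,
                 bioactive_substances = 1, nitrogenous_compounds = 3,
                 monosaccharides = 0.5, NSN = 42)
  scaled_tbl$concentration_mg_per_100g <-
    scaled_tbl$concentration_mg_per_100g *
    ifelse(is.na(cat_col), 1, factor_of[cat_col])
  scaled <- rank_foods(gen$seed_names, scaled_tbl, cmap)
  expect_equal(scaled$scores$food_id, base$scores$food_id)
  expect_equal(scaled$scores$score, base$scores$score, tolerance = 1e-9)
})

test_that("inflating a food's NSN mean never improves its rank", {
  withr::local_seed(44)
  gen <- generate_food_table(n_foods = 30, rng_seed = 13)
  base <- rank_foods(gen$seed_names, gen$food_table, gen$category_map)
  nsn_names <- gen$category_map$compound_name[
    gen$category_map$category == "NSN"
  ]
  nsn_max <- max(base$scores$NSN)
  for (trial in 1:25) {
    victim <- sample(base$scores$food_id, 1)
    tbl <- gen$food_table
    hit <- tbl$food_id == victim &
      normalize_name(tbl$compound_name) %in% nsn_names &
      tbl$detection == "quantified"
    if (!any(hit)) next
    # raise NSN concentrations but keep the cohort's NSN max fixed
    cur <- base$scores$NSN[base$scores$food_id == victim]
    if (cur >= nsn_max) next
    tbl$concentration_mg_per_100g[hit] <-
      tbl$concentration_mg_per_100g[hit] * stats::runif(1, 1, 1.5)
    res <- rank_foods(gen$seed_names, tbl, gen$category_map)
    new_nsn <- res$scores$NSN[res$scores$food_id == victim]
    if (new_nsn > max(res$scores$NSN[res$scores$food_id != victim])) next
    old_rank <- base$scores$rank[base$scores$food_id == victim]
    new_rank <- res$scores$rank[res$scores$food_id == victim]
    expect_gte(new_rank, old_rank)
  }
})

test_that("single-weight scoring reduces to ranking by that category mean", {
  gen <- generate_food_table(n_foods = 15, rng_seed = 3)
  w <- category_weights(vitamins = 1, amino_acids = 0, oligosaccharides = 0,
                        bioactive_substances = 0,
                        nitrogenous_compounds = 0, monosaccharides = 0,
                        NSN = 0)
  rf <- rank_foods(gen$seed_names, gen$food_table, gen$category_map,
                   weights = w)
  by_vit <- dplyr::arrange(rf$scores, dplyr::desc(vitamins), food_name)
  expect_equal(rf$scores$food_id, by_vit$food_id)
})

test_that("community food tables apply the coverage threshold by counting", {
  rows <- purrr::map_dfr(1:15, function(f) {
    n_cpd <- sample(4:10, 1)
    tibble::tibble(
      food_id = sprintf("F%02d", f), food_name = sprintf("food %02d", f),
      food_class = "regular",
      compound_name = sprintf("met %02d", sample(1:10, n_cpd)),
      compound_norm = NA_character_,
      category = "vitamins",
      concentration_mg_per_100g = 1, detection = "quantified"
    )
  })
  rows$compound_norm <- normalize_name(rows$compound_name)
  shared <- sprintf("met %02d", 1:10)
  cft <- community_food_tables(shared, rows, coverage = 0.7)
  brute <- rows |>
    dplyr::distinct(food_id, compound_norm) |>
    dplyr::count(food_id) |>
    dplyr::filter(n >= 7) |>
    dplyr::pull(food_id)
  expect_setequal(cft$foods$food_id, brute)
  # full-coverage food is retained at any threshold; impossible threshold
  # empties the table
  all_rows <- tibble::tibble(
    food_id = "ALL", food_name = "complete", food_class = "regular",
    compound_name = shared, compound_norm = normalize_name(shared),
    category = "vitamins", concentration_mg_per_100g = 1,
    detection = "quantified"
  )
  expect_equal(community_food_tables(shared, all_rows,
                                     coverage = 1)$foods$food_id, "ALL")
  missing_one <- all_rows[-1, ]
  expect_equal(nrow(community_food_tables(shared, missing_one,
                                          coverage = 1)$foods), 0)
})
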