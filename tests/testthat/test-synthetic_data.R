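test_that("generators are byte-identical under a fixed seed", {
  a <- generate_network(8, 3, rng_seed = 5)
  b <- generate_network(8, 3, rng_seed = 5)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$true_seeds, b$true_seeds)
  c <- generate_network(8, 3, rng_seed = 6)
  expect_false(identical(a$network$edges, c$network$edges))

  f1 <- generate_food_table(n_foods = 10, rng_seed = 2)
  f2 <- generate_food_table(n_foods = 10, rng_seed = 2)
  expect_identical(f1$food_table, f2$food_table)
  expect_identical(f1$manifest$ranking, f2$manifest$ranking)

  g1 <- generate_corpus(c("gut-microbes+immune-related" = 3), rng_seed = 4)
  g2 <- generate_corpus(c("gut-microbes+immune-related" = 3), rng_seed = 4)
  expect_identical(g1$corpus, g2$corpus)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(generate_network(5, 2, rng_seed = 9))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("network generator plants exactly the requested source components", {
  expect_error(generate_network(3, 5), "n_source_components")
  single <- generate_network(1, 1, component_sizes = 1, rng_seed = 1)
  expect_equal(single$true_seeds$confidence, 1)
  expect_equal(nrow(single$network$compounds), 1)

  chain <- generate_network(3, 1, component_sizes = c(2, 1, 1),
                            rng_seed = 2)
  expect_equal(nrow(chain$true_seeds), 2)  # the 2-cycle source members
  expect_equal(chain$true_seeds$confidence, c(0.5, 0.5))

  withr::local_seed(1)
  for (rep in 1:20) {
    n_comp <- sample(2:12, 1)
    n_src <- sample(1:n_comp, 1)
    gen <- generate_network(n_comp, n_src, rng_seed = rep)
    expect_seed_sets_equal(detect_seeds(gen$network), gen$true_seeds)
    expect_equal(detect_seeds(gen$network)$total_weight, n_src)
  }
})

test_that("community generator rejects infeasible overlap designs", {
  ov <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  expect_error(generate_community(2, 10, matrix(c(0, .75, .8, 0), 2, 2)),
               "symmetric")
  too_much <- matrix(0, 3, 3)
  too_much[1, 2] <- too_much[2, 1] <- 0.7
  too_much[1, 3] <- too_much[3, 1] <- 0.7
  expect_error(generate_community(3, 10, too_much), "Infeasible")
  expect_error(generate_community(2, 10, matrix(c(0, .33, .33, 0), 2, 2)),
               "whole numbers")
  ct <- matrix(0, 2, 2); ct[1, 2] <- 0.9
  expect_error(generate_community(2, 10, ov, complementarity_targets = ct),
               "Infeasible")
})

test_that("zero overlap programs zero competition", {
  cm <- generate_community(2, 10, rng_seed = 2)
  mats <- pairwise_matrices(cm$community)
  expect_equal(mats$competition[1, 2], 0)
  expect_equal(mats$competition[2, 1], 0)
})

test_that("random feasible community designs are recovered entrywise", {
  withr::local_seed(7)
  for (rep in 1:5) {
    k <- 4
    n_seeds <- 20
    ov <- matrix(0, k, k)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        ov[i, j] <- ov[j, i] <- sample(0:4, 1) / n_seeds
      }
    }
    cm <- generate_community(k, n_seeds, ov, rng_seed = 100 + rep)
    mats <- pairwise_matrices(cm$community)
    expect_equal(unname(mats$competition),
                 unname(cm$manifest$competition), tolerance = 1e-12)
    expect_equal(unname(mats$complementarity),
                 unname(cm$manifest$complementarity), tolerance = 1e-12)
  }
})

test_that("food generator honors planted violator counts", {
  gen <- generate_food_table(
    n_foods = 12,
    violators = c(no_match = 1, loq = 2, class = 3, growth_factor = 1),
    rng_seed = 19
  )
  cc <- gen$manifest$cascade_counts
  # 12 clean + 2 loq + 3 class + 1 growth-factor contain matched compounds
  expect_equal(unname(cc["stage1"]), 18)
  expect_equal(unname(cc["stage2"]), 16)   # the 2 LOQ foods drop
  expect_equal(unname(cc["stage3"]), 13)   # the 3 class foods drop
  expect_equal(unname(cc["stage4"]), 12)   # the vitamin-free food drops
  # all foods below LOQ leaves no survivors
  all_loq <- generate_food_table(
    n_foods = 1, violators = c(no_match = 0, loq = 3, class = 0,
                               growth_factor = 0),
    rng_seed = 20
  )
  tbl <- all_loq$food_table
  tbl$detection <- "below_LOQ"
  tbl$concentration_mg_per_100g <- NA_real_
  res <- filter_foods(tbl, normalize_name(all_loq$seed_names),
                      all_loq$category_map)
  expect_equal(res$cascade$n_foods[2], 0)
})

test_that("annotation generator plants the forced-overlap extreme correctly", {
  gen <- generate_annotation(
    n_pathways = 5, universe_size = 60, n_seed_compounds = 6,
    planted = list(pathway_size = 6, overlap = 6), rng_seed = 42
  )
  res <- enrich_seeds(gen$seed_compounds, gen$annotation)
  planted <- res[res$pathway_id == gen$manifest$planted_pathway, ]
  expect_equal(planted$k, 6)
  expect_equal(planted$p, hypergeom_upper_tail(planted$N, 6, planted$n, 6))
  expect_equal(res$pathway_id[which.min(res$p)], "path001")
})

test_that("an empty co-mention grid yields no qualifying sentences", {
  gen <- generate_corpus(
    c("gut-microbes+immune-related" = 0),
    victims = c(year = 0, title = 0, excluded_animal = 0,
                species_level = 0),
    rng_seed = 3
  )
  hits <- annotate_corpus(gen$corpus, dplyr::bind_rows(gen$dictionaries))
  main <- sort(setdiff(names(gen$dictionaries), "animal-models"))
  counts <- combination_counts(hits, main)
  expect_true(all(counts$n_sentences == 0))
})

test_that("a four-dictionary sentence qualifies for every subsumed combination", {
  gen <- generate_corpus(
    c("chemical-related+gut-microbes+immune-related+infection-disease" = 1),
    victims = c(year = 0, title = 0, excluded_animal = 0,
                species_level = 0),
    rng_seed = 13
  )
  hits <- annotate_corpus(gen$corpus, dplyr::bind_rows(gen$dictionaries))
  main <- sort(setdiff(names(gen$dictionaries), "animal-models"))
  counts <- combination_counts(hits, main)
  expect_true(all(counts$n_sentences == 1))  # all 11 combinations
  expect_equal(nrow(counts), 11)
})
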