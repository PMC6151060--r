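tiny_corpus <- function(sentences, year = 2010, section = "abstract") {
  tibble::tibble(
    doc_id = "PMID0000001", year = year, section_label = section,
    sentence_id = seq_along(sentences), sentence = sentences
  )
}

test_that("annotation is case-insensitive, word-bounded and longest-match-first", {
  dicts <- default_dictionaries()
  hits <- annotate_corpus(
    tiny_corpus("lactobacillus rhamnosus reduced diarrhea"),
    dicts[c("gut-microbes", "infection-disease")]
  )
  # the species term wins over its embedded genus term
  expect_equal(nrow(hits[hits$dictionary == "gut-microbes", ]), 1)
  expect_equal(hits$term[hits$dictionary == "gut-microbes"],
               "Lactobacillus rhamnosus")
  expect_equal(hits$level[hits$dictionary == "gut-microbes"], "species")
  # no partial-word matches
  none <- annotate_corpus(tiny_corpus("inulinase activity only"),
                          dicts["chemical-related"])
  expect_equal(nrow(none[none$term == "inulin", ]), 0)
  empty <- annotate_corpus(tiny_corpus("nothing relevant here"), dicts)
  expect_equal(nrow(empty), 0)
  # surviving spans never overlap
  multi <- annotate_corpus(
    tiny_corpus("Lactobacillus and Lactobacillus rhamnosus with inulin"),
    dicts
  )
  spans <- multi[order(multi$start), c("start", "end")]
  if (nrow(spans) > 1) {
    expect_true(all(spans$start[-1] > spans$end[-nrow(spans)]))
  }
})

test_that("annotation recall and precision are exact on a planted corpus", {
  grid <- c("gut-microbes+immune-related" = 3,
            "chemical-related+infection-disease" = 2)
  gen <- generate_corpus(grid, victims = c(year = 0, title = 0,
                                           excluded_animal = 0,
                                           species_level = 0),
                         rng_seed = 61)
  hits <- annotate_corpus(gen$corpus, dplyr::bind_rows(gen$dictionaries))
  # every planted sentence is found with exactly its planted dictionaries
  planted <- gen$corpus[gen$corpus$section_label != "title", ]
  found <- hits |>
    dplyr::distinct(doc_id, sentence_id, dictionary) |>
    dplyr::count(doc_id, sentence_id)
  expect_equal(nrow(found), nrow(planted))
  expect_true(all(found$n == 2))
  # document order permutation does not change the hit set
  withr::local_seed(5)
  shuffled <- gen$corpus[sample(nrow(gen$corpus)), ]
  hits2 <- annotate_corpus(shuffled, dplyr::bind_rows(gen$dictionaries))
  key <- function(h) {
    sort(paste(h$doc_id, h$sentence_id, h$dictionary, h$term, h$start))
  }
  expect_equal(key(hits2), key(hits))
})

test_that("co-occurrence extraction respects combination and mode contracts", {
  dicts <- default_dictionaries()
  corpus <- tiny_corpus(c(
    "Lactobacillus rhamnosus strengthened the immune system",
    "only the immune system is mentioned here",
    "Bifidobacterium longum with inulin improved the immune system"
  ))
  hits <- annotate_corpus(corpus, dicts)
  rel <- extract_cooccurrences(hits, c("gut-microbes", "immune-related"))
  expect_equal(nrow(rel), 2)
  expect_equal(attr(rel, "n_documents"), 1)
  # one-dictionary sentences never qualify
  expect_false(2 %in% rel$sentence_id)
  expect_error(extract_cooccurrences(hits, "gut-microbes"), "exactly 2")
  expect_error(
    extract_cooccurrences(hits, c("gut-microbes", "immune-related"),
                          mode = "comention"),
    "at least 3"
  )
  # adding a dictionary constraint never adds sentences
  co3 <- extract_cooccurrences(
    hits, c("gut-microbes", "immune-related", "chemical-related"),
    mode = "comention"
  )
  expect_true(all(paste(co3$doc_id, co3$sentence_id) %in%
                    paste(rel$doc_id, rel$sentence_id)))
  # a pluggable predicate can reject sentences
  none <- extract_cooccurrences(hits, c("gut-microbes", "immune-related"),
                                predicate = function(m) FALSE)
  expect_equal(nrow(none), 0)
})

test_that("planted combination grids are counted exactly, with subsumption", {
  grid <- c(
    "gut-microbes+immune-related" = 4,
    "chemical-related+gut-microbes" = 3,
    "chemical-related+gut-microbes+immune-related" = 2,
    "chemical-related+gut-microbes+immune-related+infection-disease" = 1
  )
  gen <- generate_corpus(grid, rng_seed = 71)
  hits <- annotate_corpus(gen$corpus, dplyr::bind_rows(gen$dictionaries))
  main <- sort(setdiff(names(gen$dictionaries), "animal-models"))
  counts <- combination_counts(hits, main)
  man <- gen$manifest$combination_counts
  merged <- dplyr::inner_join(counts, man, by = c("combo", "mode",
                                                  "n_dictionaries"),
                              suffix = c("", ".man"))
  expect_equal(nrow(merged), nrow(man))
  expect_equal(merged$n_sentences, merged$n_sentences.man)
  expect_equal(merged$n_documents, merged$n_documents.man)
  # the four-dictionary sentence subsumes into every pair it covers
  expect_gte(
    counts$n_sentences[counts$combo == "gut-microbes+immune-related"],
    grid[["gut-microbes+immune-related"]] +
      grid[["chemical-related+gut-microbes+immune-related"]] +
      1
  )
})

test_that("the filter chain removes sentences for the documented reasons", {
  gen <- generate_corpus(
    c("gut-microbes+immune-related" = 5),
    victims = c(year = 2, title = 1, excluded_animal = 2,
                species_level = 3),
    rng_seed = 81
  )
  hits <- annotate_corpus(gen$corpus, dplyr::bind_rows(gen$dictionaries))
  rec <- extract_cooccurrences(hits, c("gut-microbes", "immune-related"))
  fc <- filter_chain(rec)
  expect_equal(fc$removals, gen$manifest$removals)
  expect_equal(nrow(fc$records), gen$manifest$n_kept)
  # total removed equals the sum of per-rule removals
  expect_equal(nrow(rec) - nrow(fc$records), sum(fc$removals$n_removed))
  # the chain is idempotent
  fc2 <- filter_chain(fc$records)
  expect_equal(nrow(fc2$records), nrow(fc$records))
  expect_true(all(fc2$removals$n_removed == 0))
})

test_that("species frequencies count sentences once and match the manifest", {
  gen <- generate_corpus(
    c("gut-microbes+immune-related" = 8),
    victims = c(year = 1, title = 0, excluded_animal = 1,
                species_level = 2),
    rng_seed = 91
  )
  hits <- annotate_corpus(gen$corpus, dplyr::bind_rows(gen$dictionaries))
  rec <- extract_cooccurrences(hits, c("gut-microbes", "immune-related"))
  fc <- filter_chain(rec)
  sf <- species_frequency(fc$records)
  expect_equal(as.data.frame(sf),
               as.data.frame(gen$manifest$species_frequency))
  # a sentence mentioning a species twice counts once
  dicts <- default_dictionaries()
  corpus <- tiny_corpus(paste(
    "Lactobacillus rhamnosus and again Lactobacillus rhamnosus",
    "boosted the immune system"
  ))
  h2 <- annotate_corpus(corpus, dicts)
  r2 <- extract_cooccurrences(h2, c("gut-microbes", "immune-related"))
  s2 <- species_frequency(r2)
  expect_equal(s2$n_sentences, 1L)
  expect_equal(nrow(species_frequency(r2[0, ])), 0)
})

test_that("corpora round-trip through JSON lines", {
  gen <- generate_corpus(c("gut-microbes+immune-related" = 3),
                         rng_seed = 15)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(gen$corpus, path)
  back <- read_corpus(path)
  expect_equal(
    dplyr::arrange(back, doc_id, sentence_id),
    dplyr::arrange(gen$corpus, doc_id, sentence_id)
  )
})
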