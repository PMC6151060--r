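#' Read a term dictionary
#'
#' A dictionary maps surface terms to canonical concepts, with tags used by
#' the filter chain: `level` (genus/species/strain, for microbial terms),
#' `pathogen` and `excluded_animal` flags.
#'
#' @param path TSV with columns `term`, `concept`, `level`, `pathogen`,
#'   `excluded_animal`; or a data frame. Missing tag columns are filled
#'   with defaults (`NA` level, `FALSE` flags).
#' @param name Dictionary name (e.g. `"gut-microbes"`, `"immune-related"`,
#'   `"infection-disease"`, `"chemical-related"`).
#' @return Tibble with a `dictionary` column prepended.
#' @export
read_dictionary <- function(path, name) {
  tbl <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  if (!all(c("term", "concept") %in% names(tbl))) {
    rlang::abort("Dictionary needs `term` and `concept` columns.")
  }
  if (any(!nzchar(tbl$term))) rlang::abort("Dictionary terms must be non-empty.")
  if (!"level" %in% names(tbl)) tbl$level <- NA_character_
  for (col in c("pathogen", "excluded_animal")) {
    if (!col %in% names(tbl)) tbl[[col]] <- FALSE
    tbl[[col]] <- tolower(as.character(tbl[[col]])) %in% c("true", "1", "yes")
  }
  dplyr::mutate(tbl, dictionary = name, .before = 1) |>
    dplyr::select("dictionary", "term", "concept", "level",
                  "pathogen", "excluded_animal")
}

#' Read a sentence-segmented corpus from JSON lines
#'
#' One document per line: `{"doc_id": ..., "year": ..., "sections":
#' [{"label": ..., "sentences": [...]}, ...]}`.
#'
#' @param path JSONL file path.
#' @return Corpus tibble: `doc_id`, `year`, `section_label`, `sentence_id`
#'   (per document), `sentence`.
#' @export
read_corpus <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  purrr::map_dfr(docs, function(d) {
    sent_tbl <- purrr::map_dfr(d$sections, function(s) {
      tibble::tibble(
        section_label = d_chr(s$label),
        sentence = unname(vapply(s$sentences, as.character, character(1),
                                 USE.NAMES = FALSE))
      )
    })
    if (nrow(sent_tbl) == 0) return(NULL)
    dplyr::mutate(sent_tbl,
                  doc_id = d_chr(d$doc_id),
                  year = as.integer(d$year),
                  sentence_id = dplyr::row_number(),
                  .before = 1)
  })
}

d_chr <- function(x) as.character(x %||% NA_character_)

#' Write a corpus tibble as JSON lines
#'
#' @param corpus A [read_corpus()]-shaped tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  docs <- corpus |>
    dplyr::group_by(.data$doc_id, .data$year) |>
    dplyr::group_split()
  lines <- vapply(docs, function(d) {
    secs <- lapply(unique(d$section_label), function(lbl) {
      d[d$section_label == lbl, , drop = FALSE]
    })
    jsonlite::toJSON(list(
      doc_id = d$doc_id[1],
      year = d$year[1],
      sections = lapply(secs, function(s) {
        list(label = s$section_label[1], sentences = s$sentence)
      })
    ), auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Annotate a corpus with dictionary terms
#'
#' Case-insensitive, word-boundary, longest-match-first matching of every
#' dictionary term against every sentence. When candidate matches overlap
#' (e.g. a species binomial containing its genus name), the longer term
#' wins and shorter overlapping candidates are discarded, so surviving
#' spans never overlap.
#'
#' @param corpus A [read_corpus()] tibble.
#' @param dictionaries One combined dictionary tibble (rows from
#'   [read_dictionary()]) or a list of them.
#' @return Hits tibble: corpus columns plus `dictionary`, `term`,
#'   `concept`, `level`, `pathogen`, `excluded_animal`, `start`, `end`
#'   (character offsets within the sentence).
#' @export
annotate_corpus <- function(corpus, dictionaries) {
  dict <- if (is.data.frame(dictionaries)) {
    tibble::as_tibble(dictionaries)
  } else {
    dplyr::bind_rows(dictionaries)
  }
  stopifnot(nrow(dict) > 0)
  dict <- dict |>
    dplyr::arrange(dplyr::desc(nchar(.data$term)), .data$term,
                   .data$dictionary)
  patterns <- stringr::regex(
    paste0("\\b", stringr::str_replace_all(
      dict$term, "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1"
    ), "\\b"),
    ignore_case = TRUE
  )
  hits <- purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    sent <- corpus$sentence[i]
    taken <- logical(nchar(sent))
    rows <- list()
    for (j in seq_len(nrow(dict))) {
      locs <- stringr::str_locate_all(sent, patterns[j])[[1]]
      if (nrow(locs) == 0) next
      for (r in seq_len(nrow(locs))) {
        span <- locs[r, 1]:locs[r, 2]
        if (any(taken[span])) next  # longer term already claimed these chars
        taken[span] <- TRUE
        rows[[length(rows) + 1]] <- tibble::tibble(
          row = i, dict_row = j,
          start = unname(locs[r, 1]), end = unname(locs[r, 2])
        )
      }
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(hits) == 0) {
    return(dplyr::bind_cols(
      corpus[0, ],
      dict[0, c("dictionary", "term", "concept", "level", "pathogen",
                "excluded_animal")],
      tibble::tibble(start = integer(), end = integer())
    ))
  }
  dplyr::bind_cols(
    corpus[hits$row, ],
    dict[hits$dict_row, c("dictionary", "term", "concept", "level",
                          "pathogen", "excluded_animal")],
    hits[, c("start", "end")]
  ) |>
    dplyr::arrange(.data$doc_id, .data$sentence_id, .data$start)
}

#' Extract relationship / co-mention sentence records
#'
#' A sentence qualifies for a dictionary combination when it contains at
#' least one match from every dictionary in the combination and the
#' relation predicate accepts it. `relationship` mode requires exactly two
#' dictionaries; `comention` mode three or more. The default predicate is
#' same-sentence co-occurrence; a custom predicate receives the sentence's
#' hits (one tibble) and returns `TRUE`/`FALSE`, allowing stricter relation
#' classifiers to be plugged in.
#'
#' @param hits An [annotate_corpus()] tibble.
#' @param combo Character vector of dictionary names.
#' @param mode `"relationship"` (2 dictionaries) or `"comention"` (>= 3).
#' @param predicate Optional function `(sentence_hits) -> logical(1)`.
#' @return Tibble of class `cooccurrence_records`: one row per qualifying
#'   sentence (`doc_id`, `year`, `section_label`, `sentence_id`,
#'   `sentence`), with a `matches` list-column of that sentence's hits.
#'   Attributes `combo`, `mode`, `n_sentences`, `n_documents`.
#' @export
extract_cooccurrences <- function(hits, combo,
                                  mode = c("relationship", "comention"),
                                  predicate = NULL) {
  mode <- match.arg(mode)
  combo <- sort(unique(combo))
  if (mode == "relationship" && length(combo) != 2) {
    rlang::abort("relationship mode needs exactly 2 dictionaries.")
  }
  if (mode == "comention" && length(combo) < 3) {
    rlang::abort("comention mode needs at least 3 dictionaries.")
  }
  match_cols <- c("dictionary", "term", "concept", "level", "pathogen",
                  "excluded_animal", "start", "end")
  nested <- tidyr::nest(hits, matches = dplyr::all_of(match_cols))
  keep <- vapply(nested$matches, function(m) {
    all(combo %in% unique(m$dictionary)) &&
      (is.null(predicate) || isTRUE(predicate(m)))
  }, logical(1))
  out <- nested[keep, , drop = FALSE] |>
    dplyr::arrange(.data$doc_id, .data$sentence_id)
  attr(out, "combo") <- combo
  attr(out, "mode") <- mode
  attr(out, "n_sentences") <- nrow(out)
  attr(out, "n_documents") <- dplyr::n_distinct(out$doc_id)
  class(out) <- c("cooccurrence_records", class(out))
  out
}

#' Count sentences and documents for every dictionary combination
#'
#' Builds the full grid of 2-dictionary relationship combinations and
#' 3-or-more-dictionary co-mention combinations over the given
#' dictionaries, with per-combination sentence and distinct-document
#' counts.
#'
#' @param hits An [annotate_corpus()] tibble.
#' @param dictionaries Character vector of dictionary names (default: the
#'   names present in `hits`).
#' @param predicate Optional relation predicate, see
#'   [extract_cooccurrences()].
#' @return Tibble `combo` (names joined by `+`), `mode`, `n_dictionaries`,
#'   `n_sentences`, `n_documents`.
#' @export
combination_counts <- function(hits, dictionaries = NULL, predicate = NULL) {
  dicts <- sort(dictionaries %||% unique(hits$dictionary))
  stopifnot(length(dicts) >= 2)
  combos <- unlist(lapply(2:length(dicts), function(m) {
    utils::combn(dicts, m, simplify = FALSE)
  }), recursive = FALSE)
  purrr::map_dfr(combos, function(cmb) {
    mode <- if (length(cmb) == 2) "relationship" else "comention"
    rec <- extract_cooccurrences(hits, cmb, mode, predicate)
    tibble::tibble(
      combo = paste(cmb, collapse = "+"),
      mode = mode,
      n_dictionaries = length(cmb),
      n_sentences = attr(rec, "n_sentences"),
      n_documents = attr(rec, "n_documents")
    )
  })
}

#' Filter chain for extracted sentence records
#'
#' Applies the reporting filters in a fixed order, attributing each removed
#' sentence to the first rule it violates:
#' 1. `year`: document published before 2000;
#' 2. `title`: sentence from a title section;
#' 3. `excluded_animal`: sentence mentions an excluded animal term
#'    (non-mouse model organisms etc.);
#' 4. `species_level`: the sentence's microbial matches (dictionary given
#'    by `microbe_dictionary`) are all pathogen-tagged or all genus-level —
#'    no usable species/strain-level non-pathogen mention remains.
#'
#' Sentences with no microbial match at all are not touched by rule 4.
#'
#' @param records An [extract_cooccurrences()] tibble.
#' @param microbe_dictionary Name of the microbial dictionary.
#' @return List with `records` (surviving rows, same shape) and `removals`
#'   (tibble `rule`, `n_removed`).
#' @export
filter_chain <- function(records, microbe_dictionary = "gut-microbes") {
  rules <- list(
    year = function(row, m) row$year <= 1999,
    title = function(row, m) identical(row$section_label, "title"),
    excluded_animal = function(row, m) any(m$excluded_animal),
    species_level = function(row, m) {
      mic <- m[m$dictionary == microbe_dictionary, , drop = FALSE]
      if (nrow(mic) == 0) return(FALSE)
      ok <- !mic$pathogen & !is.na(mic$level) & mic$level != "genus"
      !any(ok)
    }
  )
  verdict <- vapply(seq_len(nrow(records)), function(i) {
    row <- records[i, ]
    m <- records$matches[[i]]
    for (rn in names(rules)) {
      if (isTRUE(rules[[rn]](row, m))) return(rn)
    }
    "keep"
  }, character(1))
  removals <- tibble::tibble(
    rule = names(rules),
    n_removed = vapply(names(rules), function(rn) sum(verdict == rn),
                       integer(1))
  )
  kept <- records[verdict == "keep", , drop = FALSE]
  for (a in c("combo", "mode")) attr(kept, a) <- attr(records, a)
  attr(kept, "n_sentences") <- nrow(kept)
  attr(kept, "n_documents") <- dplyr::n_distinct(kept$doc_id)
  list(records = kept, removals = removals)
}

#' Species frequency table for a combination's sentences
#'
#' Counts, per canonical species concept, the number of sentences that
#' mention it (a sentence counts once however many times the species
#' occurs), with the combination's total sentence count as denominator.
#'
#' @param records Filtered [extract_cooccurrences()] records.
#' @param microbe_dictionary Name of the microbial dictionary.
#' @return Tibble `species`, `n_sentences`, `total_sentences`, sorted by
#'   descending count then species name.
#' @export
species_frequency <- function(records, microbe_dictionary = "gut-microbes") {
  total <- nrow(records)
  if (total == 0) {
    return(tibble::tibble(species = character(), n_sentences = integer(),
                          total_sentences = integer()))
  }
  per_sentence <- purrr::map_dfr(seq_len(total), function(i) {
    m <- records$matches[[i]]
    mic <- m[m$dictionary == microbe_dictionary &
               !is.na(m$level) & m$level != "genus", , drop = FALSE]
    if (nrow(mic) == 0) return(NULL)
    tibble::tibble(sentence = i, species = unique(mic$concept))
  })
  if (nrow(per_sentence) == 0) {
    return(tibble::tibble(species = character(), n_sentences = integer(),
                          total_sentences = integer()))
  }
  per_sentence |>
    dplyr::count(.data$species, name = "n_sentences") |>
    dplyr::mutate(total_sentences = total) |>
    dplyr::arrange(dplyr::desc(.data$n_sentences), .data$species)
}
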