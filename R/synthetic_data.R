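#' @name synthetic_data
#' @title Synthetic pipeline inputs with planted ground truth
#' @description
#' Every input the analysis consumes can be generated with known, planted
#' truth: metabolic networks with known seed sets, communities with
#' programmed pairwise seed overlap, food tables with designated filter
#' violations, pathway annotations with a planted enriched pathway, and
#' corpora with planted dictionary co-mentions. Each generator records its
#' truth in a manifest sufficient to verify the consuming stage without
#' re-deriving it. A single integer seed drives a named RNG stream per
#' generator, so adding a generator never perturbs existing fixtures.
NULL

stream_seed <- function(rng_seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(rng_seed) %% 1000003L) * 1009L + (h %% 99991L)
}

with_stream <- function(rng_seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(rng_seed, stream))
  force(code)
}

#' Generate a metabolic network with a planted seed set
#'
#' Builds an acyclic skeleton over `n_components` strongly connected
#' components, exactly `n_source_components` of which have condensation
#' in-degree 0. Each component is expanded to a strongly connected subgraph
#' (a cycle plus random chords); inter-component edges follow the skeleton,
#' so the planted source components are exactly the seed components.
#'
#' @param n_components Number of strongly connected components.
#' @param n_source_components Number of source (in-degree 0) components;
#'   at least 1, at most `n_components`.
#' @param component_sizes Integer vector of component sizes (length
#'   `n_components`), or `NULL` to sample sizes from `size_range`.
#' @param size_range Inclusive range sizes are sampled from.
#' @param extra_skeleton_edges Expected number of additional component-to-
#'   component edges beyond the spanning ones.
#' @param rng_seed Integer seed.
#' @param organism_id Organism identifier.
#' @return List with `network` (a [metabolic_network()]), `true_seeds`
#'   (tibble `base_id`, `confidence`, `component`) and `manifest` (list
#'   with the construction parameters and the component layout).
#' @export
generate_network <- function(n_components, n_source_components,
                             component_sizes = NULL, size_range = c(1, 4),
                             extra_skeleton_edges = n_components,
                             rng_seed = 1, organism_id = "synthetic") {
  stopifnot(n_components >= 1,
            n_source_components >= 1,
            n_source_components <= n_components)
  with_stream(rng_seed, paste0("network/", organism_id), {
    sizes <- component_sizes %||%
      sample(size_range[1]:size_range[2], n_components, replace = TRUE)
    stopifnot(length(sizes) == n_components, all(sizes >= 1))

    offsets <- cumsum(c(0, sizes[-n_components]))
    node_of <- function(comp, idx) sprintf("cpd%04d", offsets[comp] + idx)
    members <- lapply(seq_len(n_components), function(c) {
      vapply(seq_len(sizes[c]), function(i) node_of(c, i), character(1))
    })

    # intra-component cycle + chords makes each component strongly connected
    edges <- list()
    for (c in seq_len(n_components)) {
      m <- members[[c]]
      s <- length(m)
      if (s >= 2) {
        cyc <- tibble::tibble(from = m, to = m[c(2:s, 1)])
        edges[[length(edges) + 1]] <- cyc
        n_chords <- sample(0:s, 1)
        if (n_chords > 0) {
          edges[[length(edges) + 1]] <- tibble::tibble(
            from = sample(m, n_chords, replace = TRUE),
            to = sample(m, n_chords, replace = TRUE)
          )
        }
      }
    }

    # acyclic skeleton: sources are components 1..n_source_components;
    # every later component receives at least one edge from an earlier one
    skeleton <- list()
    non_sources <- setdiff(seq_len(n_components), seq_len(n_source_components))
    for (c in non_sources) {
      parent <- sample(seq_len(c - 1), 1)
      skeleton[[length(skeleton) + 1]] <- c(parent, c)
    }
    if (extra_skeleton_edges > 0 && n_components >= 2) {
      for (e in seq_len(stats::rpois(1, extra_skeleton_edges))) {
        to <- if (length(non_sources) > 0) {
          if (length(non_sources) == 1) non_sources else sample(non_sources, 1)
        } else {
          NA_integer_
        }
        if (is.na(to) || to == 1) next
        from <- sample(seq_len(to - 1), 1)
        skeleton[[length(skeleton) + 1]] <- c(from, to)
      }
    }
    for (sk in skeleton) {
      edges[[length(edges) + 1]] <- tibble::tibble(
        from = sample(members[[sk[1]]], 1),
        to = sample(members[[sk[2]]], 1)
      )
    }
    edge_tbl <- if (length(edges) > 0) {
      dplyr::bind_rows(edges)
    } else {
      tibble::tibble(from = character(), to = character())
    }

    compounds <- tibble::tibble(
      base_id = unlist(members),
      name = paste("compound", unlist(members))
    )
    network <- metabolic_network(
      edge_tbl, compounds = compounds, organism_id = organism_id,
      provenance = list(source = "generate_network", rng_seed = rng_seed)
    )
    true_seeds <- purrr::map_dfr(seq_len(n_source_components), function(c) {
      tibble::tibble(base_id = members[[c]],
                     confidence = 1 / sizes[c],
                     component = c)
    }) |>
      dplyr::arrange(dplyr::desc(.data$confidence), .data$base_id)
    list(
      network = network,
      true_seeds = true_seeds,
      manifest = list(
        rng_seed = rng_seed,
        n_components = n_components,
        n_source_components = n_source_components,
        component_sizes = sizes,
        members = members,
        n_true_seeds = nrow(true_seeds),
        total_weight = n_source_components
      )
    )
  })
}

#' Generate a community with programmed pairwise seed overlap
#'
#' Every organism receives `n_seeds` seed compounds, each a singleton
#' source component (confidence 1). For every unordered pair a dedicated
#' pool of compounds is shared by exactly that pair, so the pairwise
#' competition index `|S_i intersect S_j| / n_seeds` equals the programmed
#' target exactly. Optional complementarity targets add compounds of
#' organism i's seed set to organism j's network as producible (non-seed)
#' nodes.
#'
#' @param k Number of organisms.
#' @param n_seeds Seeds per organism.
#' @param overlap `k x k` symmetric matrix of target competition fractions
#'   (diagonal ignored); `overlap * n_seeds` must be whole numbers and each
#'   row's shared compounds must fit into `n_seeds`.
#' @param complementarity_targets Optional `k x k` matrix of target
#'   complementarity fractions for ordered pairs (focal row, partner
#'   column); programmed from the focal organism's unique seed pool.
#' @param rng_seed Integer seed.
#' @return List with `community` (named list of `list(network, seeds)`
#'   ready for [pairwise_matrices()]), `manifest` (planted `competition`
#'   and `complementarity` matrices, seed sets).
#' @export
generate_community <- function(k, n_seeds, overlap = NULL,
                               complementarity_targets = NULL,
                               rng_seed = 1) {
  stopifnot(k >= 2, n_seeds >= 1)
  if (is.null(overlap)) overlap <- matrix(0, k, k)
  stopifnot(nrow(overlap) == k, ncol(overlap) == k)
  if (max(abs(overlap - t(overlap))) > 1e-9) {
    rlang::abort("`overlap` must be symmetric: |S_i ∩ S_j| is one set.")
  }
  counts <- overlap * n_seeds
  if (max(abs(counts - round(counts))) > 1e-9) {
    rlang::abort("overlap * n_seeds must be whole numbers for exact planting.")
  }
  counts <- round(counts)
  ids <- sprintf("org%02d", seq_len(k))

  shared_per_org <- rowSums(counts) - diag(counts)
  bad <- which(shared_per_org > n_seeds)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Infeasible overlap design: organism ", ids[bad[1]], " would need ",
      shared_per_org[bad[1]], " shared seeds but has only ", n_seeds, "."
    ))
  }

  with_stream(rng_seed, "community", {
    counter <- 0
    fresh <- function(n) {
      out <- sprintf("met%05d", counter + seq_len(n))
      counter <<- counter + n
      out
    }
    seed_sets <- stats::setNames(vector("list", k), ids)
    for (i in seq_len(k)) seed_sets[[i]] <- character()
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (counts[i, j] > 0) {
          pool <- fresh(counts[i, j])
          seed_sets[[i]] <- c(seed_sets[[i]], pool)
          seed_sets[[j]] <- c(seed_sets[[j]], pool)
        }
      }
    }
    unique_pool <- stats::setNames(vector("list", k), ids)
    for (i in seq_len(k)) {
      need <- n_seeds - length(seed_sets[[i]])
      unique_pool[[i]] <- fresh(need)
      seed_sets[[i]] <- sort(c(seed_sets[[i]], unique_pool[[i]]))
    }

    compl <- matrix(0, k, k, dimnames = list(ids, ids))
    extra_nodes <- stats::setNames(vector("list", k), ids)
    if (!is.null(complementarity_targets)) {
      ct <- complementarity_targets * n_seeds
      if (max(abs(ct - round(ct))) > 1e-9) {
        rlang::abort("complementarity_targets * n_seeds must be whole numbers.")
      }
      ct <- round(ct)
      for (i in seq_len(k)) {
        for (j in seq_len(k)) {
          if (i == j || ct[i, j] == 0) next
          candidates <- setdiff(unique_pool[[i]], seed_sets[[j]])
          if (length(candidates) < ct[i, j]) {
            rlang::abort(paste0(
              "Infeasible complementarity target for (", ids[i], ", ",
              ids[j], "): needs ", ct[i, j], " compounds unique to ",
              ids[i], ", only ", length(candidates), " available."
            ))
          }
          picked <- candidates[seq_len(ct[i, j])]
          extra_nodes[[j]] <- c(extra_nodes[[j]], picked)
          compl[i, j] <- ct[i, j] / n_seeds
        }
      }
    }

    community <- stats::setNames(vector("list", k), ids)
    for (i in seq_len(k)) {
      hub <- sprintf("hub_%s", ids[i])
      sink <- sprintf("sink_%s", ids[i])
      edges <- dplyr::bind_rows(
        tibble::tibble(from = seed_sets[[i]], to = hub),
        tibble::tibble(from = hub, to = sink),
        if (length(extra_nodes[[i]]) > 0) {
          tibble::tibble(from = hub, to = unique(extra_nodes[[i]]))
        }
      )
      nw <- metabolic_network(
        edges, organism_id = ids[i],
        provenance = list(source = "generate_community", rng_seed = rng_seed)
      )
      community[[i]] <- list(network = nw, seeds = detect_seeds(nw))
    }

    competition_truth <- counts / n_seeds
    diag(competition_truth) <- 1
    dimnames(competition_truth) <- list(ids, ids)
    list(
      community = community,
      manifest = list(
        rng_seed = rng_seed, k = k, n_seeds = n_seeds,
        seed_sets = seed_sets,
        competition = competition_truth,
        complementarity = compl
      )
    )
  })
}

#' Generate a food-composition table with planted filter violations
#'
#' Produces a food table, a category map and a list of candidate metabolite
#' names, with designated foods violating specific stages of the filter
#' cascade. Concentrations are drawn log-normally with per-category scales
#' (oligosaccharides and monosaccharides plentiful, vitamins scarce),
#' mimicking the spread of a food-composition database. The manifest
#' records the expected survivor set after each cascade stage and an
#' independently computed score ranking.
#'
#' @param n_foods Number of well-formed candidate foods (before planting
#'   violators).
#' @param n_per_category Matched compounds per category.
#' @param n_unmatched_names Candidate metabolite names absent from the
#'   table (the nomenclature-mismatch report).
#' @param violators Named integer vector: how many foods to plant violating
#'   each stage (`no_match`, `loq`, `class`, `growth_factor`).
#' @param weights Score weights used for the manifest's expected ranking.
#' @param rng_seed Integer seed.
#' @return List with `food_table`, `category_map`, `seed_names` and
#'   `manifest` (cascade survivor sets/counts, expected ranking tibble).
#' @export
generate_food_table <- function(n_foods = 20, n_per_category = 3,
                                n_unmatched_names = 5,
                                violators = c(no_match = 2, loq = 2,
                                              class = 3, growth_factor = 2),
                                weights = category_weights(),
                                rng_seed = 1) {
  stopifnot(n_foods >= 1, n_per_category >= 1)
  with_stream(rng_seed, "food", {
    scale <- c(
      vitamins = 0.5, amino_acids = 50, oligosaccharides = 300,
      bioactive_substances = 20, nitrogenous_compounds = 5,
      monosaccharides = 1000, NSN = 2
    )
    compounds <- purrr::map_dfr(FOOD_CATEGORIES, function(cat) {
      tibble::tibble(
        compound_name = sprintf("%s compound %02d", gsub("_", " ", cat),
                                seq_len(n_per_category)),
        category = cat
      )
    })
    category_map <- dplyr::mutate(
      compounds, compound_name = normalize_name(.data$compound_name)
    )
    seed_names <- c(
      compounds$compound_name,
      sprintf("model-only metabolite %02d", seq_len(n_unmatched_names))
    )

    draw_food <- function(food_id, food_name, food_class) {
      rows <- compounds |>
        dplyr::mutate(
          food_id = food_id, food_name = food_name, food_class = food_class,
          concentration_mg_per_100g = round(
            stats::rlnorm(dplyr::n(), log(scale[.data$category]), 0.8), 4
          ),
          detection = "quantified"
        )
      # each food carries a random subset (but all growth factors stay)
      keep <- stats::runif(nrow(rows)) < 0.85 |
        rows$category %in% GROWTH_FACTOR_CATEGORIES
      rows[keep, ]
    }

    foods <- purrr::map_dfr(seq_len(n_foods), function(i) {
      draw_food(sprintf("F%03d", i), sprintf("food %03d", i), "regular")
    })
    nxt <- n_foods

    planted <- list()
    # foods with no matched compound at all (fail stage 1)
    for (v in seq_len(violators[["no_match"]] %||% 0)) {
      nxt <- nxt + 1
      planted[[length(planted) + 1]] <- tibble::tibble(
        food_id = sprintf("F%03d", nxt),
        food_name = sprintf("food %03d (unmatched only)", nxt),
        food_class = "regular",
        compound_name = sprintf("exotic additive %02d", v),
        concentration_mg_per_100g = 1,
        detection = "quantified"
      )
    }
    # foods whose matched compounds are all below LOQ (fail stage 2)
    for (v in seq_len(violators[["loq"]] %||% 0)) {
      nxt <- nxt + 1
      f <- draw_food(sprintf("F%03d", nxt),
                     sprintf("food %03d (below loq)", nxt), "regular")
      f$detection <- "below_LOQ"
      f$concentration_mg_per_100g <- NA_real_
      planted[[length(planted) + 1]] <- f
    }
    # processed / alcohol / undefined classes (fail stage 3)
    classes3 <- c("processed", "alcohol", "other-undefined")
    for (v in seq_len(violators[["class"]] %||% 0)) {
      nxt <- nxt + 1
      planted[[length(planted) + 1]] <- draw_food(
        sprintf("F%03d", nxt),
        sprintf("food %03d (%s)", nxt, classes3[(v - 1) %% 3 + 1]),
        classes3[(v - 1) %% 3 + 1]
      )
    }
    # a growth-factor category entirely undetected (fail stage 4)
    for (v in seq_len(violators[["growth_factor"]] %||% 0)) {
      nxt <- nxt + 1
      f <- draw_food(sprintf("F%03d", nxt),
                     sprintf("food %03d (no vitamins)", nxt), "regular")
      hit <- f$category == "vitamins"
      f$detection[hit] <- "not_detected"
      f$concentration_mg_per_100g[hit] <- NA_real_
      planted[[length(planted) + 1]] <- f
    }
    food_table <- dplyr::bind_rows(foods, dplyr::bind_rows(planted)) |>
      dplyr::select("food_id", "food_name", "food_class", "compound_name",
                    "concentration_mg_per_100g", "detection")

    manifest <- food_manifest(food_table, category_map, seed_names, weights,
                              rng_seed)
    list(food_table = food_table, category_map = category_map,
         seed_names = seed_names, manifest = manifest)
  })
}

# independent plain-arithmetic account of the cascade and ranking,
# deliberately not calling filter_foods()/normalize_and_score()
food_manifest <- function(food_table, category_map, seed_names, weights,
                          rng_seed) {
  tbl <- as.data.frame(food_table)
  tbl$compound_norm <- normalize_name(tbl$compound_name)
  matched <- intersect(normalize_name(seed_names), tbl$compound_norm)
  cat_of <- stats::setNames(category_map$category, category_map$compound_name)
  m <- tbl[tbl$compound_norm %in% matched, ]
  m$category <- unname(cat_of[m$compound_norm])

  s1 <- sort(unique(m$food_id))
  s2 <- sort(unique(m$food_id[m$detection == "quantified"]))
  cls <- unique(tbl[, c("food_id", "food_class")])
  drop3 <- cls$food_id[cls$food_class %in%
                         c("processed", "alcohol", "other-undefined")]
  s3 <- setdiff(s2, drop3)
  s4 <- s3[vapply(s3, function(f) {
    rows <- m[m$food_id == f & m$detection != "not_detected", ]
    all(GROWTH_FACTOR_CATEGORIES %in% rows$category)
  }, logical(1))]
  s4 <- sort(s4)

  q <- m[m$food_id %in% s4 & m$detection == "quantified" &
           !is.na(m$concentration_mg_per_100g), ]
  prof <- matrix(0, length(s4), length(FOOD_CATEGORIES),
                 dimnames = list(s4, FOOD_CATEGORIES))
  for (f in s4) {
    for (cat in FOOD_CATEGORIES) {
      v <- q$concentration_mg_per_100g[q$food_id == f & q$category == cat]
      if (length(v) > 0) prof[f, cat] <- sum(v) / length(v)
    }
  }
  norm <- prof
  for (cat in FOOD_CATEGORIES) {
    lo <- min(prof[, cat]); hi <- max(prof[, cat])
    norm[, cat] <- if (hi > lo) (prof[, cat] - lo) / (hi - lo) else 0
  }
  score <- as.vector(norm[, names(weights), drop = FALSE] %*% unname(weights))
  names(score) <- s4
  name_of <- stats::setNames(tbl$food_name, tbl$food_id)
  ord <- order(-score, name_of[s4])
  ranking <- tibble::tibble(
    rank = seq_along(ord),
    food_id = s4[ord],
    food_name = unname(name_of[s4[ord]]),
    score = unname(score[ord])
  )
  list(
    rng_seed = rng_seed,
    matched = sort(matched),
    unmatched = sort(setdiff(normalize_name(seed_names), matched)),
    cascade_counts = c(stage1 = length(s1), stage2 = length(s2),
                       stage3 = length(s3), stage4 = length(s4)),
    survivors = list(stage1 = s1, stage2 = s2, stage3 = s3, stage4 = s4),
    profiles = prof,
    ranking = ranking
  )
}

#' Generate a pathway annotation with a planted enriched pathway
#'
#' Samples `n_pathways` pathways from a compound universe and, unless
#' `planted = NULL`, plants one pathway with elevated overlap with the
#' returned seed-compound list. The manifest records the realized
#' `(N, K, n, k)` for every pathway.
#'
#' @param n_pathways Number of pathways.
#' @param universe_size Compounds available for pathway membership.
#' @param n_seed_compounds Seed compounds to return.
#' @param planted `NULL`, or a list with `pathway_size` (K) and `overlap`
#'   (k <= min(K, n)).
#' @param pathway_size_range Size range for unplanted pathways.
#' @param organism Organism identifier used in the annotation table.
#' @param rng_seed Integer seed.
#' @return List with `annotation` (a [read_pathway_annotation()] tibble),
#'   `seed_compounds` (character vector) and `manifest` (per-pathway
#'   `(N, K, n, k)` tibble; `planted_pathway` id or `NA`).
#' @export
generate_annotation <- function(n_pathways = 20, universe_size = 200,
                                n_seed_compounds = 15,
                                planted = list(pathway_size = 10, overlap = 8),
                                pathway_size_range = c(5, 25),
                                organism = "org01", rng_seed = 1) {
  stopifnot(n_pathways >= 1, universe_size >= 2)
  if (!is.null(planted)) {
    stopifnot(planted$overlap <= planted$pathway_size,
              planted$overlap <= n_seed_compounds)
  }
  with_stream(rng_seed, "annotation", {
    universe <- sprintf("C%05d", seq_len(universe_size))
    planted_id <- if (!is.null(planted)) "path001" else NA_character_

    pathways <- list()
    if (!is.null(planted)) {
      pathways[["path001"]] <- sample(universe, planted$pathway_size)
    }
    start <- length(pathways) + 1
    if (start <= n_pathways) {
      for (p in start:n_pathways) {
        sz <- sample(pathway_size_range[1]:pathway_size_range[2], 1)
        pathways[[sprintf("path%03d", p)]] <- sample(universe, sz)
      }
    }

    if (!is.null(planted)) {
      inside <- sample(pathways[["path001"]], planted$overlap)
      outside_pool <- setdiff(universe, pathways[["path001"]])
      outside <- sample(outside_pool, n_seed_compounds - planted$overlap)
      seed_compounds <- sort(c(inside, outside))
    } else {
      seed_compounds <- sort(sample(universe, n_seed_compounds))
    }

    annotation <- purrr::map_dfr(names(pathways), function(pid) {
      tibble::tibble(
        organism = organism,
        pathway_id = pid,
        pathway_name = paste("pathway", sub("path", "", pid)),
        compound_id = pathways[[pid]]
      )
    })
    annotation <- read_pathway_annotation(annotation)

    univ <- sort(unique(annotation$compound_id))
    n_in <- length(intersect(seed_compounds, univ))
    manifest <- tibble::tibble(
      pathway_id = names(pathways),
      N = length(univ),
      K = unname(lengths(pathways)),
      n = n_in,
      k = unname(vapply(pathways, function(cpds) {
        length(intersect(cpds, seed_compounds))
      }, integer(1)))
    )
    list(
      annotation = annotation,
      seed_compounds = seed_compounds,
      manifest = list(rng_seed = rng_seed, counts = manifest,
                      planted_pathway = planted_id)
    )
  })
}

#' Default term dictionaries for the mining stage
#'
#' Four concept dictionaries (gut microbes with taxonomic level and
#' pathogen tags, immune-related, infection/disease, chemical-related) plus
#' an `animal-models` dictionary of excluded-animal filter terms.
#'
#' @return Named list of dictionary tibbles (see [read_dictionary()]).
#' @export
default_dictionaries <- function() {
  mk <- function(name, term, concept = term, level = NA_character_,
                 pathogen = FALSE, excluded_animal = FALSE) {
    read_dictionary(
      tibble::tibble(term = term, concept = concept, level = level,
                     pathogen = pathogen, excluded_animal = excluded_animal),
      name
    )
  }
  list(
    `gut-microbes` = mk(
      "gut-microbes",
      term = c("Lactobacillus rhamnosus", "Bifidobacterium longum",
               "Akkermansia muciniphila", "Faecalibacterium prausnitzii",
               "Lactobacillus", "Bifidobacterium", "Clostridium difficile"),
      level = c("species", "species", "species", "species",
                "genus", "genus", "species"),
      pathogen = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
    ),
    `immune-related` = mk(
      "immune-related",
      term = c("immune system", "immunoglobulin A", "regulatory T cell",
               "cytokine")
    ),
    `infection-disease` = mk(
      "infection-disease",
      term = c("diarrhea", "respiratory infection",
               "necrotizing enterocolitis", "atopic dermatitis")
    ),
    `chemical-related` = mk(
      "chemical-related",
      term = c("inulin", "oligofructose", "butyrate",
               "human milk oligosaccharide")
    ),
    `animal-models` = mk(
      "animal-models",
      term = c("piglet", "broiler chicken", "zebrafish"),
      excluded_animal = TRUE
    )
  )
}

#' Generate a corpus with planted dictionary co-mentions
#'
#' Assembles sentences from neutral filler plus planted dictionary terms so
#' that each requested dictionary combination receives a known number of
#' qualifying sentences, then adds designated filter victims (pre-2000
#' document, title sentence, excluded-animal mention, genus-only and
#' pathogen-only microbial mentions) to a designated combination. The
#' manifest computes all expected counts by direct subset arithmetic over
#' the planted roster, independent of the annotation machinery.
#'
#' @param grid Named integer vector: planted clean sentences per
#'   combination, names as dictionary names joined by `+` (e.g.
#'   `"gut-microbes+immune-related"`).
#' @param victims Named integer vector over rules `year`, `title`,
#'   `excluded_animal`, `species_level`: victim sentences planted in
#'   `victim_combo`.
#' @param victim_combo Combination (length 2) the victims are planted in.
#' @param n_docs Documents the sentences are spread over (round-robin).
#' @param dictionaries As from [default_dictionaries()].
#' @param rng_seed Integer seed.
#' @return List with `corpus` (tibble as [read_corpus()]), `dictionaries`,
#'   and `manifest` (expected per-combination counts, per-rule removals for
#'   `victim_combo`, post-filter species frequencies for `victim_combo`).
#' @export
generate_corpus <- function(grid,
                            victims = c(year = 1, title = 1,
                                        excluded_animal = 1,
                                        species_level = 2),
                            victim_combo = c("gut-microbes",
                                             "immune-related"),
                            n_docs = 8,
                            dictionaries = default_dictionaries(),
                            rng_seed = 1) {
  dict_tbl <- dplyr::bind_rows(dictionaries)
  main_dicts <- sort(setdiff(unique(dict_tbl$dictionary), "animal-models"))
  victim_combo <- sort(victim_combo)
  stopifnot(length(victim_combo) == 2,
            all(victim_combo %in% main_dicts),
            n_docs >= 2)

  pick_term <- function(dict_name, kind = "clean") {
    d <- dict_tbl[dict_tbl$dictionary == dict_name, ]
    if (dict_name == "gut-microbes") {
      d <- switch(kind,
        clean = d[!d$pathogen & !is.na(d$level) & d$level != "genus", ],
        genus = d[!is.na(d$level) & d$level == "genus", ],
        pathogen = d[d$pathogen, ]
      )
    }
    d$term[sample.int(nrow(d), 1)]
  }

  with_stream(rng_seed, "corpus", {
    fillers <- c("The randomized trial reported that",
                 "In a weaning cohort,",
                 "Observational data suggested that",
                 "The supplementation study found that")
    roster <- list()
    add_sentence <- function(dicts, kind = "clean", year = 2010,
                             section = "abstract", extra = NULL) {
      terms <- vapply(dicts, pick_term, character(1), kind = kind)
      text <- paste0(
        fillers[(length(roster) %% length(fillers)) + 1], " ",
        paste(terms, collapse = " was linked to "),
        if (!is.null(extra)) paste0(" in ", extra), " during infancy."
      )
      species <- {
        d <- dict_tbl[dict_tbl$dictionary == "gut-microbes" &
                        dict_tbl$term %in% terms, ]
        d$concept[!d$pathogen & !is.na(d$level) & d$level != "genus"]
      }
      roster[[length(roster) + 1]] <<- list(
        dicts = sort(dicts), kind = kind, year = year, section = section,
        has_excluded_animal = !is.null(extra), text = text,
        species = species
      )
    }

    for (combo_name in names(grid)) {
      dicts <- sort(strsplit(combo_name, "+", fixed = TRUE)[[1]])
      stopifnot(all(dicts %in% main_dicts))
      for (s in seq_len(grid[[combo_name]])) add_sentence(dicts)
    }
    for (rule in names(victims)) {
      for (s in seq_len(victims[[rule]])) {
        switch(rule,
          year = add_sentence(victim_combo, year = 1998),
          title = add_sentence(victim_combo, section = "title"),
          excluded_animal = add_sentence(victim_combo, extra = "piglet"),
          species_level = add_sentence(
            victim_combo, kind = if (s %% 2 == 1) "genus" else "pathogen"
          )
        )
      }
    }

    # assign sentences to documents round-robin; victims with year 1998
    # are grouped into their own document so document years stay scalar
    doc_of <- integer(length(roster))
    years <- vapply(roster, function(r) r$year, numeric(1))
    old_idx <- which(years <= 1999)
    new_idx <- which(years > 1999)
    doc_of[new_idx] <- (seq_along(new_idx) - 1) %% (n_docs - 1) + 1
    doc_of[old_idx] <- n_docs
    doc_year <- vapply(seq_len(n_docs), function(d) {
      yrs <- years[doc_of == d]
      if (length(yrs) == 0) 2010 else max(yrs)
    }, numeric(1))
    doc_year[n_docs] <- if (length(old_idx) > 0) 1998 else 2010

    corpus <- purrr::map_dfr(seq_len(n_docs), function(d) {
      idx <- which(doc_of == d)
      rows <- tibble::tibble(
        section_label = c("title",
                          vapply(roster[idx], function(r) r$section,
                                 character(1))),
        sentence = c(sprintf("Neutral title of document %02d", d),
                     vapply(roster[idx], function(r) r$text, character(1)))
      )
      dplyr::mutate(rows,
                    doc_id = sprintf("PMID%07d", 1000000 + d),
                    year = as.integer(doc_year[d]),
                    sentence_id = dplyr::row_number(),
                    .before = 1)
    })

    manifest <- corpus_manifest(roster, doc_of, main_dicts, victim_combo)
    manifest$rng_seed <- rng_seed
    list(corpus = corpus, dictionaries = dictionaries, manifest = manifest)
  })
}

# expected counts by direct subset arithmetic over the planted roster
corpus_manifest <- function(roster, doc_of, main_dicts, victim_combo) {
  dict_sets <- lapply(roster, function(r) r$dicts)
  combos <- unlist(lapply(2:length(main_dicts), function(m) {
    utils::combn(main_dicts, m, simplify = FALSE)
  }), recursive = FALSE)
  combination_counts <- purrr::map_dfr(combos, function(cmb) {
    qualifies <- vapply(dict_sets, function(d) all(cmb %in% d), logical(1))
    tibble::tibble(
      combo = paste(cmb, collapse = "+"),
      mode = if (length(cmb) == 2) "relationship" else "comention",
      n_dictionaries = length(cmb),
      n_sentences = sum(qualifies),
      n_documents = length(unique(doc_of[qualifies]))
    )
  })

  qualifies_v <- vapply(dict_sets, function(d) all(victim_combo %in% d),
                        logical(1))
  rule_of <- vapply(seq_along(roster), function(i) {
    r <- roster[[i]]
    if (!qualifies_v[i]) return("not_in_combo")
    if (r$year <= 1999) return("year")
    if (r$section == "title") return("title")
    if (r$has_excluded_animal) return("excluded_animal")
    if ("gut-microbes" %in% r$dicts && length(r$species) == 0) {
      return("species_level")
    }
    "keep"
  }, character(1))
  removals <- tibble::tibble(
    rule = c("year", "title", "excluded_animal", "species_level"),
    n_removed = vapply(c("year", "title", "excluded_animal",
                         "species_level"),
                       function(rn) sum(rule_of == rn), integer(1))
  )
  kept <- which(rule_of == "keep")
  freq_tbl <- table(unlist(lapply(roster[kept], function(r) r$species)))
  species_frequency <- tibble::tibble(
    species = as.character(names(freq_tbl) %||% character()),
    n_sentences = as.integer(freq_tbl),
    total_sentences = length(kept)
  ) |>
    dplyr::arrange(dplyr::desc(.data$n_sentences), .data$species)

  list(
    combination_counts = combination_counts,
    victim_combo = victim_combo,
    removals = removals,
    n_kept = length(kept),
    species_frequency = species_frequency
  )
}
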