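PIPELINE_CONFIG_KEYS <- c(
  "networks", "network_format", "host", "food_table", "category_map",
  "seed_names", "annotation", "kegg_map", "corpus", "dictionaries",
  "out_dir", "weighted", "min_confidence", "coverage", "alpha", "weights",
  "grouping", "parse"
)

#' Validate a pipeline configuration
#'
#' @param config Named list, or path to a YAML file. Recognized keys:
#'   `networks` (directory of edge-list `.tsv` / SBML `.xml|.sbml` files,
#'   or character vector of paths), `network_format` (`"auto"`,
#'   `"edge_list"`, `"sbml"`), `host` (optional model path), `food_table`,
#'   `category_map`, `seed_names` (text file of metabolite names, one per
#'   line; defaults to community seed compound names), `annotation`,
#'   `kegg_map` (TSV `base_id`, `kegg_id`), `corpus` (JSONL),
#'   `dictionaries` (directory of `<name>.tsv` dictionaries), `out_dir`,
#'   `weighted`, `min_confidence`, `coverage`, `alpha`, `weights` (named
#'   list overriding [category_weights()]), `grouping` (named list organism
#'   -> group label), `parse` (list of [parse_options()] arguments).
#'   Unknown keys are rejected; referenced paths must exist.
#' @return The validated config list with defaults filled in, plus a
#'   `config_hash` attribute covering the semantically meaningful options.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown config keys: ",
                        paste(unknown, collapse = ", ")))
  }
  if (is.null(config$networks)) {
    rlang::abort("Config must name `networks` (directory or file paths).")
  }
  for (key in c("networks", "host", "food_table", "category_map",
                "seed_names", "annotation", "kegg_map", "corpus",
                "dictionaries")) {
    for (p in config[[key]]) {
      if (!file.exists(p) && !dir.exists(p)) {
        rlang::abort(paste0("Config key `", key, "`: path not found: ", p))
      }
    }
  }
  config$network_format <- config$network_format %||% "auto"
  config$out_dir <- config$out_dir %||% "gutseed_run"
  config$weighted <- config$weighted %||% TRUE
  config$min_confidence <- config$min_confidence %||% 0
  config$coverage <- config$coverage %||% 0.7
  config$alpha <- config$alpha %||% 0.05
  w <- category_weights()
  if (!is.null(config$weights)) {
    w[names(config$weights)] <- unlist(config$weights)
  }
  config$weights <- w
  semantic <- config[setdiff(names(config), "out_dir")]
  attr(config, "config_hash") <- rlang::hash(
    semantic[order(names(semantic))]
  )
  config
}

read_model_file <- function(path, format = "auto", parse = NULL) {
  fmt <- if (format != "auto") {
    format
  } else if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
    "sbml"
  } else {
    "edge_list"
  }
  if (fmt == "sbml") {
    opts <- do.call(parse_options, parse %||% list())
    parse_sbml(path, options = opts)
  } else {
    read_edge_list(path)
  }
}

#' Run the full reverse-metabolic pipeline
#'
#' Executes the stages in order -- optional literature mining, model
#' parsing, seed detection, community partition, pairwise interaction
#' matrices, optional pathway enrichment, optional food sourcing -- and
#' writes fixed-name TSV/JSON outputs plus a machine-readable run summary.
#' Stages whose inputs are absent from the config are skipped and logged.
#' Outputs are staged in a temporary directory and moved into `out_dir`
#' only when every stage has succeeded, so a failing run leaves no partial
#' outputs. The analysis itself is deterministic: identical inputs and
#' config produce byte-identical outputs.
#'
#' @param config See [validate_config()].
#' @param quiet Suppress progress messages.
#' @return The run summary (list, also written as `run_summary.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  say <- function(...) if (!quiet) message("[gutseed] ", ...)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      rlang::abort(paste0("Stage `", name, "` failed: ",
                          conditionMessage(e)))
    })
  }
  staging <- tempfile("gutseed_run_")
  dir.create(staging, recursive = TRUE)
  summary <- list(
    tool = "gutseed",
    version = as.character(utils::packageVersion("gutseed")),
    config_hash = attr(config, "config_hash"),
    stages = list()
  )

  # -- mining (optional) ---------------------------------------------------
  if (!is.null(config$corpus) && !is.null(config$dictionaries)) {
    stage("mining", {
      say("mining: annotating corpus")
      corpus <- read_corpus(config$corpus)
      dict_paths <- list.files(config$dictionaries, pattern = "\\.tsv$",
                               full.names = TRUE)
      dicts <- lapply(dict_paths, function(p) {
        read_dictionary(p, tools::file_path_sans_ext(basename(p)))
      })
      dict_tbl <- dplyr::bind_rows(dicts)
      main <- dict_tbl |>
        dplyr::group_by(.data$dictionary) |>
        dplyr::summarise(all_excl = all(.data$excluded_animal),
                         .groups = "drop") |>
        dplyr::filter(!.data$all_excl) |>
        dplyr::pull("dictionary") |>
        sort()
      hits <- annotate_corpus(corpus, dict_tbl)
      counts <- combination_counts(hits, main)
      combos <- strsplit(counts$combo, "+", fixed = TRUE)
      microbe_dict <- intersect(main, "gut-microbes")
      post <- purrr::map_dfr(seq_along(combos), function(i) {
        rec <- extract_cooccurrences(
          hits, combos[[i]],
          mode = if (length(combos[[i]]) == 2) "relationship" else "comention"
        )
        fc <- filter_chain(rec, microbe_dictionary =
                             if (length(microbe_dict)) microbe_dict else
                               "gut-microbes")
        tibble::tibble(combo = counts$combo[i],
                       n_after_filter = nrow(fc$records))
      })
      counts <- dplyr::left_join(counts, post, by = "combo")
      write_tsv_atomic(counts, file.path(staging, "mining_counts.tsv"))
      if (length(microbe_dict) == 1) {
        freq <- purrr::map_dfr(
          which(vapply(combos, function(cb) microbe_dict %in% cb,
                       logical(1))),
          function(i) {
            rec <- extract_cooccurrences(
              hits, combos[[i]],
              mode = if (length(combos[[i]]) == 2) "relationship"
                     else "comention"
            )
            fc <- filter_chain(rec, microbe_dictionary = microbe_dict)
            sf <- species_frequency(fc$records,
                                    microbe_dictionary = microbe_dict)
            if (nrow(sf) == 0) return(NULL)
            dplyr::mutate(sf, combo = counts$combo[i], .before = 1)
          }
        )
        write_tsv_atomic(freq, file.path(staging, "mining_species.tsv"))
      }
      summary$stages$mining <- list(
        n_sentences = nrow(corpus),
        n_documents = dplyr::n_distinct(corpus$doc_id),
        combination_counts = counts
      )
    })
  } else {
    say("mining: skipped (no corpus/dictionaries configured)")
    summary$stages$mining <- "skipped"
  }

  # -- parse models --------------------------------------------------------
  networks <- stage("parse", {
    paths <- config$networks
    if (length(paths) == 1 && dir.exists(paths)) {
      paths <- list.files(paths, pattern = "\\.(tsv|txt|xml|sbml)$",
                          full.names = TRUE)
    }
    if (length(paths) == 0) rlang::abort("No model files found.")
    say("parse: ", length(paths), " model(s)")
    lapply(sort(paths), read_model_file,
           format = config$network_format, parse = config$parse)
  })
  summary$stages$parse <- list(
    n_models = length(networks),
    organisms = vapply(networks, function(n) n$organism_id, character(1))
  )

  # -- seeds ---------------------------------------------------------------
  community <- stage("seeds", {
    say("seeds: detecting seed sets")
    build_community(networks, min_confidence = config$min_confidence)
  })
  seed_counts <- vapply(community, function(m) nrow(m$seeds$seeds),
                        integer(1))
  for (m in community) {
    write_tsv_atomic(
      seed_report(m$seeds, m$network$compounds),
      file.path(staging, paste0("seeds_", m$seeds$organism_id, ".tsv"))
    )
  }
  write_tsv_atomic(seed_matrix(community),
                   file.path(staging, "seed_matrix.tsv"))
  summary$stages$seeds <- list(seed_counts = as.list(seed_counts))

  # -- partition -----------------------------------------------------------
  part <- stage("partition", partition_seeds(community))
  write_tsv_atomic(tidy(part), file.path(staging, "partition.tsv"))
  summary$stages$partition <- as.list(glance(part))
  if (!is.null(config$grouping)) {
    gs <- stage("partition", {
      group_summary(community, unlist(config$grouping))
    })
    write_tsv_atomic(gs$summary, file.path(staging, "group_summary.tsv"))
    write_tsv_atomic(gs$exclusives,
                     file.path(staging, "group_exclusives.tsv"))
  }

  # -- interaction matrices ------------------------------------------------
  if (length(community) >= 2) {
    mats <- stage("matrices", {
      say("matrices: pairwise indices")
      host <- if (!is.null(config$host)) {
        read_model_file(config$host, config$network_format, config$parse)
      }
      pairwise_matrices(community, host = host,
                        weighted = isTRUE(config$weighted))
    })
    write_interaction_matrices(mats, staging)
    summary$stages$matrices <- list(
      n_organisms = length(mats$organisms),
      weighted = mats$weighted,
      has_host = !is.null(mats$support)
    )
  } else {
    say("matrices: skipped (single organism)")
    summary$stages$matrices <- "skipped"
  }

  # -- enrichment (optional) -----------------------------------------------
  if (!is.null(config$annotation)) {
    stage("enrichment", {
      say("enrichment: hypergeometric pathway tests")
      annotation <- read_pathway_annotation(config$annotation)
      kegg_map <- if (!is.null(config$kegg_map)) {
        readr::read_tsv(config$kegg_map,
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
      }
      orgs <- intersect(unique(annotation$organism), names(community))
      if (length(orgs) == 0) {
        rlang::abort("Annotation organisms do not match any community member.")
      }
      results <- lapply(orgs, function(org) {
        enrich_seeds(community[[org]]$seeds, annotation, organism = org,
                     kegg_map = kegg_map, alpha = config$alpha)
      })
      combined <- dplyr::bind_rows(results)
      write_tsv_atomic(combined, file.path(staging, "enrichment.tsv"))
      agg <- community_enrichment_summary(combined, alpha = config$alpha)
      write_tsv_atomic(agg$summary,
                       file.path(staging, "enrichment_summary.tsv"))
      summary$stages$enrichment <- list(
        n_organisms = length(orgs),
        n_tests = nrow(combined),
        n_significant = sum(combined$significant),
        n_retained_pathways = sum(agg$summary$retained)
      )
    })
  } else {
    say("enrichment: skipped (no annotation configured)")
    summary$stages$enrichment <- "skipped"
  }

  # -- food sourcing (optional) --------------------------------------------
  if (!is.null(config$food_table) && !is.null(config$category_map)) {
    stage("foods", {
      say("foods: matching and ranking")
      food_table <- read_food_table(config$food_table)
      category_map <- read_category_map(config$category_map)
      seed_names <- if (!is.null(config$seed_names)) {
        readr::read_lines(config$seed_names)
      } else {
        cpds <- dplyr::bind_rows(lapply(community, function(m) {
          dplyr::filter(m$network$compounds,
                        .data$base_id %in% seed_ids(m$seeds))
        }))
        unique(dplyr::coalesce(cpds$name, cpds$base_id))
      }
      m <- match_compounds(seed_names, food_table)
      f <- filter_foods(food_table, m, category_map)
      rf <- list(matched = m$matched, unmatched = m$unmatched,
                 cascade = f$cascade,
                 scores = if (nrow(f$retained) > 0) {
                   normalize_and_score(category_profile(f$table),
                                       config$weights)
                 })
      write_tsv_atomic(rf$cascade, file.path(staging, "food_cascade.tsv"))
      write_tsv_atomic(
        tibble::tibble(compound = rf$unmatched),
        file.path(staging, "food_unmatched.tsv")
      )
      if (!is.null(rf$scores)) {
        write_tsv_atomic(as.data.frame(rf$scores),
                         file.path(staging, "food_scores.tsv"))
        cft <- community_food_tables(rf$matched, f$table,
                                     coverage = config$coverage)
        write_tsv_atomic(cft$foods, file.path(staging, "food_coverage.tsv"))
        write_tsv_atomic(cft$metabolite_food,
                         file.path(staging, "food_metabolite_relations.tsv"))
        write_tsv_atomic(cft$category_food,
                         file.path(staging, "food_category_relations.tsv"))
      }
      summary$stages$foods <- list(
        n_matched = length(rf$matched),
        n_unmatched = length(rf$unmatched),
        cascade_counts = as.list(stats::setNames(rf$cascade$n_foods,
                                                 paste0("stage",
                                                        rf$cascade$stage))),
        n_ranked = if (is.null(rf$scores)) 0L else nrow(rf$scores),
        top_food = if (is.null(rf$scores)) NA_character_ else
          rf$scores$food_name[1]
      )
    })
  } else {
    say("foods: skipped (no food table configured)")
    summary$stages$foods <- "skipped"
  }

  # -- finalize ------------------------------------------------------------
  jsonlite::write_json(summary, file.path(staging, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  for (f in list.files(staging, full.names = TRUE)) {
    ok <- file.copy(f, file.path(config$out_dir, basename(f)),
                    overwrite = TRUE)
    if (!ok) rlang::abort(paste0("Could not write output: ", basename(f)))
  }
  unlink(staging, recursive = TRUE)
  say("done: outputs in ", config$out_dir)
  invisible(summary)
}

write_tsv_atomic <- function(tbl, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(tbl, tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Generate a complete synthetic fixture bundle on disk
#'
#' Writes every pipeline input -- community edge lists, food table,
#' category map, seed metabolite names, pathway annotation, seed-to-KEGG
#' map, corpus and dictionaries -- plus a ready-to-run `config.yaml` and a
#' `manifest.json` of planted truths, so `run_pipeline(<dir>/config.yaml)`
#' exercises every stage against known expectations.
#'
#' @param dir Output directory (created).
#' @param rng_seed Integer seed driving all generators.
#' @return Invisibly, a list with the in-memory generator outputs
#'   (`community`, `food`, `annotation`, `corpus`) and the combined
#'   `manifest`.
#' @export
generate_fixture_bundle <- function(dir, rng_seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  k <- 4
  n_seeds <- 15
  overlap <- matrix(0, k, k)
  overlap[1, 2] <- overlap[2, 1] <- 0.4
  overlap[1, 3] <- overlap[3, 1] <- 0.2
  overlap[2, 3] <- overlap[3, 2] <- 0.2
  compl <- matrix(0, k, k)
  compl[1, 2] <- 0.2
  compl[2, 1] <- 0.2
  compl[4, 1] <- 0.4
  comm <- generate_community(k, n_seeds, overlap,
                             complementarity_targets = compl,
                             rng_seed = rng_seed)

  net_dir <- file.path(dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (m in comm$community) {
    write_edge_list(m$network,
                    file.path(net_dir,
                              paste0(m$network$organism_id, ".tsv")))
  }

  food <- generate_food_table(n_foods = 20, rng_seed = rng_seed)
  write_tsv_atomic(food$food_table, file.path(dir, "food_table.tsv"))
  write_tsv_atomic(food$category_map, file.path(dir, "category_map.tsv"))
  writeLines(food$seed_names, file.path(dir, "seed_names.txt"),
             useBytes = TRUE)

  ann <- generate_annotation(organism = "org01", rng_seed = rng_seed)
  write_tsv_atomic(ann$annotation, file.path(dir, "annotation.tsv"))
  org1_seeds <- sort(comm$manifest$seed_sets[["org01"]])
  stopifnot(length(org1_seeds) == length(ann$seed_compounds))
  kegg_map <- tibble::tibble(
    base_id = org1_seeds,
    kegg_id = ann$seed_compounds
  )
  write_tsv_atomic(kegg_map, file.path(dir, "kegg_map.tsv"))

  grid <- c(
    "gut-microbes+immune-related" = 4,
    "chemical-related+gut-microbes" = 3,
    "chemical-related+gut-microbes+immune-related" = 2,
    "chemical-related+gut-microbes+immune-related+infection-disease" = 1
  )
  corp <- generate_corpus(grid, rng_seed = rng_seed)
  write_corpus(corp$corpus, file.path(dir, "corpus.jsonl"))
  dict_dir <- file.path(dir, "dictionaries")
  dir.create(dict_dir, showWarnings = FALSE)
  for (nm in names(corp$dictionaries)) {
    write_tsv_atomic(
      dplyr::select(corp$dictionaries[[nm]], -"dictionary"),
      file.path(dict_dir, paste0(nm, ".tsv"))
    )
  }

  config <- list(
    networks = file.path(dir, "networks"),
    food_table = file.path(dir, "food_table.tsv"),
    category_map = file.path(dir, "category_map.tsv"),
    seed_names = file.path(dir, "seed_names.txt"),
    annotation = file.path(dir, "annotation.tsv"),
    kegg_map = file.path(dir, "kegg_map.tsv"),
    corpus = file.path(dir, "corpus.jsonl"),
    dictionaries = file.path(dir, "dictionaries"),
    out_dir = file.path(dir, "out")
  )
  yaml::write_yaml(config, file.path(dir, "config.yaml"))

  manifest <- list(
    rng_seed = rng_seed,
    community = list(
      k = k, n_seeds = n_seeds,
      seed_counts = lapply(comm$manifest$seed_sets, length),
      competition = comm$manifest$competition,
      complementarity = comm$manifest$complementarity,
      partition = {
        sets <- comm$manifest$seed_sets
        tab <- table(unlist(sets))
        list(universe = length(tab),
             core = sum(tab == length(sets)),
             unique = if (length(sets) > 1) sum(tab == 1) else 0,
             shared = sum(tab > 1 & tab < length(sets)))
      }
    ),
    food = food$manifest[c("cascade_counts", "matched", "unmatched")],
    food_top = food$manifest$ranking$food_name[1],
    enrichment = list(
      planted_pathway = ann$manifest$planted_pathway,
      counts = ann$manifest$counts
    ),
    mining = corp$manifest[c("combination_counts", "removals", "n_kept")]
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(community = comm, food = food, annotation = ann,
                 corpus = corp, manifest = manifest, config = config))
}
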