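#' Strongly connected component condensation of a metabolic network
#'
#' Partitions the compound graph into strongly connected components (maximal
#' sets of mutually reachable compounds) and builds the acyclic condensation
#' graph whose nodes are components and whose edge `i -> j` exists iff some
#' compound edge crosses from component `i` to component `j`.
#'
#' @param network A [metabolic_network()] with at least one compound.
#' @return A list of class `scc_decomposition`:
#'   * `membership`: tibble `base_id`, `component` (integer id),
#'   * `components`: list of character vectors (component members, sorted),
#'   * `condensation_edges`: tibble `from`, `to` of component ids,
#'   * `source_components`: integer ids with condensation in-degree 0.
#' @export
condensation <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  if (nrow(network$compounds) == 0) {
    rlang::abort("Cannot condense an empty network.")
  }
  g <- as_igraph(network)
  comp <- igraph::components(g, mode = "strong")
  nodes <- igraph::V(g)$name
  raw_member <- comp$membership

  # relabel components deterministically: by their lexicographically
  # smallest member, so results are invariant to igraph's internal order
  reps <- vapply(split(nodes, raw_member), min, character(1))
  new_id <- match(names(sort(reps)), names(reps))
  relabel <- match(raw_member, new_id)
  membership <- tibble::tibble(base_id = nodes, component = relabel) |>
    dplyr::arrange(.data$base_id)

  components <- lapply(
    split(membership$base_id, membership$component), sort
  )
  names(components) <- NULL

  memb <- stats::setNames(membership$component, membership$base_id)
  ce <- network$edges |>
    dplyr::transmute(
      from = unname(memb[.data$from]),
      to = unname(memb[.data$to])
    ) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$from, .data$to)

  structure(
    list(
      membership = membership,
      components = components,
      condensation_edges = ce,
      source_components = setdiff(seq_along(components), unique(ce$to))
    ),
    class = "scc_decomposition"
  )
}

#' @export
print.scc_decomposition <- function(x, ...) {
  cat("<scc_decomposition> ", length(x$components), " components, ",
      length(x$source_components), " source components\n", sep = "")
  invisible(x)
}

#' Detect the seed set of a metabolic network
#'
#' The seed set is the minimal set of compounds that cannot be synthesized
#' from other compounds in the network and must therefore be acquired
#' exogenously. At component granularity these are exactly the members of
#' the condensation's source components (in-degree 0): any one member of a
#' source component suffices to produce the rest of that component, so each
#' member receives confidence `1 / |component|`.
#'
#' @param network A [metabolic_network()].
#' @param min_confidence Seeds with confidence strictly below this value are
#'   dropped after assignment. The default `0` keeps all seeds, so the full
#'   network is reachable from the seed set.
#' @return An object of class `seed_set`: list with `organism_id`, `seeds`
#'   (tibble `base_id`, `confidence`, `component`, sorted by descending
#'   confidence then id) and `total_weight` (sum of confidences; equals the
#'   number of source components when `min_confidence = 0`).
#' @export
detect_seeds <- function(network, min_confidence = 0) {
  stopifnot(inherits(network, "metabolic_network"))
  if (nrow(network$compounds) == 0) {
    rlang::abort("Cannot detect seeds of an empty network.")
  }
  stopifnot(is.numeric(min_confidence), length(min_confidence) == 1,
            min_confidence >= 0, min_confidence <= 1)
  dec <- condensation(network)
  sizes <- lengths(dec$components)
  seeds <- dec$membership |>
    dplyr::filter(.data$component %in% dec$source_components) |>
    dplyr::mutate(confidence = 1 / sizes[.data$component]) |>
    dplyr::arrange(dplyr::desc(.data$confidence), .data$base_id) |>
    dplyr::select("base_id", "confidence", "component")
  if (min_confidence > 0) {
    seeds <- dplyr::filter(seeds, .data$confidence >= min_confidence)
  }
  structure(
    list(
      organism_id = network$organism_id,
      seeds = seeds,
      total_weight = sum(seeds$confidence)
    ),
    class = "seed_set"
  )
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", x$organism_id, ": ", nrow(x$seeds), " seed compounds, ",
      "total weight ", format(x$total_weight), "\n", sep = "")
  invisible(x)
}

#' Tidy a seed set
#'
#' @param x A `seed_set`.
#' @param ... Unused.
#' @return Tibble `organism_id`, `base_id`, `confidence`, `component`.
#' @exportS3Method generics::tidy
tidy.seed_set <- function(x, ...) {
  dplyr::mutate(x$seeds, organism_id = x$organism_id, .before = 1)
}

#' One-row summary of a seed set
#' @param x A `seed_set`.
#' @param ... Unused.
#' @return One-row tibble with seed count and total weight.
#' @exportS3Method generics::glance
glance.seed_set <- function(x, ...) {
  tibble::tibble(
    organism_id = x$organism_id,
    n_seeds = nrow(x$seeds),
    total_weight = x$total_weight,
    n_source_components = length(unique(x$seeds$component))
  )
}

seed_ids <- function(seed_set) seed_set$seeds$base_id

#' Seed report with compound annotations
#'
#' @param seed_set A `seed_set`.
#' @param catalog Optional compound catalog (tibble with `base_id`, `name`,
#'   `kegg_id`), typically `network$compounds`; matched by `base_id`.
#' @return Tibble `compound_id`, `name`, `confidence` sorted by descending
#'   confidence, ties broken by id.
#' @export
seed_report <- function(seed_set, catalog = NULL) {
  stopifnot(inherits(seed_set, "seed_set"))
  out <- seed_set$seeds |>
    dplyr::transmute(compound_id = .data$base_id,
                     confidence = .data$confidence)
  if (!is.null(catalog)) {
    out$name <- catalog$name[match(out$compound_id, catalog$base_id)]
  } else {
    out$name <- NA_character_
  }
  dplyr::select(out, "compound_id", "name", "confidence") |>
    dplyr::arrange(dplyr::desc(.data$confidence), .data$compound_id)
}

#' Wide community seed matrix
#'
#' @param community A list of `seed_set` objects, or of `list(network,
#'   seeds)` pairs as from [build_community()].
#' @return Tibble: one row per compound in any organism's seed set, one
#'   column per organism holding the seed confidence (0 when the compound is
#'   not a seed of that organism).
#' @export
seed_matrix <- function(community) {
  stopifnot(length(community) >= 1)
  long <- purrr::map_dfr(community_seed_sets(community), tidy)
  long |>
    dplyr::select("base_id", "organism_id", "confidence") |>
    tidyr::pivot_wider(names_from = "organism_id",
                       values_from = "confidence", values_fill = 0) |>
    dplyr::arrange(.data$base_id)
}
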