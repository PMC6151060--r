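#' Construct a metabolic network
#'
#' A metabolic network is a directed compound graph: nodes are
#' compartment-stripped compound ids, and an edge `from -> to` means some
#' reaction converts compound `from` into compound `to`. Stoichiometry is
#' ignored; the representation is purely topological, as required by
#' seed-set detection.
#'
#' @param edges A data frame with character columns `from` and `to`, one
#'   directed edge per row. Duplicate edges are collapsed. Self-loops are
#'   dropped (they cannot alter strongly-connected-component membership
#'   beyond the node itself) and counted in `provenance$self_loops_dropped`.
#' @param compounds Optional data frame with columns `base_id`, `name`,
#'   `kegg_id`, `chebi_id`. Nodes appearing in `edges` but not listed here
#'   are added with empty annotation. If `NULL`, the catalog is derived from
#'   the edge endpoints.
#' @param organism_id Character scalar identifying the organism.
#' @param reactions Optional data frame of source reactions (see
#'   [reaction_table()]).
#' @param provenance Named list recording source format and parse options.
#'
#' @return An object of class `metabolic_network`: a list with elements
#'   `organism_id`, `compounds` (tibble), `edges` (tibble, deduplicated and
#'   sorted), `reactions` (tibble or `NULL`) and `provenance` (list).
#' @export
metabolic_network <- function(edges,
                              compounds = NULL,
                              organism_id = "organism",
                              reactions = NULL,
                              provenance = list()) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    rlang::abort("`edges` must have columns `from` and `to`.")
  }
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character())
  }
  edges <- dplyr::mutate(edges, dplyr::across(c("from", "to"), as.character))
  n_loops <- sum(edges$from == edges$to)
  edges <- edges |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::distinct(.data$from, .data$to) |>
    dplyr::arrange(.data$from, .data$to)

  node_ids <- sort(unique(c(edges$from, edges$to)))
  if (is.null(compounds)) {
    compounds <- tibble::tibble(base_id = node_ids)
  }
  compounds <- tibble::as_tibble(compounds)
  if (!"base_id" %in% names(compounds)) {
    rlang::abort("`compounds` must have a `base_id` column.")
  }
  for (col in c("name", "kegg_id", "chebi_id")) {
    if (!col %in% names(compounds)) compounds[[col]] <- NA_character_
  }
  missing_nodes <- setdiff(node_ids, compounds$base_id)
  if (length(missing_nodes) > 0) {
    compounds <- dplyr::bind_rows(
      compounds,
      tibble::tibble(base_id = missing_nodes)
    )
  }
  compounds <- compounds |>
    dplyr::distinct(.data$base_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$base_id) |>
    dplyr::select("base_id", "name", "kegg_id", "chebi_id",
                  dplyr::everything())
  if (any(!nzchar(compounds$base_id)) || anyNA(compounds$base_id)) {
    rlang::abort("Compound `base_id` values must be non-empty.")
  }

  provenance$self_loops_dropped <- n_loops +
    (provenance$self_loops_dropped %||% 0)

  structure(
    list(
      organism_id = organism_id,
      compounds = compounds,
      edges = edges,
      reactions = reactions,
      provenance = provenance
    ),
    class = "metabolic_network"
  )
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", x$organism_id, "\n", sep = "")
  cat("  compounds: ", nrow(x$compounds),
      "  edges: ", nrow(x$edges), "\n", sep = "")
  src <- x$provenance$source %||% "constructed"
  cat("  source: ", src, "\n", sep = "")
  invisible(x)
}

#' Node ids of a metabolic network
#' @param network A `metabolic_network`.
#' @return Character vector of compound `base_id`s (sorted).
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  network$compounds$base_id
}

#' @importFrom rlang %||% .data
NULL

#' Tidy a metabolic network into its edge list
#'
#' @param x A `metabolic_network`.
#' @param ... Unused.
#' @return A tibble with columns `from` and `to`.
#' @exportS3Method generics::tidy
tidy.metabolic_network <- function(x, ...) {
  x$edges
}

#' One-row summary of a metabolic network
#'
#' @param x A `metabolic_network`.
#' @param ... Unused.
#' @return A one-row tibble with node, edge and reaction counts.
#' @exportS3Method generics::glance
glance.metabolic_network <- function(x, ...) {
  tibble::tibble(
    organism_id = x$organism_id,
    n_compounds = nrow(x$compounds),
    n_edges = nrow(x$edges),
    n_reactions = if (is.null(x$reactions)) NA_integer_ else nrow(x$reactions),
    self_loops_dropped = as.integer(x$provenance$self_loops_dropped %||% 0L)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges,
    directed = TRUE,
    vertices = data.frame(name = network$compounds$base_id)
  )
}
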