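#' Pair networks with their seed sets
#'
#' Convenience constructor for the community structure consumed by
#' [pairwise_matrices()] and [partition_seeds()].
#'
#' @param networks List of [metabolic_network()] objects.
#' @param min_confidence Passed to [detect_seeds()].
#' @return Named list (by organism id) of lists with `network` and `seeds`.
#' @export
build_community <- function(networks, min_confidence = 0) {
  stopifnot(length(networks) >= 1)
  out <- lapply(networks, function(nw) {
    list(network = nw, seeds = detect_seeds(nw, min_confidence))
  })
  names(out) <- vapply(networks, function(nw) nw$organism_id, character(1))
  out
}

community_seed_sets <- function(community) {
  if (inherits(community, "seed_set")) return(list(community))
  lapply(community, function(m) {
    if (inherits(m, "seed_set")) m else m$seeds
  })
}

#' Partition community seed compounds
#'
#' Classifies every compound required by at least one community member:
#' `core` compounds are required by all members, `unique` compounds by
#' exactly one (when the community has more than one member), and `shared`
#' compounds by two or more but not all. Membership, not confidence, drives
#' the partition. For a single-organism community every seed is core and
#' the unique and shared classes are empty (core takes precedence).
#'
#' @param community List of `seed_set` objects, or of `list(network, seeds)`
#'   pairs as from [build_community()].
#' @return Object of class `seed_partition`: list with `universe`, `core`,
#'   `unique`, `shared` (sorted character vectors), `membership` (tibble
#'   `base_id`, `n_organisms`, `class`, `organisms`), `n_organisms`.
#' @export
partition_seeds <- function(community) {
  sets <- community_seed_sets(community)
  stopifnot(length(sets) >= 1)
  k <- length(sets)
  long <- purrr::map_dfr(sets, function(s) {
    tibble::tibble(organism_id = s$organism_id, base_id = seed_ids(s))
  })
  membership <- long |>
    dplyr::distinct(.data$organism_id, .data$base_id) |>
    dplyr::group_by(.data$base_id) |>
    dplyr::summarise(
      n_organisms = dplyr::n(),
      organisms = paste(sort(.data$organism_id), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$n_organisms == k ~ "core",
      .data$n_organisms == 1 ~ "unique",
      TRUE ~ "shared"
    )) |>
    dplyr::arrange(.data$base_id)
  structure(
    list(
      universe = membership$base_id,
      core = membership$base_id[membership$class == "core"],
      unique = membership$base_id[membership$class == "unique"],
      shared = membership$base_id[membership$class == "shared"],
      membership = membership,
      n_organisms = k
    ),
    class = "seed_partition"
  )
}

#' @export
print.seed_partition <- function(x, ...) {
  cat("<seed_partition> ", x$n_organisms, " organisms\n",
      "  universe: ", length(x$universe),
      "  core: ", length(x$core),
      "  unique: ", length(x$unique),
      "  shared: ", length(x$shared), "\n", sep = "")
  invisible(x)
}

#' Tidy a seed partition
#' @param x A `seed_partition`.
#' @param ... Unused.
#' @return The membership tibble (`base_id`, `n_organisms`, `organisms`,
#'   `class`).
#' @exportS3Method generics::tidy
tidy.seed_partition <- function(x, ...) x$membership

#' One-row summary of a seed partition
#' @param x A `seed_partition`.
#' @param ... Unused.
#' @return One-row tibble with universe/core/unique/shared sizes.
#' @exportS3Method generics::glance
glance.seed_partition <- function(x, ...) {
  tibble::tibble(
    n_organisms = x$n_organisms,
    universe = length(x$universe),
    core = length(x$core),
    unique = length(x$unique),
    shared = length(x$shared)
  )
}

#' Per-group seed partitions and cross-group exclusives
#'
#' Applies [partition_seeds()] within each taxon group (e.g. genus) and
#' reports, for every ordered pair of groups, the compounds in the first
#' group's universe that are absent from the second group's universe.
#'
#' @param community As for [partition_seeds()].
#' @param grouping Named character vector mapping organism id to group
#'   label; every community member must be labeled.
#' @return List with `partitions` (named list of `seed_partition` per
#'   group), `summary` (tibble, one row per group) and `exclusives` (tibble
#'   `group`, `other_group`, `n_exclusive`, `compounds`).
#' @export
group_summary <- function(community, grouping) {
  sets <- community_seed_sets(community)
  ids <- vapply(sets, function(s) s$organism_id, character(1))
  unlabeled <- setdiff(ids, names(grouping))
  if (length(unlabeled) > 0) {
    rlang::abort(paste0("Unlabeled organisms: ",
                        paste(unlabeled, collapse = ", ")))
  }
  labels <- unname(grouping[ids])
  groups <- sort(unique(labels))
  partitions <- lapply(groups, function(g) {
    partition_seeds(sets[labels == g])
  })
  names(partitions) <- groups
  universes <- lapply(partitions, function(p) p$universe)
  exclusives <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(setdiff(groups, g), function(h) {
      excl <- sort(setdiff(universes[[g]], universes[[h]]))
      tibble::tibble(
        group = g, other_group = h,
        n_exclusive = length(excl),
        compounds = paste(excl, collapse = ";")
      )
    })
  })
  summary <- purrr::map_dfr(groups, function(g) {
    dplyr::mutate(glance(partitions[[g]]), group = g, .before = 1)
  })
  list(partitions = partitions, summary = summary, exclusives = exclusives)
}
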