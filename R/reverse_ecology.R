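#' Biosynthetic support score
#'
#' Fraction of one organism's seed compounds (its exogenous requirements)
#' that appear anywhere in a host's metabolic network: a measure of the
#' host's capacity to meet the microbe's nutritional demands, from 0 (no
#' cooperation) to 1 (full cooperation). Values above 0.75 typify parasites
#' fully provisioned by their host; lower values typify commensals.
#'
#' @param focal A `seed_set` (the microbe whose requirements are scored).
#' @param host_network A [metabolic_network()] (the potential host).
#' @param weighted If `TRUE` (default), seeds contribute their confidence
#'   (1/|source component|) and the denominator is the seed set's total
#'   weight; if `FALSE`, plain counts are used.
#' @return A one-row tibble: `focal`, `partner`, `kind = "support"`,
#'   `value`, `weighted`.
#' @export
biosynthetic_support <- function(focal, host_network, weighted = TRUE) {
  stopifnot(inherits(focal, "seed_set"),
            inherits(host_network, "metabolic_network"))
  if (nrow(focal$seeds) == 0) {
    rlang::abort("Focal organism has an empty seed set.")
  }
  hit <- focal$seeds$base_id %in% network_nodes(host_network)
  value <- if (weighted) {
    sum(focal$seeds$confidence[hit]) / focal$total_weight
  } else {
    mean(hit)
  }
  interaction_score(focal$organism_id, host_network$organism_id,
                    "support", value, weighted)
}

#' Metabolic complementarity index
#'
#' Fraction of the focal organism's seed compounds that occur in a partner's
#' metabolic network but are **not** among the partner's own seeds: the
#' partner can synthesize them rather than competing for them, so high
#' values indicate potential syntrophy/cross-feeding.
#'
#' @param focal A `seed_set`.
#' @param partner_network The partner's [metabolic_network()].
#' @param partner_seeds The partner's `seed_set` (computed from
#'   `partner_network`).
#' @param weighted Confidence-weighted (default) or plain counts.
#' @return A one-row tibble as in [biosynthetic_support()], `kind =
#'   "complementarity"`.
#' @export
complementarity <- function(focal, partner_network, partner_seeds,
                            weighted = TRUE) {
  stopifnot(inherits(focal, "seed_set"),
            inherits(partner_network, "metabolic_network"),
            inherits(partner_seeds, "seed_set"))
  if (nrow(focal$seeds) == 0) {
    rlang::abort("Focal organism has an empty seed set.")
  }
  in_net <- focal$seeds$base_id %in% network_nodes(partner_network)
  in_seed <- focal$seeds$base_id %in% seed_ids(partner_seeds)
  hit <- in_net & !in_seed
  value <- if (weighted) {
    sum(focal$seeds$confidence[hit]) / focal$total_weight
  } else {
    mean(hit)
  }
  interaction_score(focal$organism_id, partner_seeds$organism_id,
                    "complementarity", value, weighted)
}

#' Metabolic competition index
#'
#' Fraction of the focal organism's seed compounds that are also seeds of a
#' partner: both organisms must acquire them exogenously, so high values
#' indicate nutritional niche overlap. Asymmetric in general (each direction
#' is normalized by its own focal seed set).
#'
#' @param focal A `seed_set`.
#' @param partner A `seed_set`.
#' @param weighted Confidence-weighted (default) or plain counts.
#' @return A one-row tibble as in [biosynthetic_support()], `kind =
#'   "competition"`.
#' @export
competition <- function(focal, partner, weighted = TRUE) {
  stopifnot(inherits(focal, "seed_set"), inherits(partner, "seed_set"))
  if (nrow(focal$seeds) == 0) {
    rlang::abort("Focal organism has an empty seed set.")
  }
  hit <- focal$seeds$base_id %in% seed_ids(partner)
  value <- if (weighted) {
    sum(focal$seeds$confidence[hit]) / focal$total_weight
  } else {
    mean(hit)
  }
  interaction_score(focal$organism_id, partner$organism_id,
                    "competition", value, weighted)
}

interaction_score <- function(focal, partner, kind, value, weighted) {
  stopifnot(value >= 0, value <= 1 + 1e-12)
  tibble::tibble(
    focal = focal, partner = partner, kind = kind,
    value = min(value, 1), weighted = isTRUE(weighted)
  )
}

#' Pairwise interaction matrices for a community
#'
#' Computes the full ordered-pair grids of the three reverse-ecology
#' indices over a community, plus the host-support vector when a host
#' network is supplied. Matrix entry (row r, column c) holds the index with
#' focal = r and partner = c: column organisms complement (or compete with)
#' the row organism's requirements.
#'
#' @param community Named list of elements, each a list with components
#'   `network` (a [metabolic_network()]) and `seeds` (its `seed_set`), e.g.
#'   as returned by [build_community()].
#' @param host Optional host [metabolic_network()] for support scores.
#' @param weighted Confidence-weighted indices (default) or plain counts.
#' @return Object of class `interaction_matrices`: list with `competition`
#'   and `complementarity` (square numeric matrices, rows = focal),
#'   `support` (named numeric vector or `NULL`), `organisms`, `weighted`.
#' @export
pairwise_matrices <- function(community, host = NULL, weighted = TRUE) {
  stopifnot(length(community) >= 2)
  ids <- vapply(community, function(m) m$seeds$organism_id, character(1))
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("Duplicate organism_id in community: ",
                        paste(ids[duplicated(ids)], collapse = ", ")))
  }
  k <- length(community)
  comp <- matrix(0, k, k, dimnames = list(ids, ids))
  compl <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      comp[i, j] <- competition(community[[i]]$seeds, community[[j]]$seeds,
                                weighted = weighted)$value
      compl[i, j] <- complementarity(
        community[[i]]$seeds, community[[j]]$network, community[[j]]$seeds,
        weighted = weighted
      )$value
    }
  }
  support <- NULL
  if (!is.null(host)) {
    support <- vapply(community, function(m) {
      biosynthetic_support(m$seeds, host, weighted = weighted)$value
    }, numeric(1))
    names(support) <- ids
  }
  structure(
    list(competition = comp, complementarity = compl,
         support = support, organisms = ids, weighted = weighted),
    class = "interaction_matrices"
  )
}

#' @export
print.interaction_matrices <- function(x, ...) {
  cat("<interaction_matrices> ", length(x$organisms), " organisms",
      if (!is.null(x$support)) " (+host support)", ", ",
      if (x$weighted) "confidence-weighted" else "unweighted", "\n", sep = "")
  invisible(x)
}

#' Tidy pairwise interaction matrices into long format
#'
#' @param x An `interaction_matrices` object.
#' @param ... Unused.
#' @return Tibble `focal`, `partner`, `kind`, `value`, `weighted`; the host
#'   support vector appears with `kind = "support"` and `partner = "host"`.
#' @exportS3Method generics::tidy
tidy.interaction_matrices <- function(x, ...) {
  to_long <- function(m, kind) {
    tibble::tibble(
      focal = rep(rownames(m), times = ncol(m)),
      partner = rep(colnames(m), each = nrow(m)),
      kind = kind,
      value = as.vector(m)
    )
  }
  out <- dplyr::bind_rows(
    to_long(x$competition, "competition"),
    to_long(x$complementarity, "complementarity"),
    if (!is.null(x$support)) {
      tibble::tibble(focal = names(x$support), partner = "host",
                     kind = "support", value = unname(x$support))
    }
  )
  dplyr::mutate(out, weighted = x$weighted) |>
    dplyr::arrange(.data$kind, .data$focal, .data$partner)
}

#' One-row summary of interaction matrices
#' @param x An `interaction_matrices` object.
#' @param ... Unused.
#' @return One-row tibble with community size and mean off-diagonal indices.
#' @exportS3Method generics::glance
glance.interaction_matrices <- function(x, ...) {
  off <- function(m) mean(m[row(m) != col(m)])
  tibble::tibble(
    n_organisms = length(x$organisms),
    mean_competition = off(x$competition),
    mean_complementarity = off(x$complementarity),
    mean_support = if (is.null(x$support)) NA_real_ else mean(x$support),
    weighted = x$weighted
  )
}

#' Write interaction matrices as TSV files
#'
#' One file per index kind, with a provenance comment line
#' `# focal=row partner=column weighted=<bool>` so the orientation is
#' unambiguous.
#'
#' @param x An `interaction_matrices` object.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_interaction_matrices <- function(x, dir, prefix = "interaction") {
  stopifnot(inherits(x, "interaction_matrices"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_one <- function(m, kind) {
    path <- file.path(dir, paste0(prefix, "_", kind, ".tsv"))
    hdr <- paste0("# focal=row partner=column weighted=",
                  tolower(as.character(x$weighted)))
    body <- c(
      paste(c("organism", colnames(m)), collapse = "\t"),
      vapply(seq_len(nrow(m)), function(i) {
        paste(c(rownames(m)[i], format_num(m[i, ])), collapse = "\t")
      }, character(1))
    )
    writeLines(c(hdr, body), path, useBytes = TRUE)
    path
  }
  paths <- c(
    write_one(x$competition, "competition"),
    write_one(x$complementarity, "complementarity")
  )
  if (!is.null(x$support)) {
    path <- file.path(dir, paste0(prefix, "_support.tsv"))
    writeLines(c(
      "# support of host for each focal organism",
      "organism\tsupport",
      paste(names(x$support), format_num(x$support), sep = "\t")
    ), path, useBytes = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

format_num <- function(x) {
  formatC(x, digits = 15, format = "g")
}
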