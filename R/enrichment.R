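#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` marked items when `n` items are drawn
#' without replacement from a universe of `N` items of which `K` are marked:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`. Computed in log
#' space via [stats::phyper()], which is numerically stable for the
#' pathway-scale universes met in practice.
#'
#' @param N Universe size.
#' @param K Marked items in the universe (pathway compounds).
#' @param n Items drawn (seed compounds in the universe).
#' @param k Observed overlap.
#' @return The upper-tail probability; exactly 1 when `k = 0`.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  ok <- k >= 0 & k <= pmin(K, n) & pmax(K, n) <= N & N >= 0
  if (!all(ok)) {
    rlang::abort("hypergeom_upper_tail: need 0 <= k <= min(K, n) <= N.")
  }
  # P(X >= k) = P(X > k - 1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Load a pathway annotation table
#'
#' Reads an organism-scoped pathway annotation TSV (columns `organism`,
#' `pathway_id`, `pathway_name`, `compound_id`) emulating the metabolism
#' class of a pathway database. The per-organism compound universe is the
#' union of its pathway compound sets.
#'
#' @param path TSV path, or a data frame with the same columns.
#' @return A tibble of class `pathway_annotation` with one row per
#'   (organism, pathway, compound).
#' @export
read_pathway_annotation <- function(path) {
  tbl <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  need <- c("organism", "pathway_id", "pathway_name", "compound_id")
  if (!all(need %in% names(tbl))) {
    rlang::abort(paste0("Annotation table must have columns: ",
                        paste(need, collapse = ", ")))
  }
  out <- dplyr::distinct(tbl, dplyr::across(dplyr::all_of(need)))
  class(out) <- c("pathway_annotation", class(out))
  out
}

#' Hypergeometric pathway overrepresentation of seed compounds
#'
#' For each pathway of one organism, tests whether the organism's seed
#' compounds overlap the pathway's compound set more than expected when
#' drawing uniformly from the organism's pathway-compound universe. Raw
#' p-values are reported with a `p < 0.05` significance flag and no
#' multiple-testing correction by default; set `adjust = "BH"` for
#' Benjamini-Hochberg adjusted significance.
#'
#' @param seed_set A `seed_set`, or a character vector of seed compound ids.
#' @param annotation A [read_pathway_annotation()] table.
#' @param organism Which organism's pathways to use; defaults to the seed
#'   set's organism id, falling back to the single organism present in the
#'   annotation.
#' @param kegg_map Optional tibble (`base_id`, `kegg_id`) translating seed
#'   ids into the annotation's compound namespace (typically
#'   `network$compounds`). Seeds without a translation are excluded and
#'   counted.
#' @param universe `"organism"` (default): universe = union of the
#'   organism's pathway compounds; `"global"`: union over all organisms in
#'   the annotation.
#' @param alpha Significance threshold on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble of class `enrichment_result`, one row per pathway:
#'   `organism_id`, `pathway_id`, `pathway_name`, `N`, `K`, `n`, `k`, `p`,
#'   (`p_adjusted` when `adjust != "none"`), `significant`. Attributes
#'   `n_seeds_total`, `n_seeds_unmapped`, `n_seeds_outside_universe` report
#'   the exclusion counts.
#' @export
enrich_seeds <- function(seed_set, annotation, organism = NULL,
                         kegg_map = NULL, universe = c("organism", "global"),
                         alpha = 0.05, adjust = c("none", "BH")) {
  universe <- match.arg(universe)
  adjust <- match.arg(adjust)
  seeds <- if (inherits(seed_set, "seed_set")) {
    seed_ids(seed_set)
  } else {
    as.character(seed_set)
  }
  if (is.null(organism)) {
    organism <- if (inherits(seed_set, "seed_set")) {
      seed_set$organism_id
    } else {
      NULL
    }
    if (is.null(organism) || !organism %in% annotation$organism) {
      orgs <- unique(annotation$organism)
      if (length(orgs) != 1) {
        rlang::abort("Specify `organism`: annotation covers several organisms.")
      }
      organism <- orgs
    }
  }
  ann <- dplyr::filter(annotation, .data$organism == !!organism)
  if (nrow(ann) == 0) {
    rlang::abort(paste0("No pathways annotated for organism `", organism, "`."))
  }

  n_total <- length(seeds)
  if (!is.null(kegg_map)) {
    mapped <- kegg_map$kegg_id[match(seeds, kegg_map$base_id)]
    n_unmapped <- sum(is.na(mapped) | !nzchar(mapped))
    seeds <- unique(mapped[!is.na(mapped) & nzchar(mapped)])
  } else {
    n_unmapped <- 0L
    seeds <- unique(seeds)
  }

  univ <- if (universe == "global") {
    unique(annotation$compound_id)
  } else {
    unique(ann$compound_id)
  }
  if (length(univ) == 0) rlang::abort("Empty annotation universe.")
  seeds_in <- intersect(seeds, univ)
  n_outside <- length(seeds) - length(seeds_in)

  res <- ann |>
    dplyr::group_by(.data$pathway_id, .data$pathway_name) |>
    dplyr::summarise(
      K = length(unique(.data$compound_id)),
      k = length(intersect(unique(.data$compound_id), seeds_in)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$K >= 1) |>
    dplyr::mutate(
      organism_id = !!organism,
      N = length(univ),
      n = length(seeds_in),
      p = hypergeom_upper_tail(.data$N, .data$K, .data$n, .data$k)
    ) |>
    dplyr::select("organism_id", "pathway_id", "pathway_name",
                  "N", "K", "n", "k", "p") |>
    dplyr::arrange(.data$p, .data$pathway_id)
  if (adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p, method = "BH")
    res$significant <- res$p_adjusted < alpha
  } else {
    res$significant <- res$p < alpha
  }
  attr(res, "n_seeds_total") <- n_total
  attr(res, "n_seeds_unmapped") <- n_unmapped
  attr(res, "n_seeds_outside_universe") <- n_outside
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Community-level enrichment summary
#'
#' Aggregates per-organism enrichment results into a per-pathway view: the
#' mean p-value over the organisms in which the pathway exists (organisms
#' lacking a pathway contribute nothing to its mean) and the number of
#' organisms where the pathway is significantly overrepresented.
#'
#' @param results A list of [enrich_seeds()] results, or one combined
#'   tibble of such rows.
#' @param alpha Mean-p threshold for the headline `retained` flag.
#' @return List with `summary` (tibble `pathway_id`, `pathway_name`,
#'   `n_organisms`, `mean_p`, `n_significant`, `retained`, sorted by
#'   `mean_p`) and `matrix` (long tibble `organism_id`, `pathway_id`, `p`
#'   ready for heatmapping; absent pathways are absent rows).
#' @export
community_enrichment_summary <- function(results, alpha = 0.05) {
  tbl <- if (is.data.frame(results)) {
    tibble::as_tibble(results)
  } else {
    dplyr::bind_rows(results)
  }
  stopifnot(nrow(tbl) > 0)
  summary <- tbl |>
    dplyr::group_by(.data$pathway_id, .data$pathway_name) |>
    dplyr::summarise(
      n_organisms = dplyr::n_distinct(.data$organism_id),
      mean_p = mean(.data$p),
      n_significant = sum(.data$significant),
      .groups = "drop"
    ) |>
    dplyr::mutate(retained = .data$mean_p < alpha) |>
    dplyr::arrange(.data$mean_p, .data$pathway_id)
  long <- dplyr::select(tbl, "organism_id", "pathway_id", "p")
  list(summary = summary, matrix = long)
}
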