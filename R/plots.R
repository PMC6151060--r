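#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of pairwise interaction matrices
#'
#' @param object An `interaction_matrices` object.
#' @param kind Which index to draw (`"competition"`, `"complementarity"`).
#' @param ... Unused.
#' @return A ggplot: focal organisms as rows, partners as columns, tiles
#'   colored by the index value.
#' @exportS3Method ggplot2::autoplot
autoplot.interaction_matrices <- function(object,
                                          kind = c("competition",
                                                   "complementarity"),
                                          ...) {
  kind <- match.arg(kind)
  long <- tidy(object) |>
    dplyr::filter(.data$kind == !!kind)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$partner, y = .data$focal, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(
      x = "partner", y = "focal organism", fill = kind,
      title = paste("Metabolic", kind),
      subtitle = "entry (row, column) = index with focal = row"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of pathway enrichment results
#'
#' @param object An [enrich_seeds()] result.
#' @param top Number of pathways shown (smallest p first).
#' @param ... Unused.
#' @return A ggplot of -log10(p) per pathway, significant bars highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, top = 15, ...) {
  df <- object |>
    dplyr::slice_min(.data$p, n = top, with_ties = FALSE) |>
    dplyr::mutate(pathway = stats::reorder(.data$pathway_name, -.data$p))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p), y = .data$pathway, fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = expression(-log[10](italic(p))), y = NULL,
                  fill = "p < 0.05",
                  title = "Seed-compound pathway overrepresentation") +
    ggplot2::theme_minimal()
}

#' Bar chart of ranked prebiotic food scores
#'
#' @param object A [normalize_and_score()] result.
#' @param top Number of foods shown.
#' @param ... Unused.
#' @return A ggplot of the top food scores.
#' @exportS3Method ggplot2::autoplot
autoplot.food_scores <- function(object, top = 20, ...) {
  df <- object |>
    dplyr::slice_head(n = top) |>
    dplyr::mutate(food = stats::reorder(.data$food_name, .data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$food)) +
    ggplot2::geom_col(fill = "#4d9221") +
    ggplot2::labs(x = "prebiotic food score", y = NULL,
                  title = "Candidate prebiotic foods") +
    ggplot2::theme_minimal()
}

#' Tidy an enrichment result
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return The result as a plain tibble.
#' @exportS3Method generics::tidy
tidy.enrichment_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "enrichment_result")
  tibble::as_tibble(out)
}

#' One-row summary of an enrichment result
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return One-row tibble: tests run, significant count, seed exclusions.
#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    organism_id = x$organism_id[1],
    n_pathways = nrow(x),
    n_significant = sum(x$significant),
    min_p = min(x$p),
    n_seeds_total = attr(x, "n_seeds_total") %||% NA_integer_,
    n_seeds_unmapped = attr(x, "n_seeds_unmapped") %||% NA_integer_,
    n_seeds_outside_universe =
      attr(x, "n_seeds_outside_universe") %||% NA_integer_
  )
}

#' Tidy ranked food scores
#' @param x A `food_scores` tibble.
#' @param ... Unused.
#' @return Long tibble: `rank`, `food_id`, `food_name`, `score`,
#'   `category`, `mean_concentration`, `normalized`.
#' @exportS3Method generics::tidy
tidy.food_scores <- function(x, ...) {
  base <- tibble::as_tibble(x)
  raw <- tidyr::pivot_longer(
    dplyr::select(base, "rank", "food_id", "food_name", "score",
                  dplyr::all_of(FOOD_CATEGORIES)),
    dplyr::all_of(FOOD_CATEGORIES),
    names_to = "category", values_to = "mean_concentration"
  )
  norm <- tidyr::pivot_longer(
    dplyr::select(base, "food_id",
                  dplyr::all_of(paste0(FOOD_CATEGORIES, "_norm"))),
    -"food_id",
    names_to = "category", values_to = "normalized"
  ) |>
    dplyr::mutate(category = sub("_norm$", "", .data$category))
  dplyr::left_join(raw, norm, by = c("food_id", "category")) |>
    dplyr::arrange(.data$rank, .data$category)
}

#' One-row summary of ranked food scores
#' @param x A `food_scores` tibble.
#' @param ... Unused.
#' @return One-row tibble with cohort size and top food.
#' @exportS3Method generics::glance
glance.food_scores <- function(x, ...) {
  tibble::tibble(
    n_foods = nrow(x),
    top_food = x$food_name[1],
    top_score = x$score[1],
    min_score = min(x$score)
  )
}
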