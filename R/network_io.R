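#' Options controlling SBML-to-graph conversion
#'
#' @param strip_compartments Strip trailing compartment tags of the forms
#'   `[x]` (bracketed) and `_x` (underscore plus a single letter) from species
#'   ids so that the same chemical in two compartments becomes one node.
#'   Cross-organism comparison of seed sets requires a shared namespace, so
#'   this defaults to `TRUE`.
#' @param exclude_reactions Case-insensitive regular expression; reactions
#'   whose id matches are excluded from the graph. The default drops exchange
#'   and biomass pseudo-reactions (`^(EX_|biomass)`): retaining transporters
#'   would make every medium compound producible and hence a non-seed. Set to
#'   `NULL` to keep everything.
#' @param exclude_compounds Optional character vector of base ids (e.g.
#'   currency metabolites such as ATP or water) to remove from the graph. The
#'   default keeps all compounds: seed lists of gut microbes legitimately
#'   include oxygen and small cofactors.
#'
#' @return A named list of class `gutseed_parse_options`.
#' @export
parse_options <- function(strip_compartments = TRUE,
                          exclude_reactions = "^(EX_|biomass)",
                          exclude_compounds = NULL) {
  structure(
    list(
      strip_compartments = isTRUE(strip_compartments),
      exclude_reactions = exclude_reactions,
      exclude_compounds = exclude_compounds
    ),
    class = "gutseed_parse_options"
  )
}

#' Strip a compartment tag from a species id
#'
#' Removes one trailing `[x]` tag (any alphanumeric compartment label) or one
#' trailing `_x` tag (single letter), the two dialects used by genome-scale
#' model collections. Applied once, not iteratively, so `glc__D_c` becomes
#' `glc__D` and no more is removed.
#'
#' @param raw_id Character vector of model-local species ids.
#' @return Character vector of base ids.
#' @export
strip_compartment <- function(raw_id) {
  out <- stringr::str_replace(raw_id, "\\[[A-Za-z0-9]+\\]$", "")
  # only strip `_x` when something is left and the id did not carry brackets
  no_bracket <- out == raw_id
  out[no_bracket] <- stringr::str_replace(out[no_bracket], "_[A-Za-z]$", "")
  bad <- !nzchar(out)
  out[bad] <- raw_id[bad]
  out
}

sbml_ns <- function(doc) {
  ns <- xml2::xml_ns(doc)
  # find the prefix bound to an SBML level namespace; rename it `s`
  uri <- unlist(ns)
  hit <- grep("sbml\\.org/sbml", uri)
  if (length(hit) == 0) rlang::abort("Document does not declare an SBML namespace.")
  c(s = uri[[hit[1]]])
}

first_regex <- function(text, pattern) {
  m <- stringr::str_match(text, pattern)[, 2]
  m <- m[!is.na(m)]
  if (length(m) == 0) NA_character_ else m[[1]]
}

#' Parse an SBML metabolic model into a directed compound graph
#'
#' Each species becomes one node (after optional compartment stripping); each
#' retained reaction contributes an edge from every substrate to every
#' product, plus the reverse pairs when the reaction is reversible. Exchange
#' and biomass reactions are excluded by default (see [parse_options()]); the
#' choice is recorded in the network's provenance. KEGG (`C\\d{5}`) and ChEBI
#' identifiers are harvested from species annotations when present.
#'
#' @param path Path to an SBML file (Level 2 or 3), or a string of SBML XML.
#' @param options A [parse_options()] list.
#' @param organism_id Organism identifier; defaults to the model `id`
#'   attribute, falling back to the file name.
#'
#' @return A [metabolic_network()] with the harmonized reaction table
#'   attached (see [reaction_table()]).
#' @export
parse_sbml <- function(path, options = parse_options(), organism_id = NULL) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      rlang::abort(paste0("Malformed SBML XML: ", conditionMessage(e)))
    }
  )
  ns <- sbml_ns(doc)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) rlang::abort("SBML document has no <model>.")
  if (is.null(organism_id)) {
    organism_id <- xml2::xml_attr(model, "id")
    if (is.na(organism_id) || !nzchar(organism_id)) {
      organism_id <- if (is.character(path) && length(path) == 1 &&
                         file.exists(path)) {
        tools::file_path_sans_ext(basename(path))
      } else {
        "model"
      }
    }
  }

  species_nodes <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  if (length(species_nodes) == 0) rlang::abort("SBML model declares no species.")
  raw_id <- xml2::xml_attr(species_nodes, "id")
  sp_name <- xml2::xml_attr(species_nodes, "name")
  annot <- vapply(species_nodes, function(n) {
    a <- xml2::xml_find_first(n, ".//s:annotation", ns)
    if (inherits(a, "xml_missing")) "" else as.character(a)
  }, character(1))
  kegg_id <- vapply(annot, first_regex, character(1),
                    pattern = "kegg[^\"'>]*[/:](C\\d{5})")
  chebi_id <- vapply(annot, first_regex, character(1),
                     pattern = "(CHEBI:\\d+)")
  base_id <- if (options$strip_compartments) strip_compartment(raw_id) else raw_id

  species <- tibble::tibble(
    raw_id = raw_id, base_id = base_id,
    name = dplyr::coalesce(sp_name, raw_id),
    kegg_id = unname(kegg_id), chebi_id = unname(chebi_id)
  )
  id_map <- stats::setNames(species$base_id, species$raw_id)

  rx_nodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx_nodes) == 0) rlang::abort("SBML model declares no reactions.")

  get_refs <- function(rx, which) {
    refs <- xml2::xml_find_all(
      rx, paste0("./s:", which, "/s:speciesReference"), ns
    )
    xml2::xml_attr(refs, "species")
  }
  rx_list <- purrr::map(rx_nodes, function(rx) {
    rev_attr <- xml2::xml_attr(rx, "reversible")
    enz <- xml2::xml_find_all(
      rx, ".//s:listOfModifiers/s:modifierSpeciesReference", ns
    )
    notes <- xml2::xml_find_first(rx, "./s:notes", ns)
    gene_assoc <- if (!inherits(notes, "xml_missing")) {
      first_regex(as.character(notes), "GENE_ASSOCIATION:\\s*([^<]+)")
    } else NA_character_
    fbc <- xml2::xml_attr(rx, "fbc:geneProductAssociation")
    enzymes <- c(
      xml2::xml_attr(enz, "species"),
      if (!is.na(gene_assoc)) stringr::str_trim(gene_assoc),
      if (!is.na(fbc)) fbc
    )
    list(
      id = xml2::xml_attr(rx, "id"),
      substrates = get_refs(rx, "listOfReactants"),
      products = get_refs(rx, "listOfProducts"),
      # SBML L2 defaults reversible to true; L3 requires the attribute
      reversible = is.na(rev_attr) || identical(tolower(rev_attr), "true"),
      enzymes = enzymes[!is.na(enzymes) & nzchar(enzymes)]
    )
  })

  all_ref <- unique(unlist(purrr::map(rx_list, ~ c(.x$substrates, .x$products))))
  undeclared <- setdiff(all_ref, species$raw_id)
  if (length(undeclared) > 0) {
    offender <- purrr::detect(rx_list, function(r) {
      any(c(r$substrates, r$products) %in% undeclared)
    })
    rlang::abort(paste0(
      "Reaction `", offender$id, "` references undeclared species: ",
      paste(intersect(c(offender$substrates, offender$products), undeclared),
            collapse = ", ")
    ))
  }

  excluded <- if (!is.null(options$exclude_reactions)) {
    vapply(rx_list, function(r) {
      grepl(options$exclude_reactions, r$id, ignore.case = TRUE)
    }, logical(1))
  } else {
    rep(FALSE, length(rx_list))
  }

  edge_tbls <- purrr::map(rx_list[!excluded], function(r) {
    subs <- unique(unname(id_map[r$substrates]))
    prods <- unique(unname(id_map[r$products]))
    if (length(subs) == 0 || length(prods) == 0) return(NULL)
    fwd <- tidyr::expand_grid(from = subs, to = prods)
    if (r$reversible) {
      dplyr::bind_rows(fwd, tidyr::expand_grid(from = prods, to = subs))
    } else {
      fwd
    }
  })
  edges <- dplyr::bind_rows(edge_tbls)
  if (nrow(edges) == 0) edges <- tibble::tibble(from = character(), to = character())

  compounds <- species |>
    dplyr::group_by(.data$base_id) |>
    dplyr::summarise(
      name = dplyr::first(.data$name),
      kegg_id = dplyr::first(.data$kegg_id[!is.na(.data$kegg_id)], default = NA_character_),
      chebi_id = dplyr::first(.data$chebi_id[!is.na(.data$chebi_id)], default = NA_character_),
      raw_ids = paste(sort(unique(.data$raw_id)), collapse = ";"),
      .groups = "drop"
    )
  if (!is.null(options$exclude_compounds)) {
    drop <- options$exclude_compounds
    compounds <- dplyr::filter(compounds, !.data$base_id %in% drop)
    edges <- dplyr::filter(edges, !.data$from %in% drop, !.data$to %in% drop)
  }

  reactions <- tibble::tibble(
    reaction_id = vapply(rx_list, `[[`, character(1), "id"),
    substrates = vapply(rx_list, function(r) {
      paste(sort(unique(unname(id_map[r$substrates]))), collapse = ";")
    }, character(1)),
    products = vapply(rx_list, function(r) {
      paste(sort(unique(unname(id_map[r$products]))), collapse = ";")
    }, character(1)),
    reversible = vapply(rx_list, `[[`, logical(1), "reversible"),
    enzymes = vapply(rx_list, function(r) {
      paste(r$enzymes, collapse = ";")
    }, character(1)),
    excluded = excluded
  )

  metabolic_network(
    edges = edges,
    compounds = compounds,
    organism_id = organism_id,
    reactions = reactions,
    provenance = list(
      source = "sbml",
      strip_compartments = options$strip_compartments,
      exclude_reactions = options$exclude_reactions %||% "",
      n_species = length(species_nodes),
      n_reactions = length(rx_list),
      n_reactions_excluded = sum(excluded)
    )
  )
}

#' Read a two-column edge list as a metabolic network
#'
#' The text dialect is two tab-separated columns (`from<TAB>to`), one edge
#' per line, UTF-8, LF line endings; lines starting with `#` are comments.
#'
#' @param path Path to an edge-list file, or a character vector of lines.
#' @param organism_id Organism identifier; defaults to the file name.
#' @return A [metabolic_network()].
#' @export
read_edge_list <- function(path, organism_id = NULL) {
  if (length(path) == 1 && file.exists(path)) {
    lines <- readr::read_lines(path)
    if (is.null(organism_id)) {
      organism_id <- tools::file_path_sans_ext(basename(path))
    }
  } else {
    lines <- unlist(strsplit(paste(path, collapse = "\n"), "\n"))
    if (is.null(organism_id)) organism_id <- "organism"
  }
  node_lines <- grepl("^#\\s*node:\t", lines)
  isolated <- sub("^#\\s*node:\t", "", lines[node_lines])
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Edge-list format error at line ", idx[bad[1]],
      ": expected 2 tab-separated columns, found ", lengths(parts)[bad[1]], "."
    ))
  }
  edges <- if (length(parts) == 0) {
    tibble::tibble(from = character(), to = character())
  } else {
    tibble::tibble(
      from = vapply(parts, `[[`, character(1), 1),
      to = vapply(parts, `[[`, character(1), 2)
    )
  }
  compounds <- tibble::tibble(
    base_id = sort(unique(c(edges$from, edges$to, isolated)))
  )
  metabolic_network(edges, compounds = compounds, organism_id = organism_id,
                    provenance = list(source = "edge_list"))
}

#' Write a metabolic network as a two-column edge list
#'
#' Edges are written in lexicographic order so the output is byte-identical
#' across runs for the same network. Isolated nodes (no incident edge) are
#' recorded as `# node:` comment lines so that read/write round-trips
#' preserve the node set.
#'
#' @param network A [metabolic_network()].
#' @param path Output path; if `NULL` the lines are returned invisibly
#'   without writing.
#' @return Invisibly, the character vector of lines written.
#' @export
write_edge_list <- function(network, path = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  edges <- dplyr::arrange(network$edges, .data$from, .data$to)
  isolated <- setdiff(network$compounds$base_id,
                      unique(c(edges$from, edges$to)))
  lines <- c(
    paste0("# organism: ", network$organism_id),
    if (length(isolated) > 0) paste0("# node:\t", sort(isolated)),
    if (nrow(edges) > 0) paste0(edges$from, "\t", edges$to)
  )
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(lines)
}

#' Harmonized reaction table of a parsed model
#'
#' One row per reaction of the source model (excluded exchange/biomass
#' reactions included, flagged in the `excluded` column), with
#' semicolon-joined substrate and product base ids, reversibility, enzyme
#' annotations, human-readable compound names and external identifiers.
#'
#' @param network A [metabolic_network()] produced by [parse_sbml()].
#' @return A tibble with columns `reaction_id`, `substrates`, `products`,
#'   `reversible`, `enzymes`, `substrate_names`, `product_names`,
#'   `kegg_ids`, `excluded`.
#' @export
reaction_table <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(network$reactions)) {
    rlang::abort("This network carries no reaction records (edge-list source?).")
  }
  lookup_join <- function(ids, col) {
    vapply(strsplit(ids, ";", fixed = TRUE), function(v) {
      if (length(v) == 0 || identical(v, "")) return("")
      vals <- network$compounds[[col]][match(v, network$compounds$base_id)]
      paste(dplyr::coalesce(vals, ""), collapse = ";")
    }, character(1))
  }
  network$reactions |>
    dplyr::mutate(
      substrate_names = lookup_join(.data$substrates, "name"),
      product_names = lookup_join(.data$products, "name"),
      kegg_ids = lookup_join(
        paste(.data$substrates, .data$products, sep = ";"), "kegg_id"
      )
    ) |>
    dplyr::select(
      "reaction_id", "substrates", "products", "reversible", "enzymes",
      "substrate_names", "product_names", "kegg_ids", "excluded"
    )
}

#' Serialize a metabolic network to SBML
#'
#' Writes a minimal SBML Level 3 document with one species per compound and
#' one irreversible reaction per directed edge. Useful for round-trip
#' checking and for feeding the package's own parser with synthetic models.
#'
#' @param network A [metabolic_network()].
#' @param path Output path; if `NULL`, the XML string is returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the SBML string.
#' @export
write_sbml <- function(network, path = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  comp <- network$compounds
  species_xml <- sprintf(
    '      <species id="%s" name="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    esc(comp$base_id), esc(dplyr::coalesce(comp$name, comp$base_id))
  )
  edges <- dplyr::arrange(network$edges, .data$from, .data$to)
  rx_xml <- if (nrow(edges) > 0) {
    sprintf(paste0(
      '      <reaction id="R_%04d" reversible="false" fast="false">\n',
      '        <listOfReactants>\n',
      '          <speciesReference species="%s" stoichiometry="1" constant="true"/>\n',
      '        </listOfReactants>\n',
      '        <listOfProducts>\n',
      '          <speciesReference species="%s" stoichiometry="1" constant="true"/>\n',
      '        </listOfProducts>\n',
      '      </reaction>'
    ), seq_len(nrow(edges)), esc(edges$from), esc(edges$to))
  } else {
    character()
  }
  xml <- paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('  <model id="%s">', esc(network$organism_id)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    species_xml,
    '    </listOfSpecies>',
    '    <listOfReactions>',
    rx_xml,
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'
  ), collapse = "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(xml, con, sep = "\n", useBytes = TRUE)
    return(invisible(xml))
  }
  xml
}
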