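# In-code fixtures shared across test files.

sbml_toy <- function(species, reactions) {
  # reactions: list of list(id, sub = chr, prod = chr, rev = logical)
  sp <- paste0(
    '      <species id="', species, '" name="', species,
    '" compartment="c" hasOnlySubstanceUnits="false" ',
    'boundaryCondition="false" constant="false"/>',
    collapse = "\n"
  )
  rx <- vapply(reactions, function(r) {
    paste0(
      '      <reaction id="', r$id, '" reversible="',
      tolower(isTRUE(r$rev)), '" fast="false">\n',
      '        <listOfReactants>\n',
      paste0('          <speciesReference species="', r$sub,
             '" stoichiometry="1" constant="true"/>', collapse = "\n"),
      '\n        </listOfReactants>\n',
      '        <listOfProducts>\n',
      paste0('          <speciesReference species="', r$prod,
             '" stoichiometry="1" constant="true"/>', collapse = "\n"),
      '\n        </listOfProducts>\n',
      '      </reaction>'
    )
  }, character(1))
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'level="3" version="1">\n',
    '  <model id="toy">\n',
    '    <listOfCompartments>\n',
    '      <compartment id="c" constant="true"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n', sp, '\n    </listOfSpecies>\n',
    '    <listOfReactions>\n', paste(rx, collapse = "\n"),
    '\n    </listOfReactions>\n',
    '  </model>\n</sbml>'
  )
}

# network from a compact edge string "A>B B>C"
net_from_edges <- function(spec, organism_id = "toy", nodes = NULL) {
  if (nzchar(spec)) {
    parts <- strsplit(strsplit(spec, " ", fixed = TRUE)[[1]], ">",
                      fixed = TRUE)
    edges <- tibble::tibble(
      from = vapply(parts, `[[`, character(1), 1),
      to = vapply(parts, `[[`, character(1), 2)
    )
  } else {
    edges <- tibble::tibble(from = character(), to = character())
  }
  compounds <- if (!is.null(nodes)) tibble::tibble(base_id = nodes)
  metabolic_network(edges, compounds = compounds, organism_id = organism_id)
}

# seed_set literal: seed_set_of("org", A = 1, B = 0.5, ...)
seed_set_of <- function(organism_id, ...) {
  conf <- c(...)
  structure(
    list(
      organism_id = organism_id,
      seeds = tibble::tibble(
        base_id = names(conf), confidence = unname(conf),
        component = seq_along(conf)
      ),
      total_weight = sum(conf)
    ),
    class = "seed_set"
  )
}

# the printed reference profile of honey used as a verbatim fixture:
# one quantified compound per nonzero category reproduces each mean exactly
honey_food_rows <- function() {
  vals <- c(vitamins = 0.38, amino_acids = 7.92, oligosaccharides = 426.39,
            bioactive_substances = 1361.06, nitrogenous_compounds = 0,
            monosaccharides = 9352.92, NSN = 0)
  nz <- names(vals)[vals > 0]
  tibble::tibble(
    food_id = "HONEY", food_name = "Honey", food_class = "regular",
    compound_name = paste0(nz, " marker"),
    compound_norm = normalize_name(paste0(nz, " marker")),
    category = nz,
    concentration_mg_per_100g = unname(vals[nz]),
    detection = "quantified"
  )
}

honey_expected_profile <- function() {
  tibble::tibble(
    food_id = "HONEY", food_name = "Honey",
    vitamins = 0.38, amino_acids = 7.92, oligosaccharides = 426.39,
    bioactive_substances = 1361.06, nitrogenous_compounds = 0,
    monosaccharides = 9352.92, NSN = 0
  )
}
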