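---
title: "Reverse-ecology methods: seed sets, interaction indices and prebiotic food scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-ecology methods: seed sets, interaction indices and prebiotic food scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutseed)
```

## Scope and model

`gutseed` treats a genome-scale metabolic reconstruction as a directed
compound graph: one node per (compartment-stripped) compound, and an edge
from every substrate of a reaction to every product, with the reverse
pairs added for reversible reactions. This is a deliberately topological
view — stoichiometry, flux capacity and gene regulation are ignored —
because the question it answers is qualitative: *which compounds can this
organism in principle derive from others, and which must come from
outside?* A compound is derivable exactly when some other compound reaches
it along directed edges; the minimal exogenous set falls out of the
strongly connected component (SCC) condensation.

### Seed detection

After condensation, components with no incoming edges ("source
components") cannot be produced from the rest of the network. All of
their members are reported as seeds with confidence `1/m` for a component
of size `m`: the members of one source component are interconvertible, so
any single one of them suffices and the evidence for each individual
member is diluted accordingly. This confidence model makes the seed set's
total weight equal the number of source components, which is the natural
denominator for the weighted interaction indices. With the default
`min_confidence = 0` every node of the network is reachable from the seed
set, and removing all members of any one source component provably orphans
that component — both properties are asserted in the test suite.

Two parsing choices materially change seed counts on real models, and both
are explicit options rather than silent defaults:

* **Compartment handling** (`strip_compartments`, default `TRUE`): model
  collections tag species with compartments (`glc[c]`, `glc_e`). Without
  stripping, the extracellular copy of every imported compound is an
  isolated or near-isolated node and seed counts inflate with duplicated
  chemistry; moreover cross-organism index computation needs one shared
  namespace. Stripping is one trailing tag, applied once, never
  iteratively.
* **Exchange and biomass pseudo-reactions** (`exclude_reactions`, default
  `^(EX_|biomass)`, case-insensitive): exchange reactions connect medium
  compounds into the network, which would make every medium compound
  producible and hence a non-seed — the opposite of what seed detection is
  for. Both the pattern and the exclusion count are recorded in the
  network's provenance.

Currency metabolites (ATP, water, protons, oxygen) are **kept** by
default. Gut-microbe seed lists legitimately contain small cofactors and
oxygen; a caller who wants them out passes `exclude_compounds`.

### Interaction indices

The three pairwise indices are weighted set fractions over seed sets and
network node sets (see the README for the formulas). Confidence weighting
is the default; the unweighted variant (`weighted = FALSE`) divides plain
counts instead and coincides with the weighted one whenever all seed
components are singletons. The exact identity
`competition + complementarity = weighted fraction of focal seeds present
anywhere in the partner network` holds by construction and is tested to
1e-12; it is a useful diagnostic, since a silent namespace mismatch
between two models drives all three terms to zero together.

Matrix orientation is fixed and printed into every output file: entry
(row *r*, column *c*) is the index with focal = *r*, partner = *c*, i.e.
column organisms complement or compete with the row organism's
requirements.

### Community partition

The core / strain-specific / shared partition counts compound membership,
not confidence: the classes answer "how many organisms require this
compound", for which the dilution of large source components is
irrelevant. For a single-organism community every seed is simultaneously
"required by all" and "required by exactly one"; core takes precedence so
that the partition identity `|core| + |unique| + |shared| = |universe|`
holds for every community size.

### Pathway enrichment

Overrepresentation uses the upper-tail hypergeometric probability,
computed through `stats::phyper` (log-space, stable far beyond the
universe sizes met here); the test suite checks it against an explicit
binomial-coefficient enumeration for all parameter combinations with
`N ≤ 25` at 1e-12. The universe `N` defaults to the union of the
organism's own metabolism-pathway compounds (`universe = "organism"`),
since pathway complements differ between organisms; a global universe is
one flag away. Raw p-values with a 0.05 threshold are the default and a
Benjamini–Hochberg option exists but is off, so that per-pathway values
remain directly interpretable against the per-organism reports. The
community summary averages a pathway's p-values only over the organisms
that carry the pathway: an absent pathway is missing evidence, not
evidence of absence, and letting it contribute would bias means toward
organisms with small pathway complements.

### Food sourcing and scoring

Name matching is exact after Unicode NFC normalization, case folding and
whitespace collapse — never fuzzy. Nomenclature gaps between metabolic
models and food databases are real and substantial; the unmatched list is
a first-class output so the gap is visible rather than papered over.

The filter cascade runs in a fixed order (matched compound present →
above-LOQ → food class → all four growth-factor categories detected) with
survivor counts reported per stage; it is idempotent, and "baby food"
rows pass the class filter as an annotated control class. Category values
are means over matched, quantified compounds only (a flag widens this to
all compounds); min–max normalization across the retained cohort maps
each category to [0, 1], reading "normalized to the range [0–1]"
literally — it equals divide-by-max whenever the cohort minimum is zero,
which holds for most categories in practice. The normalization cohort is
the set of foods surviving the full cascade; normalizing before filtering
is the other defensible order, and the cohort used is recorded in the
output header so the choice is auditable. Ranking ties break
lexicographically by food name for byte-stable reports.

The default weights (10 / 8 / 6 / 4 / 2 / 1 / −100 for vitamins, amino
acids, oligosaccharides, bioactive substances, organic N compounds,
monosaccharides, NSN) encode a growth-factor-first preference: vitamins
and amino acids are essential and scarce (hence the largest weights),
monosaccharides are ubiquitous carbon (weight 1), and non-standard
nutritive compounds are penalized hard enough that any nonzero normalized
NSN value dominates the positive terms. All seven are overridable.

### Literature mining

Annotation is case-insensitive, word-boundary, longest-match-first;
overlapping candidate matches resolve to the longer term, so a species
binomial suppresses its embedded genus name. The "relationship" between
two dictionary concepts is approximated by same-sentence co-occurrence: a
dependency-parse relation classifier is a heavier, model-dependent
component, and the package instead exposes a pluggable predicate
(`predicate` argument) so stricter classifiers can be slotted in without
changing the counting contracts. Frequencies are sentence-level (a species
mentioned twice in a sentence counts once), filter rules run in a fixed
order with first-matching-rule attribution, and the chain is idempotent.

## What the synthetic generators emulate — and what they do not

The generators produce structurally faithful inputs with planted,
exactly recoverable truth:

* `generate_network()` plants an acyclic component skeleton with a chosen
  number of source components, each component expanded to a cycle plus
  chords; seed recovery is exact by construction.
* `generate_community()` programs pairwise seed overlaps by exact set
  construction (dedicated shared pools per pair), so recovered
  competition and complementarity equal their targets identically, not
  statistically. Infeasible designs (overlaps exceeding the seed budget)
  error instead of being approximated.
* `generate_food_table()` draws per-category log-normal concentrations
  (oligosaccharides and monosaccharides plentiful, vitamins scarce) and
  plants designated violators of each cascade stage; its manifest
  recomputes the expected ranking with independent plain arithmetic.
* `generate_annotation()` plants one pathway with elevated seed overlap
  and records realized `(N, K, n, k)` per pathway.
* `generate_corpus()` assembles sentences from neutral filler plus
  planted dictionary terms, including designated victims for every filter
  rule, and computes all expected counts by subset arithmetic over the
  roster.

What they deliberately do **not** emulate: biochemical realism (no real
reaction chemistry, no thermodynamics), the heavy-tailed degree
distributions of genome-scale reconstructions, food-database nomenclature
noise, or natural language beyond template filler. Passing tests
therefore demonstrate algorithmic correctness on the specified
structures, not biological validity of any particular model collection —
results on real models inherit the quality of those models.

Determinism is part of the contract: one integer seed drives a named RNG
stream per generator (so adding a generator never perturbs existing
fixtures), regeneration is byte-identical, and generators restore the
caller's RNG state.

## Numerical and reproducibility choices

* All set operations are on exact string ids; the only floating-point
  arithmetic is confidences (dyadic or small rationals), index ratios,
  means, min–max normalization and `phyper` — equality assertions in the
  tests use 1e-12 where rounding can occur at all and exact comparison
  elsewhere.
* Every report is deterministically ordered (lexicographic tie-breaks
  throughout), and `run_pipeline()` writes outputs through a staging
  directory: a failing stage aborts with the stage name and leaves no
  partial outputs, and two runs on identical inputs are byte-identical.
  For that reason the run summary carries a config hash and tool version
  but no wall-clock timestamp.
* Degenerate inputs have defined behavior: an empty network errors in
  `detect_seeds()`; a single retained food gets all-zero normalized
  values (max = min ⇒ 0) and score 0; a category with no quantified
  compound contributes 0; an empty record set yields an empty frequency
  table.

## Test problem sizes

The suite exercises: 200 random digraphs (n ≤ 60) against a brute-force
transitive-closure oracle; 100 planted network parameterizations and
community designs with exact recovery; 50 random network pairs for the
index identities; the complete hypergeometric parameter grid for N ≤ 25
plus a 1000-replicate null calibration; a 50-food fixture with 200
perturbation trials for the scoring invariants; an 11-combination planted
corpus; and two full pipeline runs compared byte-for-byte. These sizes
were chosen to make every property check exact or tightly calibrated
while keeping the default suite quick on a single CPU.

## Known limitations

* Seed detection is purely topological: compounds producible only in
  stoichiometrically infeasible ways still count as producible, and
  quantitative growth predictions (flux balance analysis) are out of
  scope.
* Cross-organism comparison assumes a shared compound namespace after
  compartment stripping; models drawn from different id systems must be
  mapped by the caller (the partition identity diagnostic exposes, but
  cannot fix, a mismatch).
* Exact name matching understates true food coverage of model
  metabolites; the unmatched report quantifies this.
* Same-sentence co-occurrence over-counts relative to a syntactic
  relation classifier; counts are upper bounds on linguistically asserted
  relationships.
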