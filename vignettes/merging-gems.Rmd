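---
title: "Merging genome-scale metabolic models across identifier namespaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging genome-scale metabolic models across identifier namespaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemmerge)
```

## The problem

A genome-scale metabolic model (GEM) is a triple (M, R, O): a metabolite
set, a reaction set — each reaction an ordered pair of reactant and
product sets with stoichiometric coefficients — and a set of objective
reactions (typically biomass). Reconstruction pipelines disagree on
identifiers: the same glucose molecule is `glc__D_c` (BiGG),
`cpd00027_c0` (ModelSEED) or `MNXM41` (MetaNetX), and cross-reference
tables published by the databases are mutually inconsistent. Comparing or
combining reconstructions therefore needs (i) a reconciled identifier
space and (ii) a merging procedure that is robust to the conventions each
pipeline uses (explicit protons, boundary pseudo-compartments, reaction
direction). This vignette describes how `gemmerge` implements both, the
choices left open by the underlying method and how this package resolved
them, and what the test suite does and does not demonstrate.

## The universal identifier mapper

`build_universal_mapper()` ingests flat-file dumps from, in default
precedence order, MetaNetX, ModelSEED, BiGG, KEGG and ChEBI. Every native
(database, id) pair becomes a member of exactly one *universal entity*,
identified by an integer. Processing is sequential in precedence order:
records first register singleton entities carrying their properties, then
each cross-reference pair either merges two entities or is skipped by the
conflict guard: **a pair is skipped when its target id is already linked,
through an earlier pair, to a different id of the source database.** The
guard is what makes the order of databases meaningful — the first database
in which a cross-reference appears wins. The implementation uses
union-find with the guard applied at union time; a property test checks
that the resulting partition equals a literal sequential replay of the
pairs over plain member sets.

Three further rules, with their rationale:

* **ModelSEED aliases are excluded entirely.** ModelSEED alias columns map
  one id to several dissimilar metabolites in other databases (the
  ubiquinone/ubiquinol cpd15560/cpd15561 pattern), so ModelSEED
  contributes properties but no cross-references.
* **Property consolidation mirrors id precedence.** Names and EC numbers
  are unioned; formula, molecular weight and InChI key keep the first
  non-missing value in precedence order. InChI keys are stored, never used
  for matching — structure-based matching is out of scope.
* **Proton flagging.** A universal entity is flagged as proton/hydrogen
  when its consolidated formula is exactly `"H"` or any member name
  normalizes (lower-cased, trimmed) to one of `h`, `h+`, `h(+)`,
  `proton`, `hydrogen`. The method requires ignoring protons during
  reaction matching but states no detection rule; formula-plus-name is
  conservative and testable.

Two open points were resolved as follows: intra-database cross-references
(e.g. MetaNetX deprecated-id chains) are treated as ordinary pairs subject
to the same guard, and ChEBI contributes only explicit accession
cross-references, not ontology relations. The guard itself is applied
exactly as stated — only in the source-to-target direction; we do not
additionally skip pairs whose *source* is already linked to a different
target-database id, because the stated rule plus processing order already
yields a deterministic partition.

Raw-id lookup (`map_to_universal()`) tries, in order: the id verbatim;
with an SBML `M_`/`R_` prefix stripped; with a recognized trailing
compartment tag stripped (`_c`, `_c0`, `[c]`); with a namespace prefix
stripped (`bigg.metabolite:`, `chebi:`, ...). The first known variant
wins; the fixed order makes resolution deterministic where the method only
says ids are "recognized".

## The merging algorithm

`merge_gems()` composes five steps.

**Step 1 — template absorption.** All metabolites and reactions of the
first model are copied. A metabolite translates to its *mergem id*
`mergem_<u>_<code>` (universal id + normalized compartment code) unless an
earlier template metabolite already claimed that id — chemically adjacent
pairs such as NH3/NH4 often share a universal entity; the second keeps its
original id so that no template information is lost. The original id of
every translated metabolite is stored in the reversion map σ. Reaction
keys of all template reactions are registered in the key registry Ψ.

**Step 2 — absorbing further models.** Each metabolite goes through a
branch ladder: same id already merged → source-map update only; its mergem
id claimed and this model also contains the metabolite that seeded it →
keep the original id; its mergem id claimed by a metabolite of *this same
model* → substitute the mapped twin per reaction, except inside reactions
containing both (substitution there would corrupt stoichiometry or cancel
the metabolite); its mergem id claimed by an earlier model → identify the
two; otherwise translate and add. Non-objective reactions are then matched
by key: a reaction merges when its key *or its reverse key* is registered
(bounds define the actual direction, so direction is semantic, not
structural — the existing reaction is kept as-is, without bound flipping).
Matched reactions keep the first-encountered id, name, bounds and
stoichiometry; GPRs are OR-combined with disjunct-level deduplication and
annotations unioned — the method specifies GPR merging and is silent on
bounds, and keeping the template's values honors the template-preservation
guarantee. An unmatched reaction whose id already exists gets `∼`
appended.

Reaction keys always use the *mapped* mergem ids (ID_θ), even for
metabolites whose merged-model id stayed original; this maximizes
matching. In default mode participants pair with −1/+1; in
exact-stoichiometry mode with signed coefficients rounded to 6 decimals
(biomass coefficients are floating point). Protons and
boundary-compartment metabolites (code `b`) are omitted from keys unless
`include_protons = TRUE`; if omission would empty a key — a proton-only
exchange reaction — the unfiltered key is used instead, so such reactions
do not all collapse onto one empty key.

**Step 3 — objective.** Either one model's objective reactions are copied
(adding them, with translated participants, if they are not already
present), or a single `merged_objective` reaction is built: each precursor
appears once per side, its coefficient the running mean over the objective
reactions containing it, maintained with an explicit occurrence counter
per (metabolite, side). The prose of the method could also be read as
averaging over all *n* models; the per-containing-reaction mean is what
the stated update rule computes, and that is what is implemented — a
precursor present in one of three biomass reactions keeps its coefficient.
Two deliberate refinements: when the averaged reaction coincides *exactly*
(stoichiometry-aware key) with an existing reaction — e.g. all inputs
share one biomass — it is reused rather than duplicated, which also makes
self-merging exactly neutral; and the merged objective's source entries
list every input model's objective reactions, so a shared biomass counts
as shared in the distance matrix. Consequently an input objective reaction
may be traceable both through its structural copy and through the merged
objective; all other entities appear in exactly one source-map entry.

**Step 4 — Jaccard matrix.** Entity sets per model are derived from the
source maps: a merged metabolite counts toward model *i* iff μ lists *i*.
Metabolite distances fill the upper triangle, reaction distances the
lower, the diagonal is zero. Two empty sets get distance 0 (identical).

**Step 5 — reversion.** Every mergem-id metabolite is renamed back to σ's
stored original (the first model that used it), in the metabolite table,
all reaction participants and the source maps; no internal id survives
into the output. If two distinct mergem ids would revert to the same
original string (the same original id used in two compartments), the
later one is de-conflicted with a `∼` suffix — a case the method leaves
undefined.

## Translation and annotation extension

`translate_model()` renames every entity whose universal entity holds a
member id of the target database; with several candidates the
lexicographically smallest is chosen (determinism where the method gives
no tie-break) and the rest are reported. The report partitions entities
into renamed, no-target-member, and collision-blocked; an entity renamed
despite unused extra candidates counts as translated. Reaction ids are
translated only when the original id is recognized by the reaction mapper
— reaction ids play no role in merging, so nothing else is safe to rename.
`extend_annotations()` adds all member ids as identifiers.org-style
registry/id annotations (serialized as `bqbiol:is` CVTerms in SBML);
both operations are idempotent and leave stoichiometry, bounds, GPRs and
the objective untouched.

## Model I/O

SBML L3+FBCv2 is handled with `xml2`, COBRA JSON with `jsonlite`. No
MAT-file bindings exist in this R stack, so the package implements the
MAT-file level-5 container directly (little-endian, the subset COBRA
structs need: double/int arrays, char and cell arrays, sparse matrices,
scalar structs); a test verifies interoperability in both directions
against an independent Python COBRA implementation. Conventions: `M_`/`R_`
prefixes are stripped on read and restored on write; characters illegal in
an SBML SId (such as the `∼` conflict marker) are escaped as `__uXXXX__`
and restored on read; GPRs are stored as normalized boolean strings with
explicit parentheses; participant vectors are kept in metabolite-id order
because the MAT sparse representation cannot preserve insertion order and
a fixed order keeps files byte-stable. Writing is atomic (temporary file
plus rename). Annotations in MAT files use a `metMiriam`/`rxnMiriam`
field of `registry=id;...` tokens of this package's own design, since the
plain COBRA struct has no general annotation slot.

## Fixtures and what the tests show

All tests run from generated fixtures, no network. `make_mini_dumps()`
writes dialect-faithful mini dumps (11 MetaNetX metabolites, ~50 records
total per database) engineered to cover every rule: glucose
cross-referenced across all five databases, the nh3/nh4 pair sharing one
universal entity, a proton (formula `H`), and a ubiquinone/ubiquinol
conflict whose second `q8` cross-reference must be skipped. Built with the
default order this yields exactly 14 metabolite and 5 reaction universal
entities, numbered by ingestion order so documented expectations never
drift. `make_toy_models()` returns seven two-model scenarios, one per
algorithm branch (cross-namespace chemistry, reversed reactions,
mergem-id conflicts, proton conventions, objective averaging with
coefficients 1 and 3, stoichiometry mismatches).

These fixtures are small and fully controlled: passing tests demonstrate
the algebra of the method — partition correctness against a
sequential-replay oracle, merged reaction counts against a brute-force
canonical-key census (canonical key = lexicographic minimum of key and
reverse key), template preservation, self-merge neutrality, format round
trips. They do not demonstrate behavior on genome-scale inputs: real
models bring thousands of entities, inconsistent annotations, and database
snapshots that change over time, so absolute merge percentages on real
model pairs depend on the mapper snapshot and are expected to vary.
Problem sizes used throughout (models of ≤ 8 metabolites, mapper of ≤ 50
records per database, property loops of 50–100 random draws) were chosen
to keep every expected value hand-countable.

## Known limitations

* FBA/optimization of merged models is out of scope; merged models are
  written for external solvers.
* No gap-filling and no compartment-aware sub-model extraction.
* Compressed MAT elements are read via zlib when the R runtime supports
  it, and big-endian MAT files are rejected.
* Gene identifiers are carried through GPR strings untouched; gene-level
  metadata is not merged or translated.
* The `update_mapper()` download path requires network access and is
  exercised only through its offline pre-placed-cache behavior in tests.
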