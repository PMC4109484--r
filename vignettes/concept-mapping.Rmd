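---
title: "Concept trees, fractional weights and checklist mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept trees, fractional weights and checklist mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contax)
```

## The model

`contax` treats the *circumscription* — the set of populations a name usage
refers to — as the unit of currency, not the name. Every distinct
circumscription receives one opaque identifier (16 uppercase hex
characters); congruent published concepts share that identifier, so
relationships between thousands of published concepts collapse onto
relationships between far fewer identifiers. Those relationships are kept
as rooted parent–child trees in which every internal node's leaf set is
the disjoint union of its children's leaf sets. Terminal nodes are the
finest operational units (usually subspecies); identifiers for genera and
families are deliberately not registered, because the number of child
combinations at those ranks explodes while genus-level congruence can be
answered by comparing the species-level trees directly.

When the literature contains mutually contradictory arrangements, a tree
set stores several *variants*. All variants share the root and the
terminal nodes, and any intermediate node appearing in more than one
variant keeps the identical leaf set in each — so a node means the same
populations no matter which arrangement it is read from. This is also why
pairwise relations (`congruent`, `includes`, `included_in`, `overlaps`,
`excludes`) can be computed from leaf sets alone, independent of variant.
Two deliberate design choices here:

* Concepts held in *different* tree sets are reported `unrelated`, not
  `excludes`: the store has never co-modelled them and cannot certify
  disjointness. Merging their trees under a shared root makes them
  comparable.
* Hybrids get identifiers and links to their parental concepts but stay
  outside trees, weights and validation sums; their circumscriptions do
  not nest.

A monotypic species and its nominal subspecies are circumscription-
identical, so they are one identifier carrying a species-rank and a
subspecies-rank label (label aliasing, never duplicate nodes). Name
matching is exact after canonicalization (whitespace collapsed, genus
capitalized, epithets lower-cased); fuzzy matching is out of scope.

## Fractional weights

Weights implement a completeness test for arrangements: the root gets 1
and each child an equal share of its parent, so any full cut through a
variant sums to exactly 1. The arithmetic is exact rational (reduced
numerator/denominator pairs; denominators are products of small branching
factors, far below the 2^53 integer range of a double), which makes
sum-to-one checks identity tests. Floating arithmetic would make one
third of one third "almost" sum back and force tolerances whose failure
modes are precisely the near-miss arrangements the rules exist to catch.
Weights are *displayed* rounded to three decimals (1/3 → 0.333, 1/30 →
0.033), matching how such tables are printed; the display form is never
used in comparisons.

Regional authorities are handled by `scoped_weights()`: leaves outside the
declared scope are pruned, nodes left empty are deleted, and a node left
with one child passes its full weight to that child. Scope is supplied as
a set of leaf identifiers; translating a geographic region into that set
is a curation task, not something this package infers.

## The validation rules

`validate_mapping()` and `validate_treeset()` report numbered findings:

1. species-level weights sum to exactly 1 in at least one variant and
   never exceed 1 in any;
2. only one assignment of names to identifiers attains that total;
3. subspecies weights sum to their species' weight;
4. at most one record per checklist maps to an identifier (the monotypic
   nominal alias pair excepted);
5. no two same-rank records map onto one ancestor–descendant branch;
6. checklist parent links mirror tree ancestry;
7. alternate trees share root and terminals, and shared intermediate
   nodes keep identical leaf sets.

Findings are advisory, never hard stops — a violation means either a
mis-mapped checklist or a mis-built tree, and deciding which is curator
work (the CLI's `--strict` flag turns findings into a non-zero exit for
pipelines). Rule 1 is applied at species and subspecies levels only;
above the species level a taxon is fully specified by listing its species,
so the check adds nothing. Records of rank `other` (field pairs, species
groups) are exempt from the sum rules 1–3 but subject to 4–6, since the
sums are defined over species/subspecies arrangements. The sum rules are
evaluated only for trees whose records are all mapped: a tree containing
an ambiguous or conflicting record cannot be expected to balance.

## The mapper

`resolve_candidates()` turns each record's name into a candidate
identifier set via the label and synonym tables (empty set = potential new
concept). `solve_assignment()` then searches for assignments satisfying
the rules above. The search decomposes by root tree set — subproblems are
independent except for records whose candidates span several trees, which
link trees into clusters combined under an assigned-exactly-once
constraint. Within a tree, candidates are enumerated depth-first with
species assigned before subspecies, so the duplicate, branch and ancestry
rules prune most of the product space before any sum is computed. A
configurable cap (default 10^6 combinations per tree) turns pathological
homonymy into an explicit error instead of an open-ended search.

Statuses are per record: `mapped` when every surviving solution agrees on
the record, `ambiguous` when solutions disagree (all solutions are kept on
the result as an attribute), `conflict` when no combination satisfies the
rules, `unmapped_new` when the name is unknown or its candidates lie
outside every tree. Ambiguity is never resolved by heuristics — the
package's position is that a checklist either carries the information
(usually its subspecies list) or a curator must supply it, which is what
the override table is for. Output ordering ties are broken by ascending
identifier so reports are byte-reproducible.

`diff_checklists()` supports the revision workflow: records are matched by
canonical name, leftovers are tested for renames (a new combination
resolving, through the synonym table, to the concept of exactly one
disappeared record of the same rank — genus transfers and gender
emendations), and the rest classified added/removed. The diff is
informational; it does not constrain the solver, because an unchanged name
can legitimately change circumscription between editions (the sensu lato →
sensu stricto pattern).

## Edits

All edits are append-only: published concepts must stay resolvable
forever, so nothing is deleted and no existing identifier's leaf set ever
changes (a split refines a terminal into children; the terminal keeps its
identifier and its meaning). Splitting a terminal and merging independent
trees modify all variants in place and never create alternates; grouping
sister branches and reassigning subspecies across species are the two
operations that genuinely contradict the existing arrangement, so they add
a variant — and only if no structurally identical variant exists, keeping
the variant count minimal. Wherever an edit needs a circumscription that
already exists (the residue of a reassignment collapsing to a single
child, a group that was already published), the existing identifier is
reused rather than minted: congruent concepts share one identifier, always.
`elevate()` is pure relabelling — rank changes do not touch leaf sets.

## The simulator

`simulate_history()` generates a base store of independent species (2–4
subspecies each by default; a range minimum of 1 produces monotypic
species whose nominal subspecies is, realistically, not listed) and then
publishes full-snapshot checklist versions, between which it applies
terminal splits, lumps, genus-transfer renames, elevations and
reassignments at the configured per-version probabilities, with
`homonym_rate` optionally making base species reuse an existing binomial.
Every version is emitted with its true record-to-concept mapping. Names
come from a synthetic Latin-like vocabulary; renames feed the synonym
table the way emendations do in real data. The simulator never elevates
or moves a *nominate* subspecies — the name follows the type specimen, and
allowing it would manufacture same-named monotypic species pairs that no
information could distinguish.

What the simulation does *not* emulate: misspellings and OCR noise (no
fuzzy matching exists to exercise), partially published revisions (the
snapshot policy assumes the publisher or user expands them), geographic
range data, and the editorial judgement behind real lump/split decisions.
Passing tests therefore show that the algorithm is sound on structurally
faithful histories, not that real checklists are free of the curation
problems the validator exists to flag.

Test and acceptance runs use compact problem sizes chosen to exercise
every event type while keeping the suite quick: 3 base species with 2–3
subspecies over 3 versions, 100 seeds for the recovery property, and
fixture-scale inputs (≤ 15 nodes) for the brute-force cross-checks, where
the full candidate product is still enumerable by the independent oracle.

## Numerical and procedural choices

* Exact rational weights; equality, never tolerance.
* Three-decimal display rounding, chosen to match published weight tables.
* Deterministic report and output ordering (rule number, then subject;
  identifiers ascending).
* Identifier generation is seedable for reproducible builds and tests;
  `source = "urandom"` draws from the OS entropy pool for production
  registration.
* Combination cap 10^6 per tree set; exceeding it is an error naming the
  tree, not a silent truncation.
* Degenerate inputs: single-node trees are valid tree sets (weight 1);
  an empty store is a valid document; malformed trees become rule-7
  findings on validation rather than exceptions, while structurally
  impossible weight requests (cycles, multiple roots) are errors.

## Known limitations

* No fuzzy name matching; a misspelled name is `unmapped_new`.
* The solver reports — but cannot explain — conflicts: distinguishing "new
  concept" from "mis-built tree" needs a curator.
* Tree sets that have accumulated many variants and deep homonymy can in
  principle hit the combination cap; the decomposition per root keeps this
  rare, but the cap is the safety net, not a solution.
* Genus- and family-level concepts are not registered; congruence at
  those ranks is answered by comparing species-level trees.
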