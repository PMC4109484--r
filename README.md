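# contax

Taxonomic concept trees, exact fractional-weight validation, and
checklist-to-concept mapping.

## The problem

A scientific name only unambiguously identifies a type specimen. The
*circumscription* behind a name — the set of populations the name is used
for — changes every time a species is split, lumped, or has subspecies
moved around, without the name necessarily changing at all. The same
binomial can denote several distinct circumscriptions (concept homonyms:
*Vireo solitarius* sensu lato vs. sensu stricto), and one circumscription
can carry several binomials (concept synonyms: *Francolinus gariepensis* =
*Scleroptila levaillantoides*). Anyone aggregating biodiversity data across
checklist editions and authorities — collection managers, checklist
curators, builders of trait or occurrence databases — needs to resolve
which concept a name usage meant, not just which string it used.

`contax` manages this by giving every distinct circumscription an opaque
16-hex-character identifier and organizing identifiers into *concept
trees*: rooted parent–child hierarchies in which a parent's circumscription
is the disjoint union of its children's. Where the literature contains
mutually contradictory arrangements, a tree set carries *alternate
variants* that share the same root and the same terminal nodes but differ
in their intermediate nodes. All other relationships (congruence,
inclusion, overlap, exclusion) are derived from leaf-set algebra over these
trees.

## Fractional weights

Each tree variant is weighted by the recursive equal-split rule

```
w(root) = 1,    w(child) = w(parent) / k   for k children,
```

held as exact rationals (1/3 stays 1/3; 0.333 is display only). A
checklist's species-level concepts form a *valid complete arrangement* of a
tree exactly when their weights sum to 1 in at least one variant, the
subspecies of each species sum to that species' weight, no identifier is
used twice (monotypic nominal subspecies excepted), no two same-rank
records sit on one ancestor–descendant branch, and checklist parent links
mirror tree ancestry. The mapper searches all combinations of candidate
identifiers for the names in a checklist and keeps the combinations that
satisfy these rules: exactly one survivor means the records are `mapped`,
several mean `ambiguous` (reported, never guessed), none means `conflict`.
Regional checklists are handled by pruning out-of-scope leaves and
recomputing weights.

## Worked example

```r
library(contax)
fx <- build_fixture("vireo")   # the Solitary Vireo complex, 15 concepts
w  <- compute_weights(fx$store$treesets[[1]]$variants[[1]])
head(w[order(-w$value), c("concept", "num", "den", "display")], 5)
#>           concept num den display
#>  76F95B0D1D7C03A3   1   1   1.000
#>  03C169D358A0F361   1   3   0.333
#>  353A581C812C09B5   1   3   0.333
#>  731FF53C9110E6A8   1   3   0.333
#>  08C602977A8E3019   1   6   0.167
```

The root (*V. solitarius* s.l.) has weight 1; its three species-level
children (*solitarius* s.s., *cassinii*, *plumbeus*) each get 1/3, their
subspecies 1/6 (two-way splits) or 1/15 (displayed 0.067; the five-way
split under *plumbeus*), and the two finest concepts — *jacksoni* and the
nominal *plumbeus* that excludes it — get 1/30 (0.033). Mapping a revision
that lists all three species resolves the homonym *Vireo solitarius* to the
sensu stricto concept because only that choice sums to 1:

```r
m <- solve_assignment(fx$checklists$split5, store = fx$store)
#>  taxon_id             scientific_name status          concept
#>        S1            Vireo solitarius mapped 353A581C812C09B5
#>        S2              Vireo cassinii mapped 731FF53C9110E6A8
#>        S3              Vireo plumbeus mapped 03C169D358A0F361
#>        U1 Vireo solitarius solitarius mapped 08C602977A8E3019
```

A checklist that genuinely underdetermines the concepts is reported as
such. The parrot fixture (*Poicephalus robustus* / *fuscicollis*, where the
subspecies *suahelicus* has been attached to either species) with no
subspecies listed yields two full solutions:

```r
po <- build_fixture("poicephalus")
solve_assignment(po$checklists$two_species, store = po$store)
#>  taxon_id         scientific_name    status                        candidates
#>        S1    Poicephalus robustus ambiguous 1B7F27299DA5F492;75BC762575586ADF
#>        S2 Poicephalus fuscicollis ambiguous 8C2A0FEE6021F3D5;C9879837CA215D99
```

A command-line interface (`inst/scripts/contax`) exposes `map`, `validate`,
`weights`, `relate`, `edit`, `diff`, `fixture` and `simulate` over the same
functions; checklists are comma-separated Darwin Core Taxon tables and the
tree store is a YAML document.

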