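# Pairwise concept relationships derived from leaf-set algebra.

#' Relate two concepts by leaf-set algebra
#'
#' Within one tree set, the leaf sets of two concepts determine their
#' relationship: identity of identifiers means congruence (distinct ids
#' always denote distinct circumscriptions), strict containment means
#' inclusion, non-trivial intersection means partial overlap, and
#' disjointness means exclusion. Concepts held in different tree sets have
#' never been co-modelled, so their disjointness cannot be certified; they
#' are reported as `unrelated` rather than `excludes`.
#'
#' @param a,b concept identifiers known to the store.
#' @param store a `concept_store`.
#' @return One of `"congruent"`, `"includes"`, `"included_in"`,
#'   `"overlaps"`, `"excludes"`, `"unrelated"`.
#' @export
relate <- function(a, b, store) {
  ra <- treeset_of(store, a)
  rb <- treeset_of(store, b)
  known <- store$concepts$id
  if (!a %in% known) stop("unknown concept id: ", a)
  if (!b %in% known) stop("unknown concept id: ", b)
  if (a == b) return("congruent")
  if (is.na(ra) || is.na(rb) || ra != rb) return("unrelated")
  la <- leaf_set(a, store$treesets[[ra]])
  lb <- leaf_set(b, store$treesets[[rb]])
  inter <- intersect(la, lb)
  if (length(inter) == 0) return("excludes")
  if (all(lb %in% la) && length(la) > length(lb)) return("includes")
  if (all(la %in% lb) && length(lb) > length(la)) return("included_in")
  if (setequal(la, lb)) {
    # distinct ids should never share a leaf set; surface it rather than
    # silently calling them congruent
    stop("distinct ids ", a, " and ", b, " share a leaf set; store is inconsistent")
  }
  "overlaps"
}
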