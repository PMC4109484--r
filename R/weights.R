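# Fractional weights over a tree variant.
#
# The root concept receives weight 1; every child receives an equal share
# of its parent's weight (1/k for k siblings). The arithmetic is exact
# rational throughout: a valid complete arrangement sums to exactly 1, and
# conservation (children sum to their parent) is an identity, never a
# tolerance check. Weights print rounded to three decimals, as in the
# published tables (1/3 -> 0.333, 1/30 -> 0.033).

as_variant <- function(variant) {
  if (is.list(variant) && !is.null(variant$edges)) return(variant)
  new_variant(variant)
}

#' Compute fractional weights for every node of a tree variant
#'
#' @param variant a tree variant: either a list with an `edges` field or a
#'   bare named list mapping parent id to a character vector of child ids.
#' @param root root id; only needed for a single-node variant with no
#'   edges, otherwise derived from the edge map.
#' @return A `concept_weights` data frame with columns `concept`, `num`,
#'   `den` (exact reduced fraction), `value` (numeric) and `display`
#'   (3-decimal character form).
#' @examples
#' w <- compute_weights(list(R = c("A", "B", "C")))
#' subset(w, concept == "A")$display  # "0.333"
#' @export
compute_weights <- function(variant, root = NULL) {
  variant <- as_variant(variant)
  if (length(variant$edges) == 0) {
    if (is.null(root)) stop("single-node variant: root must be given")
    return(weight_table(list(root), list(rational(1))))
  }
  err <- variant_structure_error(variant)
  if (!is.null(err)) stop("invalid tree variant: ", err)
  root <- variant_root(variant)
  ids <- list()
  wts <- list()
  recurse <- function(node, w) {
    ids[[length(ids) + 1]] <<- node
    wts[[length(wts) + 1]] <<- w
    kids <- variant_children(variant, node)
    if (length(kids)) {
      share <- w / rational(length(kids))
      for (k in kids) recurse(k, share)
    }
  }
  recurse(root, rational(1))
  weight_table(ids, wts)
}

weight_table <- function(ids, wts) {
  df <- data.frame(
    concept = unlist(ids, use.names = FALSE),
    num = vapply(wts, function(w) w$num, numeric(1)),
    den = vapply(wts, function(w) w$den, numeric(1)),
    stringsAsFactors = FALSE
  )
  df$value <- df$num / df$den
  df$display <- vapply(df$value, weight_display, character(1))
  df <- df[order(df$concept), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("concept_weights", "data.frame")
  df
}

#' Exact weight of one node
#'
#' @param weights a `concept_weights` table.
#' @param id concept identifier.
#' @return A `rational`.
#' @export
weight_of <- function(weights, id) {
  i <- match(id, weights$concept)
  if (is.na(i)) stop("unknown node: ", id)
  rational(weights$num[i], weights$den[i])
}

#' Recompute weights under a restricted scope
#'
#' Regional checklists cover only part of a tree. Leaves outside `scope`
#' are pruned, nodes whose leaf set becomes empty are deleted, and weights
#' are recomputed on the pruned tree: a node left with a single child
#' passes its full weight down to that child. With `scope` equal to the
#' full leaf set the result is identical to [compute_weights()].
#'
#' @param variant a tree variant (see [compute_weights()]).
#' @param scope non-empty character vector of in-scope leaf ids.
#' @param root root id for a single-node variant.
#' @return A `concept_weights` table over the surviving nodes.
#' @export
scoped_weights <- function(variant, scope, root = NULL) {
  if (length(scope) == 0) stop("empty scope")
  variant <- as_variant(variant)
  if (length(variant$edges) == 0) {
    if (is.null(root)) stop("single-node variant: root must be given")
    if (!root %in% scope) stop("scope excludes the whole tree")
    return(weight_table(list(root), list(rational(1))))
  }
  err <- variant_structure_error(variant)
  if (!is.null(err)) stop("invalid tree variant: ", err)
  root <- variant_root(variant)
  leaves <- variant_leaves(variant)
  keep <- intersect(leaves, scope)
  if (length(keep) == 0) stop("scope excludes the whole tree")
  # prune bottom-up: a node survives if any of its leaves is in scope
  pruned <- list()
  survives <- function(node) {
    kids <- variant_children(variant, node)
    if (length(kids) == 0) return(node %in% keep)
    alive <- kids[vapply(kids, survives, logical(1))]
    if (length(alive) == 0) return(FALSE)
    pruned[[node]] <<- alive
    TRUE
  }
  if (!survives(root)) stop("scope excludes the whole tree")
  compute_weights(list(edges = pruned), root = root)
}

#' Exact sum of weights for a set of nodes
#'
#' The building block of arrangement validation: in a complete arrangement
#' of species concepts the sum is exactly 1, and it must never exceed 1.
#'
#' @param ids character vector of concept identifiers, all present in the
#'   variant.
#' @param variant a tree variant (see [compute_weights()]).
#' @param weights optionally a precomputed `concept_weights` table.
#' @return A `rational` sum.
#' @examples
#' arrangement_sum(c("A", "B", "C"), list(R = c("A", "B", "C"))) == rational(1)
#' @export
arrangement_sum <- function(ids, variant = NULL, weights = NULL) {
  if (is.null(weights)) weights <- compute_weights(variant)
  missing <- setdiff(ids, weights$concept)
  if (length(missing)) stop("unknown node: ", paste(missing, collapse = ", "))
  rat_sum(lapply(ids, weight_of, weights = weights))
}
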