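# Taxonomic-change events applied to tree sets.
#
# Edits are append-only: published concepts are permanent, so no event ever
# deletes a node or changes the leaf set of an existing identifier. New
# circumscriptions always receive new identifiers; where a needed
# circumscription already exists in the tree set its identifier is reused
# (congruent concepts share one id). Splitting a terminal and merging
# independent trees never create alternate variants; only grouping existing
# branches and reassigning leaves across species do, and a new variant is
# only added if no structurally identical one exists (keeping the number of
# alternate trees minimal).

parent_in_variant <- function(variant, id) {
  for (p in names(variant$edges)) {
    if (id %in% variant$edges[[p]]) return(p)
  }
  NA_character_
}

normalize_edges <- function(edges) {
  edges <- lapply(edges, function(x) sort(unique(as.character(x))))
  edges[order(names(edges))]
}

same_variant <- function(v1, v2) {
  identical(normalize_edges(v1$edges), normalize_edges(v2$edges))
}

add_variant_if_new <- function(treeset, edges) {
  cand <- new_variant(edges)
  for (i in seq_along(treeset$variants)) {
    if (same_variant(treeset$variants[[i]], cand)) {
      return(list(treeset = treeset, index = i, added = FALSE))
    }
  }
  treeset$variants <- c(treeset$variants, list(cand))
  list(treeset = treeset, index = length(treeset$variants), added = TRUE)
}

take_ids <- function(store, n, ids = NULL) {
  if (!is.null(ids)) {
    stopifnot(length(ids) == n)
    return(ids)
  }
  out <- character(0)
  while (length(out) < n) {
    id <- new_concept_id(store)
    if (!id %in% out) out <- c(out, id)
  }
  out
}

#' Split a terminal concept into new child concepts
#'
#' A split of one subspecies into several extends the terminal branch with
#' new child nodes; nothing above changes and no alternate variant is
#' needed, because the former terminal keeps its identifier and its leaf
#' set grows only by refinement (every pre-existing node still covers the
#' same populations).
#'
#' @param leaf a concept identifier terminal in every variant of its tree
#'   set.
#' @param store a `concept_store`.
#' @param n_children number of new children (>= 2), ignored when `ids`
#'   given.
#' @param ids optional explicit identifiers for the new children.
#' @param kind concept kind for the new children.
#' @return A list with `store` (updated) and `new_ids`.
#' @export
split_terminal <- function(leaf, store, n_children = 2, ids = NULL,
                           kind = "subspecies") {
  root <- treeset_of(store, leaf)
  if (is.na(root)) stop("unknown node: ", leaf)
  ts <- store$treesets[[root]]
  if (length(ts$variants)) {
    for (v in ts$variants) {
      if (leaf %in% names(v$edges)) {
        stop("cannot split internal node ", leaf)
      }
    }
  }
  n <- if (is.null(ids)) n_children else length(ids)
  if (n < 2) stop("a split needs at least two children")
  ids <- take_ids(store, n, ids)
  for (id in ids) store <- add_concept(store, id, kind)
  if (length(ts$variants) == 0) {
    ts$variants <- list(new_variant(stats::setNames(list(ids), leaf)))
  } else {
    for (i in seq_along(ts$variants)) {
      ts$variants[[i]]$edges[[leaf]] <- sort(ids)
    }
  }
  store$treesets[[root]] <- ts
  list(store = store, new_ids = ids)
}

#' Merge two independent tree sets under a new root
#'
#' When two species previously held in unrelated trees are lumped, their
#' trees are merged under a new parent concept covering both. Each
#' combination of one variant from each side yields one variant of the
#' merged tree set.
#'
#' @param a_root,b_root roots of two distinct tree sets.
#' @param store a `concept_store`.
#' @param id optional identifier for the new root.
#' @param kind concept kind for the new root.
#' @return A list with `store` and `root` (the new root id).
#' @export
merge_roots <- function(a_root, b_root, store, id = NULL, kind = "species") {
  if (identical(a_root, b_root)) stop("cannot merge a tree set with itself")
  if (!a_root %in% names(store$treesets)) stop(a_root, " does not head a tree set")
  if (!b_root %in% names(store$treesets)) stop(b_root, " does not head a tree set")
  ta <- store$treesets[[a_root]]
  tb <- store$treesets[[b_root]]
  id <- if (is.null(id)) new_concept_id(store) else id
  if (!id %in% store$concepts$id) store <- add_concept(store, id, kind)
  va <- if (length(ta$variants)) ta$variants else list(new_variant(list()))
  vb <- if (length(tb$variants)) tb$variants else list(new_variant(list()))
  variants <- list()
  for (x in va) {
    for (y in vb) {
      edges <- c(x$edges, y$edges)
      edges[[id]] <- c(a_root, b_root)
      variants <- c(variants, list(new_variant(edges)))
    }
  }
  store$treesets[[a_root]] <- NULL
  store$treesets[[b_root]] <- NULL
  store$treesets[[id]] <- new_treeset(id, variants)
  list(store = store, root = id)
}

#' Group a subset of a node's children under a new intermediate concept
#'
#' Lumping some (not all) sister branches creates a new circumscription
#' covering their union. The original variant is untouched; a new variant
#' is added in which the subset hangs under the intermediate node. If a
#' node with exactly that leaf set already exists its identifier is reused.
#'
#' @param parent parent concept identifier.
#' @param subset character vector (>= 2) of children of `parent`, a proper
#'   subset of them.
#' @param store a `concept_store`.
#' @param variant index of the variant to derive from.
#' @param id optional identifier for the new intermediate node.
#' @param kind concept kind for the new node.
#' @return A list with `store`, `group_id` and `variant_index` of the
#'   variant realizing the grouping.
#' @export
group_children <- function(parent, subset, store, variant = 1L, id = NULL,
                           kind = "species") {
  root <- treeset_of(store, parent)
  if (is.na(root)) stop("unknown node: ", parent)
  ts <- store$treesets[[root]]
  v <- ts$variants[[variant]]
  kids <- variant_children(v, parent)
  if (!all(subset %in% kids)) stop("subset contains non-children of ", parent)
  if (length(subset) < 2) stop("grouping a single child is meaningless")
  if (setequal(subset, kids)) {
    stop("subset equals all children; the group would duplicate ", parent)
  }
  leaves <- sort(unique(unlist(lapply(subset, variant_leafset, variant = v))))
  gid <- find_node_by_leafset(ts, leaves)
  if (is.na(gid)) {
    gid <- if (is.null(id)) new_concept_id(store) else id
    if (!gid %in% store$concepts$id) store <- add_concept(store, gid, kind)
  }
  edges <- v$edges
  edges[[parent]] <- c(setdiff(kids, subset), gid)
  edges[[gid]] <- subset
  res <- add_variant_if_new(ts, edges)
  store$treesets[[root]] <- res$treeset
  list(store = store, group_id = gid, variant_index = res$index)
}

#' Reassign leaves from one species to another
#'
#' Moving subspecies between species cannot be expressed inside one tree:
#' it yields new species-level circumscriptions A' (receiving species plus
#' the moved leaves) and B' (source species minus them). The two species
#' are first brought under a shared root (created by [merge_roots()] if
#' their trees were independent), then an alternate variant containing A'
#' and B' is added. The original variant stays intact. Where A' or B'
#' coincides with an existing circumscription its identifier is reused; in
#' particular a residue of one remaining child is that child itself.
#'
#' @param moved character vector of direct children of `from_species` in
#'   the base variant (non-empty, not all of them).
#' @param from_species,to_species species-level concept identifiers.
#' @param store a `concept_store`.
#' @param ids optional explicit identifiers, used in order for: new shared
#'   root (if needed), A', B' (as needed).
#' @return A list with `store`, `root` (shared root id), `a_prime`,
#'   `b_prime` and `variant_index`.
#' @export
reassign <- function(moved, from_species, to_species, store, ids = NULL) {
  if (length(moved) == 0) stop("nothing to reassign")
  idq <- ids
  pop_id <- function() {
    if (is.null(idq)) return(NULL)
    if (length(idq) == 0) stop("ids exhausted")
    x <- idq[[1]]; idq <<- idq[-1]; x
  }
  ra <- treeset_of(store, from_species)
  rb <- treeset_of(store, to_species)
  if (is.na(ra)) stop("unknown node: ", from_species)
  if (is.na(rb)) stop("unknown node: ", to_species)
  if (ra != rb) {
    m <- merge_roots(ra, rb, store, id = pop_id())
    store <- m$store
    root <- m$root
  } else {
    root <- ra
  }
  ts <- store$treesets[[root]]
  base_i <- NA_integer_
  for (i in seq_along(ts$variants)) {
    nv <- variant_nodes(ts$variants[[i]])
    if (from_species %in% nv && to_species %in% nv) { base_i <- i; break }
  }
  if (is.na(base_i)) stop("no variant contains both species")
  v <- ts$variants[[base_i]]
  from_kids <- variant_children(v, from_species)
  if (length(from_kids) == 0) stop(from_species, " has no children to reassign")
  if (!all(moved %in% from_kids)) {
    stop("moved nodes must be direct children of ", from_species)
  }
  if (setequal(moved, from_kids)) {
    stop("moving every child is a lump, not a reassignment")
  }
  remaining <- setdiff(from_kids, moved)
  a_leaves <- sort(unique(c(leaf_set(to_species, ts),
                            unlist(lapply(moved, variant_leafset, variant = v)))))
  b_leaves <- sort(unique(unlist(lapply(remaining, variant_leafset, variant = v))))
  a_prime <- find_node_by_leafset(ts, a_leaves)
  if (is.na(a_prime)) {
    a_prime <- pop_id()
    if (is.null(a_prime)) a_prime <- new_concept_id(store)
    if (!a_prime %in% store$concepts$id) store <- add_concept(store, a_prime, "species")
  }
  b_prime <- find_node_by_leafset(ts, b_leaves)
  if (is.na(b_prime)) {
    b_prime <- pop_id()
    if (is.null(b_prime)) b_prime <- new_concept_id(store)
    if (!b_prime %in% store$concepts$id) store <- add_concept(store, b_prime, "species")
  }
  edges <- v$edges
  # detach the source species and hang A'/B' in place of to/from
  pf <- parent_in_variant(v, from_species)
  pt <- parent_in_variant(v, to_species)
  if (is.na(pf) || is.na(pt)) stop("species must sit below the shared root")
  edges[[from_species]] <- NULL
  edges[[pf]] <- sort(unique(c(setdiff(edges[[pf]], from_species), b_prime)))
  edges[[pt]] <- sort(unique(c(setdiff(edges[[pt]], to_species), a_prime)))
  if (!identical(a_prime, to_species)) edges[[a_prime]] <- sort(c(to_species, moved))
  if (length(remaining) > 1 && !b_prime %in% remaining) {
    edges[[b_prime]] <- sort(remaining)
  }
  ts2 <- store$treesets[[root]]
  res <- add_variant_if_new(ts2, edges)
  store$treesets[[root]] <- res$treeset
  list(store = store, root = root, a_prime = a_prime, b_prime = b_prime,
       variant_index = res$index)
}

#' Elevate a subspecies to species rank
#'
#' Elevation changes ranks, not circumscriptions, so no new leaf sets are
#' needed for the elevated taxon itself: the former subspecies identifier
#' simply gains a species-rank label. The residue of the former species
#' (its other subspecies) must, however, be listable at species rank: with
#' a single sibling that sibling's identifier is relabelled (it is the
#' congruent circumscription); with several siblings they are grouped under
#' an intermediate concept via [group_children()], which may add a variant.
#'
#' @param leaf the subspecies concept being elevated.
#' @param store a `concept_store`.
#' @param species_name species-rank name for the elevated concept
#'   (optional).
#' @param residual_name species-rank name for the residual concept;
#'   defaults to the parent species' species-rank labels.
#' @param variant index of the variant to read the parent from.
#' @return A list with `store`, `elevated` (= `leaf`), `residual_id` and
#'   `parent`.
#' @export
elevate <- function(leaf, store, species_name = NULL, residual_name = NULL,
                    variant = 1L) {
  root <- treeset_of(store, leaf)
  if (is.na(root)) stop("unknown node: ", leaf)
  ts <- store$treesets[[root]]
  v <- ts$variants[[variant]]
  parent <- parent_in_variant(v, leaf)
  if (is.na(parent)) stop(leaf, " has no parent in the chosen variant")
  sibs <- setdiff(variant_children(v, parent), leaf)
  if (length(sibs) == 0) stop(leaf, " has no siblings; elevation is a no-op")
  if (length(sibs) == 1) {
    residual <- sibs
  } else {
    g <- group_children(parent, sibs, store, variant = variant)
    store <- g$store
    residual <- g$group_id
  }
  if (is.null(residual_name)) {
    residual_name <- labels_of(store, parent, rank = "species")
  }
  for (nm in residual_name) {
    store <- add_label(store, residual, nm, rank = "species")
    store <- add_synonym(store, nm, residual)
  }
  if (!is.null(species_name)) {
    store <- add_label(store, leaf, species_name, rank = "species")
    store <- add_synonym(store, species_name, leaf)
  }
  list(store = store, elevated = leaf, residual_id = residual, parent = parent)
}
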