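# The concept store: identifiers, concept trees with alternate variants,
# name labels and synonym lookup.
#
# A store holds
#   concepts  id + kind (species / subspecies / group / other)
#   labels    rank-tagged scientific names historically attached to an id
#   synonyms  additional name -> id entries (scientific or vernacular)
#   treesets  rooted concept trees, each with >= 1 alternate variants
#   hybrids   ids linked to two or more parental ids, kept outside trees
#
# A distinct id always denotes a distinct circumscription; congruent
# published concepts share one id, so relations between concepts reduce to
# relations between ids.

CONCEPT_KINDS <- c("species", "subspecies", "group", "other")

#' Create an empty concept store
#'
#' @return An object of class `concept_store` holding empty concept, label,
#'   synonym, tree-set and hybrid tables.
#' @seealso [add_treeset()], [lookup_name()], [load_store()]
#' @export
concept_store <- function() {
  structure(list(
    concepts = data.frame(id = character(), kind = character(),
                          stringsAsFactors = FALSE),
    labels   = data.frame(concept = character(), name = character(),
                          rank = character(), stringsAsFactors = FALSE),
    synonyms = data.frame(name = character(), concept = character(),
                          name_type = character(), language = character(),
                          stringsAsFactors = FALSE),
    treesets = list(),
    hybrids  = data.frame(id = character(), components = character(),
                          stringsAsFactors = FALSE)
  ), class = "concept_store")
}

#' @export
print.concept_store <- function(x, ...) {
  cat("<concept_store> ", nrow(x$concepts), " concepts, ",
      length(x$treesets), " tree sets, ",
      nrow(x$synonyms), " synonym entries\n", sep = "")
  invisible(x)
}

#' Canonicalize a scientific name
#'
#' Collapses whitespace, capitalizes the genus and lower-cases all epithets.
#' Matching is exact after canonicalization; no fuzzy matching is applied.
#' The operation is idempotent.
#'
#' @param x character vector of names.
#' @return Character vector of canonical names.
#' @examples
#' canonicalize_name("  vireo   SOLITARIUS  ")  # "Vireo solitarius"
#' @export
canonicalize_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  vapply(x, function(nm) {
    if (!nzchar(nm)) return(nm)
    parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
    parts <- tolower(parts)
    substr(parts[1], 1, 1) <- toupper(substr(parts[1], 1, 1))
    paste(parts, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a fresh concept identifier
#'
#' Identifiers are 16-character uppercase hexadecimal strings. Draws come
#' from R's RNG so a fixed seed gives a reproducible identifier sequence;
#' with `source = "urandom"` bytes are read from the operating system's
#' entropy pool instead (for production registration, where reproducibility
#' is not wanted). A collision with an existing identifier triggers a
#' silent re-draw.
#'
#' @param store a `concept_store` (used only to avoid collisions).
#' @param source `"rng"` (seedable, default) or `"urandom"`.
#' @return A single identifier string matching `^[0-9A-F]{16}$`.
#' @export
new_concept_id <- function(store = concept_store(), source = c("rng", "urandom")) {
  source <- match.arg(source)
  hex <- c(0:9, LETTERS[1:6])
  repeat {
    id <- if (source == "rng") {
      paste(sample(hex, 16, replace = TRUE), collapse = "")
    } else {
      bytes <- readBin("/dev/urandom", "raw", n = 8)
      toupper(paste(format(bytes), collapse = ""))
    }
    if (!id %in% store$concepts$id) return(id)
  }
}

#' Register a concept identifier
#'
#' @param store a `concept_store`.
#' @param id identifier string (16 uppercase hex characters).
#' @param kind one of `"species"`, `"subspecies"`, `"group"`, `"other"`.
#' @return The updated store.
#' @export
add_concept <- function(store, id, kind) {
  stopifnot(inherits(store, "concept_store"))
  kind <- match.arg(kind, CONCEPT_KINDS)
  if (!grepl("^[0-9A-F]{16}$", id)) {
    stop("invalid concept id: ", id)
  }
  if (id %in% store$concepts$id) stop("duplicate concept id: ", id)
  store$concepts <- rbind(store$concepts,
                          data.frame(id = id, kind = kind,
                                     stringsAsFactors = FALSE))
  store
}

#' Attach a rank-tagged name label to a concept
#'
#' One concept may carry several labels (concept synonyms, or the same name
#' at two ranks for a monotypic species and its nominal subspecies); one
#' name may label several concepts (concept homonyms).
#'
#' @param store a `concept_store`.
#' @param id concept identifier already in the store.
#' @param name scientific name (canonicalized on entry).
#' @param rank rank the name is used at.
#' @return The updated store.
#' @export
add_label <- function(store, id, name, rank = c("species", "subspecies", "group", "other")) {
  rank <- match.arg(rank)
  if (!id %in% store$concepts$id) stop("unknown concept id: ", id)
  name <- canonicalize_name(name)
  hit <- store$labels$concept == id & store$labels$name == name &
    store$labels$rank == rank
  if (!any(hit)) {
    store$labels <- rbind(store$labels,
                          data.frame(concept = id, name = name, rank = rank,
                                     stringsAsFactors = FALSE))
  }
  store
}

#' Add a synonym entry (name to concept)
#'
#' @param store a `concept_store`.
#' @param name the name string (canonicalized if scientific).
#' @param id target concept identifier.
#' @param name_type `"scientific"` or `"vernacular"`.
#' @param language optional language tag for vernacular names.
#' @return The updated store.
#' @export
add_synonym <- function(store, name, id, name_type = c("scientific", "vernacular"),
                        language = NA_character_) {
  name_type <- match.arg(name_type)
  if (!id %in% store$concepts$id) stop("unknown concept id: ", id)
  if (name_type == "scientific") name <- canonicalize_name(name)
  hit <- store$synonyms$name == name & store$synonyms$concept == id
  if (!any(hit)) {
    store$synonyms <- rbind(store$synonyms,
                            data.frame(name = name, concept = id,
                                       name_type = name_type,
                                       language = language,
                                       stringsAsFactors = FALSE))
  }
  store
}

#' Register a hybrid concept
#'
#' Hybrids receive identifiers and links to their parental concepts but are
#' excluded from concept trees, weights and validation sums.
#'
#' @param store a `concept_store`.
#' @param id hybrid concept identifier (kind `"other"`, added if missing).
#' @param components character vector of two or more parental identifiers.
#' @return The updated store.
#' @export
add_hybrid <- function(store, id, components) {
  if (length(components) < 2) stop("a hybrid links at least two concepts")
  if (!all(components %in% store$concepts$id)) {
    stop("unknown parental concept id")
  }
  if (!id %in% store$concepts$id) store <- add_concept(store, id, "other")
  store$hybrids <- rbind(store$hybrids,
                         data.frame(id = id,
                                    components = paste(sort(components), collapse = ";"),
                                    stringsAsFactors = FALSE))
  store
}

# ---- tree variants -------------------------------------------------------

# A variant is a list with one field `edges`: a named list mapping a parent
# id to the character vector of its children.

variant_nodes <- function(variant) {
  unique(c(names(variant$edges), unlist(variant$edges, use.names = FALSE)))
}

variant_root <- function(variant) {
  parents <- names(variant$edges)
  children <- unlist(variant$edges, use.names = FALSE)
  root <- setdiff(parents, children)
  if (length(root) != 1) {
    stop("variant does not have a unique root (found ",
         length(root), ")")
  }
  root
}

variant_children <- function(variant, id) {
  if (is.null(variant$edges[[id]])) character() else variant$edges[[id]]
}

variant_leaves <- function(variant) {
  setdiff(variant_nodes(variant), names(variant$edges))
}

# Terminal descendants of `id` within one variant (self if terminal).
variant_leafset <- function(variant, id) {
  kids <- variant_children(variant, id)
  if (length(kids) == 0) return(id)
  out <- unlist(lapply(kids, variant_leafset, variant = variant),
                use.names = FALSE)
  sort(unique(out))
}

# Structural sanity of a single variant: unique root, no cycles, each child
# has one parent. Returns NULL or an error message.
variant_structure_error <- function(variant) {
  if (length(variant$edges) == 0) return(NULL) # single-node tree elsewhere
  children <- unlist(variant$edges, use.names = FALSE)
  if (anyDuplicated(children)) {
    return(paste0("node has multiple parents: ",
                  paste(unique(children[duplicated(children)]), collapse = ", ")))
  }
  parents <- names(variant$edges)
  root <- setdiff(parents, children)
  if (length(root) != 1) {
    return(paste0("expected one root, found ", length(root)))
  }
  # reachability: every node must descend from the root (no detached cycle)
  seen <- character()
  stack <- root
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    if (n %in% seen) return(paste0("cycle involving node ", n))
    seen <- c(seen, n)
    stack <- c(stack, variant_children(variant, n))
  }
  allnodes <- variant_nodes(variant)
  if (length(setdiff(allnodes, seen))) {
    return(paste0("nodes unreachable from root: ",
                  paste(setdiff(allnodes, seen), collapse = ", ")))
  }
  NULL
}

new_variant <- function(edges) {
  edges <- lapply(edges, function(x) sort(unique(as.character(x))))
  list(edges = edges)
}

new_treeset <- function(root, variants) {
  structure(list(root = root, variants = variants), class = "treeset")
}

#' Add a tree set to the store
#'
#' @param store a `concept_store`.
#' @param root root concept identifier.
#' @param variants list of variants, each a named list mapping parent id to
#'   a character vector of child ids. A single-node tree set is expressed
#'   as an empty edge list.
#' @return The updated store.
#' @export
add_treeset <- function(store, root, variants) {
  if (!root %in% store$concepts$id) stop("unknown root id: ", root)
  if (root %in% names(store$treesets)) stop("root already heads a tree set: ", root)
  vs <- lapply(variants, new_variant)
  ts <- new_treeset(root, vs)
  all_ids <- unique(unlist(lapply(vs, variant_nodes)))
  if (length(all_ids) == 0) all_ids <- root
  unknown <- setdiff(all_ids, store$concepts$id)
  if (length(unknown)) stop("tree references unknown ids: ",
                            paste(unknown, collapse = ", "))
  elsewhere <- intersect(all_ids, unlist(lapply(store$treesets, treeset_nodes)))
  if (length(elsewhere)) stop("ids already belong to another tree set: ",
                              paste(elsewhere, collapse = ", "))
  store$treesets[[root]] <- ts
  store
}

treeset_nodes <- function(treeset) {
  out <- unique(c(treeset$root,
                  unlist(lapply(treeset$variants, variant_nodes))))
  out
}

# Name of the treeset containing `id`, or NA.
treeset_of <- function(store, id) {
  for (root in names(store$treesets)) {
    if (id %in% treeset_nodes(store$treesets[[root]])) return(root)
  }
  NA_character_
}

#' Terminal descendants of a concept within its tree set
#'
#' The leaf set is the set of terminal identifiers descended from `id`
#' (the singleton of `id` itself if it is terminal). Because shared nodes
#' carry the same leaf set in every alternate variant, the answer does not
#' depend on which variant the node is read from.
#'
#' @param id a concept identifier occurring in `treeset`.
#' @param treeset a tree set, or a `concept_store` (the tree set containing
#'   `id` is located automatically).
#' @return Sorted character vector of terminal identifiers.
#' @export
leaf_set <- function(id, treeset) {
  if (inherits(treeset, "concept_store")) {
    root <- treeset_of(treeset, id)
    if (is.na(root)) stop("unknown node: ", id, " (not in any tree set)")
    treeset <- treeset$treesets[[root]]
  }
  if (id == treeset$root && length(treeset$variants) == 0) return(id)
  for (v in treeset$variants) {
    if (id %in% variant_nodes(v)) return(variant_leafset(v, id))
  }
  if (id == treeset$root) return(id)
  stop("unknown node: ", id, " (not in any variant of the tree set)")
}

#' Look up every concept a name may refer to
#'
#' Returns the union of identifiers from synonym entries and from concept
#' labels matching the canonical form of `name`. One name can denote
#' several distinct circumscriptions (concept homonyms); the empty set is a
#' valid answer for an unknown name.
#'
#' @param name a name string.
#' @param store a `concept_store`.
#' @return Sorted character vector of concept identifiers (possibly empty).
#' @export
lookup_name <- function(name, store) {
  cname <- canonicalize_name(name)
  ids <- c(store$labels$concept[store$labels$name == cname],
           store$synonyms$concept[store$synonyms$name == cname |
                                    (store$synonyms$name_type == "vernacular" &
                                       store$synonyms$name == trimws(gsub("\\s+", " ", name)))])
  sort(unique(ids))
}

# All current labels of a concept (rank-filtered if requested).
labels_of <- function(store, id, rank = NULL) {
  sel <- store$labels$concept == id
  if (!is.null(rank)) sel <- sel & store$labels$rank %in% rank
  store$labels$name[sel]
}

# Find a node in a treeset whose leaf set equals `leaves` (sorted), or NA.
find_node_by_leafset <- function(treeset, leaves) {
  leaves <- sort(unique(leaves))
  for (v in treeset$variants) {
    for (n in variant_nodes(v)) {
      if (identical(variant_leafset(v, n), leaves)) return(n)
    }
  }
  if (length(treeset$variants) == 0 && identical(leaves, treeset$root)) {
    return(treeset$root)
  }
  NA_character_
}
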