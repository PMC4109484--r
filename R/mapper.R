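# Mapping a checklist's names onto concept identifiers.
#
# Resolution proceeds in two stages. First every record's name is looked up
# in the label and synonym tables, yielding a candidate identifier set
# (concept homonyms give several candidates; an unknown name gives none).
# Second, a combinatorial solver searches, independently per tree set, for
# assignments of one candidate per record such that
#   - species-level fractional weights sum to exactly 1 (the scope total)
#     in at least one variant,
#   - subspecies weights sum to their species' weight (same variant),
#   - no identifier is used twice (monotypic nominal alias excepted),
#   - no two same-rank records sit on one ancestor-descendant branch,
#   - checklist parent links mirror tree ancestry.
# Exactly one surviving combination means the records are mapped; several
# mean the checklist does not carry enough information and the records are
# reported ambiguous (never guessed); none means a conflict - either a new
# concept or a mis-built tree, which is a curation question. The search is
# decomposed per root tree set, which is what keeps it tractable; a
# configurable combination cap guards pathological homonymy.

ABSENT <- ".absent."

#' Resolve name candidates for every checklist record
#'
#' @param checklist a `checklist`.
#' @param store a `concept_store`.
#' @param overrides optional named character vector `taxon_id -> concept`
#'   of curator-forced assignments; forced records get a single candidate.
#' @return Named list mapping `taxon_id` to a character vector of candidate
#'   concept identifiers (possibly empty).
#' @export
resolve_candidates <- function(checklist, store, overrides = NULL) {
  recs <- checklist$records
  out <- stats::setNames(vector("list", nrow(recs)), recs$taxon_id)
  for (i in seq_len(nrow(recs))) {
    tid <- recs$taxon_id[i]
    if (!is.null(overrides) && tid %in% names(overrides)) {
      out[[tid]] <- unname(overrides[[tid]])
      next
    }
    cands <- lookup_name(recs$scientific_name[i], store)
    if (length(cands) == 0 && !is.na(recs$vernacular[i]) &&
        nzchar(recs$vernacular[i])) {
      cands <- lookup_name(recs$vernacular[i], store)
    }
    out[[tid]] <- cands
  }
  out
}

# Leaf-set cache for one tree set.
leafset_cache <- function(treeset) {
  nodes <- treeset_nodes(treeset)
  stats::setNames(lapply(nodes, leaf_set, treeset = treeset), nodes)
}

contains_strict <- function(cache, a, b) {
  la <- cache[[a]]; lb <- cache[[b]]
  length(la) > length(lb) && all(lb %in% la)
}

on_same_branch <- function(cache, a, b) {
  if (a == b) return(TRUE)
  contains_strict(cache, a, b) || contains_strict(cache, b, a)
}

# Weights for each variant of a treeset, scoped if needed. Returns a list
# of concept_weights or NULL for variants entirely out of scope.
variant_weights <- function(treeset, scope = NULL) {
  vs <- if (length(treeset$variants)) treeset$variants else list(new_variant(list()))
  lapply(vs, function(v) {
    if (is.null(scope)) {
      compute_weights(v, root = treeset$root)
    } else {
      leaves <- if (length(v$edges)) variant_leaves(v) else treeset$root
      keep <- intersect(leaves, scope)
      if (length(keep) == 0) return(NULL)
      scoped_weights(v, keep, root = treeset$root)
    }
  })
}

# Solve one tree set: enumerate assignments of in-tree records.
# recs: checklist records restricted to this tree (species/other first,
# subspecies last); options: named list taxon_id -> candidate ids in tree,
# with ABSENT appended when the record may be mapped elsewhere.
solve_one_tree <- function(treeset, recs, options, store, scope, cap) {
  n_comb <- prod(vapply(options, length, numeric(1)))
  if (n_comb > cap) {
    stop("combinatorial budget exceeded for tree ", treeset$root,
         " (", format(n_comb, scientific = TRUE), " > ", cap, " combinations)")
  }
  cache <- leafset_cache(treeset)
  wts <- variant_weights(treeset, scope)
  parent_of <- stats::setNames(recs$parent_taxon_id, recs$taxon_id)
  rank_of <- stats::setNames(recs$rank, recs$taxon_id)
  ord <- order(match(recs$rank, c("species", "other", "subspecies")))
  tids <- recs$taxon_id[ord]
  solutions <- list()
  seen <- character()

  check_full <- function(assign) {
    active <- assign[assign != ABSENT]
    if (length(active) == 0) {
      return(list(assign = active, variant = NA_integer_))
    }
    sp <- active[rank_of[names(active)] == "species"]
    for (vi in seq_along(wts)) {
      w <- wts[[vi]]
      if (is.null(w)) next
      if (!all(active %in% w$concept)) next
      if (length(sp)) {
        if (!isTRUE(arrangement_sum(unname(sp), weights = w) == rational(1))) next
      }
      # rule 3: subspecies sums equal their species' weight
      ok <- TRUE
      for (sp_tid in names(sp)) {
        kids <- names(active)[rank_of[names(active)] == "subspecies" &
                                !is.na(parent_of[names(active)]) &
                                parent_of[names(active)] == sp_tid]
        if (length(kids) == 0) next
        s <- arrangement_sum(unname(active[kids]), weights = w)
        if (!isTRUE(s == weight_of(w, active[[sp_tid]]))) { ok <- FALSE; break }
      }
      if (!ok) next
      return(list(assign = active, variant = vi))
    }
    NULL
  }

  recurse <- function(i, assign) {
    if (i > length(tids)) {
      sol <- check_full(assign)
      if (!is.null(sol)) {
        sig <- paste(names(sol$assign), sol$assign, sep = "=", collapse = ";")
        if (!sig %in% seen) {
          seen <<- c(seen, sig)
          solutions[[length(solutions) + 1]] <<- sol
        }
      }
      return(invisible())
    }
    tid <- tids[[i]]
    for (cand in options[[tid]]) {
      if (cand != ABSENT) {
        # rule 4: duplicate id, unless monotypic nominal alias
        dup <- names(assign)[assign == cand]
        ok <- TRUE
        for (d in dup) {
          alias <- (rank_of[[tid]] == "subspecies" && rank_of[[d]] == "species" &&
                      !is.na(parent_of[[tid]]) && parent_of[[tid]] == d) ||
                   (rank_of[[tid]] == "species" && rank_of[[d]] == "subspecies" &&
                      !is.na(parent_of[[d]]) && parent_of[[d]] == tid)
          if (!alias) { ok <- FALSE; break }
        }
        if (!ok) next
        # rule 5: same-rank records must not share a branch
        same_rank <- names(assign)[rank_of[names(assign)] == rank_of[[tid]] &
                                     assign != ABSENT]
        conflict <- FALSE
        for (o in same_rank) {
          if (assign[[o]] != cand && on_same_branch(cache, assign[[o]], cand)) {
            conflict <- TRUE; break
          }
        }
        if (conflict) next
        # rule 6: a subspecies must descend from its species' concept
        if (rank_of[[tid]] == "subspecies") {
          p <- parent_of[[tid]]
          if (!is.na(p) && p %in% names(assign)) {
            pc <- assign[[p]]
            if (pc == ABSENT) next
            if (!(pc == cand || contains_strict(cache, pc, cand))) next
          } else if (!is.na(p) && !p %in% tids) {
            # parent record cannot live in this tree: orphan subspecies
            next
          }
        }
      } else {
        # a subspecies cannot stay while its species leaves, nor vice versa:
        # enforced implicitly by rule 6 above and by the exactly-once
        # combination step across trees
      }
      recurse(i + 1, c(assign, stats::setNames(cand, tid)))
    }
  }

  recurse(1, stats::setNames(character(0), character(0)))
  solutions
}

# Internal solver shared by solve_assignment() and validate_mapping().
solve_internal <- function(checklist, candidates, store, scope = NULL,
                           cap = 1e6) {
  recs <- checklist$records
  if (is.null(scope) && !identical(checklist$scope, "global")) {
    scope <- checklist$scope
  }
  tree_of_cand <- function(ids) {
    vapply(ids, function(id) treeset_of(store, id), character(1))
  }
  rec_trees <- lapply(recs$taxon_id, function(tid) {
    cands <- candidates[[tid]]
    if (is.null(cands) || length(cands) == 0) return(character())
    unique(stats::na.omit(tree_of_cand(cands)))
  })
  names(rec_trees) <- recs$taxon_id

  all_roots <- sort(unique(unlist(rec_trees)))
  # drop trees entirely outside the declared scope
  if (!is.null(scope)) {
    in_scope <- vapply(all_roots, function(r) {
      length(intersect(unlist(leafset_cache(store$treesets[[r]])[[r]]), scope)) > 0
    }, logical(1))
    all_roots <- all_roots[in_scope]
  }

  # cluster trees connected through records with candidates in several trees
  cluster_id <- stats::setNames(seq_along(all_roots), all_roots)
  for (tid in names(rec_trees)) {
    ts <- intersect(rec_trees[[tid]], all_roots)
    if (length(ts) > 1) {
      tgt <- min(cluster_id[ts])
      cluster_id[names(cluster_id) %in% ts | cluster_id %in% cluster_id[ts]] <- tgt
    }
  }
  clusters <- split(names(cluster_id), cluster_id)

  tree_solutions <- list()
  for (root in all_roots) {
    ts <- store$treesets[[root]]
    nodes <- treeset_nodes(ts)
    in_tree <- vapply(recs$taxon_id, function(tid) {
      any(candidates[[tid]] %in% nodes)
    }, logical(1))
    sub <- recs[in_tree, , drop = FALSE]
    opts <- lapply(sub$taxon_id, function(tid) {
      here <- intersect(candidates[[tid]], nodes)
      elsewhere <- length(setdiff(
        intersect(candidates[[tid]],
                  unlist(lapply(all_roots, function(r)
                    treeset_nodes(store$treesets[[r]])))), nodes)) > 0
      c(here, if (elsewhere) ABSENT)
    })
    names(opts) <- sub$taxon_id
    tree_solutions[[root]] <-
      solve_one_tree(ts, sub, opts, store, scope, cap)
  }

  # combine per cluster with the exactly-once constraint
  cluster_out <- list()
  for (ci in seq_along(clusters)) {
    roots <- clusters[[ci]]
    members <- recs$taxon_id[vapply(recs$taxon_id, function(tid) {
      length(intersect(rec_trees[[tid]], roots)) > 0
    }, logical(1))]
    combos <- list(list())
    for (root in roots) {
      sols <- tree_solutions[[root]]
      if (length(sols) == 0) { combos <- list(); break }
      nxt <- list()
      for (cmb in combos) {
        for (s in sols) {
          cmb2 <- cmb
          cmb2[[root]] <- s
          nxt[[length(nxt) + 1]] <- cmb2
        }
      }
      combos <- nxt
      if (length(combos) > cap) {
        stop("combinatorial budget exceeded while combining tree sets (",
             length(combos), " > ", cap, ")")
      }
    }
    valid <- list()
    for (cmb in combos) {
      counts <- table(unlist(lapply(cmb, function(s) names(s$assign))))
      assigned <- names(counts)
      if (any(counts > 1)) next
      if (!all(members %in% assigned)) next
      valid[[length(valid) + 1]] <- cmb
    }
    cluster_out[[ci]] <- list(roots = roots, members = members,
                              solutions = valid)
  }
  list(clusters = cluster_out, rec_trees = rec_trees)
}

#' Map checklist records to concept identifiers
#'
#' Searches for assignments of candidate identifiers to records whose
#' fractional weights form complete arrangements without breaking the
#' descendant rules (see the package vignette). One surviving combination
#' yields status `mapped`; several yield `ambiguous` for every record whose
#' assignment differs between solutions; none yields `conflict`. Records
#' whose name is unknown, or whose candidates lie outside every tree, are
#' `unmapped_new`.
#'
#' @param checklist a `checklist`.
#' @param candidates output of [resolve_candidates()]; computed if `NULL`.
#' @param store a `concept_store`.
#' @param scope optional character vector of in-scope leaf identifiers,
#'   overriding the checklist's own scope declaration.
#' @param overrides optional named vector `taxon_id -> concept` of forced
#'   assignments (curator input for cases the data cannot decide).
#' @param cap maximum number of combinations examined per tree set.
#' @return A `mapping_result` data frame with one row per record: columns
#'   `taxon_id`, `scientific_name`, `rank`, `status` (`mapped`,
#'   `ambiguous`, `unmapped_new`, `conflict`), `concept`, `candidates`
#'   (semicolon-joined), `variant` (variant index within the record's tree
#'   set). The full per-cluster solution lists are attached as attribute
#'   `"solutions"`.
#' @export
solve_assignment <- function(checklist, candidates = NULL, store,
                             scope = NULL, overrides = NULL, cap = 1e6) {
  if (is.null(candidates)) {
    candidates <- resolve_candidates(checklist, store, overrides = overrides)
  } else if (!is.null(overrides)) {
    for (tid in names(overrides)) candidates[[tid]] <- unname(overrides[[tid]])
  }
  recs <- checklist$records
  sol <- solve_internal(checklist, candidates, store, scope = scope, cap = cap)

  status <- stats::setNames(rep("unmapped_new", nrow(recs)), recs$taxon_id)
  concept <- stats::setNames(rep(NA_character_, nrow(recs)), recs$taxon_id)
  cand_col <- stats::setNames(rep(NA_character_, nrow(recs)), recs$taxon_id)
  variant <- stats::setNames(rep(NA_integer_, nrow(recs)), recs$taxon_id)

  for (tid in recs$taxon_id) {
    cands <- candidates[[tid]]
    if (length(cands)) cand_col[[tid]] <- paste(sort(unique(cands)), collapse = ";")
  }

  for (cl in sol$clusters) {
    if (length(cl$solutions) == 0) {
      status[cl$members] <- "conflict"
      next
    }
    for (tid in cl$members) {
      hits <- lapply(cl$solutions, function(cmb) {
        for (root in names(cmb)) {
          s <- cmb[[root]]
          if (tid %in% names(s$assign)) {
            return(list(concept = s$assign[[tid]], variant = s$variant))
          }
        }
        NULL
      })
      ids <- vapply(hits, function(h) h$concept, character(1))
      if (length(unique(ids)) == 1) {
        status[[tid]] <- "mapped"
        concept[[tid]] <- ids[[1]]
        variant[[tid]] <- hits[[1]]$variant
      } else {
        status[[tid]] <- "ambiguous"
        cand_col[[tid]] <- paste(sort(unique(ids)), collapse = ";")
      }
    }
  }

  out <- data.frame(
    taxon_id = recs$taxon_id,
    scientific_name = recs$scientific_name,
    rank = recs$rank,
    status = unname(status[recs$taxon_id]),
    concept = unname(concept[recs$taxon_id]),
    candidates = unname(cand_col[recs$taxon_id]),
    variant = unname(variant[recs$taxon_id]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mapping_result", "data.frame")
  attr(out, "solutions") <- sol$clusters
  out
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("<mapping_result> ", nrow(x), " records: ",
      paste(names(table(x$status)), table(x$status), sep = "=", collapse = ", "),
      "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Enumerate all valid complete arrangements of a tree set
#'
#' A valid arrangement at a given rank is a set of rank-usable nodes, with
#' no ancestor-descendant pair, whose weights sum to exactly 1 in at least
#' one variant - equivalently, a full cut through some variant using only
#' nodes usable at that rank. Arrangements are deduplicated across variants
#' (the same combination may be realizable in several trees) and returned
#' in a deterministic order.
#'
#' @param treeset a tree set from a `concept_store`.
#' @param store the `concept_store` (for concept kinds and rank labels).
#' @param rank `"species"` or `"subspecies"`.
#' @return A list of character vectors of concept identifiers.
#' @export
enumerate_valid_arrangements <- function(treeset, store, rank = "species") {
  usable <- function(id) {
    kind <- store$concepts$kind[store$concepts$id == id]
    (length(kind) && kind == rank) || length(labels_of(store, id, rank = rank)) > 0
  }
  vs <- if (length(treeset$variants)) treeset$variants else list(new_variant(list()))
  out <- list()
  seen <- character()
  for (v in vs) {
    cuts <- function(node) {
      res <- list()
      if (usable(node)) res <- list(node)
      kids <- variant_children(v, node)
      if (length(kids)) {
        parts <- lapply(kids, cuts)
        if (all(vapply(parts, length, integer(1)) > 0)) {
          combos <- list(character(0))
          for (p in parts) {
            combos <- unlist(lapply(combos, function(cmb) {
              lapply(p, function(x) c(cmb, x))
            }), recursive = FALSE)
          }
          res <- c(res, combos)
        }
      }
      res
    }
    for (arr in cuts(treeset$root)) {
      arr <- sort(unique(arr))
      sig <- paste(arr, collapse = ";")
      if (!sig %in% seen) {
        seen <- c(seen, sig)
        out[[length(out) + 1]] <- arr
      }
    }
  }
  out[order(vapply(out, length, integer(1)),
            vapply(out, paste, character(1), collapse = ";"))]
}

#' Diff two checklist versions
#'
#' Classifies every record of the new version against a fully mapped older
#' version: `unchanged` (same canonical name, same rank), `renamed` (a new
#' name - genus transfer or gender emendation - resolving to the concept of
#' exactly one disappeared old record of the same rank), `added`, or
#' `removed` (old records with no counterpart). Rename detection relies on
#' the synonym table, mirroring how revisions are matched before the
#' solver runs.
#'
#' @param old a `checklist` (the mapped version).
#' @param old_mapping its `mapping_result` (all relevant records mapped).
#' @param new a `checklist` (the incoming version).
#' @param store a `concept_store`.
#' @return A data frame with columns `change`, `taxon_id_old`,
#'   `taxon_id_new`, `name_old`, `name_new`, `concept` (the old concept for
#'   unchanged/renamed/removed rows, NA otherwise).
#' @export
diff_checklists <- function(old, old_mapping, new, store) {
  om <- as.data.frame(old_mapping)
  old_concept <- stats::setNames(om$concept, om$taxon_id)
  o <- old$records
  n <- new$records
  okey <- paste(o$canonical_name, o$rank)
  nkey <- paste(n$canonical_name, n$rank)
  rows <- list()
  matched_old <- logical(nrow(o))
  matched_new <- logical(nrow(n))
  for (i in seq_len(nrow(n))) {
    j <- which(okey == nkey[i] & !matched_old)
    if (length(j)) {
      j <- j[1]
      matched_old[j] <- TRUE
      matched_new[i] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        change = "unchanged", taxon_id_old = o$taxon_id[j],
        taxon_id_new = n$taxon_id[i], name_old = o$scientific_name[j],
        name_new = n$scientific_name[i],
        concept = unname(old_concept[o$taxon_id[j]]),
        stringsAsFactors = FALSE)
    }
  }
  # rename detection among the leftovers
  for (i in which(!matched_new)) {
    cands <- lookup_name(n$scientific_name[i], store)
    j <- which(!matched_old & o$rank == n$rank[i] &
                 old_concept[o$taxon_id] %in% cands)
    if (length(j) == 1) {
      matched_old[j] <- TRUE
      matched_new[i] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        change = "renamed", taxon_id_old = o$taxon_id[j],
        taxon_id_new = n$taxon_id[i], name_old = o$scientific_name[j],
        name_new = n$scientific_name[i],
        concept = unname(old_concept[o$taxon_id[j]]),
        stringsAsFactors = FALSE)
    }
  }
  for (i in which(!matched_new)) {
    rows[[length(rows) + 1]] <- data.frame(
      change = "added", taxon_id_old = NA_character_,
      taxon_id_new = n$taxon_id[i], name_old = NA_character_,
      name_new = n$scientific_name[i], concept = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (j in which(!matched_old)) {
    rows[[length(rows) + 1]] <- data.frame(
      change = "removed", taxon_id_old = o$taxon_id[j],
      taxon_id_new = NA_character_, name_old = o$scientific_name[j],
      name_new = NA_character_, concept = unname(old_concept[o$taxon_id[j]]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(change = character(), taxon_id_old = character(),
                      taxon_id_new = character(), name_old = character(),
                      name_new = character(), concept = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(match(out$change, c("unchanged", "renamed", "added", "removed")),
            out$taxon_id_new, out$taxon_id_old), , drop = FALSE]
}
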