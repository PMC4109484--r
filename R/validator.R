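# Rule-numbered validation of tree sets and checklist-to-concept mappings.
#
# The seven rules, numbered as reported:
#   1 species-level weights sum to exactly 1 in at least one variant and
#     never exceed 1 in any variant
#   2 only a single assignment of names to identifiers attains the total
#   3 subspecies weights sum to their species' weight
#   4 one concept identifier per checklist (monotypic nominal alias exempt)
#   5 no two same-rank concepts along one ancestor-descendant branch
#   6 checklist parent links mirror tree ancestry
#   7 alternate trees share root and terminal nodes; shared intermediate
#     nodes keep the same terminal children in every variant
#
# Findings are advisory: they flag either a mis-mapped checklist or a
# mis-built tree, and resolving them is a curation decision. Nothing here
# throws on bad data; malformed structures become report entries.

vreport_row <- function(rule, subjects, message) {
  data.frame(rule = as.integer(rule),
             subjects = paste(sort(unique(subjects)), collapse = ";"),
             message = message, stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(rule = integer(), subjects = character(), message = character(),
             stringsAsFactors = FALSE)
}

finish_report <- function(rows) {
  if (length(rows) == 0) {
    rep <- empty_report()
  } else {
    rep <- do.call(rbind, rows)
    rep <- rep[order(rep$rule, rep$subjects, rep$message), , drop = FALSE]
    rownames(rep) <- NULL
  }
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation_report> no violations\n")
  } else {
    cat("<validation_report> ", nrow(x), " violation(s)\n", sep = "")
    print.data.frame(as.data.frame(x))
  }
  invisible(x)
}

#' Validate the structure of a tree set
#'
#' Checks the alternate-tree constraints (rule 7) and basic structure:
#' every variant is a single rooted tree headed by the declared root, all
#' variants share one terminal node set, shared intermediate nodes carry
#' identical leaf sets in every variant, and no internal node has a single
#' child. A single-variant tree set is vacuously consistent across
#' variants.
#'
#' @param treeset a tree set (from `store$treesets`).
#' @return A `validation_report` data frame; empty when the tree set is
#'   sound.
#' @export
validate_treeset <- function(treeset) {
  rows <- list()
  vs <- treeset$variants
  if (length(vs) == 0) return(finish_report(rows))
  ok_struct <- logical(length(vs))
  for (i in seq_along(vs)) {
    err <- variant_structure_error(vs[[i]])
    if (!is.null(err)) {
      rows[[length(rows) + 1]] <- vreport_row(7, treeset$root,
        paste0("variant ", i, ": ", err))
      next
    }
    ok_struct[i] <- TRUE
    if (length(vs[[i]]$edges)) {
      r <- variant_root(vs[[i]])
      if (!identical(r, treeset$root)) {
        rows[[length(rows) + 1]] <- vreport_row(7, c(treeset$root, r),
          paste0("variant ", i, " is rooted at ", r,
                 " instead of the shared root"))
        ok_struct[i] <- FALSE
      }
      singles <- names(vs[[i]]$edges)[
        vapply(vs[[i]]$edges, length, integer(1)) == 1]
      for (s in singles) {
        rows[[length(rows) + 1]] <- vreport_row(7, s,
          paste0("variant ", i, ": internal node ", s,
                 " has a single child (congruent concepts must share one id)"))
      }
    }
  }
  good <- which(ok_struct)
  if (length(good) >= 2) {
    ref <- good[1]
    ref_leaves <- variant_leaves(vs[[ref]])
    for (i in good[-1]) {
      lv <- variant_leaves(vs[[i]])
      if (!setequal(lv, ref_leaves)) {
        rows[[length(rows) + 1]] <- vreport_row(7, treeset$root,
          paste0("variants ", ref, " and ", i,
                 " do not share the same terminal nodes"))
      }
    }
    # shared intermediate nodes must keep the same leaf set everywhere
    all_nodes <- unique(unlist(lapply(vs[good], variant_nodes)))
    for (n in all_nodes) {
      sets <- list()
      for (i in good) {
        if (n %in% variant_nodes(vs[[i]])) {
          sets[[length(sets) + 1]] <- variant_leafset(vs[[i]], n)
        }
      }
      if (length(sets) > 1) {
        for (k in seq_along(sets)[-1]) {
          if (!identical(sets[[k]], sets[[1]])) {
            rows[[length(rows) + 1]] <- vreport_row(7, n,
              paste0("node ", n, " has different leaf sets in different variants"))
            break
          }
        }
      }
    }
  }
  finish_report(rows)
}

#' Validate every tree set in a store
#'
#' @param store a `concept_store`.
#' @return A combined `validation_report`.
#' @export
validate_store <- function(store) {
  flat <- do.call(rbind, c(list(empty_report()),
                           lapply(unname(store$treesets), validate_treeset)))
  finish_report(if (nrow(flat) == 0) list() else
    split(as.data.frame(flat), seq_len(nrow(flat))))
}

#' Validate a checklist-to-concept mapping against the rules
#'
#' Applies rules 1-6 to the mapped records of a checklist. Sum rules (1-3)
#' and the uniqueness rule (2) are evaluated per tree set and only where
#' every record touching the tree is mapped (a tree with ambiguous or
#' conflicting records cannot be expected to sum); duplicate, branch and
#' ancestry rules (4-6) always apply. Records of rank `other` are exempt
#' from the sum rules but subject to rules 4-6.
#'
#' @param checklist a `checklist`.
#' @param mapping a `mapping_result` (or a data frame with `taxon_id`,
#'   `status`, `concept`).
#' @param store a `concept_store`.
#' @param scope optional in-scope leaf identifiers overriding the
#'   checklist's own scope.
#' @param cap combination cap for the uniqueness re-check.
#' @return A `validation_report`; empty iff the mapping satisfies all
#'   applicable rules.
#' @export
validate_mapping <- function(checklist, mapping, store, scope = NULL,
                             cap = 1e6) {
  rows <- list()
  recs <- checklist$records
  m <- as.data.frame(mapping)
  m <- m[match(recs$taxon_id, m$taxon_id), , drop = FALSE]
  mapped <- !is.na(m$status) & m$status == "mapped" & !is.na(m$concept)
  unknown <- setdiff(m$concept[mapped], store$concepts$id)
  if (length(unknown)) {
    stop("mapping references unknown concept ids: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(scope) && !identical(checklist$scope, "global")) {
    scope <- checklist$scope
  }
  concept_of <- stats::setNames(m$concept, m$taxon_id)
  rank_of <- stats::setNames(recs$rank, recs$taxon_id)
  parent_of <- stats::setNames(recs$parent_taxon_id, recs$taxon_id)

  is_alias_pair <- function(t1, t2) {
    (rank_of[[t1]] == "species" && rank_of[[t2]] == "subspecies" &&
       !is.na(parent_of[[t2]]) && parent_of[[t2]] == t1) ||
    (rank_of[[t2]] == "species" && rank_of[[t1]] == "subspecies" &&
       !is.na(parent_of[[t1]]) && parent_of[[t1]] == t2)
  }

  # ---- rule 4: one concept per checklist -------------------------------
  tids_mapped <- recs$taxon_id[mapped]
  by_concept <- split(tids_mapped, concept_of[tids_mapped])
  for (cid in names(by_concept)) {
    grp <- by_concept[[cid]]
    if (length(grp) < 2) next
    alias_ok <- length(grp) == 2 && is_alias_pair(grp[1], grp[2])
    if (!alias_ok) {
      rows[[length(rows) + 1]] <- vreport_row(4, c(grp, cid),
        paste0("concept ", cid, " is mapped by ", length(grp),
               " records (only a monotypic nominal alias pair may share an id)"))
    }
  }

  # ---- group mapped records by tree set --------------------------------
  roots <- vapply(tids_mapped, function(tid) treeset_of(store, concept_of[[tid]]),
                  character(1))
  caches <- list()
  get_cache <- function(root) {
    if (is.null(caches[[root]])) {
      caches[[root]] <<- leafset_cache(store$treesets[[root]])
    }
    caches[[root]]
  }

  # ---- rule 5: same rank, same branch ----------------------------------
  for (root in unique(stats::na.omit(roots))) {
    members <- tids_mapped[!is.na(roots) & roots == root]
    cache <- get_cache(root)
    for (rk in unique(rank_of[members])) {
      grp <- members[rank_of[members] == rk]
      if (length(grp) < 2) next
      for (i in seq_along(grp)[-length(grp)]) {
        for (j in seq((i + 1), length(grp))) {
          a <- concept_of[[grp[i]]]; b <- concept_of[[grp[j]]]
          if (a != b && on_same_branch(cache, a, b)) {
            rows[[length(rows) + 1]] <- vreport_row(5, c(grp[i], grp[j]),
              paste0("records ", grp[i], " and ", grp[j], " (rank ", rk,
                     ") map to concepts on the same branch"))
          }
        }
      }
    }
  }

  # ---- rule 6: parent links mirror ancestry ----------------------------
  for (tid in tids_mapped) {
    if (rank_of[[tid]] != "subspecies") next
    p <- parent_of[[tid]]
    if (is.na(p) || !p %in% tids_mapped) next
    pc <- concept_of[[p]]; cc <- concept_of[[tid]]
    root <- treeset_of(store, cc)
    ok <- FALSE
    if (!is.na(root) && identical(treeset_of(store, pc), root)) {
      cache <- get_cache(root)
      ok <- pc == cc || contains_strict(cache, pc, cc)
    }
    if (!ok) {
      rows[[length(rows) + 1]] <- vreport_row(6, c(tid, p),
        paste0("subspecies record ", tid, " does not descend from the concept",
               " of its species record ", p))
    }
  }

  # ---- rules 1 and 3 per fully mapped tree -----------------------------
  candidates <- resolve_candidates(checklist, store)
  tree_clean <- function(root) {
    nodes <- treeset_nodes(store$treesets[[root]])
    touching <- recs$taxon_id[vapply(recs$taxon_id, function(tid) {
      any(candidates[[tid]] %in% nodes)
    }, logical(1))]
    all(mapped[match(touching, recs$taxon_id)])
  }

  clean_roots <- character()
  for (root in unique(stats::na.omit(roots))) {
    if (!tree_clean(root)) next
    clean_roots <- c(clean_roots, root)
    members <- tids_mapped[!is.na(roots) & roots == root]
    sp <- members[rank_of[members] == "species"]
    wts <- variant_weights(store$treesets[[root]], scope)
    sp_ids <- unname(concept_of[sp])
    applicable <- integer()
    equal_in <- integer()
    for (vi in seq_along(wts)) {
      w <- wts[[vi]]
      if (is.null(w) || !all(sp_ids %in% w$concept)) next
      applicable <- c(applicable, vi)
      s <- arrangement_sum(sp_ids, weights = w)
      if (isTRUE(s == rational(1))) equal_in <- c(equal_in, vi)
      if (isTRUE(s > rational(1))) {
        rows[[length(rows) + 1]] <- vreport_row(1, sp,
          paste0("species weights sum to ", format(s), " > 1 in variant ", vi,
                 " of tree ", root))
      }
    }
    if (length(sp) && length(equal_in) == 0) {
      rows[[length(rows) + 1]] <- vreport_row(1, sp,
        paste0("species weights do not sum to 1 in any variant of tree ", root))
    }
    # rule 3 in the variants where the species level balances
    check_vs <- if (length(equal_in)) equal_in else applicable
    for (sp_tid in sp) {
      kids <- members[rank_of[members] == "subspecies" &
                        !is.na(parent_of[members]) & parent_of[members] == sp_tid]
      if (length(kids) == 0) next
      ok <- FALSE
      for (vi in check_vs) {
        w <- wts[[vi]]
        if (is.null(w)) next
        ids <- unname(concept_of[c(sp_tid, kids)])
        if (!all(ids %in% w$concept)) next
        s <- arrangement_sum(unname(concept_of[kids]), weights = w)
        if (isTRUE(s == weight_of(w, concept_of[[sp_tid]]))) { ok <- TRUE; break }
      }
      if (!ok) {
        rows[[length(rows) + 1]] <- vreport_row(3, c(sp_tid, kids),
          paste0("subspecies weights of record ", sp_tid,
                 " do not sum to the species weight in tree ", root))
      }
    }
  }

  # ---- rule 2: uniqueness of the attaining combination -----------------
  if (length(clean_roots)) {
    sol <- tryCatch(
      solve_internal(checklist, candidates, store, scope = scope, cap = cap),
      error = function(e) NULL
    )
    if (!is.null(sol)) {
      for (cl in sol$clusters) {
        if (!all(cl$roots %in% clean_roots)) next
        if (length(cl$solutions) > 1) {
          rows[[length(rows) + 1]] <- vreport_row(2, cl$members,
            paste0(length(cl$solutions),
                   " distinct assignments attain the weight total for tree(s) ",
                   paste(cl$roots, collapse = ", ")))
        }
      }
    }
  }

  finish_report(rows)
}
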