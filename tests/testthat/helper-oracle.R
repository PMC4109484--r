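# Brute-force oracle for the assignment search: enumerates the full
# cartesian product of candidate choices (no decomposition, no pruning)
# and keeps assignments that satisfy the arrangement rules, checked
# directly from leaf sets and freshly computed weights. Only suitable for
# tiny inputs; used to cross-check solve_assignment().

oracle_leafset <- function(store, id) leaf_set(id, store)

oracle_valid <- function(assign, recs, store) {
  tids <- names(assign)
  rank_of <- stats::setNames(recs$rank, recs$taxon_id)
  parent_of <- stats::setNames(recs$parent_taxon_id, recs$taxon_id)
  roots <- vapply(assign, function(c) treeset_of(store, c), character(1))
  if (anyNA(roots)) return(FALSE)
  # rule 4
  dup <- split(tids, unname(assign))
  for (grp in dup) {
    if (length(grp) == 1) next
    if (length(grp) > 2) return(FALSE)
    alias <- (rank_of[[grp[1]]] == "species" && rank_of[[grp[2]]] == "subspecies" &&
                identical(parent_of[[grp[2]]], grp[1])) ||
             (rank_of[[grp[2]]] == "species" && rank_of[[grp[1]]] == "subspecies" &&
                identical(parent_of[[grp[1]]], grp[2]))
    if (!alias) return(FALSE)
  }
  for (root in unique(roots)) {
    members <- tids[roots == root]
    ts <- store$treesets[[root]]
    ls <- lapply(stats::setNames(assign[members], members),
                 oracle_leafset, store = store)
    # rule 5
    for (rk in unique(rank_of[members])) {
      grp <- members[rank_of[members] == rk]
      if (length(grp) >= 2) {
        for (i in seq_len(length(grp) - 1)) for (j in seq(i + 1, length(grp))) {
          a <- ls[[grp[i]]]; b <- ls[[grp[j]]]
          if (assign[[grp[i]]] != assign[[grp[j]]] &&
              (all(a %in% b) || all(b %in% a))) return(FALSE)
        }
      }
    }
    # rule 6
    for (t in members) {
      if (rank_of[[t]] != "subspecies") next
      p <- parent_of[[t]]
      if (is.na(p)) next
      if (!p %in% members) return(FALSE)
      if (assign[[p]] != assign[[t]] &&
          !all(ls[[t]] %in% ls[[p]])) return(FALSE)
      if (assign[[p]] != assign[[t]] &&
          length(ls[[p]]) <= length(ls[[t]])) return(FALSE)
    }
    # rules 1 and 3 in some variant
    vs <- if (length(ts$variants)) ts$variants else list(list(edges = list()))
    found <- FALSE
    for (v in vs) {
      w <- tryCatch(compute_weights(v, root = ts$root), error = function(e) NULL)
      if (is.null(w) || !all(assign[members] %in% w$concept)) next
      sp <- members[rank_of[members] == "species"]
      if (length(sp)) {
        s <- arrangement_sum(unname(assign[sp]), weights = w)
        if (!isTRUE(s == rational(1))) next
      }
      ok <- TRUE
      for (t in sp) {
        kids <- members[rank_of[members] == "subspecies" &
                          !is.na(parent_of[members]) & parent_of[members] == t]
        if (length(kids) == 0) next
        s <- arrangement_sum(unname(assign[kids]), weights = w)
        if (!isTRUE(s == weight_of(w, assign[[t]]))) { ok <- FALSE; break }
      }
      if (ok) { found <- TRUE; break }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

oracle_solutions <- function(cl, cands, store) {
  recs <- cl$records
  tids <- recs$taxon_id[vapply(recs$taxon_id, function(t)
    length(cands[[t]]) > 0, logical(1))]
  if (length(tids) == 0) return(list())
  grid <- do.call(expand.grid,
                  c(stats::setNames(lapply(tids, function(t) cands[[t]]), tids),
                    stringsAsFactors = FALSE))
  sols <- list()
  for (i in seq_len(nrow(grid))) {
    assign <- stats::setNames(as.character(grid[i, ]), tids)
    if (oracle_valid(assign, recs, store)) sols[[length(sols) + 1]] <- assign
  }
  sols
}

# Per-record status/concept implied by the oracle's solution set, in the
# same shape as solve_assignment() output.
oracle_statuses <- function(cl, cands, store) {
  sols <- oracle_solutions(cl, cands, store)
  recs <- cl$records
  out <- data.frame(taxon_id = recs$taxon_id, status = "unmapped_new",
                    concept = NA_character_, stringsAsFactors = FALSE)
  considered <- recs$taxon_id[vapply(recs$taxon_id, function(t)
    length(cands[[t]]) > 0, logical(1))]
  for (t in considered) {
    vals <- unique(vapply(sols, function(s) s[[t]], character(1)))
    if (length(sols) == 0) {
      out$status[out$taxon_id == t] <- "conflict"
    } else if (length(vals) == 1) {
      out$status[out$taxon_id == t] <- "mapped"
      out$concept[out$taxon_id == t] <- vals
    } else {
      out$status[out$taxon_id == t] <- "ambiguous"
    }
  }
  out
}
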