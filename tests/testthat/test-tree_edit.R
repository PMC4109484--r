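# Projection of a post-split leaf set back onto the pre-edit terminals:
# every new node is collapsed into the old terminal it refines.
project_onto <- function(leaves, old_nodes, store_after) {
  vapply(leaves, function(x) {
    if (x %in% old_nodes) return(x)
    best <- x
    best_n <- Inf
    for (o in old_nodes) {
      anc <- leaf_set(o, store_after)
      if (x %in% anc && length(anc) < best_n) {
        best <- o
        best_n <- length(anc)
      }
    }
    best
  }, character(1), USE.NAMES = FALSE)
}

test_that("splitting a terminal extends the branch without new variants", {
  fx <- build_fixture("vireo")
  n_var <- length(fx$store$treesets[[1]]$variants)
  res <- split_terminal(fx$ids[["plu_jac"]], fx$store)
  expect_length(res$new_ids, 2)
  expect_length(res$store$treesets[[1]]$variants, n_var)
  expect_setequal(leaf_set(fx$ids[["plu_jac"]], res$store), res$new_ids)
  w <- compute_weights(res$store$treesets[[1]]$variants[[1]])
  # each new child receives half the former leaf's weight: (1/30)/2
  for (id in res$new_ids) expect_true(weight_of(w, id) == rational(1, 60))
  # repeated application: four grandchildren, still one variant
  res2 <- split_terminal(res$new_ids[1], res$store)
  res3 <- split_terminal(res$new_ids[2], res2$store)
  expect_length(res3$store$treesets[[1]]$variants, n_var)
  expect_length(leaf_set(fx$ids[["plu_jac"]], res3$store), 4)
  expect_error(split_terminal(fx$ids[["plu"]], fx$store), "internal")
})

test_that("merging independent trees yields a shared root with equal shares", {
  st <- concept_store()
  st <- add_concept(st, tid(1), "species")
  st <- add_concept(st, tid(2), "species")
  st <- add_treeset(st, tid(1), list())
  st <- add_treeset(st, tid(2), list())
  m <- merge_roots(tid(1), tid(2), st)
  expect_length(contax:::treeset_nodes(m$store$treesets[[m$root]]), 3)
  w <- compute_weights(m$store$treesets[[m$root]]$variants[[1]])
  expect_true(weight_of(w, tid(1)) == rational(1, 2))
  expect_true(weight_of(w, tid(2)) == rational(1, 2))
  arrs <- enumerate_valid_arrangements(m$store$treesets[[m$root]], m$store)
  expect_true(any(vapply(arrs, identical, logical(1), y = m$root)))
  expect_true(any(vapply(arrs, setequal, logical(1), y = c(tid(1), tid(2)))))
  expect_error(merge_roots(m$root, m$root, m$store), "itself")
})

test_that("grouping children adds a variant and reuses congruent nodes", {
  fx <- build_fixture("vireo")
  g <- group_children(fx$ids[["sl"]], unname(fx$ids[c("cas", "plu")]), fx$store)
  expect_identical(g$variant_index, 2L)
  expect_setequal(leaf_set(g$group_id, g$store),
                  c(leaf_set(fx$ids[["cas"]], fx$store),
                    leaf_set(fx$ids[["plu"]], fx$store)))
  expect_identical(nrow(validate_treeset(g$store$treesets[[1]])), 0L)
  before <- enumerate_valid_arrangements(fx$store$treesets[[1]], fx$store)
  after <- enumerate_valid_arrangements(g$store$treesets[[1]], g$store)
  expect_identical(length(after), length(before) + 1L)
  # applying the same grouping again reuses the node and adds no variant
  g2 <- group_children(fx$ids[["sl"]], unname(fx$ids[c("cas", "plu")]), g$store)
  expect_identical(g2$group_id, g$group_id)
  expect_length(g2$store$treesets[[1]]$variants, 2)
  expect_error(group_children(fx$ids[["sl"]],
                              unname(fx$ids[c("ss", "cas", "plu")]), fx$store),
               "all children")
  expect_error(group_children(fx$ids[["sl"]], fx$ids[["cas"]], fx$store),
               "single child")
})

test_that("reassigning leaves creates primed species in a new variant", {
  # two independent species, each with two subspecies
  st <- two_species_store()
  rs <- reassign(tid(21), tid(2), tid(1), st)
  expect_true(rs$root %in% names(rs$store$treesets))
  expect_setequal(leaf_set(rs$a_prime, rs$store), c(tid(11), tid(12), tid(21)))
  expect_setequal(leaf_set(rs$b_prime, rs$store), c(tid(22), tid(23)))
  expect_identical(nrow(validate_treeset(rs$store$treesets[[rs$root]])), 0L)
  expect_error(reassign(character(0), tid(2), tid(1), st), "nothing")
  expect_error(reassign(c(tid(21), tid(22), tid(23)), tid(2), tid(1), st),
               "lump")
})

test_that("the two-variant petrel arrangement is reproducible by a reassignment", {
  # base tree: root -> {a, bc}, bc -> {b, c}; moving c to the a side must
  # produce the alternate arrangement root -> {ac, b}, ac -> {a, c}
  kinds <- stats::setNames(c("species", "species", "species", "species",
                             "species"),
                           c(tid(1), tid(2), tid(3), tid(4), tid(5)))
  st <- mini_store(kinds, trees = list(list(
    root = tid(1),
    variants = list(stats::setNames(list(c(tid(2), tid(3)),
                                         c(tid(4), tid(5))),
                                    c(tid(1), tid(3)))))))
  rs <- reassign(tid(5), tid(3), tid(2), st)
  ts <- rs$store$treesets[[tid(1)]]
  expect_length(ts$variants, 2)
  expect_setequal(leaf_set(rs$a_prime, rs$store), c(tid(2), tid(5)))
  expect_identical(rs$b_prime, tid(4))
  expect_identical(nrow(validate_treeset(ts)), 0L)
  # structure matches the petrel fixture: same leaf partition per variant
  pt <- build_fixture("pterodroma")
  part <- function(ts) {
    lapply(ts$variants, function(v) {
      kids <- v$edges[[contax:::variant_root(v)]]
      sets <- lapply(kids, contax:::variant_leafset, variant = v)
      sort(vapply(sets, function(s) paste(length(s)), character(1)))
    })
  }
  expect_setequal(part(ts), part(pt$store$treesets[[1]]))
  arrs <- enumerate_valid_arrangements(ts, rs$store)
  expect_length(arrs, 4)
})

test_that("elevating a subspecies relabels concepts without new leaf sets", {
  fx <- build_fixture("vireo")
  res <- elevate(fx$ids[["ss_alt"]], fx$store, species_name = "Vireo alticola")
  expect_identical(res$residual_id, unname(fx$ids[["ss_sol"]]))
  hits <- lookup_name("Vireo solitarius", res$store)
  expect_length(hits, 3)
  w <- compute_weights(res$store$treesets[[1]]$variants[[1]])
  expect_setequal(vapply(hits, function(h) w$display[w$concept == h],
                         character(1)),
                  c("1.000", "0.333", "0.167"))
  expect_length(lookup_name("Vireo alticola", res$store), 1)
})

test_that("edits never change the leaf set of a pre-existing identifier", {
  fx <- build_fixture("vireo")
  old_nodes <- contax:::treeset_nodes(fx$store$treesets[[1]])
  old_sets <- lapply(stats::setNames(old_nodes, old_nodes),
                     leaf_set, treeset = fx$store)
  edited <- list(
    group_children(fx$ids[["sl"]], unname(fx$ids[c("cas", "plu")]),
                   fx$store)$store,
    elevate(fx$ids[["ss_alt"]], fx$store)$store,
    split_terminal(fx$ids[["cas_luc"]], fx$store)$store
  )
  for (st2 in edited) {
    for (n in old_nodes) {
      projected <- unique(project_onto(leaf_set(n, st2), old_nodes, st2))
      expect_setequal(projected, old_sets[[n]])
    }
    expect_identical(nrow(validate_treeset(st2$treesets[[1]])), 0L)
  }
})
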