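test_that("candidate resolution reports homonym sets and unknown names", {
  fx <- build_fixture("vireo")
  cl <- fx$checklists$split5
  cands <- resolve_candidates(cl, fx$store)
  expect_length(cands[["S1"]], 2)            # sensu lato and sensu stricto
  expect_length(cands[["U5"]], 2)            # nominal plumbeus, both senses
  expect_length(cands[["S2"]], 1)
  cl2 <- checklist("A", "1", 2000, simple_record("S1", "Novus ignotus", "species"))
  expect_identical(resolve_candidates(cl2, fx$store)[["S1"]], character(0))
  po <- build_fixture("poicephalus")
  pc <- resolve_candidates(po$checklists$two_species, po$store)
  expect_length(pc[["S1"]], 2)
  expect_length(pc[["S2"]], 2)
})

test_that("a lone broad name maps to sensu lato; a split revision to sensu stricto", {
  fx <- build_fixture("vireo")
  m1 <- solve_assignment(fx$checklists$lumped, store = fx$store)
  expect_identical(m1$status, "mapped")
  expect_identical(m1$concept, unname(fx$ids[["sl"]]))
  m2 <- solve_assignment(fx$checklists$split5, store = fx$store)
  expect_true(all(m2$status == "mapped"))
  expect_identical(m2$concept[m2$taxon_id == "S1"], unname(fx$ids[["ss"]]))
  # the ambiguous nominal plumbeus resolves through the subspecies sum
  expect_identical(m2$concept[m2$taxon_id == "U5"],
                   unname(fx$ids[["plu_plu_incl"]]))
  m3 <- solve_assignment(fx$checklists$split6, store = fx$store)
  expect_identical(m3$concept[m3$taxon_id == "U5"],
                   unname(fx$ids[["plu_plu_excl"]]))
  expect_identical(m3$concept[m3$taxon_id == "U10"],
                   unname(fx$ids[["plu_jac"]]))
})

test_that("an underspecified parrot checklist is ambiguous with two solutions", {
  po <- build_fixture("poicephalus")
  m <- solve_assignment(po$checklists$two_species, store = po$store)
  expect_identical(m$status, c("ambiguous", "ambiguous"))
  sols <- attr(m, "solutions")[[1]]$solutions
  expect_length(sols, 2)
  # candidates column lists both possible senses of each name
  expect_length(strsplit(m$candidates[1], ";")[[1]], 2)
})

test_that("adding the subspecies list removes the parrot ambiguity", {
  po <- build_fixture("poicephalus")
  cl <- checklist("A", "2", 2005, rbind(
    simple_record("S1", "Poicephalus robustus", "species"),
    simple_record("S2", "Poicephalus fuscicollis", "species"),
    simple_record("U1", "Poicephalus robustus robustus", "subspecies", "S1"),
    simple_record("U2", "Poicephalus robustus suahelicus", "subspecies", "S1")))
  m <- solve_assignment(cl, store = po$store)
  expect_true(all(m$status == "mapped"))
  expect_identical(m$concept[m$taxon_id == "S1"], unname(po$ids[["rs"]]))
  expect_identical(m$concept[m$taxon_id == "S2"], unname(po$ids[["f"]]))
  # monotonicity: never more surviving solutions than without subspecies
  n_before <- length(attr(solve_assignment(po$checklists$two_species,
                                           store = po$store),
                          "solutions")[[1]]$solutions)
  n_after <- length(attr(m, "solutions")[[1]]$solutions)
  expect_lte(n_after, n_before)
})

test_that("unknown names and curator overrides behave as specified", {
  fx <- build_fixture("vireo")
  cl <- checklist("A", "1", 2000, rbind(
    simple_record("S1", "Vireo solitarius", "species"),
    simple_record("S2", "Novus ignotus", "species")))
  m <- solve_assignment(cl, store = fx$store)
  expect_identical(m$status[m$taxon_id == "S2"], "unmapped_new")
  expect_identical(m$status[m$taxon_id == "S1"], "mapped")
  # force the parrot ambiguity with an override file entry
  po <- build_fixture("poicephalus")
  m2 <- solve_assignment(po$checklists$two_species, store = po$store,
                         overrides = c(S1 = unname(po$ids[["rs"]])))
  expect_identical(m2$status, c("mapped", "mapped"))
  expect_identical(m2$concept, unname(po$ids[c("rs", "f")]))
})

test_that("arrangement enumeration counts match the worked examples", {
  pt <- build_fixture("pterodroma")
  arrs <- enumerate_valid_arrangements(pt$store$treesets[[1]], pt$store)
  expect_length(arrs, 4)
  for (a in arrs) {
    # every valid combination covers each terminal exactly once
    ls <- unlist(lapply(a, leaf_set, treeset = pt$store$treesets[[1]]))
    expect_setequal(ls, unname(pt$ids[c("a", "b", "c")]))
    expect_length(ls, 3)
  }
  vx <- build_fixture("vireo")
  expect_length(enumerate_valid_arrangements(vx$store$treesets[[1]], vx$store),
                2)
  st <- concept_store()
  st <- add_concept(st, tid(1), "species")
  st <- add_treeset(st, tid(1), list())
  expect_identical(enumerate_valid_arrangements(st$treesets[[1]], st),
                   list(tid(1)))
})

test_that("the solver agrees with brute-force enumeration on small trees", {
  cases <- list()
  po <- build_fixture("poicephalus")
  cases[[1]] <- list(cl = po$checklists$two_species, store = po$store)
  pt <- build_fixture("pterodroma")
  cases[[2]] <- list(cl = pt$checklists$three_species, store = pt$store)
  cases[[3]] <- list(cl = pt$checklists$two_species, store = pt$store)
  vx <- build_fixture("vireo")
  cases[[4]] <- list(cl = vx$checklists$split6, store = vx$store)
  # simulated histories, species rows only, with injected homonymy
  for (s in 1:6) {
    sim <- simulate_history(n_species = 3, subspecies_range = c(1, 2),
                            n_versions = 2,
                            rates = c(split_terminal = 0.5, lump = 0.5,
                                      rename = 0.3, elevate = 0.3,
                                      reassign = 0.3),
                            homonym_rate = 0.4, seed = 7000 + s)
    cl <- sim$checklists[[2]]
    sp <- cl$records[cl$records$rank == "species",
                     c("taxon_id", "scientific_name", "rank", "parent_taxon_id")]
    cases[[length(cases) + 1]] <-
      list(cl = checklist(cl$authority, cl$version_label, cl$year, sp),
           store = sim$store)
  }
  for (case in cases) {
    cands <- resolve_candidates(case$cl, case$store)
    got <- solve_assignment(case$cl, cands, case$store)
    want <- oracle_statuses(case$cl, cands, case$store)
    expect_identical(got$status, want$status)
    expect_identical(got$concept, want$concept)
  }
})

test_that("the combination cap guards pathological homonymy", {
  po <- build_fixture("poicephalus")
  expect_error(solve_assignment(po$checklists$two_species, store = po$store,
                                cap = 1),
               "combinatorial budget")
})

test_that("diffing checklist versions classifies renames, additions, removals", {
  fx <- build_fixture("vireo")
  old <- fx$checklists$split5
  m <- solve_assignment(old, store = fx$store)
  d0 <- diff_checklists(old, m, old, fx$store)
  expect_true(all(d0$change == "unchanged"))
  # genus transfer: same concept reachable through the synonym table
  st <- add_synonym(fx$store, "Vireolanius cassinii", fx$ids[["cas"]])
  recs <- old$records[, c("taxon_id", "scientific_name", "rank",
                          "parent_taxon_id")]
  recs$scientific_name[recs$taxon_id == "S2"] <- "Vireolanius cassinii"
  recs <- rbind(recs, simple_record("S9", "Novus additus", "species"))
  recs <- recs[recs$taxon_id != "U9", ]
  new <- checklist("Fixture authority", "2b", 1999, recs)
  d1 <- diff_checklists(old, m, new, st)
  expect_identical(d1$change[d1$taxon_id_new == "S2" & !is.na(d1$taxon_id_new)],
                   "renamed")
  expect_identical(d1$concept[d1$change == "renamed"], unname(fx$ids[["cas"]]))
  expect_identical(d1$change[!is.na(d1$taxon_id_new) & d1$taxon_id_new == "S9"],
                   "added")
  expect_identical(d1$change[!is.na(d1$taxon_id_old) & d1$taxon_id_old == "U9"],
                   "removed")
})
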