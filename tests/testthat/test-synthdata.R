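test_that("fixture stores match their published structure", {
  vx <- build_fixture("vireo")
  expect_identical(nrow(vx$store$concepts), 15L)
  expect_length(vx$store$treesets[[1]]$variants, 1)
  pt <- build_fixture("pterodroma")
  expect_identical(nrow(pt$store$concepts), 6L)
  expect_length(pt$store$treesets[[1]]$variants, 2)
  expect_length(enumerate_valid_arrangements(pt$store$treesets[[1]], pt$store),
                4)
  po <- build_fixture("poicephalus")
  expect_length(po$store$treesets[[1]]$variants, 2)
  # both species binomials attach to two distinct circumscriptions
  expect_length(lookup_name("Poicephalus robustus", po$store), 2)
  expect_length(lookup_name("Poicephalus fuscicollis", po$store), 2)
  expect_error(build_fixture("dodo"))
  # every fixture tree set satisfies the structural rules
  for (fx in list(vx, pt, po)) {
    expect_identical(nrow(validate_store(fx$store)), 0L)
  }
})

test_that("zero event rates give identical snapshots with constant truth", {
  sim <- simulate_history(n_species = 3, n_versions = 3,
                          rates = c(split_terminal = 0, lump = 0, rename = 0,
                                    elevate = 0, reassign = 0),
                          seed = 42)
  expect_length(sim$checklists, 3)
  for (v in 2:3) {
    expect_identical(sim$checklists[[v]]$records,
                     sim$checklists[[1]]$records)
    expect_identical(sim$truths[[v]]$concept, sim$truths[[1]]$concept)
  }
})

test_that("a certain split produces new subspecies and preserves old meanings", {
  sim <- simulate_history(n_species = 1, subspecies_range = c(2, 2),
                          n_versions = 2,
                          rates = c(split_terminal = 1, lump = 0, rename = 0,
                                    elevate = 0, reassign = 0),
                          seed = 9)
  r1 <- sim$checklists[[1]]$records
  r2 <- sim$checklists[[2]]$records
  expect_identical(sum(r2$rank == "subspecies"),
                   sum(r1$rank == "subspecies") + 1L)
  # the species concept is untouched by the split below it
  expect_identical(sim$truths[[1]]$concept[1], sim$truths[[2]]$concept[1])
})

test_that("histories are reproducible from the seed", {
  args <- list(n_species = 4, n_versions = 4,
               rates = c(split_terminal = .5, lump = .4, rename = .4,
                         elevate = .3, reassign = .3), seed = 77)
  s1 <- do.call(simulate_history, args)
  s2 <- do.call(simulate_history, args)
  p1 <- withr::local_tempfile(fileext = ".yaml")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  save_store(s1$store, p1)
  save_store(s2$store, p2)
  expect_identical(readLines(p1), readLines(p2))
  for (v in seq_along(s1$checklists)) {
    expect_identical(s1$checklists[[v]]$records, s2$checklists[[v]]$records)
  }
})

test_that("ground-truth mappings always validate clean", {
  for (s in c(3, 14, 159)) {
    sim <- simulate_history(n_species = 3, subspecies_range = c(1, 3),
                            n_versions = 3,
                            rates = c(split_terminal = .4, lump = .3,
                                      rename = .3, elevate = .25,
                                      reassign = .25),
                            seed = s)
    expect_identical(nrow(validate_store(sim$store)), 0L)
    for (v in seq_along(sim$checklists)) {
      rep <- validate_mapping(sim$checklists[[v]], sim$truths[[v]], sim$store)
      expect_identical(nrow(rep), 0L)
    }
  }
})

test_that("parameter validation rejects malformed settings", {
  expect_error(simulate_history(n_species = 2, n_versions = 2), "seed")
  expect_error(simulate_history(n_species = 0, seed = 1))
  expect_error(simulate_history(n_species = 2,
                                rates = c(split_terminal = 2, lump = 0,
                                          rename = 0, elevate = 0,
                                          reassign = 0), seed = 1),
               "probabilities")
  expect_error(simulate_history(n_species = 2,
                                rates = c(split_terminal = 0.1), seed = 1),
               "rates lack")
})
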