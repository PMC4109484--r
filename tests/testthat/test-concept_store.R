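test_that("concept identifiers are 16 uppercase hex characters and seedable", {
  st <- concept_store()
  set.seed(0)
  id1 <- new_concept_id(st)
  expect_match(id1, "^[0-9A-F]{16}$")
  set.seed(0)
  expect_identical(new_concept_id(st), id1)
  set.seed(1)
  ids <- replicate(50, new_concept_id(st))
  expect_true(all(grepl("^[0-9A-F]{16}$", ids)))
  # a published identifier is a valid id
  st2 <- add_concept(st, "2624054ED644AABB", "species")
  expect_true("2624054ED644AABB" %in% st2$concepts$id)
  expect_error(add_concept(st, "xyz", "species"), "invalid concept id")
})

test_that("name canonicalization capitalizes genus, lowers epithets, idempotent", {
  expect_identical(canonicalize_name("  vireo   SOLITARIUS "), "Vireo solitarius")
  expect_identical(canonicalize_name("VIREO SOLITARIUS ALTICOLA"),
                   "Vireo solitarius alticola")
  x <- c("parus  Major", "Vireo solitarius")
  expect_identical(canonicalize_name(canonicalize_name(x)), canonicalize_name(x))
})

test_that("leaf sets: terminals of the Vireo complex and variant independence", {
  fx <- build_fixture("vireo")
  ids <- fx$ids
  # direct enumeration of the structure: 2 + 2 + (4 + 2) terminals
  expect_length(leaf_set(ids[["sl"]], fx$store), 10)
  expect_identical(leaf_set(ids[["plu_jac"]], fx$store),
                   unname(ids[["plu_jac"]]))
  expect_setequal(leaf_set(ids[["cas"]], fx$store),
                  unname(ids[c("cas_cas", "cas_luc")]))
  expect_error(leaf_set("0000000000000000", fx$store), "unknown node")
  pt <- build_fixture("pterodroma")
  # heraldica sensu lato exists only in variant B and covers {a, c}
  expect_setequal(leaf_set(pt$ids[["ac"]], pt$store),
                  unname(pt$ids[c("a", "c")]))
  # the root's leaf set is identical whichever variant it is read from
  ts <- pt$store$treesets[[1]]
  for (v in ts$variants) {
    expect_setequal(contax:::variant_leafset(v, pt$ids[["root"]]),
                    unname(pt$ids[c("a", "b", "c")]))
  }
})

test_that("children partition their parent's leaf set in every variant", {
  fixtures <- lapply(c("vireo", "pterodroma", "poicephalus"), build_fixture)
  for (fx in fixtures) {
    for (ts in fx$store$treesets) {
      for (v in ts$variants) {
        for (p in names(v$edges)) {
          kid_sets <- lapply(v$edges[[p]], contax:::variant_leafset, variant = v)
          expect_length(unlist(kid_sets), length(unique(unlist(kid_sets))))
          expect_setequal(unlist(kid_sets), contax:::variant_leafset(v, p))
        }
      }
    }
  }
})

test_that("name lookup unions labels and synonyms; homonyms and synonyms", {
  fx <- build_fixture("vireo")
  expect_length(lookup_name("Vireo solitarius", fx$store), 2)
  expect_length(lookup_name("vireo  solitarius", fx$store), 2)
  expect_identical(lookup_name("Xx yy", fx$store), character(0))
  expect_length(lookup_name("Solitary Vireo", fx$store), 1)
  # several binomials resolving to one circumscription cluster
  st <- concept_store()
  st <- add_concept(st, "8E833C63E70A547C", "species")
  st <- add_label(st, "8E833C63E70A547C", "Scleroptila levaillantoides", "species")
  for (nm in c("Francolinus gariepensis", "Francolinus levaillantoides",
               "Scleroptila gutturalis")) {
    st <- add_synonym(st, nm, "8E833C63E70A547C")
  }
  expect_identical(lookup_name("Scleroptila levaillantoides", st),
                   "8E833C63E70A547C")
  expect_identical(lookup_name("Francolinus gariepensis", st),
                   "8E833C63E70A547C")
})

test_that("store construction rejects inconsistent trees and hybrids work", {
  st <- two_species_store()
  expect_error(add_treeset(st, tid(1), list()), "already heads")
  st2 <- add_concept(st, tid(99), "species")
  expect_error(
    add_treeset(st2, tid(99),
                list(stats::setNames(list(c(tid(11), tid(12))), tid(99)))),
    "another tree set")
  hy <- add_concept(st, tid(50), "other")
  hy <- add_hybrid(hy, tid(50), c(tid(1), tid(2)))
  expect_true(tid(50) %in% hy$hybrids$id)
  # hybrids stay outside trees: no tree set contains them
  expect_true(is.na(contax:::treeset_of(hy, tid(50))))
  expect_error(add_hybrid(st, tid(51), tid(1)), "at least two")
})
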