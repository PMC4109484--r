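# Worked fixtures: three classic bird examples that exercise every part of
# the model.
#
#   vireo       the Solitary Vireo complex: one tree, one variant; a
#               sensu lato / sensu stricto homonym pair for the species
#               name, five-way and two-way splits below the species, and a
#               nominal subspecies that exists in a jacksoni-including and
#               a jacksoni-excluding circumscription.
#   pterodroma  a three-leaf superspecies with two contradictory alternate
#               variants, giving four valid species-level arrangements.
#   poicephalus the parrot case in which a subspecies (suahelicus) has
#               been attached to either of two species, so a checklist
#               bearing only the two species binomials is genuinely
#               ambiguous.
#
# Identifiers are drawn from a seeded generator, so every call builds the
# same store byte for byte.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fixture_ids <- function(keys, seed) {
  local_seed(seed, {
    store <- concept_store()
    ids <- character(length(keys))
    for (i in seq_along(keys)) {
      ids[i] <- new_concept_id(store)
      store <- add_concept(store, ids[i], "other")
    }
    stats::setNames(ids, keys)
  })
}

#' Build a packaged fixture
#'
#' @param name `"vireo"`, `"pterodroma"` or `"poicephalus"`.
#' @return A list with `store` (a `concept_store`), `ids` (named vector of
#'   concept identifiers keyed by mnemonic), and `checklists` (named list
#'   of example `checklist` objects).
#' @examples
#' fx <- build_fixture("vireo")
#' lookup_name("Vireo solitarius", fx$store)  # two distinct concepts
#' @export
build_fixture <- function(name = c("vireo", "pterodroma", "poicephalus")) {
  name <- match.arg(name)
  switch(name,
         vireo = fixture_vireo(),
         pterodroma = fixture_pterodroma(),
         poicephalus = fixture_poicephalus())
}

fixture_vireo <- function() {
  keys <- c("sl", "ss", "cas", "plu",
            "ss_sol", "ss_alt", "cas_cas", "cas_luc",
            "plu_plu_incl", "plu_pin", "plu_rep", "plu_mon", "plu_not",
            "plu_plu_excl", "plu_jac")
  ids <- fixture_ids(keys, seed = 4101)
  kinds <- c(sl = "species", ss = "species", cas = "species", plu = "species",
             ss_sol = "subspecies", ss_alt = "subspecies",
             cas_cas = "subspecies", cas_luc = "subspecies",
             plu_plu_incl = "subspecies", plu_pin = "subspecies",
             plu_rep = "subspecies", plu_mon = "subspecies",
             plu_not = "subspecies", plu_plu_excl = "subspecies",
             plu_jac = "subspecies")
  labels <- list(
    sl = c("species", "Vireo solitarius"),
    ss = c("species", "Vireo solitarius"),
    cas = c("species", "Vireo cassinii"),
    plu = c("species", "Vireo plumbeus"),
    ss_sol = c("subspecies", "Vireo solitarius solitarius"),
    ss_alt = c("subspecies", "Vireo solitarius alticola"),
    cas_cas = c("subspecies", "Vireo cassinii cassinii"),
    cas_luc = c("subspecies", "Vireo cassinii lucasanus"),
    plu_plu_incl = c("subspecies", "Vireo plumbeus plumbeus"),
    plu_pin = c("subspecies", "Vireo plumbeus pinicolus"),
    plu_rep = c("subspecies", "Vireo plumbeus repetens"),
    plu_mon = c("subspecies", "Vireo plumbeus montanus"),
    plu_not = c("subspecies", "Vireo plumbeus notius"),
    plu_plu_excl = c("subspecies", "Vireo plumbeus plumbeus"),
    plu_jac = c("subspecies", "Vireo plumbeus jacksoni")
  )
  store <- concept_store()
  for (k in keys) store <- add_concept(store, ids[[k]], kinds[[k]])
  for (k in names(labels)) {
    store <- add_label(store, ids[[k]], labels[[k]][2], rank = labels[[k]][1])
  }
  store <- add_synonym(store, "Solitary Vireo", ids[["sl"]],
                       name_type = "vernacular", language = "en")
  edges <- stats::setNames(list(
    c(ids[["ss"]], ids[["cas"]], ids[["plu"]]),
    c(ids[["ss_sol"]], ids[["ss_alt"]]),
    c(ids[["cas_cas"]], ids[["cas_luc"]]),
    c(ids[["plu_plu_incl"]], ids[["plu_pin"]], ids[["plu_rep"]],
      ids[["plu_mon"]], ids[["plu_not"]]),
    c(ids[["plu_plu_excl"]], ids[["plu_jac"]])
  ), c(ids[["sl"]], ids[["ss"]], ids[["cas"]], ids[["plu"]],
       ids[["plu_plu_incl"]]))
  store <- add_treeset(store, ids[["sl"]], list(edges))

  rec <- function(tid, name, rank, parent = NA_character_) {
    data.frame(taxon_id = tid, scientific_name = name, rank = rank,
               parent_taxon_id = parent, stringsAsFactors = FALSE)
  }
  cl_lumped <- checklist("Fixture authority", "1", 1983, do.call(rbind, list(
    rec("S1", "Vireo solitarius", "species")
  )))
  split_core <- list(
    rec("S1", "Vireo solitarius", "species"),
    rec("S2", "Vireo cassinii", "species"),
    rec("S3", "Vireo plumbeus", "species"),
    rec("U1", "Vireo solitarius solitarius", "subspecies", "S1"),
    rec("U2", "Vireo solitarius alticola", "subspecies", "S1"),
    rec("U3", "Vireo cassinii cassinii", "subspecies", "S2"),
    rec("U4", "Vireo cassinii lucasanus", "subspecies", "S2"),
    rec("U5", "Vireo plumbeus plumbeus", "subspecies", "S3"),
    rec("U6", "Vireo plumbeus pinicolus", "subspecies", "S3"),
    rec("U7", "Vireo plumbeus repetens", "subspecies", "S3"),
    rec("U8", "Vireo plumbeus montanus", "subspecies", "S3"),
    rec("U9", "Vireo plumbeus notius", "subspecies", "S3")
  )
  cl_split5 <- checklist("Fixture authority", "2", 1997,
                         do.call(rbind, split_core))
  cl_split6 <- checklist("Fixture authority", "3", 2005, do.call(rbind, c(
    split_core,
    list(rec("U10", "Vireo plumbeus jacksoni", "subspecies", "S3"))
  )))
  list(store = store, ids = ids,
       checklists = list(lumped = cl_lumped, split5 = cl_split5,
                         split6 = cl_split6))
}

fixture_pterodroma <- function() {
  keys <- c("root", "ab", "ac", "a", "b", "c")
  ids <- fixture_ids(keys, seed = 4102)
  store <- concept_store()
  for (k in keys) store <- add_concept(store, ids[[k]], "species")
  lbl <- list(root = "Pterodroma arminjoniana", ab = "Pterodroma arminjoniana",
              ac = "Pterodroma heraldica", a = "Pterodroma heraldica",
              b = "Pterodroma arminjoniana", c = "Pterodroma atrata")
  for (k in names(lbl)) store <- add_label(store, ids[[k]], lbl[[k]], "species")
  v_a <- stats::setNames(list(c(ids[["ab"]], ids[["c"]]),
                              c(ids[["a"]], ids[["b"]])),
                         c(ids[["root"]], ids[["ab"]]))
  v_b <- stats::setNames(list(c(ids[["ac"]], ids[["b"]]),
                              c(ids[["a"]], ids[["c"]])),
                         c(ids[["root"]], ids[["ac"]]))
  store <- add_treeset(store, ids[["root"]], list(v_a, v_b))
  rec <- function(tid, name) {
    data.frame(taxon_id = tid, scientific_name = name, rank = "species",
               parent_taxon_id = NA_character_, stringsAsFactors = FALSE)
  }
  cl3 <- checklist("Fixture authority", "1", 2010, rbind(
    rec("S1", "Pterodroma heraldica"),
    rec("S2", "Pterodroma arminjoniana"),
    rec("S3", "Pterodroma atrata")))
  cl2 <- checklist("Fixture authority", "2", 2012, rbind(
    rec("S1", "Pterodroma arminjoniana"),
    rec("S2", "Pterodroma atrata")))
  list(store = store, ids = ids,
       checklists = list(three_species = cl3, two_species = cl2))
}

fixture_poicephalus <- function() {
  keys <- c("root", "rs", "sf", "r", "s", "f")
  ids <- fixture_ids(keys, seed = 4103)
  store <- concept_store()
  kinds <- c(root = "group", rs = "species", sf = "species",
             r = "subspecies", s = "subspecies", f = "subspecies")
  for (k in keys) store <- add_concept(store, ids[[k]], kinds[[k]])
  store <- add_label(store, ids[["rs"]], "Poicephalus robustus", "species")
  store <- add_label(store, ids[["sf"]], "Poicephalus fuscicollis", "species")
  # the South African nominate and the western fuscicollis are monotypic in
  # one arrangement each: one id, labels at both ranks
  store <- add_label(store, ids[["r"]], "Poicephalus robustus", "species")
  store <- add_label(store, ids[["r"]], "Poicephalus robustus robustus", "subspecies")
  store <- add_label(store, ids[["f"]], "Poicephalus fuscicollis", "species")
  store <- add_label(store, ids[["f"]], "Poicephalus fuscicollis fuscicollis", "subspecies")
  store <- add_label(store, ids[["s"]], "Poicephalus robustus suahelicus", "subspecies")
  store <- add_label(store, ids[["s"]], "Poicephalus fuscicollis suahelicus", "subspecies")
  v_a <- stats::setNames(list(c(ids[["rs"]], ids[["f"]]),
                              c(ids[["r"]], ids[["s"]])),
                         c(ids[["root"]], ids[["rs"]]))
  v_b <- stats::setNames(list(c(ids[["r"]], ids[["sf"]]),
                              c(ids[["s"]], ids[["f"]])),
                         c(ids[["root"]], ids[["sf"]]))
  store <- add_treeset(store, ids[["root"]], list(v_a, v_b))
  cl <- checklist("Fixture authority", "1", 2004, data.frame(
    taxon_id = c("S1", "S2"),
    scientific_name = c("Poicephalus robustus", "Poicephalus fuscicollis"),
    rank = "species", parent_taxon_id = NA_character_,
    stringsAsFactors = FALSE))
  list(store = store, ids = ids, checklists = list(two_species = cl))
}
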