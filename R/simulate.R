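# Simulated checklist histories with known ground truth.
#
# The simulator builds a base store of independent species trees, then
# publishes a sequence of full-snapshot checklist versions, applying
# sampled taxonomic-change events between versions: terminal splits,
# lumps of independent trees, renames (genus transfers feeding the synonym
# table, as happens with gender agreement emendations), elevation of a
# subspecies to species rank, and reassignment of a subspecies to another
# species. Every version is emitted together with the true record-to-
# concept mapping, so mapper recovery and validation round trips can be
# measured exactly. All randomness flows through R's RNG under the given
# seed; two runs with one seed are identical.

SYLLABLES <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni", "po", "ra",
               "se", "tu", "ve", "xa", "zo", "chi", "bre", "cor", "dul", "fer")

#' Simulate a checklist history with ground truth
#'
#' @param n_species number of base species (each starts as its own tree).
#' @param subspecies_range integer range `c(min, max)` of subspecies per
#'   base species; 1 gives a monotypic species (a single-node tree whose
#'   nominal subspecies is not listed in checklists).
#' @param n_versions number of checklist versions to publish (>= 1).
#' @param rates per-version event probabilities, named
#'   `split_terminal`, `lump`, `rename`, `elevate`, `reassign`.
#' @param homonym_rate probability that a base species reuses another base
#'   species' binomial, injecting concept homonyms across trees.
#' @param seed integer seed; the whole history is reproducible from it.
#' @return A list with `store` (final `concept_store`), `checklists`
#'   (list of `checklist`, one per version), `truths` (list of
#'   `mapping_result` data frames giving the true concept of every
#'   record), and `params`.
#' @export
simulate_history <- function(n_species = 6, subspecies_range = c(2, 4),
                             n_versions = 4,
                             rates = c(split_terminal = 0.25, lump = 0.15,
                                       rename = 0.2, elevate = 0.1,
                                       reassign = 0.1),
                             homonym_rate = 0, seed) {
  if (missing(seed)) stop("a seed is required for a reproducible history")
  stopifnot(n_species >= 1, n_versions >= 1,
            length(subspecies_range) == 2,
            subspecies_range[1] >= 1,
            subspecies_range[2] >= subspecies_range[1])
  needed <- c("split_terminal", "lump", "rename", "elevate", "reassign")
  miss <- setdiff(needed, names(rates))
  if (length(miss)) stop("rates lack entries: ", paste(miss, collapse = ", "))
  if (any(rates < 0 | rates > 1) || homonym_rate < 0 || homonym_rate > 1) {
    stop("event rates must be probabilities in [0, 1]")
  }
  local_seed(seed, simulate_history_impl(n_species, subspecies_range,
                                         n_versions, rates, homonym_rate,
                                         seed))
}

simulate_history_impl <- function(n_species, subspecies_range, n_versions,
                                  rates, homonym_rate, seed) {
  store <- concept_store()
  used_words <- character()
  epithets <- character()  # concept id -> epithet

  gen_word <- function(n_syll = 3) {
    repeat {
      w <- paste(sample(SYLLABLES, n_syll, replace = TRUE), collapse = "")
      w <- paste0(w, sample(c("us", "a", "um", "is"), 1))
      if (!w %in% used_words) {
        used_words <<- c(used_words, w)
        return(w)
      }
    }
  }
  gen_genus <- function() {
    w <- gen_word(2)
    paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
  }
  mint <- function(kind) {
    id <- new_concept_id(store)
    store <<- add_concept(store, id, kind)
    id
  }

  slots <- list()
  binomials <- character()
  for (i in seq_len(n_species)) {
    genus <- gen_genus()
    epithet <- gen_word()
    name <- paste(genus, epithet)
    if (length(binomials) && stats::runif(1) < homonym_rate) {
      name <- sample(binomials, 1)
      genus <- strsplit(name, " ")[[1]][1]
      epithet <- strsplit(name, " ")[[1]][2]
    }
    binomials <- c(binomials, name)
    k <- sample(seq(subspecies_range[1], subspecies_range[2]), 1)
    sp <- mint("species")
    store <- add_label(store, sp, name, "species")
    epithets[[sp]] <- epithet
    if (k == 1) {
      store <- add_treeset(store, sp, list())
      store <- add_label(store, sp, paste(name, epithet), "subspecies")
      ssp <- character(0)
    } else {
      ssp <- character(k)
      for (j in seq_len(k)) {
        ssp[j] <- mint("subspecies")
        epithets[[ssp[j]]] <- if (j == 1) epithet else gen_word()
      }
      store <- add_treeset(store, sp, list(stats::setNames(list(ssp), sp)))
    }
    slots[[length(slots) + 1]] <- list(species = sp, ssp = ssp,
                                       genus = genus, epithet = epithet,
                                       name = name)
  }

  is_root_slot <- function(slot) slot$species %in% names(store$treesets)

  # sample() expands a numeric scalar n into 1:n; always pick from the set
  pick1 <- function(x) if (length(x) == 1) x else sample(x, 1)

  ev_split <- function() {
    j <- pick1(seq_along(slots))
    slot <- slots[[j]]
    leaf <- if (length(slot$ssp) == 0) slot$species else pick1(slot$ssp)
    res <- split_terminal(leaf, store, n_children = 2)
    store <<- res$store
    kids <- res$new_ids
    epithets[[kids[1]]] <<- epithets[[leaf]]
    epithets[[kids[2]]] <<- gen_word()
    slot$ssp <- c(setdiff(slot$ssp, leaf), kids)
    slots[[j]] <<- slot
  }

  ev_lump <- function() {
    eligible <- which(vapply(slots, is_root_slot, logical(1)))
    if (length(eligible) < 2) return(invisible())
    jj <- sort(sample(eligible, 2))
    s1 <- slots[[jj[1]]]; s2 <- slots[[jj[2]]]
    res <- merge_roots(s1$species, s2$species, store)
    store <<- res$store
    store <<- add_label(store, res$root, s1$name, "species")
    store <<- add_synonym(store, s1$name, res$root)
    leaves1 <- if (length(s1$ssp)) s1$ssp else s1$species
    leaves2 <- if (length(s2$ssp)) s2$ssp else s2$species
    slots[[jj[1]]] <<- list(species = res$root, ssp = c(leaves1, leaves2),
                            genus = s1$genus, epithet = s1$epithet,
                            name = s1$name)
    slots[[jj[2]]] <<- NULL
  }

  ev_rename <- function() {
    j <- pick1(seq_along(slots))
    slot <- slots[[j]]
    slot$genus <- gen_genus()
    slot$name <- paste(slot$genus, slot$epithet)
    store <<- add_label(store, slot$species, slot$name, "species")
    store <<- add_synonym(store, slot$name, slot$species)
    slots[[j]] <<- slot
  }

  ev_elevate <- function() {
    for (j in sample(seq_along(slots))) {
      slot <- slots[[j]]
      if (length(slot$ssp) < 2) next
      root <- treeset_of(store, slot$species)
      ts <- store$treesets[[root]]
      for (vi in seq_along(ts$variants)) {
        ch <- variant_children(ts$variants[[vi]], slot$species)
        # the nominate stays with its species: never elevate the child
        # carrying the species epithet
        direct <- intersect(ch, slot$ssp)
        direct <- direct[vapply(direct, function(x)
          epithets[[x]] != slot$epithet, logical(1))]
        if (length(ch) >= 2 && length(direct) >= 1) {
          leaf <- pick1(direct)
          new_name <- paste(slot$genus, epithets[[leaf]])
          res <- elevate(leaf, store, species_name = new_name,
                         residual_name = slot$name, variant = vi)
          store <<- res$store
          remaining <- setdiff(slot$ssp, leaf)
          if (identical(remaining, res$residual_id)) remaining <- character(0)
          slots[[j]] <<- list(species = res$residual_id, ssp = remaining,
                              genus = slot$genus, epithet = slot$epithet,
                              name = slot$name)
          slots[[length(slots) + 1]] <<- list(
            species = leaf, ssp = character(0), genus = slot$genus,
            epithet = epithets[[leaf]], name = new_name)
          return(invisible())
        }
      }
    }
  }

  ev_reassign <- function() {
    roots <- which(vapply(slots, is_root_slot, logical(1)))
    if (length(roots) < 2) return(invisible())
    movable <- function(slot) {
      ts <- store$treesets[[slot$species]]
      if (length(ts$variants) == 0) return(character())
      ch <- variant_children(ts$variants[[1]], slot$species)
      if (length(ch) < 2) return(character())
      direct <- intersect(ch, slot$ssp)
      # the nominate subspecies follows its species name; never move it
      direct[vapply(direct, function(x)
        epithets[[x]] != slot$epithet, logical(1))]
    }
    froms <- roots[vapply(roots, function(j) {
      slot <- slots[[j]]
      length(slot$ssp) >= 2 && length(movable(slot)) >= 1
    }, logical(1))]
    if (length(froms) == 0) return(invisible())
    jf <- pick1(froms)
    others <- setdiff(roots, jf)
    if (length(others) == 0) return(invisible())
    jt <- pick1(others)
    from <- slots[[jf]]; to <- slots[[jt]]
    direct <- movable(from)
    moved <- pick1(direct)
    res <- reassign(moved, from$species, to$species, store)
    store <<- res$store
    store <<- add_label(store, res$a_prime, to$name, "species")
    store <<- add_synonym(store, to$name, res$a_prime)
    store <<- add_label(store, res$b_prime, from$name, "species")
    store <<- add_synonym(store, from$name, res$b_prime)
    to_leaves <- if (length(to$ssp)) to$ssp else to$species
    slots[[jt]] <<- list(species = res$a_prime, ssp = c(to_leaves, moved),
                         genus = to$genus, epithet = to$epithet,
                         name = to$name)
    remaining <- setdiff(from$ssp, moved)
    if (identical(remaining, res$b_prime)) remaining <- character(0)
    slots[[jf]] <<- list(species = res$b_prime, ssp = remaining,
                         genus = from$genus, epithet = from$epithet,
                         name = from$name)
  }

  emit <- function(version) {
    rows <- list()
    truth <- list()
    for (j in seq_along(slots)) {
      slot <- slots[[j]]
      sid <- sprintf("S%02d", j)
      rows[[length(rows) + 1]] <- data.frame(
        taxon_id = sid, scientific_name = slot$name, rank = "species",
        parent_taxon_id = NA_character_, stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(
        taxon_id = sid, scientific_name = slot$name, rank = "species",
        status = "mapped", concept = slot$species, stringsAsFactors = FALSE)
      for (k in seq_along(slot$ssp)) {
        leaf <- slot$ssp[k]
        tri <- paste(slot$name, epithets[[leaf]])
        store <<- add_label(store, leaf, tri, "subspecies")
        uid <- sprintf("%s.%02d", sid, k)
        rows[[length(rows) + 1]] <- data.frame(
          taxon_id = uid, scientific_name = tri, rank = "subspecies",
          parent_taxon_id = sid, stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          taxon_id = uid, scientific_name = tri, rank = "subspecies",
          status = "mapped", concept = leaf, stringsAsFactors = FALSE)
      }
    }
    cl <- checklist("Simulated authority", as.character(version),
                    2000 + version, do.call(rbind, rows))
    tr <- do.call(rbind, truth)
    tr$candidates <- NA_character_
    tr$variant <- NA_integer_
    class(tr) <- c("mapping_result", "data.frame")
    list(checklist = cl, truth = tr)
  }

  checklists <- list()
  truths <- list()
  first <- emit(1)
  checklists[[1]] <- first$checklist
  truths[[1]] <- first$truth
  if (n_versions > 1) {
    for (v in 2:n_versions) {
      if (stats::runif(1) < rates[["split_terminal"]]) ev_split()
      if (stats::runif(1) < rates[["lump"]]) ev_lump()
      if (stats::runif(1) < rates[["rename"]]) ev_rename()
      if (stats::runif(1) < rates[["elevate"]]) ev_elevate()
      if (stats::runif(1) < rates[["reassign"]]) ev_reassign()
      out <- emit(v)
      checklists[[v]] <- out$checklist
      truths[[v]] <- out$truth
    }
  }
  list(store = store, checklists = checklists, truths = truths,
       params = list(n_species = n_species,
                     subspecies_range = subspecies_range,
                     n_versions = n_versions, rates = rates,
                     homonym_rate = homonym_rate, seed = seed))
}
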