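# Small hand-built stores with readable identifiers.

tid <- function(i) sprintf("%016X", as.integer(i))

# A store with the given concepts (named vector id -> kind) and one tree
# set per element of `trees` (list of lists: root + variants as edge maps).
mini_store <- function(kinds, trees = list(), labels = list()) {
  st <- concept_store()
  for (id in names(kinds)) st <- add_concept(st, id, kinds[[id]])
  for (tr in trees) st <- add_treeset(st, tr$root, tr$variants)
  for (lb in labels) st <- add_label(st, lb$id, lb$name, lb$rank)
  st
}

# Two independent polytypic species A (leaves A1, A2) and B (leaves B1-B3).
two_species_store <- function() {
  kinds <- c(stats::setNames("species", tid(1)),
             stats::setNames(rep("subspecies", 2), c(tid(11), tid(12))),
             stats::setNames("species", tid(2)),
             stats::setNames(rep("subspecies", 3), c(tid(21), tid(22), tid(23))))
  mini_store(kinds, trees = list(
    list(root = tid(1),
         variants = list(stats::setNames(list(c(tid(11), tid(12))), tid(1)))),
    list(root = tid(2),
         variants = list(stats::setNames(list(c(tid(21), tid(22), tid(23))),
                                         tid(2))))
  ))
}

simple_record <- function(tid_, name, rank, parent = NA_character_) {
  data.frame(taxon_id = tid_, scientific_name = name, rank = rank,
             parent_taxon_id = parent, stringsAsFactors = FALSE)
}
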