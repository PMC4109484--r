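# Readers and writers: Darwin Core flavoured checklists, mapping tables,
# and the tree-store document.
#
# Checklists are comma-separated UTF-8 text with a header row using Darwin
# Core Taxon terms (taxonID, scientificName, taxonRank, parentNameUsageID,
# vernacularName) preceded by '#key: value' metadata lines (authority,
# version, year, scope). The tree store is a YAML document; it is
# schema-checked on load and reconstructed through the store constructors,
# so structural errors surface with the offending path.

TAXON_RANKS <- c("species", "subspecies", "other")

#' Construct a checklist
#'
#' A checklist is a full snapshot of one authority's published name usages
#' at one version: partial revisions are expected to be expanded by the
#' publisher (or the user) into complete lists before mapping.
#'
#' @param authority publishing authority name.
#' @param version_label version or edition label.
#' @param year publication year.
#' @param records data frame with columns `taxon_id`, `scientific_name`,
#'   `rank` (`species`/`subspecies`/`other`), `parent_taxon_id` (NA for
#'   top-level rows) and optionally `vernacular`.
#' @param scope `"global"`, or a character vector of in-scope leaf concept
#'   identifiers for a regional authority.
#' @return An object of class `checklist`.
#' @export
checklist <- function(authority, version_label, year, records, scope = "global") {
  stopifnot(is.data.frame(records))
  needed <- c("taxon_id", "scientific_name", "rank", "parent_taxon_id")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (!"vernacular" %in% names(records)) records$vernacular <- NA_character_
  records$vernacular[!is.na(records$vernacular) &
                       !nzchar(records$vernacular)] <- NA_character_
  records$taxon_id <- as.character(records$taxon_id)
  records$parent_taxon_id <- as.character(records$parent_taxon_id)
  records$parent_taxon_id[!nzchar(records$parent_taxon_id) |
                            is.na(records$parent_taxon_id)] <- NA_character_
  if (anyDuplicated(records$taxon_id)) {
    stop("duplicate taxonID: ",
         paste(unique(records$taxon_id[duplicated(records$taxon_id)]),
               collapse = ", "))
  }
  bad_rank <- setdiff(unique(records$rank), TAXON_RANKS)
  if (length(bad_rank)) stop("unknown taxonRank: ", paste(bad_rank, collapse = ", "))
  dangling <- setdiff(stats::na.omit(records$parent_taxon_id), records$taxon_id)
  if (length(dangling)) {
    stop("parentNameUsageID not found in checklist: ",
         paste(dangling, collapse = ", "))
  }
  ssp <- records$rank == "subspecies"
  if (any(ssp & is.na(records$parent_taxon_id))) {
    stop("subspecies rows must reference a species row via parentNameUsageID")
  }
  records$canonical_name <- canonicalize_name(records$scientific_name)
  rownames(records) <- NULL
  structure(list(authority = authority, version_label = as.character(version_label),
                 year = as.integer(year), scope = scope, records = records),
            class = "checklist")
}

#' @export
print.checklist <- function(x, ...) {
  cat("<checklist> ", x$authority, " v", x$version_label, " (", x$year, "): ",
      nrow(x$records), " records, scope ",
      if (identical(x$scope, "global")) "global" else
        paste0(length(x$scope), " leaves"), "\n", sep = "")
  invisible(x)
}

#' Read a checklist file
#'
#' @param path path to a comma-separated checklist with Darwin Core header
#'   columns and leading `#key: value` metadata lines.
#' @return A `checklist`.
#' @export
read_checklist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_n <- 0
  meta <- list()
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    meta_n <- meta_n + 1
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- if (meta_n > 0) lines[-seq_len(meta_n)] else lines
  if (length(body) == 0) stop("checklist file has no header row: ", path)
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse ", path, " (after line ", meta_n,
                             "): ", conditionMessage(e))
  )
  needed <- c("taxonID", "scientificName", "taxonRank", "parentNameUsageID")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
  records <- data.frame(
    taxon_id = df$taxonID,
    scientific_name = df$scientificName,
    rank = df$taxonRank,
    parent_taxon_id = df$parentNameUsageID,
    vernacular = if ("vernacularName" %in% names(df)) df$vernacularName else NA_character_,
    stringsAsFactors = FALSE
  )
  scope <- meta$scope
  if (is.null(scope) || identical(scope, "global")) {
    scope <- "global"
  } else {
    scope <- strsplit(scope, ";", fixed = TRUE)[[1]]
  }
  checklist(
    authority = if (is.null(meta$authority)) "unknown" else meta$authority,
    version_label = if (is.null(meta$version)) "1" else meta$version,
    year = if (is.null(meta$year)) NA_integer_ else as.integer(meta$year),
    scope = scope,
    records = records
  )
}

#' Write a checklist file
#'
#' @param x a `checklist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(x, path) {
  stopifnot(inherits(x, "checklist"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("#authority: ", x$authority),
    paste0("#version: ", x$version_label),
    paste0("#year: ", x$year),
    paste0("#scope: ", if (identical(x$scope, "global")) "global" else
      paste(x$scope, collapse = ";"))
  ), con)
  out <- data.frame(
    taxonID = x$records$taxon_id,
    scientificName = x$records$scientific_name,
    taxonRank = x$records$rank,
    parentNameUsageID = ifelse(is.na(x$records$parent_taxon_id), "",
                               x$records$parent_taxon_id),
    vernacularName = ifelse(is.na(x$records$vernacular), "",
                            x$records$vernacular),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a mapping result
#'
#' Columns: taxonID, scientificName, status, conceptID, candidates
#' (semicolon-joined), variant.
#'
#' @param result a `mapping_result` (see [solve_assignment()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(result, path) {
  df <- as.data.frame(result)
  out <- data.frame(
    taxonID = df$taxon_id,
    scientificName = df$scientific_name,
    status = df$status,
    conceptID = ifelse(is.na(df$concept), "", df$concept),
    candidates = ifelse(is.na(df$candidates), "", df$candidates),
    variant = ifelse(is.na(df$variant), "", as.character(df$variant)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a mapping result
#'
#' @param path path written by [write_mapping()].
#' @return A `mapping_result` data frame.
#' @export
read_mapping <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  res <- data.frame(
    taxon_id = df$taxonID,
    scientific_name = df$scientificName,
    status = df$status,
    concept = ifelse(nzchar(df$conceptID), df$conceptID, NA_character_),
    candidates = ifelse(nzchar(df$candidates), df$candidates, NA_character_),
    variant = ifelse(nzchar(df$variant), df$variant, NA_character_),
    stringsAsFactors = FALSE
  )
  class(res) <- c("mapping_result", "data.frame")
  res
}

#' Save a concept store
#'
#' Serializes the full store (concepts, labels, synonyms, tree sets,
#' hybrids) as a YAML document. Tables are written in sorted order so that
#' identical stores produce byte-identical files.
#'
#' @param store a `concept_store`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "concept_store"))
  srt <- function(df, cols) {
    if (nrow(df) == 0) return(df)
    df[do.call(order, df[cols]), , drop = FALSE]
  }
  concepts <- srt(store$concepts, "id")
  labels <- srt(store$labels, c("concept", "name", "rank"))
  synonyms <- srt(store$synonyms, c("name", "concept"))
  hybrids <- srt(store$hybrids, "id")
  doc <- list(
    concepts = unname(apply(concepts, 1, as.list)),
    labels = unname(apply(labels, 1, as.list)),
    synonyms = unname(apply(synonyms, 1, as.list)),
    treesets = lapply(unname(store$treesets[sort(names(store$treesets))]),
                      function(ts) {
                        list(root = ts$root,
                             variants = lapply(ts$variants, function(v) {
                               normalize_edges(v$edges)
                             }))
                      }),
    hybrids = unname(apply(hybrids, 1, as.list))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load a concept store
#'
#' The document is schema-checked field by field and rebuilt through the
#' store constructors, so any structural problem (duplicate identifiers,
#' an id in two tree sets, references to unknown ids) is reported with the
#' offending path.
#'
#' @param path path to a document written by [save_store()].
#' @return A `concept_store`.
#' @export
load_store <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- yaml::read_yaml(path)
  need_field <- function(x, field, where) {
    if (is.null(x[[field]])) stop("store schema error at ", where,
                                  ": missing '", field, "'")
    x[[field]]
  }
  store <- concept_store()
  for (i in seq_along(doc$concepts)) {
    cc <- doc$concepts[[i]]
    store <- tryCatch(
      add_concept(store, need_field(cc, "id", paste0("concepts[", i, "]")),
                  need_field(cc, "kind", paste0("concepts[", i, "]"))),
      error = function(e) stop("store schema error at concepts[", i, "]: ",
                               conditionMessage(e))
    )
  }
  for (i in seq_along(doc$treesets)) {
    tsd <- doc$treesets[[i]]
    root <- need_field(tsd, "root", paste0("treesets[", i, "]"))
    variants <- if (is.null(tsd$variants)) list() else tsd$variants
    store <- tryCatch(
      add_treeset(store, root, variants),
      error = function(e) stop("store schema error at treesets[", i, "]: ",
                               conditionMessage(e))
    )
  }
  for (i in seq_along(doc$labels)) {
    lb <- doc$labels[[i]]
    store <- tryCatch(
      add_label(store, need_field(lb, "concept", paste0("labels[", i, "]")),
                need_field(lb, "name", paste0("labels[", i, "]")),
                need_field(lb, "rank", paste0("labels[", i, "]"))),
      error = function(e) stop("store schema error at labels[", i, "]: ",
                               conditionMessage(e))
    )
  }
  for (i in seq_along(doc$synonyms)) {
    sy <- doc$synonyms[[i]]
    lang <- if (is.null(sy$language) || is.na(sy$language)) NA_character_ else sy$language
    store <- tryCatch(
      add_synonym(store, need_field(sy, "name", paste0("synonyms[", i, "]")),
                  need_field(sy, "concept", paste0("synonyms[", i, "]")),
                  need_field(sy, "name_type", paste0("synonyms[", i, "]")),
                  lang),
      error = function(e) stop("store schema error at synonyms[", i, "]: ",
                               conditionMessage(e))
    )
  }
  for (i in seq_along(doc$hybrids)) {
    hy <- doc$hybrids[[i]]
    comps <- strsplit(need_field(hy, "components", paste0("hybrids[", i, "]")),
                      ";", fixed = TRUE)[[1]]
    store <- tryCatch(
      add_hybrid(store, need_field(hy, "id", paste0("hybrids[", i, "]")), comps),
      error = function(e) stop("store schema error at hybrids[", i, "]: ",
                               conditionMessage(e))
    )
  }
  store
}

#' Read a scope file (one leaf concept identifier per line)
#'
#' @param path text file; blank lines and `#` comments ignored.
#' @return Character vector of leaf identifiers.
#' @export
read_scope <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
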