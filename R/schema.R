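## Fixed domain knowledge: the 14 entity types, 5 relation labels, the
## entity-entity relation map, and the 22-question staging catalogue.
## All four are shipped as plain-text data files under
## inst/extdata/schema/ and can be overridden (CLI --schema) by pointing
## at a directory with the same file names.

.schema_env <- new.env(parent = emptyenv())

#' Load the extraction schema
#'
#' Reads the entity-type table, the admissible-relation map, the staging
#' question catalogue and the surface-form lexicon from a schema
#' directory. The default directory shipped with the package encodes the
#' published task definition: 14 entity types, the relations
#' At/SizeOf/Related/Negate (plus NoRelation), and 22 questions.
#'
#' @param path directory containing `entity_types.tsv`,
#'   `relation_map.json`, `questions.tsv` and `lexicon.json`. Default:
#'   the schema shipped with the package.
#' @return an object of class `ie_schema`: a list with elements
#'   `entity_types` (data.frame), `relation_types` (character),
#'   `relation_map` (named list of 2-column matrices), `questions`
#'   (data.frame) and `lexicon` (named list of character vectors).
#' @export
load_schema <- function(path = NULL) {
  if (is.null(path)) path <- ctstager_file("extdata", "schema")
  ents <- utils::read.delim(file.path(path, "entity_types.tsv"),
                            stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(ents) != 14L) stopf("schema must define exactly 14 entity types, got %d", nrow(ents))
  if (anyDuplicated(ents$name)) stopf("duplicated entity type names in schema")

  rmap <- jsonlite::fromJSON(file.path(path, "relation_map.json"),
                             simplifyMatrix = TRUE)
  rmap <- lapply(rmap, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "character"
    m
  })
  rel_types <- c(names(rmap), "NoRelation")
  if (!setequal(names(rmap), c("At", "SizeOf", "Related", "Negate"))) {
    stopf("relation map must define exactly the relations At, SizeOf, Related, Negate")
  }
  ## validate endpoints and at-most-one-relation-per-pair
  seen <- character()
  for (rt in names(rmap)) {
    m <- rmap[[rt]]
    bad <- setdiff(c(m), ents$name)
    if (length(bad)) stopf("relation map references unknown entity type(s): %s",
                           paste(bad, collapse = ", "))
    keys <- apply(m, 1L, function(p) paste(sort(p), collapse = "|"))
    dup <- intersect(keys, seen)
    if (length(dup)) stopf("entity-type pair has more than one admissible relation: %s", dup[1])
    seen <- c(seen, keys)
  }

  qs <- utils::read.delim(file.path(path, "questions.tsv"),
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          na.strings = "NA")
  if (nrow(qs) != 22L || !identical(qs$id, 1:22)) {
    stopf("question catalogue must contain questions with ids 1..22 in order")
  }
  if (!all(qs$answer_type %in% c("boolean", "numeric", "text"))) {
    stopf("unknown answer_type in question catalogue")
  }

  lex <- lapply(jsonlite::fromJSON(file.path(path, "lexicon.json")), enc2utf8)

  ## fast symmetric lookup table: "A|B" (sorted) -> relation
  edge_env <- new.env(parent = emptyenv())
  for (rt in names(rmap)) {
    m <- rmap[[rt]]
    for (i in seq_len(nrow(m))) {
      assign(paste(sort(m[i, ]), collapse = "|"), rt, envir = edge_env)
    }
  }

  structure(list(entity_types = ents,
                 relation_types = rel_types,
                 relation_map = rmap,
                 questions = qs,
                 lexicon = lex,
                 .edges = edge_env),
            class = "ie_schema")
}

#' Default schema (cached)
#' @return the `ie_schema` shipped with the package.
#' @export
default_schema <- function() {
  if (is.null(.schema_env$schema)) .schema_env$schema <- load_schema()
  .schema_env$schema
}

#' Entity types of the extraction task
#' @param schema an `ie_schema`; default the shipped schema.
#' @return data.frame with columns `name`, `description`, `instance`.
#' @export
entity_types <- function(schema = default_schema()) schema$entity_types

#' Relation labels (four true relations plus NoRelation)
#' @inheritParams entity_types
#' @return character vector of length 5.
#' @export
relation_types <- function(schema = default_schema()) schema$relation_types

#' The admissible relation for a pair of entity types
#'
#' Any two entity types admit at most one true relation; all other pairs
#' are NoRelation. The lookup is symmetric in its arguments and total:
#' unknown edges return "NoRelation", invalid type names are an error.
#'
#' @param type_a,type_b entity type names.
#' @inheritParams entity_types
#' @return one of "At", "SizeOf", "Related", "Negate", "NoRelation".
#' @export
admissible_relation <- function(type_a, type_b, schema = default_schema()) {
  ok <- schema$entity_types$name
  if (!(type_a %in% ok) || !(type_b %in% ok)) {
    stopf("unknown entity type: %s",
          paste(setdiff(c(type_a, type_b), ok), collapse = ", "))
  }
  key <- paste(sort(c(type_a, type_b)), collapse = "|")
  get0(key, envir = schema$.edges, ifnotfound = "NoRelation")
}

#' The 22 staging questions
#'
#' @inheritParams entity_types
#' @return data.frame with columns `id` (1..22), `text`, `answer_type`
#'   (boolean / numeric / text) and `stage_label` (TNM category, NA for
#'   the three diagnosis-only questions 20-22).
#' @export
load_questions <- function(schema = default_schema()) schema$questions

#' All BIO labels for the entity inventory
#' @inheritParams entity_types
#' @return character vector: "O" plus B-/I- for each of the 14 types (29 labels).
#' @export
bio_labels <- function(schema = default_schema()) {
  tys <- schema$entity_types$name
  c("O", as.vector(rbind(paste0("B-", tys), paste0("I-", tys))))
}
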