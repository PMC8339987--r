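## Report and corpus containers. All spans are 0-based, half-open
## character offsets (brat's native convention).

SENT_DELIMS <- c("。", "；", "!", "！", "?", "？", "\n")

#' Create a report object
#'
#' Splits the text into sentences on the Chinese/ASCII terminators
#' (full stop, semicolon, ! ? and newline); delimiters are excluded from
#' the sentence spans.
#'
#' @param doc_id document identifier.
#' @param text full report text (UTF-8).
#' @return object of class `ct_report`: list(doc_id, text, sentences),
#'   where `sentences` is a data.frame with 0-based half-open `start`,`end`.
#' @export
new_report <- function(doc_id, text) {
  text <- enc2utf8(text)
  cs <- if (nzchar(text)) chars(text) else character()
  is_delim <- cs %in% SENT_DELIMS
  starts <- integer(); ends <- integer()
  i <- 1L; n <- length(cs)
  while (i <= n) {
    if (is_delim[i]) { i <- i + 1L; next }
    j <- i
    while (j <= n && !is_delim[j]) j <- j + 1L
    starts <- c(starts, i - 1L); ends <- c(ends, j - 1L)
    i <- j
  }
  structure(list(doc_id = doc_id, text = text,
                 sentences = data.frame(start = starts, end = ends)),
            class = "ct_report")
}

#' @export
print.ct_report <- function(x, ...) {
  cat(sprintf("<ct_report %s: %d chars, %d sentences>\n",
              x$doc_id, nchar(x$text), nrow(x$sentences)))
  invisible(x)
}

## substring by 0-based half-open char offsets
slice_text <- function(text, start, end) substr(text, start + 1L, end)

## index of the sentence fully containing [start, end), or NA
sentence_containing <- function(report, start, end) {
  s <- report$sentences
  idx <- which(s$start <= start & end <= s$end)
  if (length(idx) == 1L) idx else NA_integer_
}

empty_entities <- function() {
  data.frame(id = character(), type = character(),
             start = integer(), end = integer(), text = character(),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = character(), type = character(),
             arg1 = character(), arg2 = character(),
             stringsAsFactors = FALSE)
}

#' Create an annotated document
#'
#' Bundles a report with its entity and relation mention tables, checking
#' every corpus invariant: surfaces match offsets, entities lie within a
#' single sentence and do not overlap, relations link same-sentence
#' entities and carry the admissible relation type for their endpoints.
#'
#' @param report a `ct_report`.
#' @param entities data.frame(id, type, start, end, text).
#' @param relations data.frame(id, type, arg1, arg2).
#' @param schema an `ie_schema`.
#' @return object of class `ct_document`.
#' @export
new_document <- function(report, entities = empty_entities(),
                         relations = empty_relations(),
                         schema = default_schema()) {
  stopifnot(inherits(report, "ct_report"))
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (nrow(entities)) {
    bad <- setdiff(entities$type, schema$entity_types$name)
    if (length(bad)) stopf("unknown entity type(s): %s", paste(bad, collapse = ", "))
    entities$sentence <- NA_integer_
    for (i in seq_len(nrow(entities))) {
      e <- entities[i, ]
      surf <- slice_text(report$text, e$start, e$end)
      if (!identical(surf, e$text)) {
        stopf("corrupt annotation %s: surface %s does not match text slice %s",
              e$id, dQuote(e$text), dQuote(surf), class = "ctstager_corrupt_annotation")
      }
      si <- sentence_containing(report, e$start, e$end)
      if (is.na(si)) {
        stopf("entity %s [%d,%d) crosses a sentence boundary", e$id, e$start, e$end,
              class = "ctstager_corrupt_annotation")
      }
      entities$sentence[i] <- si
    }
    if (anyDuplicated(entities$id)) stopf("duplicated entity ids")
  } else {
    entities$sentence <- integer()
  }
  if (nrow(relations)) {
    et <- stats::setNames(entities$type, entities$id)
    es <- stats::setNames(entities$sentence, entities$id)
    for (i in seq_len(nrow(relations))) {
      r <- relations[i, ]
      if (!(r$arg1 %in% entities$id) || !(r$arg2 %in% entities$id)) {
        stopf("relation %s references unknown entity id", r$id,
              class = "ctstager_corrupt_annotation")
      }
      if (es[[r$arg1]] != es[[r$arg2]]) {
        stopf("relation %s links entities in different sentences", r$id,
              class = "ctstager_schema_violation")
      }
      adm <- admissible_relation(et[[r$arg1]], et[[r$arg2]], schema)
      if (!identical(r$type, adm)) {
        stopf("relation %s: type %s violates the relation map (admissible: %s)",
              r$id, r$type, adm, class = "ctstager_schema_violation")
      }
    }
  }
  structure(list(report = report, entities = entities, relations = relations),
            class = "ct_document")
}

#' @export
print.ct_document <- function(x, ...) {
  cat(sprintf("<ct_document %s: %d entities, %d relations>\n",
              x$report$doc_id, nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

#' Create a corpus (list of annotated documents)
#' @param docs list of `ct_document`.
#' @param answers optional named list of per-report answer sets
#'   (names = doc ids), as produced by the synthetic generator.
#' @return object of class `ct_corpus`.
#' @export
new_corpus <- function(docs, answers = NULL) {
  stopifnot(all(vapply(docs, inherits, logical(1), "ct_document")))
  names(docs) <- vapply(docs, function(d) d$report$doc_id, character(1))
  structure(list(docs = docs, answers = answers), class = "ct_corpus")
}

#' @export
length.ct_corpus <- function(x) length(x$docs)

#' @export
print.ct_corpus <- function(x, ...) {
  ne <- sum(vapply(x$docs, function(d) nrow(d$entities), integer(1)))
  nr <- sum(vapply(x$docs, function(d) nrow(d$relations), integer(1)))
  cat(sprintf("<ct_corpus: %d reports, %d entities, %d relations%s>\n",
              length(x$docs), ne, nr,
              if (!is.null(x$answers)) ", with gold answers" else ""))
  invisible(x)
}

#' Split a corpus into train / validation / test sets
#'
#' Report-granular, deterministic for a fixed seed, exhaustive and
#' disjoint. The default fractions follow the published 70/10/20 split.
#'
#' @param corpus a `ct_corpus`.
#' @param fractions length-3 numeric summing to 1.
#' @param seed integer seed.
#' @return named list of three `ct_corpus`: train, validation, test.
#' @export
split_corpus <- function(corpus, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(inherits(corpus, "ct_corpus"))
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stopf("fractions must be three numbers summing to 1")
  }
  n <- length(corpus$docs)
  if (n < 3L) stopf("insufficient data: corpus has %d < 3 reports", n,
                    class = "ctstager_insufficient_data")
  old <- .Random.seed_exists()
  set.seed(seed)
  perm <- sample.int(n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  cuts <- floor(cumsum(fractions) * n)
  sizes <- diff(c(0L, cuts))
  idx <- split(perm, rep.int(seq_len(3L), sizes))
  take <- function(i) {
    ids <- names(corpus$docs)[sort(idx[[as.character(i)]] %||% integer())]
    new_corpus(corpus$docs[ids],
               answers = if (!is.null(corpus$answers)) corpus$answers[ids])
  }
  out <- lapply(1:3, take)
  names(out) <- c("train", "validation", "test")
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
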