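## brat standoff I/O (T-lines for entities, R-lines for relations) and
## character-level BIO conversion. Only T/R records are supported;
## attribute (A), event (E) and discontinuous spans are out of scope.

#' Parse a brat standoff document
#'
#' @param txt_content report text.
#' @param ann_content content of the matching `.ann` file ("" for none).
#' @param doc_id document id.
#' @param schema an `ie_schema` used to validate entity and relation types.
#' @return a `ct_document`.
#' @export
read_brat <- function(txt_content, ann_content, doc_id = "doc",
                      schema = default_schema()) {
  report <- new_report(doc_id, txt_content)
  lines <- strsplit(enc2utf8(ann_content), "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  ents <- list(); rels <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    id <- fields[1]
    if (startsWith(id, "T")) {
      if (length(fields) < 3L) stopf("malformed T-line: %s", ln,
                                     class = "ctstager_corrupt_annotation")
      meta <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      if (length(meta) != 3L) stopf("malformed T-line (need 'Type start end'): %s", ln,
                                    class = "ctstager_corrupt_annotation")
      ents[[length(ents) + 1L]] <- data.frame(
        id = id, type = meta[1],
        start = as.integer(meta[2]), end = as.integer(meta[3]),
        text = fields[3], stringsAsFactors = FALSE)
    } else if (startsWith(id, "R")) {
      meta <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      if (length(meta) != 3L || !startsWith(meta[2], "Arg1:") ||
          !startsWith(meta[3], "Arg2:")) {
        stopf("malformed R-line: %s", ln, class = "ctstager_corrupt_annotation")
      }
      rels[[length(rels) + 1L]] <- data.frame(
        id = id, type = meta[1],
        arg1 = sub("^Arg1:", "", meta[2]), arg2 = sub("^Arg2:", "", meta[3]),
        stringsAsFactors = FALSE)
    } else {
      stopf("unsupported brat record (only T/R lines handled): %s", ln,
            class = "ctstager_corrupt_annotation")
    }
  }
  entities <- if (length(ents)) do.call(rbind, ents) else empty_entities()
  relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  new_document(report, entities, relations, schema = schema)
}

#' Serialize a document to brat standoff
#' @param doc a `ct_document`.
#' @return list(txt = report text, ann = standoff annotation content).
#' @export
write_brat <- function(doc) {
  stopifnot(inherits(doc, "ct_document"))
  e <- doc$entities; r <- doc$relations
  tl <- if (nrow(e)) sprintf("%s\t%s %d %d\t%s", e$id, e$type, e$start, e$end, e$text)
  rl <- if (nrow(r)) sprintf("%s\t%s Arg1:%s Arg2:%s", r$id, r$type, r$arg1, r$arg2)
  list(txt = doc$report$text,
       ann = paste0(paste(c(tl, rl), collapse = "\n"),
                    if (nrow(e) + nrow(r) > 0) "\n" else ""))
}

#' Write a corpus as .txt/.ann file pairs
#'
#' @param corpus a `ct_corpus`.
#' @param dir output directory (created if missing). If the corpus carries
#'   gold answer sets they are written to `answers.tsv` alongside.
#' @return `dir`, invisibly.
#' @export
write_brat_dir <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus$docs) {
    out <- write_brat(doc)
    id <- doc$report$doc_id
    writeLines(out$txt, file.path(dir, paste0(id, ".txt")), useBytes = TRUE)
    cat(out$ann, file = file.path(dir, paste0(id, ".ann")))
  }
  if (!is.null(corpus$answers)) {
    write_answers(corpus$answers, file.path(dir, "answers.tsv"))
  }
  invisible(dir)
}

#' Read a corpus of .txt/.ann pairs
#' @param dir directory holding `<doc>.txt` / `<doc>.ann` pairs.
#' @param schema an `ie_schema`.
#' @return a `ct_corpus` (with answers when `answers.tsv` is present).
#' @export
read_brat_dir <- function(dir, schema = default_schema()) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, function(f) {
    id <- sub("\\.txt$", "", basename(f))
    annf <- file.path(dir, paste0(id, ".ann"))
    txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    ann <- if (file.exists(annf)) {
      paste(readLines(annf, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    } else ""
    read_brat(txt, ann, doc_id = id, schema = schema)
  })
  ansf <- file.path(dir, "answers.tsv")
  new_corpus(docs, answers = if (file.exists(ansf)) read_answers(ansf))
}

#' Character-level BIO labels for one sentence
#'
#' @param doc a `ct_document`.
#' @param sentence_index 1-based sentence index.
#' @return list(tokens = characters, labels = BIO labels).
#' @export
to_bio <- function(doc, sentence_index) {
  s <- doc$report$sentences
  if (sentence_index < 1L || sentence_index > nrow(s)) {
    stopf("sentence %d does not exist", sentence_index)
  }
  st <- s$start[sentence_index]; en <- s$end[sentence_index]
  toks <- chars(slice_text(doc$report$text, st, en))
  labels <- rep("O", length(toks))
  e <- doc$entities[doc$entities$sentence == sentence_index, , drop = FALSE]
  if (nrow(e) > 1L) {
    e <- e[order(e$start), ]
    if (any(e$start[-1L] < e$end[-nrow(e)])) {
      stopf("overlapping entities in sentence %d of %s", sentence_index,
            doc$report$doc_id, class = "ctstager_annotation_conflict")
    }
  }
  for (i in seq_len(nrow(e))) {
    a <- e$start[i] - st + 1L; b <- e$end[i] - st
    labels[a] <- paste0("B-", e$type[i])
    if (b >= a + 1L) labels[(a + 1L):b] <- paste0("I-", e$type[i])
  }
  list(tokens = toks, labels = labels)
}

#' Recover entity spans from a BIO label sequence
#'
#' Total after repair: a stray `I-x` that does not continue a `B-x`/`I-x`
#' run is treated as `B-x`.
#'
#' @param labels character vector of BIO labels.
#' @return data.frame(type, start, end) with sentence-local 0-based
#'   half-open spans.
#' @export
from_bio <- function(labels) {
  n <- length(labels)
  out <- list()
  cur_type <- NULL; cur_start <- NA_integer_
  flush <- function(endpos) {
    if (!is.null(cur_type)) {
      out[[length(out) + 1L]] <<- data.frame(
        type = cur_type, start = cur_start, end = endpos,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (lab == "O") { flush(i - 1L); cur_type <- NULL; next }
    tag <- substr(lab, 1L, 1L); ty <- substr(lab, 3L, nchar(lab))
    if (tag == "B" || is.null(cur_type) || !identical(ty, cur_type)) {
      flush(i - 1L)               # stray I-x repaired to B-x here
      cur_type <- ty; cur_start <- i - 1L
    }
  }
  flush(n)
  if (length(out)) do.call(rbind, out) else
    data.frame(type = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
}

#' Export a corpus in CoNLL-style two-column BIO format
#'
#' One character and its label per line separated by a tab; blank line
#' between sentences; `-DOCSTART- <doc_id>` line between documents.
#'
#' @param corpus a `ct_corpus`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (doc in corpus$docs) {
    writeLines(paste0("-DOCSTART- ", doc$report$doc_id), con)
    for (si in seq_len(nrow(doc$report$sentences))) {
      bio <- to_bio(doc, si)
      writeLines(paste(bio$tokens, bio$labels, sep = "\t"), con)
      writeLines("", con)
    }
  }
  invisible(path)
}
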