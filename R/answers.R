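## Answer sets: the per-report answers to the 22 staging questions.
## Booleans for questions 1, 3-19; a numeric greatest dimension in mm for
## question 2 (NA when unknown); free text for questions 20-22 ("" when
## absent).

#' Construct an answer set
#'
#' @param values list of 22 answers indexed by question id; types must
#'   match the catalogue (logical / numeric mm / character).
#' @param schema an `ie_schema`.
#' @return object of class `answer_set` (a named list q1..q22).
#' @export
answer_set <- function(values, schema = default_schema()) {
  qs <- schema$questions
  if (length(values) != 22L) stopf("an answer set has exactly 22 answers")
  names(values) <- paste0("q", qs$id)
  for (i in qs$id) {
    v <- values[[i]]
    ok <- switch(qs$answer_type[i],
                 boolean = is.logical(v) && length(v) == 1L && !is.na(v),
                 numeric = is.numeric(v) && length(v) == 1L,
                 text    = is.character(v) && length(v) == 1L && !is.na(v))
    if (!ok) stopf("answer to question %d must be %s", i, qs$answer_type[i])
  }
  structure(values, class = "answer_set")
}

## empty/default answers: all No / NA / ""
empty_answer_set <- function(schema = default_schema()) {
  qs <- schema$questions
  answer_set(lapply(qs$answer_type, function(t) {
    switch(t, boolean = FALSE, numeric = NA_real_, text = "")
  }), schema)
}

#' @export
print.answer_set <- function(x, ...) {
  fmt <- vapply(seq_along(x), function(i) format_answer(x[[i]]), character(1))
  cat(paste0("Q", seq_along(x), ": ", fmt, collapse = "\n"), "\n")
  invisible(x)
}

format_answer <- function(v) {
  if (is.logical(v)) return(if (v) "Yes" else "No")
  if (is.numeric(v)) return(if (is.na(v)) "NA" else format(v, digits = 15))
  v
}

parse_answer <- function(s, type) {
  switch(type,
         boolean = identical(s, "Yes"),
         numeric = if (identical(s, "NA")) NA_real_ else as.numeric(s),
         text = s)
}

#' Write per-report answer sets to a sidecar TSV
#' @param answers named list (doc id -> `answer_set`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_answers <- function(answers, path) {
  rows <- lapply(names(answers), function(id) {
    a <- answers[[id]]
    data.frame(doc_id = id, question_id = seq_along(a),
               answer = vapply(seq_along(a), function(i) format_answer(a[[i]]),
                               character(1)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an answers sidecar TSV
#' @param path file written by [write_answers()].
#' @param schema an `ie_schema`.
#' @return named list of `answer_set`.
#' @export
read_answers <- function(path, schema = default_schema()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = c("character", "integer", "character"),
                          na.strings = NULL)
  qs <- schema$questions
  out <- lapply(split(df, df$doc_id), function(d) {
    d <- d[order(d$question_id), ]
    answer_set(lapply(qs$id, function(i) parse_answer(d$answer[i], qs$answer_type[i])),
               schema)
  })
  out[unique(df$doc_id)]
}
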