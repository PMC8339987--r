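#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  if (is.null(class)) stop(msg, call. = FALSE)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Split a string into single characters
#'
#' Unicode-aware: one element per character, which is the token unit used
#' throughout (Chinese clinical text is labeled at the character level).
#'
#' @param x a length-1 character string.
#' @return character vector of single characters.
#' @keywords internal
chars <- function(x) {
  if (length(x) != 1L) stopf("chars() expects a single string")
  strsplit(enc2utf8(x), "", fixed = FALSE)[[1]]
}

## numerically stable log(sum(exp(v)))
logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

## column-wise logsumexp of a matrix
col_logsumexp <- function(M) {
  m <- apply(M, 2L, max)
  finite <- is.finite(m)
  out <- m
  if (any(finite)) {
    Ms <- sweep(M[, finite, drop = FALSE], 2L, m[finite], "-")
    out[finite] <- m[finite] + log(colSums(exp(Ms)))
  }
  out
}

## package file helper (works installed and under pkgload)
ctstager_file <- function(...) {
  system.file(..., package = "ctstager", mustWork = TRUE)
}
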