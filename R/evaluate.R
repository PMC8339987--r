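## Metric suite: precision/recall/F1 per class with macro and micro
## aggregation, under exact and inexact span matching for NER, 5-class
## metrics for relation classification, per-question metrics for the
## final answers, and Cohen's kappa for inter-annotator agreement.
## All values are on the 0-100 scale.
##
## The inexact scheme deliberately permits recall above 100%: every
## predicted span overlapping any same-type gold span counts as a match
## and gold mentions are NOT deduplicated, so two partial predictions
## over one gold mention give recall 200% on that instance. This mirrors
## the published behaviour (lymph-node inexact recall of 100.42%).

prf <- function(tp, np, ng) {
  if (np == 0 && ng == 0) return(c(precision = 100, recall = 100, f1 = 100))
  p <- if (np > 0) 100 * tp / np else 0
  r <- if (ng > 0) 100 * tp / ng else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

make_metric_report <- function(per_class_counts) {
  ## per_class_counts: data.frame(class, tp, np, ng)
  pc <- per_class_counts
  m <- t(vapply(seq_len(nrow(pc)), function(i) prf(pc$tp[i], pc$np[i], pc$ng[i]),
                numeric(3)))
  per_class <- cbind(pc, as.data.frame(m))
  macro <- colMeans(m)
  macro["f1"] <- mean(m[, "f1"])    # macro F1 = mean of per-class F1
  micro <- prf(sum(pc$tp), sum(pc$np), sum(pc$ng))
  structure(list(per_class = per_class, macro = macro, micro = micro),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  df <- x$per_class
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f1 <- round(df$f1, digits)
  print(df[, c("class", "precision", "recall", "f1")], row.names = FALSE)
  cat(sprintf("Macroaverage  P %.2f  R %.2f  F1 %.2f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("Microaverage  P %.2f  R %.2f  F1 %.2f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"]))
  invisible(x)
}

## normalize a mention table: doc_id, type, start, end
as_mention_table <- function(x) {
  if (inherits(x, "ct_corpus")) {
    rows <- lapply(x$docs, function(d) {
      if (nrow(d$entities) == 0L) return(NULL)
      cbind(doc_id = d$report$doc_id,
            d$entities[, c("type", "start", "end"), drop = FALSE])
    })
    x <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(x)) x <- data.frame(doc_id = character(), type = character(),
                                    start = integer(), end = integer())
  }
  stopifnot(all(c("doc_id", "type", "start", "end") %in% names(x)))
  x
}

#' NER metrics under exact or inexact span matching
#'
#' Exact: a prediction is a true positive iff its type and span match a
#' gold mention exactly, matched greedily one-to-one in document order.
#' Inexact: every prediction sharing at least one character with any
#' same-type gold mention counts as a match, without deduplicating gold,
#' so recall may exceed 100%.
#'
#' @param gold,pred mention tables (data.frame doc_id/type/start/end) or
#'   `ct_corpus` objects.
#' @param scheme "exact" or "inexact".
#' @return a `metric_report`.
#' @export
ner_metrics <- function(gold, pred, scheme = c("exact", "inexact")) {
  scheme <- match.arg(scheme)
  gold <- as_mention_table(gold); pred <- as_mention_table(pred)
  classes <- sort(unique(c(gold$type, pred$type)))
  counts <- lapply(classes, function(cl) {
    g <- gold[gold$type == cl, , drop = FALSE]
    p <- pred[pred$type == cl, , drop = FALSE]
    tp <- 0
    for (doc in unique(c(g$doc_id, p$doc_id))) {
      gd <- g[g$doc_id == doc, , drop = FALSE]
      pd <- p[p$doc_id == doc, , drop = FALSE]
      gd <- gd[order(gd$start), , drop = FALSE]
      pd <- pd[order(pd$start), , drop = FALSE]
      if (scheme == "exact") {
        used <- rep(FALSE, nrow(gd))
        for (i in seq_len(nrow(pd))) {
          hit <- which(!used & gd$start == pd$start[i] & gd$end == pd$end[i])
          if (length(hit)) { used[hit[1]] <- TRUE; tp <- tp + 1 }
        }
      } else {
        for (i in seq_len(nrow(pd))) {
          if (any(pd$start[i] < gd$end & gd$start < pd$end[i])) tp <- tp + 1
        }
      }
    }
    data.frame(class = cl, tp = tp, np = nrow(p), ng = nrow(g),
               stringsAsFactors = FALSE)
  })
  counts <- if (length(counts)) do.call(rbind, counts) else
    data.frame(class = character(), tp = numeric(), np = numeric(), ng = numeric())
  make_metric_report(counts)
}

#' Relation classification metrics
#'
#' Both arguments are label vectors over the same candidate-pair
#' universe (one gold and one predicted label per pair).
#'
#' @param gold,pred character vectors of relation labels.
#' @param classes label inventory; defaults to the 5 relation labels.
#' @return a `metric_report`.
#' @export
rc_metrics <- function(gold, pred, classes = relation_types()) {
  if (length(gold) != length(pred)) {
    stopf("gold and predicted labels must cover the same pair universe")
  }
  counts <- lapply(classes, function(cl) {
    data.frame(class = cl,
               tp = sum(gold == cl & pred == cl),
               np = sum(pred == cl), ng = sum(gold == cl),
               stringsAsFactors = FALSE)
  })
  make_metric_report(do.call(rbind, counts))
}

#' Question-answering metrics over the 22 questions
#'
#' Per question: boolean answers treat Yes as the positive class;
#' numeric answers count a positive when gold has a value, and a true
#' positive requires an exact value match; text answers likewise require
#' an exact string match, with non-empty gold as positive.
#'
#' @param gold,pred named lists of `answer_set` over the same report set.
#' @param schema an `ie_schema`.
#' @return a `metric_report` with one class per question id.
#' @export
answer_metrics <- function(gold, pred, schema = default_schema()) {
  if (!setequal(names(gold), names(pred))) {
    stopf("gold and predicted answers must cover the same report set")
  }
  qs <- schema$questions
  ids <- names(gold)
  counts <- lapply(qs$id, function(qi) {
    ty <- qs$answer_type[qi]
    tp <- np <- ng <- 0
    for (d in ids) {
      gv <- gold[[d]][[qi]]; pv <- pred[[d]][[qi]]
      if (ty == "boolean") {
        gpos <- isTRUE(gv); ppos <- isTRUE(pv)
      } else if (ty == "numeric") {
        gpos <- !is.na(gv); ppos <- !is.na(pv)
      } else {
        gpos <- nzchar(gv); ppos <- nzchar(pv)
      }
      np <- np + ppos; ng <- ng + gpos
      if (gpos && ppos) {
        ok <- switch(ty, boolean = TRUE,
                     numeric = isTRUE(gv == pv),   # strict value match
                     text = identical(enc2utf8(gv), enc2utf8(pv)))
        tp <- tp + ok
      }
    }
    data.frame(class = sprintf("Q%d", qi), tp = tp, np = np, ng = ng,
               stringsAsFactors = FALSE)
  })
  make_metric_report(do.call(rbind, counts))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two equal-length label sequences.
#' When expected agreement is 1 (both raters constant and identical) the
#' statistic is defined as 1.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return kappa in [-1, 1].
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stopf("label sequences must have equal length")
  if (!length(labels_a)) stopf("empty label sequences")
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev); b <- factor(labels_b, levels = lev)
  po <- mean(a == b)
  pe <- sum(prop.table(table(a)) * prop.table(table(b)))
  if (abs(1 - pe) < 1e-12) return(1.0)
  (po - pe) / (1 - pe)
}
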