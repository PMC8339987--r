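## Relation classification: attention-BiLSTM over entity-marked sentences
## with the relation-sign-constraint (RSC) tag. For each candidate pair
## the single admissible relation for the two entity types is prepended
## to the marked sentence as its first token, turning the 5-way decision
## into an effectively binary one (tag relation vs NoRelation); at
## prediction time the admissibility constraint is additionally applied
## as a hard mask.

#' RC training configuration
#' @param embedding_dim,hidden_units,attention_dim model sizes.
#' @param dropout_rate,learning_rate,batch_size,max_epochs,early_stopping_patience,seed
#'   training controls (early stopping on validation macro-F1).
#' @param rsc_enabled prepend the relation-sign-constraint tag and apply
#'   the admissibility mask at prediction.
#' @return list of class `rc_config`.
#' @export
rc_config <- function(embedding_dim = 100L, hidden_units = 128L,
                      attention_dim = 64L, dropout_rate = 0.5,
                      learning_rate = 0.01, batch_size = 32L,
                      max_epochs = 50L, early_stopping_patience = 5L,
                      seed = 1L, rsc_enabled = TRUE) {
  stopifnot(embedding_dim > 0, hidden_units > 0, attention_dim > 0)
  structure(as.list(environment()), class = "rc_config")
}

#' Enumerate candidate mention pairs within one sentence
#'
#' @param mentions data.frame of mentions of one sentence.
#' @return list of 2-row data.frames; in each pair e1 is the earlier
#'   mention by start offset (all C(n,2) pairs).
#' @export
enumerate_pairs <- function(mentions) {
  m <- as.data.frame(mentions, stringsAsFactors = FALSE)
  n <- nrow(m)
  if (n < 2L) return(list())
  m <- m[order(m$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      out[[length(out) + 1L]] <- m[c(i, j), , drop = FALSE]
    }
  }
  out
}

#' Build an entity-marked RC instance
#'
#' Inserts `<e1>...</e1>` and `<e2>...</e2>` around the two mentions (e1
#' the earlier) and, when RSC is enabled, prepends the admissible
#' relation tag for the two entity types as the first token.
#'
#' @param sentence_text sentence string.
#' @param pair 2-row mention data.frame with sentence-local `start`,`end`.
#' @param rsc_enabled prepend the RSC tag?
#' @param label optional gold label (training data).
#' @param schema an `ie_schema`.
#' @return list of class `rc_instance`: marked_text, tokens (markers and
#'   the tag are atomic), rsc_tag, label, types.
#' @export
build_instance <- function(sentence_text, pair, rsc_enabled = TRUE,
                           label = NULL, schema = default_schema()) {
  stopifnot(nrow(pair) == 2L)
  pair <- pair[order(pair$start), , drop = FALSE]
  if (pair$end[1] > pair$start[2]) {
    stopf("mentions overlap; cannot insert entity markers",
          class = "ctstager_marker_conflict")
  }
  cs <- chars(sentence_text)
  n <- length(cs)
  if (pair$end[2] > n) stopf("pair does not lie within the sentence")
  seg <- function(a, b) if (b >= a + 1L) cs[(a + 1L):b] else character()
  tag <- admissible_relation(pair$type[1], pair$type[2], schema)
  tokens <- c(if (rsc_enabled) tag,
              seg(0L, pair$start[1]),
              "<e1>", seg(pair$start[1], pair$end[1]), "</e1>",
              seg(pair$end[1], pair$start[2]),
              "<e2>", seg(pair$start[2], pair$end[2]), "</e2>",
              seg(pair$end[2], n))
  structure(list(marked_text = paste(tokens, collapse = ""),
                 tokens = tokens, rsc_tag = tag,
                 types = pair$type, label = label),
            class = "rc_instance")
}

## all RC instances of a corpus (gold entities; labels from gold
## relations, NoRelation for unlinked pairs)
rc_corpus_instances <- function(corpus, rsc_enabled = TRUE,
                                schema = default_schema()) {
  out <- list()
  for (doc in corpus$docs) {
    rel_key <- if (nrow(doc$relations)) {
      stats::setNames(doc$relations$type,
                      paste(pmin(doc$relations$arg1, doc$relations$arg2),
                            pmax(doc$relations$arg1, doc$relations$arg2)))
    } else character()
    for (si in unique(doc$entities$sentence)) {
      ments <- doc$entities[doc$entities$sentence == si, , drop = FALSE]
      st <- doc$report$sentences$start[si]
      sent <- slice_text(doc$report$text,
                         st, doc$report$sentences$end[si])
      for (pair in enumerate_pairs(ments)) {
        loc <- pair
        loc$start <- loc$start - st; loc$end <- loc$end - st
        key <- paste(min(pair$id), max(pair$id))
        lab <- unname(rel_key[key])
        if (is.na(lab) || !length(lab)) lab <- "NoRelation"
        out[[length(out) + 1L]] <- build_instance(sent, loc, rsc_enabled,
                                                  label = lab, schema = schema)
      }
    }
  }
  out
}

## gold/pred relation labels over the gold-entity pair universe of two
## corpora that share texts; pairs are matched by entity spans
rc_labels_from_corpora <- function(gold, pred, schema = default_schema()) {
  span_key <- function(doc_id, e1, e2) {
    k1 <- sprintf("%d:%d", e1$start, e1$end); k2 <- sprintf("%d:%d", e2$start, e2$end)
    paste(doc_id, pmin(k1, k2), pmax(k1, k2))
  }
  rel_map <- function(corpus) {
    out <- character()
    for (doc in corpus$docs) {
      r <- doc$relations
      if (!nrow(r)) next
      e <- doc$entities
      rownames(e) <- e$id
      for (i in seq_len(nrow(r))) {
        out[span_key(doc$report$doc_id, e[r$arg1[i], ], e[r$arg2[i], ])] <- r$type[i]
      }
    }
    out
  }
  gmap <- rel_map(gold); pmap <- rel_map(pred)
  gl <- character(); pl <- character()
  for (doc in gold$docs) {
    for (si in unique(doc$entities$sentence)) {
      ments <- doc$entities[doc$entities$sentence == si, , drop = FALSE]
      for (pair in enumerate_pairs(ments)) {
        key <- span_key(doc$report$doc_id, pair[1, ], pair[2, ])
        gl <- c(gl, if (is.na(gmap[key])) "NoRelation" else gmap[[key]])
        pl <- c(pl, if (is.na(pmap[key])) "NoRelation" else pmap[[key]])
      }
    }
  }
  list(gold = gl, pred = pl)
}

rc_build_vocab <- function(instances) {
  ## radix sort: locale-independent (see build_vocab)
  toks <- sort(unique(unlist(lapply(instances, `[[`, "tokens"))),
               method = "radix")
  stats::setNames(seq_along(toks) + 1L, toks)
}

rc_forward <- function(p, ids, config, train = FALSE) {
  X <- p$E[ids, , drop = FALSE]
  mx <- if (train) dropout_mask(nrow(X), ncol(X), config$dropout_rate)
  if (!is.null(mx)) X <- X * mx
  bi <- bilstm_forward(X, p$lstm_f, p$lstm_b)
  at <- attn_forward(bi$H, p$attn)
  ctx <- at$ctx
  mc <- if (train) dropout_mask(1L, length(ctx), config$dropout_rate)
  ctxd <- if (!is.null(mc)) ctx * as.vector(mc) else ctx
  logits <- as.vector(ctxd %*% p$Wo) + p$bo
  list(X = X, bi = bi, at = at, ctx = ctx, ctxd = ctxd, logits = logits,
       mx = mx, mc = mc)
}

rc_backward <- function(p, ids, config, fwd, dlogits) {
  g <- list(Wo = fwd$ctxd %o% dlogits, bo = dlogits)
  dctx <- as.vector(p$Wo %*% dlogits)
  if (!is.null(fwd$mc)) dctx <- dctx * as.vector(fwd$mc)
  ab <- attn_backward(dctx, fwd$at, p$attn)
  g$attn <- ab$grads
  bb <- bilstm_backward(ab$dH, fwd$bi, p$lstm_f, p$lstm_b)
  g$lstm_f <- bb$grads_f; g$lstm_b <- bb$grads_b
  dX <- bb$dX
  if (!is.null(fwd$mx)) dX <- dX * fwd$mx
  g$E <- emb_grad(dX, ids, nrow(p$E))
  g
}

rc_macro_f1 <- function(p, config, ds, classes) {
  pred <- vapply(ds, function(ex) {
    fwd <- rc_forward(p, ex$ids, config, train = FALSE)
    classes[which.max(fwd$logits)]
  }, character(1))
  gold <- vapply(ds, `[[`, character(1), "label")
  unname(rc_metrics(gold, pred, classes)$macro["f1"])
}

#' Train the attention-BiLSTM relation classifier
#'
#' A 5-way classifier (At / SizeOf / Related / Negate / NoRelation); by
#' design, candidate pairs whose entity types admit no relation are
#' excluded from training (they are auto-labeled NoRelation at
#' prediction and would only dilute the NoRelation class).
#'
#' @param instances_train,instances_val lists of `rc_instance` with labels.
#' @param config an `rc_config`.
#' @param schema an `ie_schema`.
#' @param quiet suppress per-epoch progress.
#' @return object of class `rc_model`.
#' @export
train_rc <- function(instances_train, instances_val, config = rc_config(),
                     schema = default_schema(), quiet = TRUE) {
  classes <- relation_types(schema)
  keep <- function(xs) Filter(function(x) x$rsc_tag != "NoRelation", xs)
  tr <- keep(instances_train); va <- keep(instances_val)
  if (!length(tr)) stopf("no trainable instances")
  labs <- vapply(tr, `[[`, character(1), "label")
  if (length(unique(labs)) < 2L) {
    stopf("degenerate training data: a relation classifier needs >= 2 classes",
          class = "ctstager_degenerate_data")
  }
  vocab <- rc_build_vocab(tr)
  set.seed(config$seed)
  d <- config$embedding_dim; H <- config$hidden_units; A <- config$attention_dim
  p <- list(E = init_mat(length(vocab) + 1L, d),
            lstm_f = init_lstm(d, H), lstm_b = init_lstm(d, H),
            attn = list(Wa = init_mat(2L * H, A), ba = rep(0, A),
                        va = stats::runif(A, -0.1, 0.1)),
            Wo = init_mat(2L * H, length(classes)), bo = rep(0, length(classes)))

  to_ids <- function(x) { v <- unname(vocab[x$tokens]); v[is.na(v)] <- 1L; v }
  ds_tr <- lapply(tr, function(x) list(ids = to_ids(x), label = x$label,
                                       y = match(x$label, classes)))
  ds_va <- lapply(va, function(x) list(ids = to_ids(x), label = x$label))

  st <- adam_new(p)
  best <- list(f1 = -Inf, p = p, epoch = 0L)
  history <- numeric(); wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(ds_tr))
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      g <- NULL; loss <- 0
      for (k in idx) {
        ex <- ds_tr[[k]]
        fwd <- rc_forward(p, ex$ids, config, train = TRUE)
        pr <- softmax(fwd$logits)
        loss <- loss - log(max(pr[ex$y], 1e-12))
        dlog <- pr; dlog[ex$y] <- dlog[ex$y] - 1
        g <- acc_grads(g, rc_backward(p, ex$ids, config, fwd, dlog))
      }
      if (!is.finite(loss)) stopf("training diverged: non-finite loss",
                                  class = "ctstager_divergence")
      g <- rapply(g, function(x) x / length(idx), how = "replace")
      up <- adam_step(p, g, st, config$learning_rate)
      p <- up$params; st <- up$state
      i <- i + config$batch_size
    }
    f1 <- if (length(ds_va)) rc_macro_f1(p, config, ds_va, classes) else NA_real_
    history <- c(history, f1)
    if (!quiet) message(sprintf("epoch %d: val macro-F1 %.2f", epoch, f1))
    if (!is.na(f1) && f1 > best$f1 + 1e-9) {
      best <- list(f1 = f1, p = p, epoch = epoch); wait <- 0L
    } else {
      wait <- wait + 1L
      if (!is.na(f1) && wait >= config$early_stopping_patience) break
    }
  }
  if (is.infinite(best$f1)) best$p <- p
  structure(list(params = best$p, config = config, vocab = vocab,
                 classes = classes, history = history,
                 best_epoch = best$epoch, best_val_f1 = best$f1),
            class = "rc_model")
}

#' @export
print.rc_model <- function(x, ...) {
  cat(sprintf("<rc_model%s: best val macro-F1 %.2f (epoch %d)>\n",
              if (x$config$rsc_enabled) " (RSC)" else "", x$best_val_f1,
              x$best_epoch))
  invisible(x)
}

#' Predict the relation label for one instance
#'
#' Pairs whose entity types admit no relation return NoRelation without
#' invoking the model. When RSC is enabled, any prediction outside
#' {admissible tag, NoRelation} is coerced to NoRelation (hard
#' admissibility constraint).
#'
#' @param model an `rc_model`.
#' @param instance an `rc_instance`.
#' @return one of the 5 relation labels.
#' @export
predict_relation <- function(model, instance) {
  if (instance$rsc_tag == "NoRelation") return("NoRelation")
  ids <- unname(model$vocab[instance$tokens]); ids[is.na(ids)] <- 1L
  fwd <- rc_forward(model$params, ids, model$config, train = FALSE)
  lab <- model$classes[which.max(fwd$logits)]
  if (model$config$rsc_enabled && !(lab %in% c(instance$rsc_tag, "NoRelation"))) {
    lab <- "NoRelation"
  }
  lab
}
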