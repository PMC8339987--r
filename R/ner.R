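## Character-level sequence taggers: a bidirectional-LSTM-CRF core and an
## iterated-dilated-CNN-CRF alternative. Inputs are character embeddings
## concatenated with word-segmentation position embeddings
## (single/first/middle/last of the segmented word).

#' NER training configuration
#'
#' Defaults follow standard values for these architectures (the source
#' hyperparameter appendix is not published); every test and example at
#' desk scale passes smaller dimensions explicitly.
#'
#' @param char_embedding_dim,seg_embedding_dim embedding sizes.
#' @param hidden_units LSTM hidden units per direction / CNN filters.
#' @param dropout_rate inverted-dropout rate on embeddings and encoder output.
#' @param learning_rate Adam step size.
#' @param batch_size sentences per gradient step.
#' @param max_epochs,early_stopping_patience early stopping on validation
#'   exact micro-F1.
#' @param seed integer; training is fully deterministic given it.
#' @param dilation_widths,block_repeats ID-CNN block structure (width-3
#'   kernels with these dilations, the block applied this many times with
#'   shared weights).
#' @param char_embeddings optional pre-trained embedding matrix with
#'   characters as rownames; matching rows initialize the character table.
#' @return list of class `ner_config`.
#' @export
ner_config <- function(char_embedding_dim = 100L, seg_embedding_dim = 20L,
                       hidden_units = 128L, dropout_rate = 0.5,
                       learning_rate = 0.01, batch_size = 32L,
                       max_epochs = 50L, early_stopping_patience = 5L,
                       seed = 1L, dilation_widths = c(1L, 1L, 2L),
                       block_repeats = 4L, char_embeddings = NULL) {
  stopifnot(char_embedding_dim > 0, seg_embedding_dim > 0, hidden_units > 0,
            early_stopping_patience >= 1, max_epochs >= 1)
  structure(as.list(environment()), class = "ner_config")
}

## ---- segmentation features ------------------------------------------

#' Build a greedy longest-match segmenter
#'
#' @param words character vector of lexicon words (multi-character words
#'   drive the segmentation; everything else falls out as single
#'   characters).
#' @return function(character vector of tokens) -> integer seg tags
#'   (1 = single, 2 = first, 3 = middle, 4 = last).
#' @export
make_segmenter <- function(words) {
  words <- unique(words[nchar(words) > 1L])
  wset <- new.env(parent = emptyenv())
  for (w in words) assign(w, TRUE, envir = wset)
  maxlen <- if (length(words)) max(nchar(words)) else 1L
  function(toks) {
    n <- length(toks)
    tags <- integer(n)
    i <- 1L
    while (i <= n) {
      hit <- 0L
      for (L in seq.int(min(maxlen, n - i + 1L), 2L)) {
        if (L < 2L) break
        w <- paste(toks[i:(i + L - 1L)], collapse = "")
        if (!is.null(get0(w, envir = wset))) { hit <- L; break }
      }
      if (hit >= 2L) {
        tags[i] <- 2L
        if (hit > 2L) tags[(i + 1L):(i + hit - 2L)] <- 3L
        tags[i + hit - 1L] <- 4L
        i <- i + hit
      } else {
        tags[i] <- 1L
        i <- i + 1L
      }
    }
    tags
  }
}

default_segmenter_words <- function(schema = default_schema()) {
  lex <- schema$lexicon
  c(unlist(lex, use.names = FALSE),
    "肺门", "纵隔", "隆突下", "锁骨上",
    "胸腔", "心包", "肺叶", "上叶", "中叶", "下叶")
}

#' Character features for one sentence
#'
#' @param sentence sentence string.
#' @param vocab named integer vector mapping characters to ids
#'   (id 1 is the unknown character).
#' @param segmenter a function as returned by [make_segmenter()].
#' @return list(char_ids, seg_ids), one entry per character.
#' @export
featurize <- function(sentence, vocab, segmenter) {
  toks <- chars(sentence)
  if (!length(toks)) stopf("featurize() expects a non-empty sentence")
  ids <- unname(vocab[toks])
  ids[is.na(ids)] <- 1L
  list(char_ids = ids, seg_ids = segmenter(toks))
}

build_vocab <- function(sentences) {
  ## radix sort: locale-independent ordering, so a model is bit-identical
  ## across sessions and collation settings
  cs <- sort(unique(unlist(lapply(sentences, chars))), method = "radix")
  stats::setNames(seq_along(cs) + 1L, cs)   # id 1 reserved for <unk>
}

## ---- dataset ----------------------------------------------------------

ner_dataset <- function(corpus, vocab, segmenter, label_set) {
  out <- list()
  for (doc in corpus$docs) {
    for (si in seq_len(nrow(doc$report$sentences))) {
      bio <- to_bio(doc, si)
      if (!length(bio$tokens)) next
      fe <- featurize(paste(bio$tokens, collapse = ""), vocab, segmenter)
      out[[length(out) + 1L]] <- list(
        doc_id = doc$report$doc_id, sentence = si,
        char_ids = fe$char_ids, seg_ids = fe$seg_ids,
        gold = match(bio$labels, label_set))
    }
  }
  out
}

## ---- forward/backward for the two architectures ----------------------

init_ner_params <- function(arch, V, config, L) {
  dc <- config$char_embedding_dim; ds <- config$seg_embedding_dim
  H <- config$hidden_units
  E_char <- init_mat(V, dc)
  if (!is.null(config$char_embeddings)) {
    pre <- config$char_embeddings
    stopifnot(ncol(pre) == dc)
    ## vocab rows are filled where the external table knows the character
  }
  p <- list(E_char = E_char, E_seg = init_mat(4L, ds))
  D <- dc + ds
  if (arch == "bilstm_crf") {
    p$lstm_f <- init_lstm(D, H); p$lstm_b <- init_lstm(D, H)
    p$Wp <- init_mat(2L * H, L)
  } else {
    p$conv0 <- init_conv(D, H)
    p$block <- list(c1 = init_conv(H, H), c2 = init_conv(H, H), c3 = init_conv(H, H))
    p$Wp <- init_mat(H, L)
  }
  p$bp <- rep(0, L)
  p$crf <- list(transitions = matrix(0, L, L), start = rep(0, L), stop = rep(0, L))
  p
}

ner_encode <- function(p, arch, ex, config, train = FALSE) {
  X <- cbind(p$E_char[ex$char_ids, , drop = FALSE],
             p$E_seg[ex$seg_ids, , drop = FALSE])
  mx <- if (train) dropout_mask(nrow(X), ncol(X), config$dropout_rate)
  if (!is.null(mx)) X <- X * mx
  if (arch == "bilstm_crf") {
    bi <- bilstm_forward(X, p$lstm_f, p$lstm_b)
    H <- bi$H; enc <- bi
  } else {
    dil <- config$dilation_widths; R <- config$block_repeats
    c0 <- conv_forward(X, p$conv0, 1L)
    h <- c0$A
    blocks <- vector("list", R)
    for (r in seq_len(R)) {
      s1 <- conv_forward(h, p$block$c1, dil[1]); s2 <- conv_forward(s1$A, p$block$c2, dil[2])
      s3 <- conv_forward(s2$A, p$block$c3, dil[3])
      blocks[[r]] <- list(s1 = s1, s2 = s2, s3 = s3)
      h <- s3$A
    }
    H <- h; enc <- list(c0 = c0, blocks = blocks)
  }
  mh <- if (train) dropout_mask(nrow(H), ncol(H), config$dropout_rate)
  Hd <- if (!is.null(mh)) H * mh else H
  em <- sweep(Hd %*% p$Wp, 2L, p$bp, "+")
  list(X = X, H = H, Hd = Hd, emissions = em, enc = enc, mx = mx, mh = mh)
}

ner_backward <- function(p, arch, ex, config, fwd, d_em) {
  dWp <- t(fwd$Hd) %*% d_em
  dbp <- colSums(d_em)
  dHd <- d_em %*% t(p$Wp)
  dH <- if (!is.null(fwd$mh)) dHd * fwd$mh else dHd
  g <- list(Wp = dWp, bp = dbp)
  if (arch == "bilstm_crf") {
    bb <- bilstm_backward(dH, fwd$enc, p$lstm_f, p$lstm_b)
    dX <- bb$dX
    g$lstm_f <- bb$grads_f; g$lstm_b <- bb$grads_b
  } else {
    dil <- config$dilation_widths
    gb <- NULL
    dh <- dH
    for (r in rev(seq_along(fwd$enc$blocks))) {
      bl <- fwd$enc$blocks[[r]]
      b3 <- conv_backward(dh, bl$s3, p$block$c3, dil[3])
      b2 <- conv_backward(b3$dX, bl$s2, p$block$c2, dil[2])
      b1 <- conv_backward(b2$dX, bl$s1, p$block$c1, dil[1])
      gb <- acc_grads(gb, list(c1 = b1$grads, c2 = b2$grads, c3 = b3$grads))
      dh <- b1$dX
    }
    b0 <- conv_backward(dh, fwd$enc$c0, p$conv0, 1L)
    g$block <- gb; g$conv0 <- b0$grads
    dX <- b0$dX
  }
  if (!is.null(fwd$mx)) dX <- dX * fwd$mx
  dc <- config$char_embedding_dim
  g$E_char <- emb_grad(dX[, seq_len(dc), drop = FALSE], ex$char_ids, nrow(p$E_char))
  g$E_seg <- emb_grad(dX[, (dc + 1L):ncol(dX), drop = FALSE], ex$seg_ids, 4L)
  g
}

as_crf_params <- function(crf, label_set) {
  structure(list(transitions = crf$transitions, start = crf$start,
                 stop = crf$stop, label_set = label_set),
            class = "crf_params")
}

## BIO-validity mask added to transitions/start at decoding time:
## I-x may only follow B-x or I-x
bio_constraint <- function(label_set) {
  L <- length(label_set)
  trans <- matrix(0, L, L)
  start <- rep(0, L)
  ty <- sub("^[BI]-", "", label_set)
  tag <- substr(label_set, 1L, 1L)
  for (j in seq_len(L)) {
    if (tag[j] == "I") {
      ok <- tag %in% c("B", "I") & ty == ty[j]
      trans[!ok, j] <- -1e9
      start[j] <- -1e9
    }
  }
  list(transitions = trans, start = start)
}

## ---- training ---------------------------------------------------------

decode_dataset <- function(p, arch, config, ds, label_set, constrained = TRUE) {
  crfp <- as_crf_params(p$crf, label_set)
  if (constrained) {
    bc <- bio_constraint(label_set)
    crfp$transitions <- crfp$transitions + bc$transitions
    crfp$start <- crfp$start + bc$start
  }
  lapply(ds, function(ex) {
    fwd <- ner_encode(p, arch, ex, config, train = FALSE)
    viterbi_decode(fwd$emissions, crfp)
  })
}

dataset_mentions <- function(ds, labels_list, label_set) {
  rows <- list()
  for (k in seq_along(ds)) {
    labs <- label_set[labels_list[[k]]]
    sp <- from_bio(labs)
    if (nrow(sp)) {
      sp$doc_id <- paste0(ds[[k]]$doc_id, "#", ds[[k]]$sentence)
      rows[[length(rows) + 1L]] <- sp
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), start = integer(), end = integer(),
               doc_id = character())
}

val_micro_f1 <- function(p, arch, config, ds, label_set) {
  pred <- dataset_mentions(ds, decode_dataset(p, arch, config, ds, label_set),
                           label_set)
  gold <- dataset_mentions(ds, lapply(ds, `[[`, "gold"), label_set)
  unname(ner_metrics(gold, pred, "exact")$micro["f1"])
}

#' Train a character-level sequence tagger
#'
#' @param corpus_train,corpus_val `ct_corpus` objects with gold entities.
#' @param config a `ner_config`.
#' @param arch "bilstm_crf" (default) or "idcnn_crf".
#' @param schema an `ie_schema`.
#' @param segmenter optional segmentation function; default: greedy
#'   longest match over the package lexicon.
#' @param quiet suppress per-epoch progress.
#' @return object of class `ner_model` with the best-validation
#'   parameters and the validation-F1 trajectory in `$history`.
#' @export
train_tagger <- function(corpus_train, corpus_val, config = ner_config(),
                         arch = c("bilstm_crf", "idcnn_crf"),
                         schema = default_schema(), segmenter = NULL,
                         quiet = TRUE) {
  arch <- match.arg(arch)
  if (!length(corpus_train$docs)) stopf("empty training corpus")
  label_set <- bio_labels(schema)
  seg_words <- default_segmenter_words(schema)
  segf <- segmenter %||% make_segmenter(seg_words)
  sent_texts <- unlist(lapply(corpus_train$docs, function(d) {
    vapply(seq_len(nrow(d$report$sentences)), function(i)
      slice_text(d$report$text, d$report$sentences$start[i], d$report$sentences$end[i]),
      character(1))
  }))
  vocab <- build_vocab(sent_texts)

  set.seed(config$seed)
  p <- init_ner_params(arch, length(vocab) + 1L, config, length(label_set))
  if (!is.null(config$char_embeddings)) {
    pre <- config$char_embeddings
    hit <- intersect(rownames(pre), names(vocab))
    if (length(hit)) p$E_char[vocab[hit], ] <- pre[hit, , drop = FALSE]
  }

  ds_train <- ner_dataset(corpus_train, vocab, segf, label_set)
  ds_val <- ner_dataset(corpus_val, vocab, segf, label_set)

  st <- adam_new(p)
  best <- list(f1 = -Inf, p = p, epoch = 0L)
  history <- numeric()
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(ds_train))
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      g <- NULL; loss <- 0
      for (k in idx) {
        ex <- ds_train[[k]]
        fwd <- ner_encode(p, arch, ex, config, train = TRUE)
        crfp <- as_crf_params(p$crf, label_set)
        cg <- crf_loss_grad(fwd$emissions, crfp, ex$gold)
        loss <- loss + cg$loss
        gk <- ner_backward(p, arch, ex, config, fwd, cg$d_emissions)
        gk$crf <- list(transitions = cg$d_transitions, start = cg$d_start,
                       stop = cg$d_stop)
        g <- acc_grads(g, gk)
      }
      if (!is.finite(loss)) stopf("training diverged: non-finite loss",
                                  class = "ctstager_divergence")
      g <- rapply(g, function(x) x / length(idx), how = "replace")
      up <- adam_step(p, g, st, config$learning_rate)
      p <- up$params; st <- up$state
      i <- i + config$batch_size
    }
    f1 <- if (length(ds_val)) val_micro_f1(p, arch, config, ds_val, label_set) else NA_real_
    history <- c(history, f1)
    if (!quiet) message(sprintf("epoch %d: val exact micro-F1 %.2f", epoch, f1))
    if (!is.na(f1) && f1 > best$f1 + 1e-9) {
      best <- list(f1 = f1, p = p, epoch = epoch); wait <- 0L
    } else {
      wait <- wait + 1L
      if (!is.na(f1) && wait >= config$early_stopping_patience) break
    }
  }
  if (is.infinite(best$f1)) best$p <- p
  structure(list(arch = arch, params = best$p, config = config, vocab = vocab,
                 seg_words = seg_words, label_set = label_set,
                 history = history, best_epoch = best$epoch,
                 best_val_f1 = best$f1),
            class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat(sprintf("<ner_model %s: |V|=%d, best val exact micro-F1 %.2f (epoch %d)>\n",
              x$arch, length(x$vocab), x$best_val_f1, x$best_epoch))
  invisible(x)
}

#' Predict entity mentions for a report
#'
#' Decodes every sentence with the BIO-constrained Viterbi path and maps
#' sentence-local spans to document offsets.
#'
#' @param model a `ner_model`.
#' @param doc a `ct_document` or `ct_report`.
#' @return entity table (id, type, start, end, text).
#' @export
predict_entities <- function(model, doc) {
  report <- if (inherits(doc, "ct_document")) doc$report else doc
  segf <- make_segmenter(model$seg_words)
  crfp <- as_crf_params(model$params$crf, model$label_set)
  bc <- bio_constraint(model$label_set)
  crfp$transitions <- crfp$transitions + bc$transitions
  crfp$start <- crfp$start + bc$start
  rows <- list()
  for (si in seq_len(nrow(report$sentences))) {
    st <- report$sentences$start[si]; en <- report$sentences$end[si]
    sent <- slice_text(report$text, st, en)
    if (!nchar(sent)) next
    ex <- featurize(sent, model$vocab, segf)
    fwd <- ner_encode(model$params, model$arch, ex, model$config, train = FALSE)
    path <- viterbi_decode(fwd$emissions, crfp)
    sp <- from_bio(model$label_set[path])
    if (nrow(sp)) {
      sp$start <- sp$start + st; sp$end <- sp$end + st
      sp$text <- vapply(seq_len(nrow(sp)), function(i)
        slice_text(report$text, sp$start[i], sp$end[i]), character(1))
      rows[[length(rows) + 1L]] <- sp
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), start = integer(), end = integer(),
               text = character())
  out$id <- if (nrow(out)) paste0("T", seq_len(nrow(out))) else character()
  out[, c("id", "type", "start", "end", "text")]
}

#' Model checkpoint I/O (single serialized file with config embedded)
#' @param model a `ner_model` or `rc_model`.
#' @param path file path.
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
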