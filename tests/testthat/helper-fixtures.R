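# Shared fixtures: desk-scale model configs, brute-force CRF oracle,
# small document builders. All corpora are generated in code.

desk_ner_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(char_embedding_dim = 24L, seg_embedding_dim = 8L, hidden_units = 24L,
         dropout_rate = 0.1, learning_rate = 0.01, batch_size = 8L,
         max_epochs = 15L, early_stopping_patience = 3L, seed = seed),
    list(...))
  do.call(ner_config, args)
}

desk_rc_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(embedding_dim = 24L, hidden_units = 24L, attention_dim = 16L,
         dropout_rate = 0.1, learning_rate = 0.01, batch_size = 8L,
         max_epochs = 15L, early_stopping_patience = 3L, seed = seed),
    list(...))
  do.call(rc_config, args)
}

# independent oracle: exhaustive enumeration over all label paths
brute_force_crf <- function(emissions, params) {
  L <- ncol(emissions); T_ <- nrow(emissions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), T_)))
  scores <- apply(paths, 1L, function(path) {
    s <- params$start[path[1]] + sum(emissions[cbind(seq_len(T_), path)]) +
      params$stop[path[T_]]
    if (T_ > 1L) s <- s + sum(params$transitions[cbind(path[-T_], path[-1])])
    s
  })
  m <- max(scores)
  list(logZ = m + log(sum(exp(scores - m))), best = m,
       best_path = paths[which.max(scores), ])
}

random_crf_instance <- function(max_T = 6L, max_L = 7L) {
  T_ <- sample(seq_len(max_T), 1L)
  L <- sample(2:max_L, 1L)
  params <- crf_params(paste0("L", seq_len(L)))
  params$transitions[] <- stats::rnorm(L * L)
  params$start[] <- stats::rnorm(L)
  params$stop[] <- stats::rnorm(L)
  list(emissions = matrix(stats::rnorm(T_ * L), T_, L), params = params)
}

# one annotated document built by hand (UTF-8 Chinese clinical phrases)
tiny_document <- function(doc_id = "tiny") {
  #        0.......8....13   (chars)
  text <- "右肺下叶见肿块，约25×22mm。双侧胸腔未见积液。"
  ents <- data.frame(
    id = c("T1", "T2", "T3", "T4", "T5", "T6"),
    type = c("Location", "Mass", "Size", "Location", "Negation", "Effusion"),
    start = c(0L, 5L, 9L, 17L, 21L, 23L),
    end = c(4L, 7L, 16L, 21L, 23L, 25L),
    text = c("右肺下叶", "肿块", "25×22mm", "双侧胸腔", "未见", "积液"),
    stringsAsFactors = FALSE)
  rels <- data.frame(
    id = c("R1", "R2", "R3", "R4"),
    type = c("At", "SizeOf", "At", "Negate"),
    arg1 = c("T1", "T3", "T4", "T5"),
    arg2 = c("T2", "T2", "T6", "T6"),
    stringsAsFactors = FALSE)
  new_document(new_report(doc_id, text), ents, rels)
}

# boolean question ids (1, 3..19)
BOOL_QS <- c(1L, 3:19)

answers_match <- function(a, b) {
  vapply(seq_len(22L), function(i) {
    if (is.numeric(a[[i]])) {
      (is.na(a[[i]]) && is.na(b[[i]])) || isTRUE(a[[i]] == b[[i]])
    } else identical(a[[i]], b[[i]])
  }, logical(1))
}
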