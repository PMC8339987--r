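## Rendering: scenario -> annotated report text. Each finding becomes one
## sentence built from templates with lexicon-sampled slots; entity spans
## and relations are tracked while the sentence is assembled, so the gold
## standard is correct by construction.

## A sentence under construction: `parts` is a list of either plain
## strings or list(type=, text=) entity slots; `rels` is a list of
## c(relation, i, j) where i/j index the entity slots in order of
## appearance.
mk_sentence <- function(parts, rels = list()) {
  text <- ""
  ents <- list()
  for (p in parts) {
    if (is.character(p)) {
      text <- paste0(text, p)
    } else {
      st <- nchar(text)
      text <- paste0(text, p$text)
      ents[[length(ents) + 1L]] <- data.frame(
        type = p$type, start = st, end = nchar(text), text = p$text,
        stringsAsFactors = FALSE)
    }
  }
  list(text = text,
       ents = if (length(ents)) do.call(rbind, ents) else
         data.frame(type = character(), start = integer(), end = integer(),
                    text = character(), stringsAsFactors = FALSE),
       rels = rels)
}

ent <- function(type, text) list(type = type, text = text)

side_zh <- function(side) if (side == "left") "左" else "右"     # 左 / 右
lobe_zh <- function(lobe) switch(lobe, upper = "上叶",           # 上叶
                                 middle = "中叶",                # 中叶
                                 lower = "下叶")                 # 下叶

## "右肺下叶基底段"-style lung location
lung_location <- function(side, lobe, config, with_segment = NA) {
  if (is.na(with_segment)) with_segment <- rb(config$render$segment_present)
  paste0(side_zh(side), "肺", lobe_zh(lobe),
         if (with_segment) pick(config$lexicon$Segment) else "")
}

## node-group location surface, e.g. "左肺门及纵隔4、5组"
node_location <- function(node) {
  sz <- if (!is.na(node$side)) side_zh(node$side) else ""
  med <- sort(setdiff(node$stations, c(1L, 7L, 10:14)))
  med_txt <- paste0("纵隔", paste(med, collapse = "、"), "组")
  switch(node$style,
         hilar = paste0(sz, "肺门"),
         mediastinal = paste0(sz, "侧", med_txt),
         merged = paste0(sz, "肺门及", med_txt),
         subcarinal = "隆突下7组",
         supraclavicular = paste0(sz, "锁骨上区"))
}

fmt_cm <- function(v) sub("\\.?0+$", "", sprintf("%.1f", v / 10))

## size surface in mm or cm, one or two dimensions; the unit token is
## occasionally rendered malformed ("m"), which downstream parsing
## defaults back to mm.
size_surface <- function(size_mm, config) {
  r <- config$render
  unit_cm <- rb(r$size_cm)
  unit <- if (unit_cm) "cm" else if (rb(r$size_malformed_unit)) "m" else "mm"
  f <- function(v) if (unit_cm) fmt_cm(v) else as.character(v)
  if (rb(r$size_single_dim) || length(size_mm) < 2L) {
    paste0(f(size_mm[1]), unit)
  } else {
    paste0(f(size_mm[1]), pick(c("×", "x", "*")), f(size_mm[2]), unit)
  }
}

about <- function(config) pick(config$lexicon$AboutMarker)

## primary-tumor sentence (optionally with attached invasions and one
## absorbed satellite)
render_primary <- function(scenario, config, attached_inv, absorbed_sat) {
  lex <- config$lexicon
  prim <- scenario$primary
  parts <- list(ent("Location", lung_location(prim$side, prim$lobe, config)),
                pick(c("见", "可见")),
                ent("Mass", pick(lex$Mass)),
                "，", about(config),
                ent("Size", size_surface(prim$size_mm, config)))
  rels <- list(c("At", 1L, 2L), c("SizeOf", 3L, 2L))
  k <- 3L
  for (sh in prim$shape) {
    parts <- c(parts, "，", list(ent("Shape", sh)))
    k <- k + 1L; rels[[length(rels) + 1L]] <- c("Related", 2L, k)
  }
  if (length(prim$density)) {
    parts <- c(parts, "，呈", list(ent("Density", prim$density)))
    k <- k + 1L; rels[[length(rels) + 1L]] <- c("Related", 2L, k)
  }
  if (length(prim$enhancement)) {
    parts <- c(parts, "，", list(ent("Enhancement", prim$enhancement)))
    k <- k + 1L; rels[[length(rels) + 1L]] <- c("Related", 2L, k)
  }
  for (iv in attached_inv) {
    parts <- c(parts, "，", list(ent(iv$type, iv$surface)))
    k <- k + 1L; rels[[length(rels) + 1L]] <- c("Related", 2L, k)
  }
  if (!is.null(absorbed_sat)) {
    s <- absorbed_sat
    parts <- c(parts, "，",
               list(ent("Location", lung_location(s$side, s$lobe, config))),
               "另见", list(ent("Mass", pick(lex$MassSmall))))
    rels[[length(rels) + 1L]] <- c("At", k + 1L, k + 2L)
    k <- k + 2L
    if (!is.null(s$size_mm)) {
      parts <- c(parts, "，", about(config),
                 list(ent("Size", size_surface(s$size_mm, config))))
      k <- k + 1L
      rels[[length(rels) + 1L]] <- c("SizeOf", k, k - 1L)
    }
  }
  mk_sentence(parts, rels)
}

render_satellite <- function(sat, config) {
  parts <- list(ent("Location", lung_location(sat$side, sat$lobe, config)),
                pick(c("另见", "见")),
                ent("Mass", pick(config$lexicon$MassSmall)))
  rels <- list(c("At", 1L, 2L))
  if (!is.null(sat$size_mm)) {
    parts <- c(parts, "，", about(config),
               list(ent("Size", size_surface(sat$size_mm, config))))
    rels[[length(rels) + 1L]] <- c("SizeOf", 3L, 2L)
  }
  mk_sentence(parts, rels)
}

render_node_group <- function(node, config) {
  lex <- config$lexicon
  if (node$negated) {
    mk_sentence(list(ent("Location", node_location(node)),
                     ent("Negation", pick(lex$Negation)),
                     ent("LymphNode", pick(lex$LymphNode))),
                list(c("At", 1L, 3L), c("Negate", 2L, 3L)))
  } else {
    parts <- list(ent("Location", node_location(node)),
                  pick(c("见", "可见")),
                  ent("LymphNode", pick(lex$LymphNode)))
    rels <- list(c("At", 1L, 2L))
    if (!is.null(node$size_mm)) {
      parts <- c(parts, "，较大", about(config),
                 list(ent("Size", size_surface(node$size_mm, config))))
      rels[[length(rels) + 1L]] <- c("SizeOf", 3L, 2L)
    }
    mk_sentence(parts, rels)
  }
}

## concatenate two rendered sentences into one (shared sentence; cross
## pairs become NoRelation training signal)
combine_sentences <- function(s1, s2) {
  off <- nchar(s1$text) + 1L   # "，" joins them
  e2 <- s2$ents
  if (nrow(e2)) { e2$start <- e2$start + off; e2$end <- e2$end + off }
  r2 <- lapply(s2$rels, function(r) c(r[1], as.integer(r[2]) + nrow(s1$ents),
                                      as.integer(r[3]) + nrow(s1$ents)))
  list(text = paste0(s1$text, "，", s2$text),
       ents = rbind(s1$ents, e2),
       rels = c(s1$rels, r2))
}

invasion_surface <- function(kind, lex) {
  switch(kind,
         bronchus = ent("Bronchus", pick(lex$Bronchus)),
         visceral_pleura = ent("Pleura", pick(lex$PleuraInvasion)),
         great_vessel = ent("Vessel", pick(lex$Vessel)),
         vertebral_body = ent("VertebralBody", pick(lex$VertebralBody)))
}

#' Render a scenario into an annotated report
#'
#' Every latent finding is rendered by a sampled template into one
#' sentence with entity spans and relations consistent with the relation
#' map; negated findings carry a Negation entity linked by Negate;
#' annotation-free distractor sentences are interleaved.
#'
#' @param scenario a `scenario_spec`.
#' @param config a `gen_config`.
#' @param doc_id document id for the resulting report.
#' @return a `ct_document` with gold entities and relations.
#' @export
render_report <- function(scenario, config, doc_id = "doc") {
  lex <- config$lexicon
  r <- config$render

  inv <- lapply(scenario$invasions, function(kind) {
    list(kind = kind, attached = rb(r$attach_invasion),
         surface = invasion_surface(kind, lex))
  })
  attached <- lapply(Filter(function(x) x$attached, inv), function(x)
    list(type = x$surface$type, surface = x$surface$text))
  loose <- Filter(function(x) !x$attached, inv)

  sats <- scenario$satellites
  absorbed <- NULL
  if (length(sats) && rb(r$satellite_in_primary)) {
    absorbed <- sats[[1]]
    sats <- sats[-1]
  }

  sentences <- list(render_primary(scenario, config, attached, absorbed))
  tail_s <- list()
  add <- function(s) tail_s[[length(tail_s) + 1L]] <<- s

  for (s in sats) add(render_satellite(s, config))
  for (x in loose) {
    add(mk_sentence(list("局部", x$surface)))
  }
  if (identical(scenario$paop, "present_hilar")) {
    add(mk_sentence(list(ent("Location", paste0(side_zh(scenario$primary$side), "肺门")),
                         "见", ent("PAOP", pick(lex$PAOP))),
                    list(c("At", 1L, 2L))))
  }

  node_sents <- lapply(scenario$nodes, render_node_group, config = config)
  if (length(node_sents) >= 2L && rb(r$combine_node_sentences)) {
    node_sents <- c(list(combine_sentences(node_sents[[1]], node_sents[[2]])),
                    node_sents[-(1:2)])
  }
  for (s in node_sents) add(s)

  if (identical(scenario$effusion, "present")) {
    loc <- pick(c("右侧胸腔", "左侧胸腔",
                  "双侧胸腔", "心包"))
    add(mk_sentence(list(ent("Location", loc), "见",
                         ent("Effusion", pick(lex$Effusion))),
                    list(c("At", 1L, 2L))))
  } else if (identical(scenario$effusion, "negated")) {
    loc <- pick(c("双侧胸腔", "心包",
                  "胸腔及心包"))
    add(mk_sentence(list(ent("Location", loc),
                         ent("Negation", pick(lex$Negation)),
                         ent("Effusion", pick(lex$Effusion))),
                    list(c("At", 1L, 3L), c("Negate", 2L, 3L))))
  }
  if (isTRUE(scenario$pleural_nodules)) {
    add(mk_sentence(list("另见", ent("Pleura", pick(lex$PleuraNodule)))))
  }

  ## render-only negated findings (pure noise w.r.t. the oracle)
  if (rb(r$negated_mass)) {
    side <- pick(c("left", "right"))
    add(mk_sentence(list(ent("Location", lung_location(side, pick(lobes_for(side)), config)),
                         ent("Negation", pick(lex$Negation)),
                         ent("Mass", pick(lex$MassSmall))),
                    list(c("At", 1L, 3L), c("Negate", 2L, 3L))))
  }
  neg_standalone <- function(etype, surf_pool) {
    mk_sentence(list(ent("Negation", pick(lex$Negation)),
                     ent(etype, pick(surf_pool))),
                list(c("Negate", 1L, 2L)))
  }
  if (rb(r$negated_paop)) add(neg_standalone("PAOP", lex$PAOP))
  if (rb(r$negated_vessel)) add(neg_standalone("Vessel", lex$Vessel))
  if (rb(r$negated_vertebral)) add(neg_standalone("VertebralBody", lex$VertebralBody))
  if (rb(r$negated_pleura)) add(neg_standalone("Pleura", lex$PleuraInvasion))

  ## clean-lung closing sentence (Location + Negation, no relation edge)
  add(mk_sentence(list(ent("Location", pick(lex$CleanLocation)),
                       ent("Negation", pick(lex$Negation)),
                       pick(lex$CleanTail))))

  tail_s <- if (length(tail_s) > 1L) tail_s[sample.int(length(tail_s))] else tail_s

  n_findings <- 1L + length(tail_s)
  n_distract <- max(1L, round(r$distractor_ratio * n_findings))
  distract <- lapply(sample(lex$Distractor, n_distract, replace = n_distract > length(lex$Distractor)),
                     function(d) mk_sentence(list(d)))
  pos <- sort(sample.int(length(tail_s) + n_distract, n_distract))
  merged <- vector("list", length(tail_s) + n_distract)
  merged[pos] <- distract
  merged[setdiff(seq_along(merged), pos)] <- tail_s
  sentences <- c(sentences, merged)

  ## assemble document text and global offsets
  text <- ""
  ents <- list(); rels <- list()
  tcount <- 0L; rcount <- 0L
  for (s in sentences) {
    off <- nchar(text)
    text <- paste0(text, s$text, "。")
    e <- s$ents
    if (nrow(e)) {
      ids <- paste0("T", tcount + seq_len(nrow(e)))
      tcount <- tcount + nrow(e)
      e$id <- ids
      e$start <- e$start + off; e$end <- e$end + off
      ents[[length(ents) + 1L]] <- e[, c("id", "type", "start", "end", "text")]
      for (rl in s$rels) {
        rcount <- rcount + 1L
        rels[[length(rels) + 1L]] <- data.frame(
          id = paste0("R", rcount), type = rl[1],
          arg1 = ids[as.integer(rl[2])], arg2 = ids[as.integer(rl[3])],
          stringsAsFactors = FALSE)
      }
    }
  }
  new_document(new_report(doc_id, text),
               if (length(ents)) do.call(rbind, ents) else empty_entities(),
               if (length(rels)) do.call(rbind, rels) else empty_relations(),
               schema = config$schema)
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given `config$seed`. The returned corpus carries the
#' per-report oracle answer sets.
#'
#' @param config a `gen_config`.
#' @return a `ct_corpus` with gold annotations and `$answers`.
#' @export
generate_corpus <- function(config) {
  set.seed(config$seed)
  docs <- vector("list", config$n_reports)
  answers <- vector("list", config$n_reports)
  ids <- sprintf("report_%04d", seq_len(config$n_reports))
  for (i in seq_len(config$n_reports)) {
    sc <- sample_scenario(config)
    docs[[i]] <- render_report(sc, config, doc_id = ids[i])
    answers[[i]] <- oracle_answers(sc, config$schema)
  }
  names(answers) <- ids
  new_corpus(docs, answers = if (config$n_reports > 0L) answers)
}

#' Entity counts by type over a corpus
#' @param corpus a `ct_corpus`.
#' @return named integer vector (descending).
#' @export
corpus_entity_counts <- function(corpus) {
  tys <- unlist(lapply(corpus$docs, function(d) d$entities$type))
  sort(table(factor(tys, levels = default_schema()$entity_types$name)),
       decreasing = TRUE)
}
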