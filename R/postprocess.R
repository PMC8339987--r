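## Rule-based postprocessing: assembles (entity, relation, entity)
## triples into a per-report finding graph and answers the 22 staging
## questions. The rules reconstruct the published question semantics from
## the question wording; each answer rule lives in a registry entry so
## individual rules can be inspected or overridden.

#' Parse a size surface into millimetres
#'
#' Extracts up to two dimensions split on x-like separators. A `cm` unit
#' multiplies all dimensions by 10; a missing or malformed unit (the
#' source reports contain strings like "14×12m") defaults to millimetres.
#'
#' @param text size surface string, e.g. "25×22mm", "2.5cm".
#' @return list(dims_mm, greatest_mm) or NULL when no number is parsable
#'   (the consuming question then falls back to unanswered).
#' @export
parse_size <- function(text) {
  text <- enc2utf8(text)
  nums <- regmatches(text, gregexpr("[0-9]+(?:\\.[0-9]+)?", text))[[1]]
  if (!length(nums)) return(NULL)
  dims <- as.numeric(nums[seq_len(min(2L, length(nums)))])
  ## unit applies to all dimensions; cm -> mm, anything else (mm, "m",
  ## missing) stays mm
  if (grepl("cm", text, fixed = TRUE)) dims <- round(dims * 10, 6)
  list(dims_mm = dims, greatest_mm = max(dims))
}

#' Parse a location surface
#'
#' Side from the characters for right/left (both present = bilateral, the
#' bilateral marker also counts); lobe from upper/middle/lower adjacent
#' to a lung/lobe word; regions from the hilar / mediastinal / subcarinal
#' / supraclavicular keywords plus the station map; stations from digit
#' groups preceding a station marker.
#'
#' @param text location surface string (may be a partial span).
#' @return list(side, lobe, regions, stations); unknown fields are
#'   "unknown" / empty.
#' @export
parse_location <- function(text) {
  text <- enc2utf8(text)
  has <- function(pat) grepl(pat, text)
  r <- has("右"); l <- has("左"); bi <- has("双")
  side <- if (bi || (r && l)) "bilateral" else if (r) "right" else if (l) "left" else "unknown"
  lobe <- if (has("上叶|肺上|上肺")) "upper"
          else if (has("中叶|肺中|中肺")) "middle"
          else if (has("下叶|肺下|下肺")) "lower"
          else "unknown"
  stations <- integer()
  grp <- regmatches(text, gregexpr("[0-9]+(?:[、,，][0-9]+)*(?=[组区])", text, perl = TRUE))[[1]]
  if (length(grp)) {
    stations <- as.integer(unlist(strsplit(grp, "[、,，]")))
    stations <- stations[stations >= 1 & stations <= 14]
  }
  regions <- character()
  if (has("肺门")) regions <- c(regions, "hilar")
  if (has("纵隔")) regions <- c(regions, "mediastinal")
  if (has("隆突下")) regions <- c(regions, "subcarinal")
  if (has("锁骨上")) regions <- c(regions, "supraclavicular")
  regions <- unique(c(regions, station_region(stations)))
  list(side = side, lobe = lobe, regions = regions, stations = sort(unique(stations)))
}

#' Assemble a finding graph from mentions and relations
#'
#' At triples attach locations, SizeOf sizes, Related attributes and
#' invasions to masses; Negate sets the negated flag. Findings that no
#' relation touches become standalone entries.
#'
#' @param mentions data.frame(id, type, start, end, text).
#' @param relations data.frame(type, arg1, arg2) over those mention ids.
#' @return object of class `finding_graph` with elements `masses`,
#'   `nodes` and `standalone`.
#' @export
assemble_findings <- function(mentions, relations) {
  m <- as.data.frame(mentions, stringsAsFactors = FALSE)
  rel <- as.data.frame(relations, stringsAsFactors = FALSE)
  info <- stats::setNames(split(m, seq_len(nrow(m))), m$id)

  finding_types <- c("Mass", "LymphNode", "Bronchus", "Pleura", "Vessel",
                     "VertebralBody", "Effusion", "PAOP")
  node <- function(row) {
    list(id = row$id, type = row$type, text = row$text, start = row$start,
         location = NULL, size = NULL, negated = FALSE,
         attributes = list(), attached_to = NULL)
  }
  graph <- lapply(info, function(r) node(r[1, ]))

  typeof_id <- stats::setNames(m$type, m$id)
  for (i in seq_len(nrow(rel))) {
    ty <- rel$type[i]; a <- rel$arg1[i]; b <- rel$arg2[i]
    ## orient: the "head" finding is the Mass/LymphNode/negatable side
    if (ty == "At") {
      loc <- if (typeof_id[a] == "Location") a else b
      tgt <- setdiff(c(a, b), loc)
      graph[[tgt]]$location <- info[[loc]]$text
    } else if (ty == "SizeOf") {
      sz <- if (typeof_id[a] == "Size") a else b
      tgt <- setdiff(c(a, b), sz)
      graph[[tgt]]$size <- parse_size(info[[sz]]$text)
    } else if (ty == "Negate") {
      neg <- if (typeof_id[a] == "Negation") a else b
      tgt <- setdiff(c(a, b), neg)
      graph[[tgt]]$negated <- TRUE
    } else if (ty == "Related") {
      mass <- if (typeof_id[a] == "Mass") a else b
      oth <- setdiff(c(a, b), mass)
      graph[[mass]]$attributes <- c(graph[[mass]]$attributes, list(info[[oth]][1, ]))
      graph[[oth]]$attached_to <- mass
    }
  }

  graph_views(graph)
}

## (re)derive the mass/node/standalone views from the flat entry list;
## kept separate so tests can mutate entries and rebuild consistently
graph_views <- function(all) {
  standalone_types <- c("Bronchus", "Pleura", "Vessel", "VertebralBody",
                        "Effusion", "PAOP")
  structure(list(
    masses = Filter(function(g) g$type == "Mass", all),
    nodes = Filter(function(g) g$type == "LymphNode", all),
    standalone = Filter(function(g) g$type %in% standalone_types &&
                          is.null(g$attached_to), all),
    all = all),
    class = "finding_graph")
}

## test/mutation helpers: flip a negation flag or add a fresh non-negated
## finding entry, returning a consistent graph
graph_set_negated <- function(graph, id, negated = TRUE) {
  graph$all[[id]]$negated <- negated
  graph_views(graph$all)
}

graph_add_finding <- function(graph, type, text = type, location = NULL,
                              size = NULL) {
  id <- paste0("X", length(graph$all) + 1L)
  entry <- list(id = id, type = type, text = text,
                start = max(c(0, vapply(graph$all, function(g) g$start, numeric(1)))) + 1000,
                location = location, size = size, negated = FALSE,
                attributes = list(), attached_to = NULL)
  graph$all[[id]] <- entry
  graph_views(graph$all)
}

#' Select the primary tumor from a finding graph
#'
#' The non-negated mass with the largest greatest dimension; ties and
#' size-less graphs fall back to the first-mentioned; NULL when no
#' non-negated mass exists.
#'
#' @param graph a `finding_graph`.
#' @return a mass entry or NULL.
#' @export
select_primary_tumor <- function(graph) {
  ms <- Filter(function(g) !g$negated, graph$masses)
  if (!length(ms)) return(NULL)
  sizes <- vapply(ms, function(g) if (is.null(g$size)) -Inf else g$size$greatest_mm,
                  numeric(1))
  starts <- vapply(ms, function(g) g$start, numeric(1))
  best <- max(sizes)
  cand <- which(sizes == best)
  ms[[cand[which.min(starts[cand])]]]
}

## attribute surfaces of a given entity type attached to a mass, in
## document order
mass_attributes <- function(mass, type) {
  at <- Filter(function(a) a$type == type, mass$attributes)
  if (!length(at)) return(character())
  ord <- order(vapply(at, function(a) a$start, numeric(1)))
  vapply(at[ord], function(a) a$text, character(1))
}

## non-negated findings of a type: standalone entries plus entries
## attached to a non-negated mass
active_findings <- function(graph, type) {
  alive <- Filter(function(g) g$type == type && !g$negated, graph$all)
  Filter(function(g) {
    if (is.null(g$attached_to)) return(TRUE)
    !graph$all[[g$attached_to]]$negated
  }, alive)
}

#' Answer the 22 staging questions from a finding graph
#'
#' Boolean questions default to No absent supporting non-negated
#' findings. Laterality questions compare the node or satellite side with
#' the primary tumor's side; when no primary tumor (or no parsable
#' primary side) exists, side-dependent questions are answered No and a
#' warning is recorded, mirroring the missed-Mass failure mode of
#' pipeline extraction.
#'
#' @param graph a `finding_graph`.
#' @param schema an `ie_schema`.
#' @return an `answer_set`; attribute `warnings` carries rule warnings.
#' @export
answer_questions <- function(graph, schema = default_schema()) {
  warns <- character()
  primary <- select_primary_tumor(graph)
  ploc <- if (!is.null(primary) && !is.null(primary$location)) {
    parse_location(primary$location)
  } else NULL
  pside <- if (!is.null(ploc) && ploc$side %in% c("left", "right")) ploc$side else NA
  oside <- if (!is.na(pside)) (if (pside == "left") "right" else "left") else NA

  has_active <- function(type) length(active_findings(graph, type)) > 0L

  ## lymph-node groups with parsed locations
  live_nodes <- Filter(function(g) !g$negated, graph$nodes)
  nlocs <- lapply(live_nodes, function(g) {
    if (is.null(g$location)) NULL else parse_location(g$location)
  })
  node_q <- function(region, want_side = NULL) {
    if (!is.null(want_side) && is.na(want_side)) return(FALSE)
    any(vapply(nlocs, function(L) {
      if (is.null(L)) return(FALSE)
      region %in% L$regions &&
        (is.null(want_side) ||
           L$side == "bilateral" || identical(L$side, want_side))
    }, logical(1)))
  }
  side_dependent_miss <- function() {
    if (is.na(pside)) {
      warns <<- c(warns, "no primary tumor side available; side-dependent question answered No")
    }
  }

  ## satellite nodules: non-primary, non-negated masses with a location
  sats <- Filter(function(g) !g$negated && !identical(g$id, primary$id %||% ""),
                 graph$masses)
  sat_rel <- vapply(sats, function(g) {
    if (is.null(g$location) || is.na(pside) || is.null(ploc)) return("unknown")
    L <- parse_location(g$location)
    if (!(L$side %in% c("left", "right"))) return("unknown")
    if (L$side != pside) return("contralateral_lobe")
    if (L$lobe != "unknown" && ploc$lobe != "unknown" && L$lobe == ploc$lobe) {
      "same_lobe"
    } else if (L$lobe != "unknown" && ploc$lobe != "unknown") {
      "ipsilateral_other_lobe"
    } else "unknown"
  }, character(1))
  if (length(sats) && (is.na(pside) || is.null(ploc))) side_dependent_miss()

  ## pleura: nodule-style surfaces answer Q18, the rest answer Q4
  pleura <- active_findings(graph, "Pleura")
  pl_nodule <- vapply(pleura, function(g) grepl("结节", g$text), logical(1))

  paop_hilar <- any(vapply(active_findings(graph, "PAOP"), function(g) {
    inloc <- !is.null(g$location) && "hilar" %in% parse_location(g$location)$regions
    insurf <- grepl("肺门", g$text)
    att <- if (!is.null(g$attached_to)) {
      mloc <- graph$all[[g$attached_to]]$location
      !is.null(mloc) && "hilar" %in% parse_location(mloc)$regions
    } else FALSE
    inloc || insurf || att
  }, logical(1)))

  if (is.na(pside)) {
    if (node_q("hilar") || node_q("mediastinal")) side_dependent_miss()
  }

  ans <- answer_set(list(
    !is.null(primary),                                        # Q1
    if (!is.null(primary) && !is.null(primary$size)) primary$size$greatest_mm else NA_real_, # Q2
    has_active("Bronchus"),                                   # Q3
    length(pleura[!pl_nodule]) > 0L,                          # Q4
    paop_hilar,                                               # Q5
    any(sat_rel == "same_lobe"),                              # Q6
    has_active("Vessel"),                                     # Q7
    has_active("VertebralBody"),                              # Q8
    any(sat_rel == "ipsilateral_other_lobe"),                 # Q9
    length(live_nodes) > 0L,                                  # Q10
    node_q("hilar", pside),                                   # Q11
    node_q("mediastinal", pside),                             # Q12
    node_q("subcarinal"),                                     # Q13
    node_q("mediastinal", oside),                             # Q14
    node_q("hilar", oside),                                   # Q15
    node_q("supraclavicular"),                                # Q16
    any(sat_rel == "contralateral_lobe"),                     # Q17
    length(pleura[pl_nodule]) > 0L,                           # Q18
    has_active("Effusion"),                                   # Q19
    if (!is.null(primary)) paste(mass_attributes(primary, "Shape"), collapse = "，") else "",  # Q20
    if (!is.null(primary)) paste(mass_attributes(primary, "Density"), collapse = "，") else "", # Q21
    if (!is.null(primary)) paste(mass_attributes(primary, "Enhancement"), collapse = "，") else "" # Q22
  ), schema)
  attr(ans, "warnings") <- unique(warns)
  ans
}

#' Answer the questions for one annotated document
#' @param doc a `ct_document` (gold or predicted annotations).
#' @param schema an `ie_schema`.
#' @return an `answer_set`.
#' @export
answer_document <- function(doc, schema = default_schema()) {
  answer_questions(assemble_findings(doc$entities, doc$relations), schema)
}

#' Answer the questions for every document of a corpus
#' @param corpus a `ct_corpus`.
#' @param schema an `ie_schema`.
#' @return named list of `answer_set`.
#' @export
answer_corpus <- function(corpus, schema = default_schema()) {
  lapply(corpus$docs, answer_document, schema = schema)
}
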