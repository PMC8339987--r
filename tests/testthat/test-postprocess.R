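# Size/location parsing, finding assembly, the 22-question rule engine.

test_that("parse_size handles units, separators, and malformed input", {
  s <- parse_size("25×22 cm")
  expect_equal(s$dims_mm, c(250, 220))
  expect_equal(s$greatest_mm, 250)
  # malformed unit defaults to millimetres (the sources print "14×12m")
  s <- parse_size("14×12m")
  expect_equal(s$dims_mm, c(14, 12))
  expect_equal(s$greatest_mm, 14)
  expect_equal(parse_size("8mm")$greatest_mm, 8)
  expect_equal(parse_size("2.5cm")$greatest_mm, 25)
  expect_equal(parse_size("约12x10mm")$dims_mm, c(12, 10))
  expect_equal(parse_size("30*18mm")$greatest_mm, 30)
  expect_null(parse_size("大小不详"))
})

test_that("parse_location extracts side, lobe, regions and stations", {
  # partial span still yields side + lobe
  L <- parse_location("右肺下叶基")
  expect_identical(L$side, "right")
  expect_identical(L$lobe, "lower")
  L <- parse_location("左肺门及纵隔4、5组")
  expect_identical(L$side, "left")
  expect_setequal(L$regions, c("hilar", "mediastinal"))
  expect_equal(L$stations, c(4L, 5L))
  L <- parse_location("实性")
  expect_identical(L$side, "unknown")
  expect_identical(L$lobe, "unknown")
  expect_length(L$regions, 0L)
  expect_identical(parse_location("双侧胸腔")$side, "bilateral")
  L <- parse_location("隆突下7组")
  expect_identical(L$regions, "subcarinal")
  expect_identical(parse_location("左锁骨上区")$regions, "supraclavicular")
  # stations imply regions via the station map even without keywords
  expect_true("mediastinal" %in% parse_location("4组")$regions)
})

test_that("station/region map follows the IASLC convention", {
  expect_identical(station_region(c(1, 4, 7, 10)),
                   c("supraclavicular", "mediastinal", "subcarinal", "hilar"))
  expect_error(station_region(15), "1..14")
})

test_that("assemble_findings attaches triples and negation flags", {
  doc <- tiny_document()
  g <- assemble_findings(doc$entities, doc$relations)
  expect_length(g$masses, 1L)
  m <- g$masses[[1]]
  expect_identical(m$location, "右肺下叶")
  expect_equal(m$size$greatest_mm, 25)
  eff <- Filter(function(x) x$type == "Effusion", g$standalone)
  expect_length(eff, 1L)
  expect_true(eff[[1]]$negated)
  expect_identical(eff[[1]]$location, "双侧胸腔")
})

test_that("every gold relation produces exactly one attachment", {
  corpus <- generate_corpus(generator_config(n_reports = 20, seed = 23))
  for (doc in corpus$docs) {
    g <- assemble_findings(doc$entities, doc$relations)
    r <- doc$relations
    n_at <- sum(r$type == "At")
    n_size <- sum(r$type == "SizeOf")
    n_neg <- sum(r$type == "Negate")
    n_rel <- sum(r$type == "Related")
    expect_equal(sum(vapply(g$all, function(x) !is.null(x$location), logical(1))), n_at)
    expect_equal(sum(vapply(g$all, function(x) !is.null(x$size), logical(1))), n_size)
    expect_equal(sum(vapply(g$all, function(x) isTRUE(x$negated), logical(1))), n_neg)
    expect_equal(sum(lengths(lapply(g$all, `[[`, "attributes"))), n_rel)
  }
})

test_that("select_primary_tumor picks the largest non-negated mass", {
  g <- assemble_findings(
    data.frame(id = c("T1", "T2", "T3", "T4"),
               type = c("Mass", "Size", "Mass", "Size"),
               start = c(0, 2, 10, 12), end = c(1, 3, 11, 13),
               text = c("肿块", "25mm", "结节", "8mm")),
    data.frame(type = c("SizeOf", "SizeOf"), arg1 = c("T2", "T4"),
               arg2 = c("T1", "T3")))
  expect_identical(select_primary_tumor(g)$id, "T1")
  # single mass: itself; all-negated: none and Q1 answered No
  g1 <- assemble_findings(
    data.frame(id = "T1", type = "Mass", start = 0, end = 1, text = "肿块"),
    data.frame(type = character(), arg1 = character(), arg2 = character()))
  expect_identical(select_primary_tumor(g1)$id, "T1")
  gneg <- assemble_findings(
    data.frame(id = c("T1", "T2"), type = c("Negation", "Mass"),
               start = c(0, 1), end = c(1, 2), text = c("未见", "肿块")),
    data.frame(type = "Negate", arg1 = "T1", arg2 = "T2"))
  expect_null(select_primary_tumor(gneg))
  expect_false(answer_questions(gneg)$q1)
})

test_that("laterality questions compare node side against the primary", {
  ents <- data.frame(
    id = c("T1", "T2", "T3", "T4"),
    type = c("Location", "Mass", "Location", "LymphNode"),
    start = c(0, 5, 10, 18), end = c(4, 7, 17, 23),
    text = c("右肺下叶", "肿块", "左侧纵隔4组", "肿大淋巴结"))
  rels <- data.frame(type = c("At", "At"), arg1 = c("T1", "T3"),
                     arg2 = c("T2", "T4"))
  a <- answer_questions(assemble_findings(ents, rels))
  expect_true(a$q1)
  expect_true(a$q10)
  expect_false(a$q12)   # ipsilateral (right) mediastinal: no
  expect_true(a$q14)    # contralateral (left) mediastinal: yes
  expect_false(a$q11); expect_false(a$q15)
})

test_that("empty graphs answer No / NA / empty everywhere", {
  g <- assemble_findings(ctstager:::empty_entities()[, 1:5],
                         ctstager:::empty_relations())
  a <- answer_questions(g)
  expect_false(a$q1)
  expect_true(is.na(a$q2))
  for (qi in BOOL_QS) expect_false(a[[qi]])
  expect_identical(a$q20, "")
})

test_that("gold annotations of any scenario reproduce the oracle answers", {
  corpus <- generate_corpus(generator_config(n_reports = 100, seed = 29))
  mismatches <- 0L
  for (id in names(corpus$docs)) {
    got <- answer_document(corpus$docs[[id]])
    mismatches <- mismatches + sum(!answers_match(got, corpus$answers[[id]]))
  }
  expect_equal(mismatches, 0L)
})

test_that("negation dominance: negating a finding never turns No into Yes", {
  corpus <- generate_corpus(generator_config(n_reports = 25, seed = 33))
  set.seed(33)
  checked <- 0L
  for (doc in corpus$docs) {
    g <- assemble_findings(doc$entities, doc$relations)
    before <- answer_questions(g)
    primary_id <- select_primary_tumor(g)$id
    # negating the primary re-anchors laterality; all other findings qualify
    cand <- Filter(function(x) x$type %in% c("Mass", "LymphNode", "Bronchus",
                                             "Pleura", "Vessel", "VertebralBody",
                                             "Effusion", "PAOP") &&
                     !x$negated && !identical(x$id, primary_id), g$all)
    if (!length(cand)) next
    pickid <- cand[[sample.int(length(cand), 1L)]]$id
    after <- answer_questions(ctstager:::graph_set_negated(g, pickid))
    for (qi in BOOL_QS) expect_false(!before[[qi]] && after[[qi]])
    checked <- checked + 1L
  }
  expect_gte(checked, 15L)
})

test_that("monotonicity: adding a supporting finding never turns Yes into No", {
  corpus <- generate_corpus(generator_config(n_reports = 25, seed = 34))
  set.seed(34)
  addable <- list(
    list(type = "Bronchus", text = "支气管狭窄"),
    list(type = "Vessel", text = "大血管受侵"),
    list(type = "Effusion", text = "胸腔积液"),
    list(type = "PAOP", text = "阻塞性肺不张", location = "左肺门"),
    list(type = "Pleura", text = "胸膜结节"),
    list(type = "LymphNode", text = "肿大淋巴结", location = "隆突下7组"))
  for (doc in corpus$docs) {
    g <- assemble_findings(doc$entities, doc$relations)
    before <- answer_questions(g)
    spec <- addable[[sample.int(length(addable), 1L)]]
    g2 <- ctstager:::graph_add_finding(g, spec$type, spec$text,
                                       location = spec$location)
    after <- answer_questions(g2)
    for (qi in BOOL_QS) expect_false(before[[qi]] && !after[[qi]])
  }
})
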