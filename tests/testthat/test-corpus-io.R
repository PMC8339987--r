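# brat standoff I/O, BIO conversion, corpus splitting.

test_that("read_brat parses T-lines with verified offsets", {
  txt <- "右肺下叶基底段见软组织密度肿块。"
  ann <- "T1\tLocation 0 7\t右肺下叶基底段\n"
  doc <- read_brat(txt, ann)
  expect_equal(nrow(doc$entities), 1L)
  expect_identical(doc$entities$type, "Location")
  expect_equal(doc$entities$start, 0L)
  expect_equal(doc$entities$end, 7L)
  expect_identical(doc$entities$text, "右肺下叶基底段")
})

test_that("empty annotation content yields zero mentions", {
  doc <- read_brat("右肺见肿块。", "")
  expect_equal(nrow(doc$entities), 0L)
  expect_equal(nrow(doc$relations), 0L)
})

test_that("corrupt annotations are rejected with informative errors", {
  txt <- "右肺下叶基底段见肿块。"
  expect_error(read_brat(txt, "T1\tLocation 0 7\t左肺上叶尖段\n"),
               class = "ctstager_corrupt_annotation")
  # relation type violating the admissible-relation map
  ann <- paste0("T1\tLocation 0 7\t右肺下叶基底段\n",
                "T2\tMass 8 10\t肿块\n",
                "R1\tSizeOf Arg1:T1 Arg2:T2\n")
  expect_error(read_brat(txt, ann), class = "ctstager_schema_violation")
  # cross-sentence relation
  txt2 <- "右肺下叶见肿块。左肺门见肿大淋巴结。"
  ann2 <- paste0("T1\tLocation 0 4\t右肺下叶\n",
                 "T2\tLymphNode 12 17\t肿大淋巴结\n",
                 "R1\tAt Arg1:T1 Arg2:T2\n")
  expect_error(read_brat(txt2, ann2), class = "ctstager_schema_violation")
})

test_that("write_brat emits one T-line per entity and R-lines naming both args", {
  doc <- tiny_document()
  out <- write_brat(doc)
  lines <- strsplit(out$ann, "\n")[[1]]
  expect_equal(sum(startsWith(lines, "T")), 6L)
  expect_equal(sum(startsWith(lines, "R")), 4L)
  expect_true(any(grepl("^R1\tAt Arg1:T1 Arg2:T2$", lines)))
  # single mention, no relations
  r <- new_report("m", "见肿块。")
  d1 <- new_document(r, data.frame(id = "T1", type = "Mass", start = 1L,
                                   end = 3L, text = "肿块"))
  o1 <- write_brat(d1)
  l1 <- strsplit(o1$ann, "\n")[[1]]
  expect_equal(sum(startsWith(l1, "T")), 1L)
  expect_equal(sum(startsWith(l1, "R")), 0L)
})

test_that("brat round-trip is the identity over a generated corpus", {
  corpus <- generate_corpus(generator_config(n_reports = 50, seed = 21))
  for (doc in corpus$docs) {
    out <- write_brat(doc)
    doc2 <- read_brat(out$txt, out$ann, doc_id = doc$report$doc_id)
    expect_identical(doc2$report$text, doc$report$text)
    expect_identical(doc2$entities, doc$entities)
    expect_identical(doc2$relations, doc$relations)
    # and a second serialization is bit-identical
    expect_identical(write_brat(doc2), out)
  }
})

test_that("brat directory round-trip preserves the corpus and answers", {
  corpus <- generate_corpus(generator_config(n_reports = 10, seed = 3))
  dir <- withr::local_tempdir()
  write_brat_dir(corpus, dir)
  back <- read_brat_dir(dir)
  expect_identical(names(back$docs), names(corpus$docs))
  for (id in names(corpus$docs)) {
    expect_identical(back$docs[[id]]$entities, corpus$docs[[id]]$entities)
    expect_identical(back$docs[[id]]$relations, corpus$docs[[id]]$relations)
  }
  for (id in names(corpus$answers)) {
    expect_true(all(answers_match(back$answers[[id]], corpus$answers[[id]])))
  }
})

test_that("to_bio reproduces the published character-level labeling", {
  txt <- "右肺下叶基底段见软组织密度肿块。"
  ann <- paste0("T1\tLocation 0 7\t右肺下叶基底段\n",
                "T2\tMass 8 15\t软组织密度肿块\n",
                "R1\tAt Arg1:T1 Arg2:T2\n")
  doc <- read_brat(txt, ann)
  bio <- to_bio(doc, 1L)
  expect_identical(bio$labels,
                   c("B-Location", rep("I-Location", 6), "O",
                     "B-Mass", rep("I-Mass", 6)))
  # sentence with no mentions is all O
  doc0 <- read_brat("请结合临床。", "")
  expect_identical(to_bio(doc0, 1L)$labels, rep("O", 5L))
})

test_that("to_bio rejects overlapping entities", {
  r <- new_report("o", "右肺下叶见肿块。")
  # bypass new_document to build the conflict directly
  doc <- tiny_document()
  doc$entities <- rbind(doc$entities,
                        data.frame(id = "T9", type = "Mass", start = 0L, end = 2L,
                                   text = "右肺", sentence = 1L))
  expect_error(to_bio(doc, 1L), class = "ctstager_annotation_conflict")
})

test_that("from_bio inverts to_bio and repairs stray I-labels", {
  expect_identical(from_bio(c("B-Mass", "I-Mass", "O")),
                   data.frame(type = "Mass", start = 0L, end = 2L,
                              stringsAsFactors = FALSE))
  # stray I-x becomes B-x
  expect_identical(from_bio(c("O", "I-Location", "I-Location")),
                   data.frame(type = "Location", start = 1L, end = 3L,
                              stringsAsFactors = FALSE))
  expect_equal(nrow(from_bio(rep("O", 5))), 0L)
  # adjacent entities: B starts a new mention even after I of the same type
  got <- from_bio(c("B-Mass", "I-Mass", "B-Mass"))
  expect_equal(nrow(got), 2L)
})

test_that("BIO round-trip recovers the exact mention set on a generated corpus", {
  corpus <- generate_corpus(generator_config(n_reports = 50, seed = 22))
  for (doc in corpus$docs) {
    for (si in seq_len(nrow(doc$report$sentences))) {
      bio <- to_bio(doc, si)
      got <- from_bio(bio$labels)
      st <- doc$report$sentences$start[si]
      want <- doc$entities[doc$entities$sentence == si,
                           c("type", "start", "end"), drop = FALSE]
      want <- want[order(want$start), , drop = FALSE]
      rownames(want) <- NULL
      got$start <- got$start + st; got$end <- got$end + st
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("write_conll emits two-column character/label lines", {
  corpus <- new_corpus(list(tiny_document()))
  f <- withr::local_tempfile()
  write_conll(corpus, f)
  lines <- readLines(f, encoding = "UTF-8")
  expect_identical(lines[1], "-DOCSTART- tiny")
  expect_identical(lines[2], "右\tB-Location")
  expect_true("" %in% lines)  # sentence separator
})

test_that("split_corpus is exhaustive, disjoint, deterministic, 70/10/20", {
  corpus <- generate_corpus(generator_config(n_reports = 100, seed = 5))
  parts <- split_corpus(corpus, seed = 42)
  expect_equal(lengths(lapply(parts, function(p) p$docs)),
               c(train = 70L, validation = 10L, test = 20L))
  parts2 <- split_corpus(corpus, seed = 42)
  expect_identical(names(parts$train$docs), names(parts2$train$docs))
  for (sd in 1:10) {
    p <- split_corpus(corpus, seed = sd)
    ids <- c(names(p$train$docs), names(p$validation$docs), names(p$test$docs))
    expect_equal(sort(ids), sort(names(corpus$docs)))
    expect_equal(anyDuplicated(ids), 0L)
  }
  small <- new_corpus(corpus$docs[1:2])
  expect_error(split_corpus(small, seed = 1),
               class = "ctstager_insufficient_data")
})
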