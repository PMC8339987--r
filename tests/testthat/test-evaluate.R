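# Metric suite: exact/inexact NER matching, RC and QA metrics, kappa.

mt <- function(doc_id, type, start, end) {
  data.frame(doc_id = doc_id, type = type, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("identical predictions score 100 under both schemes", {
  gold <- mt("d1", c("Mass", "Location"), c(0L, 5L), c(3L, 9L))
  for (scheme in c("exact", "inexact")) {
    r <- ner_metrics(gold, gold, scheme)
    expect_equal(unname(r$micro), c(100, 100, 100))
    expect_true(all(r$per_class$f1 == 100))
  }
})

test_that("a truncated prediction is an exact miss but an inexact hit", {
  # gold 3-char Location vs prediction missing the final character
  gold <- mt("d1", "Location", 0L, 3L)
  pred <- mt("d1", "Location", 0L, 2L)
  ex <- ner_metrics(gold, pred, "exact")
  expect_equal(unname(ex$micro["f1"]), 0)
  inx <- ner_metrics(gold, pred, "inexact")
  expect_equal(unname(inx$micro["precision"]), 100)
  expect_equal(unname(inx$micro["recall"]), 100)
})

test_that("inexact recall can exceed 100% (gold not deduplicated)", {
  gold <- mt("d1", "LymphNode", 0L, 6L)
  pred <- mt("d1", c("LymphNode", "LymphNode"), c(0L, 3L), c(2L, 6L))
  r <- ner_metrics(gold, pred, "inexact")
  expect_equal(unname(r$micro["recall"]), 200)
  expect_equal(unname(r$micro["precision"]), 100)
})

test_that("exact matching is one-to-one: duplicate predictions cost precision", {
  gold <- mt("d1", "Mass", 0L, 2L)
  pred <- mt("d1", c("Mass", "Mass"), c(0L, 0L), c(2L, 2L))
  r <- ner_metrics(gold, pred, "exact")
  expect_equal(unname(r$micro["precision"]), 50)
  expect_equal(unname(r$micro["recall"]), 100)
})

test_that("inexact dominates exact per class on arbitrary prediction sets", {
  set.seed(77)
  types <- c("Mass", "Location", "Size")
  for (rep_ in 1:20) {
    gold <- do.call(rbind, lapply(1:3, function(d) {
      n <- sample(0:5, 1)
      if (n == 0) return(NULL)
      st <- sort(sample(0:40, n)) * 3L
      mt(paste0("d", d), sample(types, n, TRUE), st, st + sample(1:3, n, TRUE))
    }))
    pred <- do.call(rbind, lapply(1:3, function(d) {
      n <- sample(0:5, 1)
      if (n == 0) return(NULL)
      st <- sample(0:120, n)
      mt(paste0("d", d), sample(types, n, TRUE), st, st + sample(1:4, n, TRUE))
    }))
    if (is.null(gold) || is.null(pred)) next
    ex <- ner_metrics(gold, pred, "exact")$per_class
    inx <- ner_metrics(gold, pred, "inexact")$per_class
    expect_identical(ex$class, inx$class)
    expect_true(all(inx$precision >= ex$precision - 1e-9))
    expect_true(all(inx$recall >= ex$recall - 1e-9))
  }
})

test_that("metrics are invariant to mention ordering", {
  gold <- mt("d1", c("Mass", "Location", "Mass"), c(0L, 5L, 10L), c(3L, 9L, 12L))
  pred <- mt("d1", c("Mass", "Location"), c(0L, 6L), c(3L, 9L))
  r1 <- ner_metrics(gold, pred, "exact")
  r2 <- ner_metrics(gold[c(3, 1, 2), ], pred[2:1, ], "exact")
  expect_equal(r1$per_class$f1, r2$per_class$f1)
})

test_that("rc_metrics: per-class, macro as mean of F1s, micro as pooled", {
  classes <- relation_types()
  gold <- c("At", "At", "SizeOf", "Related", "Negate", "NoRelation")
  pred_ok <- gold
  r <- rc_metrics(gold, pred_ok)
  expect_true(all(r$per_class$f1 == 100))
  expect_equal(unname(r$macro["f1"]), 100)
  # make one class (Related) fully wrong
  pred <- gold; pred[gold == "Related"] <- "NoRelation"
  r <- rc_metrics(gold, pred)
  pc <- r$per_class
  # hand computation: Related P=R=F1=0; NoRelation P=1/2,R=1,F1=2/3
  expect_equal(pc$f1[pc$class == "Related"], 0)
  expect_equal(pc$f1[pc$class == "NoRelation"], 200/3, tolerance = 1e-9)
  expect_equal(unname(r$macro["f1"]), mean(c(100, 100, 0, 100, 200/3)),
               tolerance = 1e-9)
  # single-label universe: micro P = micro R
  expect_equal(unname(r$micro["precision"]), unname(r$micro["recall"]))
  expect_error(rc_metrics(gold, pred[-1]), "universe")
})

test_that("micro F1 is the harmonic mean of micro P and R", {
  gold <- mt("d1", c("Mass", "Mass", "Location"), c(0L, 5L, 10L), c(2L, 7L, 12L))
  pred <- mt("d1", c("Mass", "Location", "Location"), c(0L, 10L, 20L), c(2L, 12L, 22L))
  r <- ner_metrics(gold, pred, "exact")
  p <- r$micro["precision"]; rr <- r$micro["recall"]
  expect_equal(unname(r$micro["f1"]), unname(2 * p * rr / (p + rr)))
})

test_that("answer metrics treat booleans, numerics and text correctly", {
  qs <- load_questions()
  mk <- function(q3, q2, q20) {
    a <- lapply(qs$answer_type, function(t)
      switch(t, boolean = FALSE, numeric = NA_real_, text = ""))
    a[[3]] <- q3; a[[2]] <- q2; a[[20]] <- q20
    answer_set(a)
  }
  gold <- list(r1 = mk(TRUE, 25, "分叶状"), r2 = mk(TRUE, 30, ""),
               r3 = mk(TRUE, NA_real_, ""), r4 = mk(TRUE, 12, ""),
               r5 = mk(TRUE, 8, ""))
  pred_same <- gold
  r <- answer_metrics(gold, pred_same)
  expect_true(all(r$per_class$f1 == 100))
  # one missed Yes among 5 positives -> recall 80 on that question
  pred <- gold
  pred$r5 <- mk(FALSE, 8, "")
  r <- answer_metrics(gold, pred)
  expect_equal(r$per_class$recall[r$per_class$class == "Q3"], 80)
  # numeric off by any margin counts wrong
  pred <- gold
  pred$r1 <- mk(TRUE, 26, "分叶状")
  r <- answer_metrics(gold, pred)
  expect_lt(r$per_class$f1[r$per_class$class == "Q2"], 100)
  # text must match exactly
  pred <- gold
  pred$r1 <- mk(TRUE, 25, "边缘见毛刺")
  r <- answer_metrics(gold, pred)
  expect_lt(r$per_class$f1[r$per_class$class == "Q20"], 100)
  expect_error(answer_metrics(gold, gold[1:3]), "report set")
})

test_that("cohen_kappa: identity, chance level, and closed form", {
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1.0)
  # both raters constant and identical: defined as 1
  expect_equal(cohen_kappa(rep("x", 5), rep("x", 5)), 1.0)
  # independent random labels are near zero
  set.seed(8)
  a <- sample(c("x", "y"), 10000, TRUE)
  b <- sample(c("x", "y"), 10000, TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
  # hand-built 2x2 confusion (45/5/5/45): kappa = 0.8
  a <- c(rep("p", 50), rep("n", 50))
  b <- c(rep("p", 45), rep("n", 5), rep("p", 5), rep("n", 45))
  expect_equal(cohen_kappa(a, b), 0.8)
  expect_error(cohen_kappa(c("a"), c("a", "b")), "equal length")
})
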