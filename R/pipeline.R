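## End-to-end pipeline: generate -> split -> train NER -> train RC ->
## predict entities -> predict relations -> answer questions -> evaluate.
## Predicted entities feed the relation classifier and predicted triples
## feed the rule engine (pipeline manner); --use-gold-entities reproduces
## the RC-on-gold evaluation mode.

#' Pipeline configuration
#'
#' @param gen a `gen_config` (corpus to generate).
#' @param ner a `ner_config`.
#' @param rc an `rc_config`.
#' @param arch NER architecture.
#' @param split train/validation/test fractions.
#' @param seed global seed: propagated to the generator, the split and
#'   both model seeds (offset so the streams differ).
#' @param use_gold_entities skip NER and feed gold entities to RC.
#' @param outdir where to write artifacts (brat dirs, answers, metrics,
#'   manifest); default a fresh temporary directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(gen = generator_config(n_reports = 500L),
                            ner = ner_config(), rc = rc_config(),
                            arch = c("bilstm_crf", "idcnn_crf"),
                            split = c(0.7, 0.1, 0.2), seed = 1L,
                            use_gold_entities = FALSE,
                            outdir = tempfile("ctstager_run_")) {
  arch <- match.arg(arch)
  seed <- as.integer(seed)
  gen$seed <- seed
  ner$seed <- seed + 1L
  rc$seed <- seed + 2L
  structure(list(gen = gen, ner = ner, rc = rc, arch = arch, split = split,
                 seed = seed, use_gold_entities = use_gold_entities,
                 outdir = outdir),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

## predict entities + relations for one document, returning a new
## ct_document carrying the predictions
predict_document <- function(doc, ner_model, rc_model, use_gold = FALSE,
                             schema = default_schema()) {
  ents <- if (use_gold) doc$entities[, c("id", "type", "start", "end", "text")]
          else predict_entities(ner_model, doc)
  pred_doc <- new_document(doc$report, ents, schema = schema)
  rels <- list()
  k <- 0L
  for (si in unique(pred_doc$entities$sentence)) {
    ments <- pred_doc$entities[pred_doc$entities$sentence == si, , drop = FALSE]
    st <- pred_doc$report$sentences$start[si]
    sent <- slice_text(pred_doc$report$text, st, pred_doc$report$sentences$end[si])
    for (pair in enumerate_pairs(ments)) {
      loc <- pair; loc$start <- loc$start - st; loc$end <- loc$end - st
      inst <- build_instance(sent, loc, rc_model$config$rsc_enabled, schema = schema)
      lab <- predict_relation(rc_model, inst)
      if (lab != "NoRelation") {
        k <- k + 1L
        rels[[k]] <- data.frame(id = paste0("R", k), type = lab,
                                arg1 = pair$id[1], arg2 = pair$id[2],
                                stringsAsFactors = FALSE)
      }
    }
  }
  new_document(pred_doc$report, pred_doc$entities[, c("id", "type", "start", "end", "text")],
               if (length(rels)) do.call(rbind, rels) else empty_relations(),
               schema = schema)
}

write_metric_report <- function(report, path) {
  df <- report$per_class[, c("class", "precision", "recall", "f1")]
  df <- rbind(df,
              data.frame(class = "Macroaverage", precision = report$macro["precision"],
                         recall = report$macro["recall"], f1 = report$macro["f1"]),
              data.frame(class = "Microaverage", precision = report$micro["precision"],
                         recall = report$micro["recall"], f1 = report$micro["f1"]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress progress messages.
#' @return list with the three `metric_report`s (`ner_exact`,
#'   `ner_inexact`, `rc`, `qa`), the trained models and the output
#'   directory.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("generating %d reports (seed %d)", config$gen$n_reports, config$gen$seed)
  corpus <- with_stage("generate", generate_corpus(config$gen))
  parts <- with_stage("split", split_corpus(corpus, config$split, seed = config$seed))
  write_brat_dir(parts$test, file.path(config$outdir, "gold_test"))

  ner_model <- NULL
  if (!config$use_gold_entities) {
    say("training %s tagger on %d reports", config$arch, length(parts$train$docs))
    ner_model <- with_stage("train-ner",
      train_tagger(parts$train, parts$validation, config$ner, arch = config$arch,
                   quiet = quiet))
  }
  say("training relation classifier (RSC %s)",
      if (config$rc$rsc_enabled) "on" else "off")
  inst_train <- with_stage("rc-instances", rc_corpus_instances(parts$train,
                                                               config$rc$rsc_enabled))
  inst_val <- rc_corpus_instances(parts$validation, config$rc$rsc_enabled)
  rc_model <- with_stage("train-rc", train_rc(inst_train, inst_val, config$rc,
                                              quiet = quiet))

  say("predicting on %d test reports", length(parts$test$docs))
  pred_docs <- with_stage("predict", lapply(parts$test$docs, predict_document,
                                            ner_model = ner_model,
                                            rc_model = rc_model,
                                            use_gold = config$use_gold_entities))
  pred_corpus <- new_corpus(pred_docs)
  write_brat_dir(pred_corpus, file.path(config$outdir, "predicted_test"))

  ## metrics: NER on spans, RC on gold-entity pairs (as published), QA
  ## end-to-end against the latent oracle answers
  ner_exact <- ner_metrics(parts$test, pred_corpus, "exact")
  ner_inexact <- ner_metrics(parts$test, pred_corpus, "inexact")
  inst_test <- rc_corpus_instances(parts$test, config$rc$rsc_enabled)
  rc_gold <- vapply(inst_test, `[[`, character(1), "label")
  rc_pred <- vapply(inst_test, function(x) predict_relation(rc_model, x), character(1))
  rc_report <- rc_metrics(rc_gold, rc_pred)

  pred_answers <- with_stage("answer", answer_corpus(pred_corpus))
  write_answers(pred_answers, file.path(config$outdir, "predicted_answers.tsv"))
  qa_report <- answer_metrics(parts$test$answers, pred_answers)

  write_metric_report(ner_exact, file.path(config$outdir, "metrics_ner_exact.tsv"))
  write_metric_report(ner_inexact, file.path(config$outdir, "metrics_ner_inexact.tsv"))
  write_metric_report(rc_report, file.path(config$outdir, "metrics_rc.tsv"))
  write_metric_report(qa_report, file.path(config$outdir, "metrics_qa.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ctstager")),
    seed = config$seed, arch = config$arch,
    use_gold_entities = config$use_gold_entities,
    n_reports = config$gen$n_reports,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  list(ner_exact = ner_exact, ner_inexact = ner_inexact, rc = rc_report,
       qa = qa_report, ner_model = ner_model, rc_model = rc_model,
       outdir = config$outdir)
}
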