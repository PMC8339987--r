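# ctstager

Lung-cancer staging information extraction from free-text (Chinese) chest
CT reports, as a three-stage pipeline:

1. **NER** — character-level sequence labeling over 14 clinical entity
   types (mass, lymph node, location, size, negation, density,
   enhancement, shape, bronchus, pleura, vessel, vertebral body,
   effusion, atelectasis/obstructive pneumonitis), with a
   bidirectional-LSTM-CRF core and an iterated-dilated-CNN-CRF
   alternative. The linear-chain CRF (forward algorithm, forward-backward
   marginals, Viterbi decoding) is implemented from scratch and verified
   against exhaustive path enumeration.
2. **RC** — relation classification for each same-sentence entity pair
   (`At`, `SizeOf`, `Related`, `Negate`, `NoRelation`) with an
   attention-BiLSTM over the entity-marked sentence
   (`<e1>…</e1>`/`<e2>…</e2>`). Any two entity types admit at most one
   true relation; the **relation sign constraint (RSC)** prepends that
   admissible relation tag to the input and masks inadmissible
   predictions, e.g. `At<e1>左肺门及纵隔4、5组</e1>见<e2>肿大淋巴结</e2>，较大约14×12m`.
3. **PP** — a rule engine that assembles (entity, relation, entity)
   triples into per-report findings (primary tumor, satellite nodules,
   lymph-node groups by IASLC station/region, invasions, effusion) and
   answers 22 TNM staging questions (e.g. Q2 "greatest dimension of the
   tumor", Q12 "metastasis in ipsilateral mediastinal lymph nodes", N2).

The clinical corpus behind the original study is private, so the package
ships a **synthetic report generator**: each report is rendered from a
latent clinical scenario whose true answers to the 22 questions are known
by construction, with entity-frequency rank order and positive-answer
prevalences calibrated to the published annotation statistics. All three
stages are trained and evaluated offline on this corpus. The evaluation
suite implements exact and inexact (overlap) span matching — inexact
recall deliberately may exceed 100%, matching the published convention —
plus relation and question-answer metrics and Cohen's kappa.

The neural layers are plain R matrix code with hand-written
backpropagation (no deep-learning runtime is required); every layer is
covered by finite-difference gradient checks.

## Worked example

```r
library(ctstager)
corpus <- generate_corpus(generator_config(n_reports = 4, seed = 7))
doc <- corpus$docs[[1]]
cat(doc$report$text)
#> 右肺下叶见肿块影，约40×30mm，呈软组织密度，无明显强化，胸膜凹陷。对比剂注入顺利。
#> 左肺下叶舌段见结节。心包不伴中量胸腔积液。双肺余未见确切异常征象。
#> 左侧纵隔3、8组可见多发肿大淋巴结。右肺上叶尖段另见结节，范围约6x5mm。局部叶支气管闭塞。膈面光整。

head(doc$entities[, c("id", "type", "text")], 6)
#>   id        type       text
#> 1 T1    Location   右肺下叶
#> 2 T2        Mass     肿块影
#> 3 T3        Size    40×30mm
#> 4 T4     Density 软组织密度
#> 5 T5 Enhancement 无明显强化
#> 6 T6      Pleura   胸膜凹陷

answer_document(doc)
#> Q1: Yes      <- a tumor is visualized (non-negated Mass)
#> Q2: 40       <- greatest dimension, mm
#> Q3: Yes      <- bronchial invasion (支气管闭塞)
#> Q4: Yes      <- visceral pleura (胸膜凹陷 related to the mass)
#> ...
#> Q14: Yes     <- contralateral (left) mediastinal nodes, stations 3/8
#> Q17: Yes     <- separate nodule in a contralateral lobe
#> Q21: 软组织密度
```

On gold annotations the rule engine reproduces the generator's latent
oracle answers exactly (22/22 here; ≥99% of question instances is the
acceptance bar over 200 reports).

Full pipeline (generate → train NER → train RC → predict → answer →
evaluate):

```r
res <- run_pipeline(pipeline_config(
  gen = generator_config(n_reports = 120),
  ner = ner_config(char_embedding_dim = 24, seg_embedding_dim = 8,
                   hidden_units = 24, dropout_rate = 0.1, batch_size = 8,
                   max_epochs = 15, early_stopping_patience = 3),
  rc  = rc_config(embedding_dim = 24, hidden_units = 24, attention_dim = 16,
                  dropout_rate = 0.1, batch_size = 8, max_epochs = 15,
                  early_stopping_patience = 3),
  seed = 1, outdir = tempfile()))
res$ner_exact$micro["f1"]   #> 100.00
res$rc$micro["f1"]          #> 99.36
res$qa$micro["f1"]          #> 98.48
```

A command-line entry point with the same stages is installed at
`system.file("cli", "ctstager", package = "ctstager")`
(subcommands `generate`, `train-ner`, `train-rc`, `predict`, `answer`,
`evaluate`, `run-all`; brat standoff in and out).

## Data formats

* Corpora: brat standoff (`<doc>.txt` + `<doc>.ann`, T/R records,
  0-based half-open character offsets), read/written by
  `read_brat_dir()` / `write_brat_dir()`.
* Character-level BIO: `to_bio()` / `from_bio()`, CoNLL-style export via
  `write_conll()`.
* Answers: TSV sidecar (`doc_id`, `question_id`, `answer`).
* Schema (entity types, relation map, 22-question catalogue, lexicon):
  plain-text files under `inst/extdata/schema/`, overridable with the
  CLI `--schema` flag or `load_schema(path)`.
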