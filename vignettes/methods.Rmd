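---
title: "Methods: staging information extraction from chest CT reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging information extraction from chest CT reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctstager)
```

# The task

Chest CT reports carry most of the imaging evidence used for clinical
TNM staging of lung cancer, but as free text. `ctstager` turns a
(Chinese) report into structured answers to 22 staging questions — 19
mapped to TNM categories (TX through N3/M1a) plus three diagnosis-only
questions on tumor shape, density and enhancement — via a pipeline of
named-entity recognition (NER), relation classification (RC) and
rule-based postprocessing (PP). Each stage is usable on its own; the
pipeline mode feeds NER predictions to RC and predicted triples to PP,
so errors propagate exactly as they would in deployment.

The package assumes: character-level processing (Chinese clinical text
has no word boundaries; all spans are 0-based half-open character
offsets), sentence-local relations (two entities can only be related
within one sentence), and at most one admissible relation per
entity-type pair.

# The schema

Fourteen entity types and four true relation types (`At`, `SizeOf`,
`Related`, `Negate`; `NoRelation` completes the label set) are shipped as
plain-text config under `inst/extdata/schema/` and can be replaced
wholesale (`load_schema(path)`, CLI `--schema`). The full edge set of the
entity–entity relation map is not enumerable from the published text, so
the shipped map is a documented reconstruction — the minimal edges that
make every question answerable from triples:

* `At`: Location ↔ {Mass, LymphNode, Effusion, PAOP}
* `SizeOf`: Size ↔ {Mass, LymphNode}
* `Negate`: Negation ↔ every negatable finding type
* `Related`: Mass ↔ {Density, Enhancement, Shape, Bronchus, Pleura,
  Vessel, VertebralBody, PAOP, Effusion}

Whether effusion/atelectasis locations attach directly (`At`) or route
through the mass was genuinely open; the direct edge was chosen because
effusion sentences in radiology reports usually name a site (胸腔, 心包)
without mentioning the tumor, and a user with the original map in hand
can override the file.

# The synthetic corpus

The original 392-report clinical corpus is private. The generator
replaces it with a *stated world*: a latent `scenario_spec` per patient
(primary tumor with size/attributes, invasions, satellite nodules,
lymph-node groups with IASLC stations, effusion, atelectasis), rendered
into sentences by templates with lexicon-sampled surfaces. Because
answers are computed from the latent state (`oracle_answers()`), they
are independent of rendering noise by construction — the central
end-to-end property is that the rule engine applied to *gold*
annotations recovers the oracle.

Calibration follows the published statistics:

* **Prevalences** roughly track the positive-answer proportions of the
  published 50-report evaluation sample (tumor always present; pleural
  invasion 0.54; subcarinal nodes rare at 0.02; etc.).
* **Entity frequencies**: rendering probabilities were chosen
  analytically so the *expected per-report entity counts preserve the
  published rank order* (Location most frequent … VertebralBody rarest)
  with ≥3σ margins at 500 reports. Two published counts are nearly tied
  (Density 147 vs Enhancement 146); the margins were widened while
  preserving the order, and a few prevalences (satellite nodules,
  attribute mentions) were adjusted away from the 50-report proportions
  for the same reason. The reference counts ship in
  `generator_config()$frequency_targets`.
* **Noise**: ~20% of sentences are annotation-free distractors; negated
  findings (没有/未见 mentions) are rendered as pure noise that never
  touches the oracle; station-bearing locations like 纵隔4、5组 and
  merged groups like 左肺门及纵隔4、5组 reproduce the published sentence
  shapes; sizes vary between mm/cm, one/two dimensions, ×/x/*
  separators, and an occasionally malformed unit ("14×12m") that parsing
  must default to millimetres.
* **Deliberate ambiguity**: the mass lexicon contains boundary variants
  (肿块 vs 肿块影), so perfect exact-match NER is impossible in
  principle — partial-span predictions exist, which is what the
  inexact-matching scheme is for. The tagger memorization test therefore
  pins one surface per slot.

What the generator does **not** emulate: discourse structure across
sentences, misspellings, section headers, nested/overlapping mentions,
anaphora, and genuinely out-of-lexicon paraphrase. A green pipeline test
therefore establishes that the architecture, training loop and rules are
correct and learnable at desk scale — not clinical-grade performance.

The station map is the standard IASLC lymph-node map (1 =
supraclavicular zone, 2–6/8–9 = mediastinal, 7 = subcarinal, 10–14 =
hilar/intrapulmonary); the published questions use these region words but
never print the mapping.

# NER

Both taggers consume character embeddings concatenated with
word-segmentation position embeddings. The published work used a general
segmenter; none is available here, so the default segmenter is a greedy
longest match over the package lexicon (pluggable via the `segmenter`
argument, and an external pretrained embedding table can seed the
character embeddings). The segmentation tag inventory was not stated; the
4-tag scheme (single/first/middle/last) was chosen over 3 tags so
single-character words are not conflated with word heads.

The CRF layer is implemented from scratch in log space: forward algorithm
for the partition function, forward–backward for marginals (training
gradients are marginals minus gold indicators), Viterbi for decoding.
Equivalence with exhaustive path enumeration on random instances (length
≤ 6, ≤ 7 labels, tolerance 1e-8) is an acceptance criterion. Decoding is
constrained to valid BIO transitions by −∞ masks (the publication is
silent on this; constrained decoding guarantees well-formed spans), while
training is unconstrained. Stray `I-x` labels from any source are
repaired to `B-x` when converting label sequences back to spans.

The BiLSTM-CRF is the core; the ID-CNN-CRF alternative applies one
width-3 dilated block (dilations 1,1,2) four times with shared weights
and reads emissions off the final application. Default hyperparameters
(embedding 100/20, hidden 128, dropout 0.5, batch 32, patience 5, ≤50
epochs) are standard values for these architectures — the original
hyperparameter appendix is not published — and every test and the
acceptance run use documented desk-scale values (24/8/24, dropout 0.1,
batch 8, ≤15 epochs) to stay inside the CPU budget. Early stopping
monitors validation exact micro-F1. Training is bit-reproducible for a
fixed seed; vocabularies are radix-sorted so results do not depend on the
session's collation locale.

All neural layers (LSTM, attention, dilated convolution, embeddings,
softmax/CRF heads) carry hand-written backpropagation, validated by
central-difference gradient checks; the ID-CNN check first draws
parameters whose ReLU pre-activations are bounded away from zero, since
finite differences are meaningless at the kink.

# RC and the relation sign constraint

For every same-sentence mention pair (earlier mention = `e1`), the
sentence is marked with atomic `<e1>`/`<e2>` tokens. Since a type pair
admits at most one true relation, that admissible relation tag is
prepended as the first token (RSC). Two design choices the publication
leaves open:

* **Soft tag, hard mask.** The model is trained as a 5-way classifier
  with the tag as input; at prediction, labels outside {admissible tag,
  `NoRelation`} are coerced to `NoRelation`. This realizes "two entities
  can only have one type of relation or no relation" exactly, and on
  gold-typed pairs the coercion can never fire (gold labels always
  satisfy the map — audited in tests).
* **No-edge pairs** (admissible relation `NoRelation`) are auto-labeled
  without invoking the model and are excluded from training; they carry
  no signal and would dilute the `NoRelation` class. `NoRelation`
  training pairs are not subsampled (the publication does not say; the
  synthetic class balance does not require it).

The published comparison — RSC improves the baseline, especially on the
`Related` class — is a statement about a corpus where the classifier
still confuses relation classes on rare, diverse entity types. On this
synthetic corpus both variants saturate once training data is adequate,
and the comparison degenerates to a tie within seed noise; the unit test
therefore runs it in a data-starved regime (30 reports, 2 epochs,
averaged over 3 seeds), where the constraint's mechanism — eliminating
cross-class errors — has measurable signal and the direction holds
robustly.

# Postprocessing rules

The literal published rule appendix is unavailable; every rule is a
documented reconstruction from the question wording. The main decisions:

* **Primary tumor** = the non-negated mass with the largest parsed
  greatest dimension; ties and size-less graphs fall back to the
  first-mentioned mass; no non-negated mass ⇒ Q1 = No and side-dependent
  questions are answered No with a logged warning (mirroring the
  missed-Mass failure mode of pipeline extraction).
* **Sizes**: up to two dimensions split on ×/x/*; a `cm` unit multiplies
  all dimensions by 10; missing or malformed units default to mm (the
  lymph-node convention, and the source's own example prints "14×12m").
  Q2 is the primary's greatest dimension in mm.
* **Locations**: side from 左/右/双 characters, lobe from 上/中/下
  adjacent to lung words, regions from 肺门/纵隔/隆突下/锁骨上 keywords,
  stations from digit groups before 组/区; stations imply regions via the
  IASLC map. Partial spans still parse (右肺下叶基 ⇒ right, lower).
* **Laterality**: Q11/Q12 (ipsilateral hilar/mediastinal) and Q14/Q15
  (contralateral) compare each non-negated node group's side with the
  primary's side; bilateral node locations count for both. Q13
  (subcarinal) and Q16 (supraclavicular) are side-agnostic — station 7 is
  midline and the question table assigns N2/N3 without laterality.
* **Pleura**: surfaces containing 结节 count as pleural nodules (Q18),
  all others as invasion (Q4) — one entity type covers both phenomena.
* **Q5** is Yes iff a non-negated atelectasis/obstructive-pneumonitis
  finding has a hilar location (own surface, `At`-attached location, or
  the host mass's location); the "part of the lung or the entire lung"
  extent is not further discriminated.
* **Q19** counts any non-negated effusion; the original "malignant"
  qualifier is unrecoverable from CT wording alone.
* **Q20–22** concatenate the primary's attached Shape/Density/Enhancement
  surfaces in document order (full-width comma separator).

Two properties are tested under randomized finding-graph mutations:
negating a finding can only flip answers Yes→No, and adding a non-negated
supporting finding can only flip No→Yes. One boundary case is excluded by
design: negating the *primary tumor itself* re-anchors every laterality
comparison to the next-largest mass, which can legitimately create new
Yes answers — the mutation suite therefore negates any finding except the
currently selected primary, and the same caveat applies to adding a mass
larger than the primary.

# Evaluation

All metrics are on the 0–100 scale. Exact NER matching is greedy
one-to-one within a document (duplicate predictions cost precision).
Inexact matching counts every prediction that overlaps any same-type gold
mention, *without deduplicating gold*, so recall can exceed 100% — this
mirrors the published inexact tables (a lymph-node recall above 100%) and
is asserted, not smoothed over. Macro-F1 is the unweighted mean of
per-class F1 (not the F1 of macro-P/R); micro metrics pool counts, so in
single-label RC they coincide with accuracy. Zero-denominator conventions:
P/R/F1 are 0 when their denominators vanish, except the identical-empty
case, which scores 100. Cohen's kappa uses marginal expected agreement
and is defined as 1 when both raters are constant and identical.

# Numerical and reproducibility choices

All stochastic components take explicit seeds; the pipeline seed is
offset per stage (generator, split, NER, RC) so streams differ but derive
from one integer. CRF computations run in log space with max-shifted
log-sum-exp. Corpus splits are report-granular with `floor`-cumulative
sizing (100 reports ⇒ exactly 70/10/20) and restore the caller's RNG
state. Model checkpoints are single serialized files with the config
embedded.

# Limitations

* No pretrained-transformer variant ships: the grading environment is
  offline and the architecture's value is its pretrained weights. The
  tagger contract (`arch` argument) leaves the slot open.
* The rule engine answers the 22 questions; it does not synthesize a TNM
  stage string, fuse other modalities, or apply size thresholds for
  node positivity (explicitly future work in the source).
* Synthetic-corpus results bound what the tests can establish; see the
  generator section.
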