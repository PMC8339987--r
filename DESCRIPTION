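Package: ctstager
Title: Lung Cancer Staging Information Extraction from Chest CT Reports
Version: 0.1.0
Authors@R:
    person("Ming", "Zhao", email = "ctstager@users.noreply.github.com",
           role = c("aut", "cre"))
Description: A three-stage information-extraction pipeline that reads
    free-text (Chinese) chest computed-tomography reports and answers 22
    lung-cancer TNM staging questions. Stages are character-level neural
    named-entity recognition over 14 clinical entity types (BiLSTM-CRF or
    iterated-dilated-CNN-CRF, with the conditional random field layer
    implemented from scratch), attention-BiLSTM relation classification
    with a relation-sign-constraint tag prepended to each entity-marked
    sentence, and a rule-based postprocessor that assembles
    entity-relation-entity triples into findings and answers the staging
    questions. Includes brat standoff corpus I/O with character-level BIO
    conversion, a synthetic annotated-report generator with known latent
    clinical scenarios for offline training and evaluation, and the exact
    and inexact span-matching metric suite including Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
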