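Package: thyromqa
Title: Retrieval-Grounded Question Answering for Thyroid Surgical
    Pathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A locally runnable medical question answering (MQA) pipeline
    for thyroid cancer surgical pathology reports. Long narratives are
    split into fixed-length 1200-character segments, embedded with a
    deterministic hashed term-frequency embedder, scored against each
    question by cosine similarity, and the top-scoring segments are
    assembled into a compact context that fits a language model's token
    budget. A fixed 12-question schema extracts tumor size, location,
    extrathyroidal extension, nodal status, TNM stage, lymphovascular
    invasion, histology, aggressive variants and second cancers; answers
    are normalized to typed canonical values and compared between answer
    sources with per-question and pooled concordance rates, means, SDs
    and two-sided t tests. Includes a seeded synthetic report generator
    with complete ground truth, a deterministic rule-based reference
    answer backend standing in for an LLM, and a simplified AJCC-TNM
    (8th edition) / ATA recurrence-risk staging rules engine used as a
    consistency oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    dplyr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
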