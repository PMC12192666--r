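Package: ddisignal
Title: Drug-Drug Interaction Signal Detection with Attention Models and
    Beta-Binomial Bayesian Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and interpreting drug-drug interaction (DDI)
    signals from spontaneous adverse-event reports. Implements pairwise
    stratification of report tables into contingency counts, empirical-Bayes
    beta-binomial inference with Bayes-factor hypothesis testing and
    F1-optimal thresholding, and classical disproportionality baselines
    (Omega, log-likelihood ratio, interaction signal score, additive excess
    risk). A companion prediction stack provides molecular graph parsing and
    descriptors from SMILES, graph-attention and granule-granule interaction
    encoders, constrained tensor factorization of multi-view drug similarity,
    a dual-stage attention recurrent predictor with active-learning sample
    selection, evaluation and ablation harnesses, and a typed
    drug-target-enzyme-transporter-adverse-event network for mechanistic
    interpretation. A synthetic-data module generates FAERS-like report
    corpora with injected interaction signals, toy molecules, labeled drug
    pair-cell triplets and toy biological networks so the full pipeline runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    e1071,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
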