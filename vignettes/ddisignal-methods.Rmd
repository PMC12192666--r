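---
title: "Methods: beta-binomial DDI signal calibration and the attention prediction stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-binomial DDI signal calibration and the attention prediction stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ddisignal` detects and interprets drug--drug interaction (DDI) signals in
spontaneous adverse-event (AE) report data, and couples that statistical
core to a multi-source prediction stack for drug-combination effects. This
vignette documents the models, the tunable parameters, the synthetic study
conditions, and the numerical and design choices, so that every reported
behavior can be traced to an explicit assumption.

## 1. The statistical core: stratified beta-binomial calibration

### Stratification

Every (drug A, drug B, AE) triple is reduced to six counts from disjoint
report strata: AE occurrences and report totals under co-administration
(`d_combo`, `n_combo`), under A without B (`d_first`, `n_first`), and under
B without A (`d_second`, `n_second`). Other co-medications are ignored —
all drugs in a report are treated equivalently. `stratify()` handles one
triple; `signal_table()` scans all pairs and AE terms in one pass.

### The no-interaction baseline

The monotherapy strata give rate estimates `p1`, `p2`; the null model for
the combination rate is independence of causes,

    e = p1 + p2 - p1 * p2,

i.e. the AE occurs under the combination if either constituent would have
caused it. This surrogate is analytically checkable (the synthetic
generator simulates it exactly) and is the reference for all baseline
statistics: `delta_add = d_combo/n_combo - e` measures additive excess,
`omega = log2((O + 0.5)/(E + 0.5))` and `intss = (O + 0.5)/(E + 0.5)` are
shrinkage-stabilized observed/expected contrasts with `O = d_combo` and
`E = e * n_combo`, and `llr` is the one-sided binomial log-likelihood ratio
of the observed combination rate against `e` (zero when the observed rate
does not exceed `e`). These formulas follow standard pharmacovigilance
practice; they are this package's definitions, stated here because the
statistic names alone do not pin them down.

### Beta-binomial model and empirical-Bayes priors

AE counts are overdispersed relative to a binomial (report heterogeneity,
underreporting), so the combination count is modeled as binomial with a
Beta-distributed rate. Conjugacy makes the posterior `Beta(a + X, b + n -
X)`. Hyperparameters are estimated by method-of-moments empirical Bayes
(`fit_prior_mom()`): with sample mean `m` and variance `v` of observed
rates, `c = m(1 - m)/v - 1`, `alpha = m c`, `beta = (1 - m) c`. Degenerate
or over-dispersed moment sets fall back to the uniform `Beta(1, 1)` with a
warning.

The hypothesis test contrasts two priors:

* **H1 (interaction)** — a method-of-moments fit to the observed
  co-administration rates across pairs, per AE term.
* **H0 (no interaction)** — a Beta centered at the stratum's own expected
  rate `e`, with concentration matched to the sampling variance of `e`
  propagated from the monotherapy strata
  (`Var(e) = (1-p2)^2 p1(1-p1)/n1 + (1-p1)^2 p2(1-p2)/n2`).

The second construction is a deliberate design choice. Fitting H0 to the
*population* of expected rates across pairs (a literal global
empirical-Bayes fit) makes the null prior nearly as diffuse as H1, so the
Bayes factor degenerates into a measure of deviation from the population
average rather than from the pair-specific baseline — in simulation its
ranking is no better than chance. Re-centering per stratum restores the
meaning of H0 ("the combination rate is the no-interaction baseline, known
up to estimation error") while keeping every number data-driven.

The Bayes factor is the ratio of beta-binomial marginal likelihoods,
computed in log space via `lbeta()`; binomial coefficients cancel. The
detector additionally truncates the H1 prior to rates *above* `e`
(one-sided, closed form through regularized incomplete-beta ratios),
because an interaction signal means excess risk: without truncation,
large-exposure strata that happen to *undershoot* their baseline produce
enormous two-sided Bayes factors and dominate the ranking. The plain
two-sided factor remains available (`signal_table(..., one_sided =
FALSE)`); its null distribution concentrates near 1, while the truncated
detector is deflated under the null by roughly the prior tail odds (its
null median sits near 0.5).

Decision thresholds come from `choose_threshold()`: candidate thresholds at
midpoints between sorted unique Bayes factors (plus sentinels), the F1
score of `BF > t` evaluated at each, ties resolved toward the smallest
threshold.

### Posterior-feature classification and ranking

`classify_ae()` fits a Gaussian naive-Bayes model (via `e1071`) on two
features per combination — posterior AE probability and log usage
frequency — and `rank_for_ae()` orders combinations by the predicted class
probability of a queried AE. Confidence scores are class probabilities;
the calibrated posteriors themselves are also exported in the signal table
so either notion of "confidence" can be ranked.

## 2. The prediction stack

### Molecular graphs and descriptors

SMILES strings are parsed with OpenBabel (ChemmineR/ChemmineOB), which
preserves heavy-atom input order; implicit hydrogens are recovered from a
standard-valence model adjusted for formal charge, and molecular weight is
the sum of pinned IUPAC 2021 standard atomic masses plus 1.008 per
hydrogen, reported to 2 decimals. Heavy atoms are the atom count (the
"13 atoms" convention for aspirin counts heavy atoms). Hydrogen-bond
counts are exposed as separate Lipinski-style donor (N/O bearing H) and
acceptor (N/O) counts; a single merged "hydrogen bond count" is ambiguous
between toolkits and is deliberately not part of the descriptor contract.
logP is not computed: published values are method-dependent fits, not
reproducible from structure alone with the tools packaged here.

### Graph attention encoder

`gat_attention()`/`gat_layer()` implement multi-head graph attention:
`alpha_ij = softmax_j(LeakyReLU(a'[W h_i || W h_j]))`, node update
`h_i' = sigma((1/K) sum_k sum_j alpha_ij^k W^k h_j)`. Heads are averaged
by default — that is what the update equation states — with
`head_combine = "concat"` as a switch, since concatenation is the other
convention in circulation. Self-loops are always added so no neighborhood
is empty. The reference configuration is 2 stacked layers; molecule
embeddings sum-pool the atoms so molecular size survives pooling.

### Granules and granule-granule interaction (GGI)

`granulate()` decomposes a molecule into granules: each ring system
(biconnected components with at least 3 atoms, merged when sharing atoms)
is one granule, and each maximal connected non-ring fragment is one
granule; a singleton scheme (one atom per granule) exists for testing.
This decomposition is deterministic and chemically meaningful (ring
systems and substituents), which is why it was chosen over learned or
enumeration-based fragmentations. Pair interaction scores are
`GGI(g_i, g_j) = sigmoid(W1 g_i + W2 g_j + b)` reduced to a scalar by
averaging output units (so the score stays in (0, 1) for any output
width), and `ggi_total()` is the mask-weighted double sum; the mask
defaults to all ones.

`attention_importance()` exposes interpretability: a compact attention-
pooling classifier over granule features is trained on labels, and its
softmax attention over a molecule's granules (non-negative, summing to 1)
scores substructure importance; atom scores spread each granule's mass
uniformly over its atoms.

### Constrained tensor factorization (CTF)

A three-view drug similarity tensor (structural, fingerprint-like, profile
views; cosine similarities mapped to [0, 1] with unit diagonal) is
decomposed as a rank-R CP model minimizing

    || chi - U o V o W ||_F^2 + lambda1 ||U||_{2,1} + lambda2 tr(U' L U)

with `L` the Laplacian of the mean similarity slice (the objective needs
one graph; the mean slice is the neutral choice when no single view is
privileged). The solver is block-coordinate descent: exact ridge-
stabilized least squares for V and W via Khatri-Rao unfoldings, and for U
an iteratively-reweighted (majorize-minimize) step that turns the L2,1
term into a row-weighted quadratic and solves the resulting Sylvester
system through an eigendecomposition of the symmetric left operator. A
"Hessian regularization" is sometimes mentioned alongside this objective
in the literature; the objective optimized here contains exactly the
Laplacian trace, nothing else. After convergence the factors are put in a
canonical form (unit-norm columns of U and V, scales folded into W) to fix
the CP scale indeterminacy. Defaults: `R = 16`, `lambda1 = lambda2 =
0.01`, `tol = 1e-6` on the relative objective change, 500 iterations. The
smoothing constant in the IRLS row weights is 1e-10, which bounds any
monotonicity slack well below the 1e-8 tested for.

### Dual-stage attention recurrent predictor

The predictor consumes a short driving-series matrix per sample: T ordered
feature blocks (drug A encoding, drug B encoding, GGI, CTF, cell line,
report-derived signal) each padded to a common width n. Treating the
ordered blocks as pseudo-time is the package's convention for applying a
sequence model to fused static features: it preserves the two attention
stages (which features within a step; which steps overall) while making T
concrete and configurable. No claim is made that the blocks are temporal
in the calendar sense.

Input attention scores each driving series `x^k` (a column across all T
steps) as `e^k = v_e' tanh(W_e [h; s] + U_e x^k)` using the encoder LSTM's
previous hidden and cell state, and reweights the current step's inputs by
`softmax(e)`. Temporal attention scores encoder states as
`l_i = v_t' tanh(W_t h_i + U_t d)` and pools them into a context vector.
Classification has no target series to decode, so a single decoding step
with `d = 0` is used; `U_t` is retained but inert at that point. A sigmoid
head maps the context to an interaction probability.

Forward and backward passes are plain matrix code; the full analytic
gradient (BPTT through the LSTM, both attention stages, and the head) is
verified against central finite differences to a relative error below
1e-4 in the test suite. Training uses Adam with early stopping on a
stratified validation split; two named presets ship, `darnn` (lr 0.001
with cosine annealing, batch 256, patience 10) and `mfsyndcp` (lr 1e-4,
weight decay 1e-5, batch 2048, patience 15), because both configurations
are in reasonable use for this architecture family; `darnn` is the
default. Hidden dimension defaults to 256 and dropout to 0.3 (applied to
the driving features during training only; evaluation-mode forward passes
are deterministic). Benchmark-scale runs in this package use smaller
hidden sizes (16–32); the defaults describe the full-size configuration.

### Active learning

`uncertainty()` is binary entropy by default (`margin` as an alternative
with the same ordering); `select_batch()` takes the k most uncertain pool
samples with deterministic index tie-breaks; `al_loop()` runs the
train–score–select–reveal cycle, retraining from scratch each round to
avoid warm-start confounds (configurable through the factory). The loop is
learner-agnostic via model factories (`darnn_factory()`,
`glm_factory()`).

A caution documented deliberately: uncertainty sampling is only as good as
the learner's uncertainty. With a misspecified learner (a plain linear
model on a task with multiplicative structure) entropy-based selection
concentrates on the wrong boundary and can *underperform* random
selection. The label-efficiency experiments therefore use a learner that
can represent the task — logistic regression on block-summary interaction
features (`interaction_features()`) — and the package exposes the
phenomenon rather than hiding it.

### Evaluation and ablation

`metrics()` defines AUROC as the rank statistic with 0.5 tie credit,
PR-AUC by step-wise (non-interpolated) integration, confusion metrics at a
threshold, and MSE/RMSE against binary labels. `kfold_cv()` builds
shuffled stratified folds whose sizes differ by at most one.

`run_ablation()` retrains the pipeline with components replaced by neutral
stand-ins: zeroed feature blocks for the encoder components (`mfsyndcp`,
`ggi`, `ctf`, `bayes`), mean-pooling over pseudo-time plus a linear head
for `lstm` (identity pass-through: no sequence modeling), and random
instead of uncertainty-driven subset selection for `active_learning`. The
training subset is acquired with a probe model over two uncertainty-
sampling rounds; an averaged ensemble of independently seeded trainings
(default 2) reduces optimization variance in the evaluated scores. On the
packaged benchmark the single-component contrasts are small by design —
the feature blocks are partially redundant views, as real multi-source
pipelines are — so ablation *orderings*, not magnitudes, are the
meaningful output, and contrasts near zero for individual components
should be read as "this view is redundant under these conditions", not as
a failure of the harness.

## 3. The synthetic study conditions

`gen_reports()` emulates a curated, deduplicated spontaneous-report
corpus: 20 drugs, 50,000 reports, 41.68% of reports listing a drug pair
(the multi-drug share of the curated corpus the simulator emulates),
Zipf-like (1/rank) drug popularity so pair exposure is heavy-tailed,
per-drug per-AE baseline rates drawn from `Beta(2, 38)` (mean 5%), 10 AE
terms, 10% of pairs truly interacting, risk ratio 3. For a non-interacting
pair the combination AE probability is exactly the independence baseline;
for a flagged pair its injected AE occurs at `min(1, RR * e)`. Reports
carry one or two drugs only (pairwise stratification is the analysis
unit), and AE sets may be empty — forcing at least one AE per report would
distort the null the generator is designed to make exact. What this
corpus does *not* emulate: reporting biases, duplicated reports,
multi-drug (>2) regimens, MedDRA coding noise, and time trends. Passing
detection tests here shows the machinery is correct under the stated
model, not that real-FAERS performance follows.

`gen_molecules()` assembles SMILES from a fixed template library (12
drug-like cores, including polycyclic scaffolds, with prefix/suffix
substituents). `gen_triplets()` crosses all molecule pairs with synthetic
cell lines; the default `"synergy"` label rule is deterministic from
descriptors and symmetric in the pair: with the standardized structural
term `z` combining molecular size and ring complexity (via the cyclomatic
number `bonds - atoms + 1`, weighted so ring complexity carries about a
third of the structural variance), the label is `z * latent + 0.5 z +
0.5 latent > 0`. The multiplicative term makes synergy context-dependent — the same
pair can be synergistic in one cell context and not in another — which is
the qualitative behavior of real combination screens and is what gives
the sequence model headroom over linear baselines. Rule constants are
calibrated once against the template population (expected positive rate
near 0.5; realized benchmark balance stays within [0.3, 0.7]).

`make_benchmark()` packs everything into the N x 6 x 10 sequence array.
Feature blocks are deliberately *complementary noisy views*: GAT
embeddings (no exact descriptor counts), coarse granule composition
summaries (granule/ring counts, not atom tallies), CTF similarity
embeddings, cell expression with the latent context factor, and report-
derived beta-binomial evidence from a corpus whose injected pairs are the
benchmark's high-propensity pairs (risk ratio 4, 30,000 reports). Problem
sizes used in the shipped experiments — 16 molecules x 16 cell lines
(1,920 triplets) for the headline benchmark, 14 x 12 for ablations, 12 x
10 for label-efficiency runs — were chosen as the smallest scales at which
training is stable on a single CPU.

`gen_bio_network()` emits typed edge lists (drug, target, enzyme,
transporter, AE) with STRING-style integer PPI confidences and guarantees
a drug-to-AE mechanism chain per drug.

## 4. The attribute network

`build_network()` applies the strict confidence filter (`> 700` of 1,000)
to PPI edges and rescales survivors by 1/1000; all other weights are
clipped to [0, 1]. `shortest_path()` uses edge cost `1 - weight + eps`
with `eps = 1e-6`: strong interactions are cheap to traverse, every hop
still costs something (so paths stay short), and ties break on the
lexicographically smallest node sequence. `rank_mechanisms()` scores
enzymes/transporters adjacent to both drugs by the product of the two
incident edge weights — the product favors mechanisms strongly coupled to
*both* drugs, which is the intended reading of a shared-pathway score —
with node-id tie-breaks. How to combine literature frequency, functional
relevance and computational scores into one edge weight is left to the
user: the weight column is an input, not a derived quantity.

## 5. Known limitations

* The beta-binomial detector assumes the independence-of-causes null; real
  "no interaction" baselines are debatable, and any misspecification there
  propagates to every statistic built on `e`.
* The one-sided detector deliberately ignores protective (risk-lowering)
  interactions.
* The DA-RNN implementation favors clarity over speed; it is adequate for
  the packaged benchmark scales, not for screening-scale training.
* Alternating least squares for the CP factorization converges slowly
  ("swamps") when the true factors are nearly collinear — e.g. all-positive
  factors with similar profiles. The leading-singular-vector
  initialization mitigates but does not remove this; budget more
  iterations for ill-conditioned tensors.
* Ablation contrasts for individual feature blocks are within optimization
  noise when the blocks are mutually redundant; only the recurrent-encoder
  and tensor-factor contrasts are consistently large on the packaged
  benchmark.
* Uncertainty sampling helps only with a well-specified learner, and at
  equal label budgets on a noise-free synthetic task its advantage over
  random selection is small; the packaged experiments quantify label
  *efficiency* (reaching the all-data ceiling with 60% of labels), not a
  universal superiority claim.
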