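---
title: "Benchmarking multi-omic survival models: methods and design notes"
author: "survomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking multi-omic survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survomics)
```

## The question and the design

Tumor cohorts profiled on several genomic platforms pose a recurring
question: which data type — mRNA expression (EXPR), microRNA expression
(MIRNA), segmented copy-number alteration (CNA), or binary somatic
mutation status (MUT) — carries the most prognostic information, and does
merging them help? `survomics` frames this as a factorial benchmark: five
data types (the four sources plus their merged metabase) crossed with
three feature-selection algorithms, every cell filled with a multivariate
Cox proportional hazards model and scored with one shared evaluation
protocol.

The Cox model assumes proportional hazards, h(t|x) = h0(t) exp(β'x), and
all three selectors differ only in how they choose the columns of x:

* **CPSO** searches fixed-size feature subsets with a particle swarm,
  scoring each subset by bootstrap concordance — a pure wrapper search
  that ignores biology.
* **NFS** grows models along a protein-interaction network, so selected
  features must form a connected subgraph — a biologically constrained
  search.
* **LASSO** penalizes the partial likelihood, letting correlated weak
  signals shrink away — a convex embedded search.

Comparing three structurally different searches guards against
conclusions that are artifacts of a single algorithm.

## The synthetic cohort generator

Every stage of the pipeline is exercised on synthetic cohorts with known
ground truth (`generateCohort()` / `syntheticConfig()`). The generator
emulates the following features of multi-platform tumor data:

* **Correlated continuous features.** EXPR, MIRNA and CNA matrices are
  built from latent modules: blocks of `moduleSize` features (default 4)
  share a latent factor with within-module correlation `moduleCor`
  (default 0.75). CNA modules additionally share a random segment-level
  shift, mimicking regionally correlated segmented data.
* **Sparse binary mutations.** Each gene's mutation frequency is drawn
  from `mutationFrequencyRange` (default 5–30 %) and patient calls are
  independent Bernoulli draws.
* **A shared prognostic axis.** The j-th planted module of *every* source
  loads on the same latent factor u_j, and planted mutations are enriched
  in patients high on u_j. This is deliberate: in real tumors all
  platforms measure the same underlying biology (copy-number dosage,
  miRNA repression of targets, downstream expression), which is what
  makes risk predictions from different data types agree at all. Without
  a shared axis, cross-data-type agreement would be exactly zero by
  construction and the agreement analyses would be vacuous. A useful
  consequence to know: with median-split risk groups, the achievable
  kappa between two perfectly estimated single-source models is roughly
  (2/π)·arcsin(moduleCor) ≈ 0.55 at the default correlation — not 1.
* **Survival driven by a Cox model.** The linear predictor η sums
  `effectSize` × the standardized planted features (default 0.8 per
  feature, a strong single-gene effect on the log-hazard scale). Event
  times are Weibull with scale `baselineScale` (days) and shape
  `weibullShape` (default 1, i.e. exponential), with hazard scaled by
  exp(η): T = scale · (−log U / exp(η))^(1/shape).
* **Calibrated censoring.** Censoring times are exponential with rate
  chosen by bisection (`calibrateCensoring()`) so that the *expected*
  censored fraction, mean(1 − exp(−θ·t_i)) over the realized event
  times, equals `censoringTarget`. An exponential family was chosen
  because it is single-parameter and the censored fraction is monotone in
  the rate, so bisection always converges; a target of 0 maps to rate 0
  (no censoring). The achieved fraction is recorded in the truth record.
* **An interaction network and miRNA targets.** A preferential-attachment
  graph over the expression features (power `networkDegreeParam`), with
  the planted expression features rewired into one connected chain so the
  network selector has a recoverable connected answer, plus an optional
  hub of configurable degree for hub-exclusion tests. Every miRNA is
  assigned 1–3 expression-gene targets.

What it does **not** emulate: platform-specific artifacts (probe effects,
batch effects, GC bias), non-proportional hazards, informative censoring,
and methylation data. Passing tests therefore demonstrate correctness of
the algorithms and the qualitative behavior of the pipeline, not
performance levels to be expected on any particular real cohort.

## Filtering choices

* The Spearman **co-correlation filter** keeps a feature iff its maximum
  absolute correlation with *another feature of the same matrix* exceeds
  `rhoThreshold` (0.6). Correlating against survival instead would be
  ill-defined under censoring; partnering within the matrix reads the
  filter as "keep features that participate in coordinated variation".
* The **quantization filter** cuts each feature's own observed range into
  `nBins` (5) equal-width segments and requires at least
  `minOccupiedBins` (3, i.e. "more than two") occupied segments. The
  range is per-feature, not global: an invariance filter must judge each
  gene on its own scale. Constant features occupy one segment and always
  drop.
* The **CNA filter** scores each probe by the log-rank p-value of the
  median-split univariate prognostic index and keeps the top
  `cnaTopFraction` (10 %); failed fits rank last, remaining ties break
  lexicographically. The filter sees the full cohort (as the original
  design does), so downstream blind-test c-indices on CNA carry a mild
  optimistic bias — a property of the protocol being reproduced, not a
  bug.
* Fraction-to-count conversions use `ceiling()`, so a positive fraction
  never keeps zero features.
* Everywhere a median split occurs, patients with index ≤ median form the
  low-risk group — one convention shared by filters and evaluation.

## Cox core and numerical choices

`fitCox()` delegates to the damped Newton solver of
`survival::coxph.fit` with the Efron tie correction (better than Breslow
with tied event times, and the standard default). Aliased (collinear)
columns get coefficient 0 and flip the `converged` flag; runaway
coefficients (|β| > 50, monotone likelihood / separation) are likewise
flagged rather than silently returned. Inside the bootstrap fitness loop,
covariates are standardized (concordance is scale-invariant) and a
separation-prone resample falls back to an early-stopped Newton iterate
(15, then 5 iterations): a truncated iterate on a monotone likelihood
still orders patients correctly, which is all a concordance fitness
needs.

Harrell's c-index is computed by exact pair enumeration: a pair is usable
iff the times differ and the earlier time is an event; tied indices score
0.5. Censoring-weighted variants (e.g. Uno's) are out of scope. The
two-group log-rank test delegates to `survival::survdiff`; Cohen's kappa
is the textbook (p_o − p_e)/(1 − p_e) and is reported as undefined when
both classifications are constant.

The train/test split (2/3 : 1/3) and the bootstrap are stratified by
event status, so every resample and both split halves preserve the event
fraction; mutation models and penalized models are evaluated by
resubstitution because sparse binary columns can produce training
resamples with no mutated patients at all.

## CPSO design

Positions are continuous k-vectors over the feature-index range; decoding
rounds each coordinate and repairs duplicates by advancing to the next
unused index (wrapping). This keeps the swarm update entirely standard
(inertia 0.72, cognitive = social = 1.49, velocity clamped to ±25 % of
the range) while guaranteeing exactly k distinct features per particle.
Fitness is the mean bootstrap concordance of the decoded subset, and the
bootstrap stream is seeded deterministically *per subset*, which makes
fitness a pure function of the subset: exhaustive search over all subsets
is then well-defined and the swarm can be tested against it exactly. The
winning subset across all restarts is refit once, unpenalized, on the
full training set; bootstrap fits are fitness-only. The reference
protocol used k = 5, 500 iterations and 1000 restarts; the package
default is 20 restarts, a desk-scale choice — both are plain
configuration.

## NFS design

Each feature seeds a one-feature model; a generation grows every model by
one eligible neighbor (in the data, not already a member, network degree
≤ 1000 — the hub rule that keeps promiscuous nodes like UBC from pulling
everything in), deduplicates candidate feature sets, scores them, and
keeps the global top 5 % for the next generation, up to 10 generations.
Two genuinely open points were resolved as follows:

* **Model score.** "Performance" of a grown model is the
  likelihood-ratio-test p-value of its multivariate Cox fit against the
  null model. It extends the univariate p-value criterion naturally and
  penalizes added features through the extra degree of freedom. Seeds are
  scored with the same LRT so one-feature and multi-feature models
  compete on one scale. A c-index-based score is a plausible alternative;
  the LRT was chosen for determinism and cost.
* **Top 5 % globally,** not per parent: per-parent quotas would keep
  weak lineages alive indefinitely.

For miRNA data the network is the surrogate graph: each miRNA inherits
all edges of its target genes. For merged data, gene-level edges expand
to every feature carrying that gene id regardless of source, and features
sharing a base id are linked to each other.

## Penalized selection

The penalized path is solved by `glmnet` (coordinate descent on the
elastic-net Cox partial likelihood) — the one deliberately bought
component, with the module contract enforced by tests (empty active set
at lambda_max, convergence to the unpenalized fit as lambda → 0, KKT
subgradient bounds for inactive features). glmnet sometimes terminates
the path early; the path routine then retries on the full explicit
log-spaced grid and keeps whichever path got further, because the
explicit grid can itself fail numerically on low-event data. Model choice
is "closest active-set size to the target (10), ties by cross-validated
partial-likelihood deviance", over event-stratified folds; this
operationalizes "the best model containing around 10 features", which
states an outcome rather than a rule. The mixing parameter defaults to 1
(pure lasso) with `enAlpha` exposed, since the reference protocol is
ambiguous between lasso and elastic net. The chosen feature set is refit
unpenalized so that all three selectors report coefficients on the same
(unshrunken) scale.

## The benchmark grid and agreement analyses

One event-stratified split per cohort and master seed is shared by every
cell, so kappa comparisons between cells are computed on identical
patients; blind-test cells compare on the common test third, and
mixed-mode pairs on the intersection of their evaluation sets. Table
cells display c-index × 100 rounded half-up, with tier letters a/b/c for
log-rank p < 0.05/0.01/0.001 and "-" for cells where a selector generated
no model; raw values are retained in the machine-readable grid. One known
inconsistency in the shipped reference composition table: its printed
overall model-size total (216) disagrees with the sum of its own rows
(39 + 26 + 43 = 108); `sourceDistribution()` reports the actual sum.

## Experiment problem sizes

The packaged experiments use sizes chosen to finish in minutes on one
CPU while leaving clear statistical margins:

* *Recovery*: 20 cohorts of n = 300, three planted expression features at
  effect 1.2 (a deliberately strong, single-source signal so that blind
  performance reflects selector quality rather than signal split across
  unobserved sources), 30 % censoring; each selector must reach blind
  c-index ≥ 0.65 with ≥ 1 planted feature in ≥ 80 % of cohorts.
* *Censoring vs agreement*: 20 matched cohort pairs (identical matrices,
  censoring 0 vs 0.8) of n = 200 with 150/80/100/25 features and effects
  of 0.5 — moderate on purpose: the agreement drop under censoring is an
  estimation-noise phenomenon, so effects must be recoverable with full
  follow-up yet noisy with ~40 events.

## Known limitations

Selector comparisons at desk-scale settings (few swarm restarts, reduced
iterations) understate CPSO relative to its full-budget configuration.
The generator's proportional-hazards survival model cannot probe
robustness to non-proportionality. The CNA filter's use of the full
cohort leaks evaluation information into feature ranking, faithfully to
the protocol being reproduced. Kappa agreement is computed on median
splits only; agreement of the continuous prognostic indices (e.g. rank
correlation) would be a finer-grained alternative.
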