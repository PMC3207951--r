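---
title: "Interspecies disease-network learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interspecies disease-network learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gene regulatory networks inferred from a single expression study are
fragile: samples are few and variable, a gene is measured through several
transcript isoforms of unequal quality, and each model system carries its
own artifacts.  This package implements a cross-species strategy for a
disease gene module: learn Bayesian networks within one species under
cross-validation, translate the learned relationships to other species
through ortholog groups, re-optimize them on the other species' data, and
keep only the relationships that recur with sufficient confidence in
*every* species.  The surviving consensus network, and the Markov blanket
of the disease-state node within it, are the analysis products.

```{r setup}
library(dandelion)
```

## The model

Each network is a conditional linear Gaussian (CLG) Bayesian network over
the standardized expression features plus one discrete **class node**
encoding the per-sample disease state (disease = 1, control = 0).  The
class node is the only discrete node, and because a CLG forbids continuous
parents of discrete nodes it is restricted to be a root: links between
genes and the disease state are class-to-gene edges.  Each gene node $x_j$
follows, per class configuration $c$,

$$x_j \mid \mathrm{pa}(x_j), c \;\sim\;
  N\!\big(\alpha_{jc} + \beta_{jc}^\top \mathrm{pa}(x_j),\; \sigma^2_{jc}\big),$$

fitted by per-stratum ordinary least squares with the maximum-likelihood
residual variance.  Structures are scored by the BIC (penalized
log-likelihood, higher is better), which decomposes over node families:

$$\mathrm{BIC}(G) = \log \hat L(G) - \tfrac{k}{2}\,\log n ,$$

with $k$ counting intercepts, weights, variances and the free class-prior
probability.  The penalty is what keeps small-sample structures sparse.

### Numerical safeguards

* Residual variances are floored at $10^{-6}$; singular designs fall back
  to a ridge-regularized solve ($\lambda = 10^{-6}$) with a warning.
* A class stratum smaller than (number of parents + 2) cannot support a
  per-class fit; the family is then fitted pooled across classes with a
  warning.  This matters for designs like 4 disease cases in 4 folds,
  where a training fold holds only 3 cases.
* Prediction assembles the per-class joint Gaussian
  $\mu = (I-W)^{-1}\alpha$, $\Sigma = (I-W)^{-1} D (I-W)^{-\top}$ and
  conditions by Cholesky-based Schur complements; missing evidence is
  marginalized exactly through the joint, never imputed.

## Structure search

Structures are learned by simulated annealing from the empty DAG, with
single-edge operators (add, remove, swap = reversal), geometric cooling
$t_i = t_0 r^i$, $r = (t_n/t_0)^{1/\mathrm{maxfc}}$, and the standard
Metropolis acceptance $\exp(\Delta/t_i)$ for worsening moves.  Defaults
follow the published procedure: $t_0 = 10$, $t_n = 0.001$, 1000 proposals
for intraspecies training and 500 during translation.  Decisions taken
where the procedure was open:

* **Cooling shape** — endpoints and budget are fixed by the procedure,
  the schedule shape is not; geometric cooling is the standard default.
* **maxfc counts proposals**, not accepted moves; exposed in the config.
* **Move selection** — uniform over the three operators, then uniform
  over that operator's slots; illegal draws (cycles, duplicate edges,
  constraint violations) are redrawn up to 50 times before the
  neighborhood is declared exhausted.
* **Ties reject**: a move with exactly zero score change keeps the
  incumbent.
* The **best-ever** structure is returned, not the final one, and only
  the families touched by a move are re-scored (a per-(child, parent-set)
  cache exploits BIC decomposability).

## Translation across species

A learned transcript-level structure is collapsed to a gene-level
**network map**: each edge becomes the unordered pair of its endpoint
genes, duplicates merge with a provenance count, and edges between
isoforms of the same gene are dropped (they have no gene-level reading).
Maps are undirected because re-learning in the target species re-orients
edges anyway, and confidence counting operates on relationships, not
arrows.

The map crosses species through an ortholog-group table.  One-to-many
orthology expands to *all* combinations — no one-to-one assignment is
forced — and links touching a gene without a target ortholog are dropped
and reported.  In the target species the search runs in *test mode*: an
edge is admissible only if its gene-level projection lies in the mapped
candidate set.  The two published variants differ exactly here:

* **naive** — transcript profiles are averaged per gene first
  ([naive_summarize()]); learning and translation proceed gene-to-gene.
  Averaging can cancel informative isoforms (anti-correlated isoforms
  average to a constant, which raises an error at re-standardization).
* **exhaustive** — everything stays at transcript level and the search
  itself chooses which transcript pair instantiates an allowed gene-gene
  link (model-driven transcript selection).

## Confidence, consensus and the disease domain

With $k$ training folds and $k'$ folds in a test species, a full run
produces $k$ intraspecies and $k \times k'$ interspecies networks per
test species.  A link's **confidence** in a species is the fraction of
that species' networks containing it (in either direction, counted once
per network).  The **consensus** at threshold $\tau$ keeps links whose
confidence reaches $\tau$ in *every* species — an intentionally stringent
intersection rule.  **Translatability** is the fraction of the training
species' above-threshold links that reappear above threshold in a test
species.  Because different species use different gene identifiers,
confidence tables key links by ortholog-group pairs whenever an orthology
map is supplied.

The **disease domain** is the Markov blanket of the class node — its
children plus their co-parents, given the class-as-root restriction —
read off a representative directed structure (the highest-BIC training
fold network, since the undirected consensus carries no orientations) and
then intersected with the thresholded consensus.  Fig-style exports bin
edge styles at confidences 0.25 and 0.75 (configurable).

## The synthetic study design

Everything is testable offline through a generative model that mirrors
the structure the method assumes: a shared acyclic weighted gene network;
class children with mean shifts in residual-sd units; per-species
sampling with species-private spurious edges (confounding a single
species sees), transcript isoforms
$t = \phi\,\tilde g + \sqrt{1-\phi^2}\,\varepsilon$ with per-rank
fidelity $\phi$, and ortholog dropout; quantile normalization and
standardization downstream.  The reference design
(`default_truth_spec()`) fixes the conditions used throughout the test
suite: 25 genes (15 disease-module genes carrying 8 true edges, 10 random
controls), 4 class children at effect 1.5 sd, 3 species of 40 samples
each with 3 private spurious edges, 4 folds per species.  Problem sizes
in the validation suite (for example 10-seed robustness replicates and
20-seed permutation nulls at these dimensions) were chosen as the
smallest designs at which the contrasts of interest are comfortably
powered on one CPU.

What the generator does *not* emulate: probe-level artifacts (background,
dye and batch effects), non-Gaussian expression, and realistic platform
differences.  Passing tests therefore demonstrate that the pipeline's
machinery behaves as designed under its own model assumptions — not that
the method recovers truth on arbitrary real microarray data.

One caveat worth knowing: quantile normalization is applied to the
module-sized matrix the generator emits.  With only a few dozen features
the transformation is far more aggressive than on a genome-wide array, so
generative-identity checks in the tests disable it
(`species_spec(quantile_normalize = FALSE)`), while pipeline-level tests
keep it on.

## Choices where the design was genuinely open

* **Standardization order** — features are standardized once per species
  before fold splitting (the pipeline diagrams place standardization
  ahead of cross-validation); fold training sets are not re-standardized.
* **Sample sd** ($n-1$) is used everywhere, matching common microarray
  practice.
* **Stratified folds** — plain random folds can leave a fold without a
  disease case, which makes the fold unevaluable; class-stratified
  assignment is forced, and a minority class smaller than the fold count
  is an error.
* **Class SSE** — the published figures report an SSE for the discrete
  class node; this is read as the Brier-style squared posterior shortfall
  $\sum_i (1 - P(\text{true class}_i))^2$, exposed in the metrics report.
* **Classification rule** — argmax posterior with ties to control
  (conservative toward the majority class).
* **Class evidence during expression prediction** — the class node is
  marginalized by default (`condition_on_class = FALSE` in
  [run_config()]), since test folds should not need the label.
* **Links lost in translation** (target gene absent from the platform or
  orthology) are dropped with logging rather than remapped.

## Known limitations

* Two class states only; no latent variables; no dynamic networks.
* Confidence scores carry no significance calibration (no permutation
  null is attached to them).
* The annealer is stochastic: on plateaus of score-equivalent structures
  it can return a non-optimal member within its proposal budget; the
  validation suite quantifies this on small exhaustively-enumerable
  cases.
* With weak class effects and very small folds, class-to-gene links may
  fall below the consensus threshold, leaving an empty disease domain;
  the extraction warns rather than fails.
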