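---
title: "Comparing single-gene, gene-set and network-based prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing single-gene, gene-set and network-based prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progsig)
```

## The problem

A prognostic gene expression signature is built in two steps: select
informative features from a genes x samples expression matrix of a two-class
cohort (good prognosis, `GP`, versus poor prognosis, `PP`), then train a
classifier on per-sample values of those features. Methods differ in what a
"feature" is. progsig implements and compares three families under one
cross-validated protocol:

* **single-gene** — rank genes by an empirical-Bayes moderated t statistic;
  features are gene expression values;
* **gene-set** — gene-sets are hub sub-networks of a protein-protein
  interaction (PPI) network with the edges ignored, summarised per sample by
  the median expression of their members and ranked by the same moderated t;
* **network-based** — three methods that use the PPI edges themselves:
  a PageRank-style damped ranking mixing each gene's expression-survival
  correlation with its neighbours' scores (`netrank`); ranking hub
  sub-networks by the mean absolute difference of within-class
  hub-interactor correlations (`taylor`, classified on per-edge expression
  differences); and ranking them by a between/within sum-of-squares ratio of
  those correlations (`bss_wss`, classified on hub gene expression).

A *hub* is a node of degree at least 5, the conventional threshold for a
highly connected node in interaction networks; a *hub sub-network* is the
hub, its immediate interactors, and only the hub-interactor edges.

## The statistics

**Moderated t.** For gene $g$ with class means $\bar x_{PP,g}, \bar x_{GP,g}$
and pooled variance $s_g^2$ on $d_g = n_1 + n_2 - 2$ degrees of freedom, the
variance is shrunk toward a prior,
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and
$\tilde t_g = (\bar x_{PP,g} - \bar x_{GP,g}) / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$
is referred to a t distribution on $d_0 + d_g$ degrees of freedom. The
hyperparameters $(d_0, s_0^2)$ of the scaled inverse-chi-square prior are
estimated by moment matching on $\log s_g^2$ (digamma/trigamma inversion);
when the observed log-variances are under-dispersed relative to pure
sampling, $d_0 = \infty$ and all variances shrink to $s_0^2$. Setting
`d0 = 0` recovers the ordinary pooled t exactly, which the tests exploit.

**NetRank.** With $c_j = |\mathrm{cor}(x_j, \text{survival})|$ normalised to
sum 1 and $M$ the degree-row-normalised adjacency matrix, iterate
$r \leftarrow (1-a)\,c + a\,M^\top r$ from $r^{(0)} = c$. The map is an L1
contraction with factor $a \in [0,1)$, so the iteration converges
geometrically to the solution of $(I - aM^\top)r = (1-a)c$ (the test oracle
solves this dense system directly). Degree-0 genes distribute nothing;
genes absent from the network are ranked after all network genes, by $c$
descending. The damping default is $a = 0.3$ (configurable): the ranking is
dominated by the survival correlation with a moderate network contribution.

**Taylor score.** Mean over a hub's edges of $|r_{GP} - r_{PP}|$, range
$[0, 2]$. The absolute value is deliberate: flips of opposite sign on
different edges must not cancel. A signed variant is available via
`signed = TRUE`.

**BSS/WSS score.** The per-edge within-class correlations are treated as
$m$ observations in each of the two classes:
$BSS = \sum_k m(\bar r_k - \bar r)^2$,
$WSS = \sum_k \sum_e (r_{ek} - \bar r_k)^2$, score $= BSS/(WSS + 10^{-9})$.
The epsilon keeps hubs with exactly constant within-class correlations
finite; hubs with fewer than two measured edges are dropped because their
WSS is degenerate. This edges-as-observations reading is one of several
possible operationalisations of "the BSS/WSS ratio of correlation values";
it was chosen because it yields a well-defined per-hub ratio from exactly
the per-edge class correlations the method names.

## Classifiers

All classifiers satisfy one contract: features x samples matrices in, GP/PP
factors out, prediction only on the training features in training order.

* **DLDA** is implemented from its standard definition: diagonal Gaussian
  class model with pooled per-feature variances, assign to the class
  minimising $\sum_g (x_g - \bar x_{kg})^2 / s_g^2$. Zero variances are
  floored at `1e-8 * max(var)`; exact ties go to GP (a fixed, documented
  convention used everywhere in the package).
* **rf / svm** — the comparison's decision-forest and maximum-margin
  classifiers. The reference implementations these would normally wrap
  (`randomForest`, `e1071`) are not in this package's supported dependency
  set, so compact implementations live in-package: a bagged CART forest
  (gini splits, `mtry = floor(sqrt(p))`, 500 trees by default, majority
  vote, seeded bootstrap) and a linear L2-regularised squared-hinge SVM
  solved in the primal by BFGS (cost 1 by default, deterministic). At the
  cohort sizes this package targets (tens of samples, at most a few hundred
  features) both are exact enough and fast; they are not tuned, and results
  should be read method-relative, as in any comparison where classifier
  hyperparameters are held fixed.

## Cross-validation protocol

`make_fold_plan()` builds `R` rounds of `K`-fold partitions, sizes differing
by at most one ("as equal as possible"), stratified by class so small
cohorts cannot produce single-class training folds (cohorts with a class
smaller than `K` fall back to unstratified folds with a warning).
`run_cv()` performs *in-fold* feature selection: the survival correlations,
within-class edge correlations and all rankings are computed on training
samples only, feature definitions are frozen and applied unchanged to the
test fold, and every sample is predicted exactly once per round. A
dedicated test corrupts test-fold labels and expression and asserts the
selections do not move.

One fold plan is shared across all method x classifier combinations:
patient-level comparison ("is this patient captured by method A but not
B?") is only meaningful on identical resampling.

**Overall error** is the fraction of misclassified predictions over all
rounds and samples. With unequal fold sizes this differs (at order $1/n$)
from the unweighted mean of per-fold error rates; the pooled definition is
used because it makes two conservation identities exact, and the tests
assert them on every run: the class-size-weighted class-specific errors
reconstruct the overall error, and so does the patient accuracy matrix
(`1 - mean(correct)/R`).

**Stability** is the mean number of features shared by pairs of the
`R * K` selected top-`n` lists (`n` in 20, 30, 40, 50), reported also as a
fraction of `n`. The mean over all pairs is computed exactly through
per-feature occurrence counts ($\sum_f \binom{m_f}{2}$ intersecting pairs),
so 500 lists cost a table, not 124,750 intersections.

**Patient-level accuracy** counts, per sample, the rounds in which it was
correctly classified. A patient is *easy* when correct in at least 95% of
rounds under every method, *hard* when at most 5% under every method, and
*differential* otherwise; the thresholds operationalise "almost
always/never" and are configurable.

## The synthetic cohort generator

`simulate_dataset()` emulates a small two-class prognosis cohort with three
planted, ground-truth-labelled archetypes of informative feature:

* **differential expression** — `n_de_genes` genes shifted by
  `delta * sigma` in PP (default 20 genes at `delta = 2`);
* **differential median expression** — `n_de_sets` hub gene-sets whose
  every member is shifted (default 5);
* **differential correlation** — `n_flip_hubs` hub sub-networks whose
  interactors are generated as $\rho_k h + \sqrt{1-\rho_k^2}\,\varepsilon$
  with `rho_gp = 0.8` versus `rho_pp = -0.8` (default 5), so marginals stay
  $N(0, \sigma^2)$ while the within-class edge correlation flips.

Defaults mirror a realistic regime: 2,000 genes, 25 GP / 22 PP samples, a
network of 50 disjoint hub stars (degrees 5-8) plus 1,000 background edges
among non-hub genes (capped at degree 4 so the generated network has
exactly 50 hubs), and survival drawn uniformly from 4-10 years (GP) versus
0.1-1 years (PP) — a complete separation emulating a "more than 4 years"
versus "less than 1 year" prognosis definition, which gives NetRank's
survival correlation real signal. The cohort size and network sparsity
(about 1.3k edges for 2k genes) are desk-scale stand-ins for
platform-sized cohorts and curated interactomes.

Two generator choices matter for interpretation. First, planted DE genes
are placed among *network* genes (background-edge genes outside all hub
sub-networks) by default: a network-blind placement would make recovery by
a network-based ranking impossible by construction, which would test the
placement, not the method. Second, `subspace_split = TRUE` plants the DE
shift in only the first half of the PP samples and the correlation flip in
only the second half, producing cohorts where the single-gene and
differential-correlation methods genuinely capture different patients.

What the generator does *not* emulate: platform artifacts, batch effects,
heavy-tailed or heteroscedastic noise (a t-distributed option exists but is
off by default), censored survival, and correlated background genes beyond
the planted structure. A green recovery test therefore establishes that a
method finds its matched archetype under clean Gaussian conditions — not
that it will do so on real microarray data.

## Numerical and design notes

* Tie-breaking is by feature identifier ascending everywhere, and hubs are
  ordered by degree descending then identifier, so all five selection
  methods are bit-reproducible; no RNG is consumed inside selection.
* Hubs are recomputed on the expression-restricted (aligned) network:
  correlations and medians are only defined for measured genes. Users who
  want platform-independent hubs can call `find_hubs()` before
  `align_dataset()`.
* Undefined Pearson correlations (zero-variance profiles) are set to 0 with
  a warning wherever they occur — a constant profile carries no
  co-expression or survival signal.
* Duplicate gene rows at load keep the highest-variance row; missing values
  are rejected outright, since inputs are expected to be fully
  pre-processed.
* The even-sized median is the mean of the two central values; edge
  features are oriented hub minus interactor. Both are arbitrary but fixed.
* The DLDA path of the pipeline is bit-reproducible from the run seed; the
  forest derives per-fold seeds from it, so reruns of a config are
  identical.
* In the null-calibration test, the 99% binomial band around 0.5 is
  computed with the *patient* as the independent unit (n = cohort size),
  not the R x n prediction count: a patient's predictions across rounds are
  strongly dependent (same data, overlapping training sets), and the
  empirical spread of the null overall error matches the per-patient band.
* The differential-subspace demonstration uses the forest classifier:
  DLDA compares class means, and a pure correlation flip leaves the means
  of edge-difference features unchanged in both classes, so a mean-based
  classifier is provably blind to it. Trees split on the dispersion of
  those features instead. The demonstration cohort is 20 GP / 24 PP with
  the PP class split 12/12 between archetypes, and 200 trees (scaled down
  from the 500-tree default purely for runtime).

## A worked run

```{r example, eval = FALSE}
cfg <- list(
  simulation = list(seed = 7),             # the default stated world
  methods = c("mod_t", "netrank", "taylor"),
  classifiers = "dlda",
  R = 20, n_features = 50, seed = 7)
report <- run_all(validate_config(cfg), out_dir = "progsig_out")
report$errors
report$stability
head(report$patients)
```

The same run is available from the command line via
`inst/cli/progsig.R run --config cfg.yaml --out dir/`, and
`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the package's acceptance quantities (oracle agreements, planted-signal
recalls, null calibration, conservation identities, stability extremes and
the subspace Jaccard) from scratch.

## Known limitations

* The BSS/WSS operationalisation and the NetRank damping default are
  package choices where the method descriptions admit alternatives; both
  are parameterised.
* The in-package forest and SVM are small-data implementations; for
  thousands of features or samples a dedicated library would be
  preferable.
* Survival enters only through Pearson correlation (as NetRank requires);
  no survival modelling, censoring, or significance testing between method
  error rates is provided.
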