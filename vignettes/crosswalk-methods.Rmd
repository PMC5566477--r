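---
title: "Connecting protein changes to transcriptional changes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connecting protein changes to transcriptional changes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosswalk)
```

## The problem

When tumor cells are perturbed - for instance, co-incubated with platelets -
two read-outs are commonly collected: a protein array (RPPA) measuring
abundance and phosphorylation of a few hundred antibodies, and a genome-wide
expression profile. Each produces its own list of hits: differentially
regulated proteins (DRPs) on one side, differentially expressed genes (DEGs)
on the other. The scientific question is which protein *connects* the two
layers: which signaling protein, altered at the protein level, plausibly
drives the observed transcriptional program.

`crosswalk` answers this with a network-propagation approach: a random walk
is started at the DRPs on a background gene network assembled from curated
pathways, with transition probabilities gated by how transcriptionally
interesting each target gene is. Walk probability accumulates along routes
that lead from the seed proteins into the differential-expression signal;
the top-ranked genes are mapped back onto the network, and the major
connected component of that subgraph is read as the crosstalk pathway. A
seed protein sitting inside that component is the nominated connector.

Around this core, the package provides the stages any such analysis needs:
the differential tests themselves, a compound covariate predictor (CCP) for
translating a signature into patient stratification, survival utilities
with a percentile cutoff scan, and synthetic-data generators with planted
ground truth so that everything is testable offline.

## Differential stages

Proteins are tested with a per-feature linear model containing an intercept
and a two-level group effect; the group effect is assessed by an F-test on
(1, n - 2) degrees of freedom. For a two-group design this is exactly the
squared pooled-variance t statistic, an identity the test suite checks to
1e-12 on random data. DRPs are selected on **raw p < 0.05** - selection on
raw p rather than FDR is deliberate, mirroring standard RPPA practice where
the antibody panel is small and pre-curated.

Genes are tested with a two-sided two-sample t-test (pooled by default;
Welch by flag, since published analyses rarely state which form was used)
and adjusted with the Benjamini-Hochberg step-up procedure. The per-gene
FDR is what feeds the walk. The reported DEG list uses p < 0.001 by
default, the conventional threshold for microarray heat-map/GSEA input.

Features with zero residual variance have no defined p-value. They are
flagged and excluded from selection rather than assigned p = 0: a constant
row is evidence of a saturated or failed probe, not of an infinitely
significant one.

## The FDR-weighted walk

The background network is the union of pathway edge lists: undirected,
unweighted, deduplicated, with pathway provenance kept per edge. Edges are
binary because the transition formula multiplies adjacency by a node
weight; any confidence weighting would double-count. Node order is
lexicographic everywhere so matrices and tie-breaks are reproducible.

With adjacency $A = \{a_{ij}\}$ and node weights $Q = \{q_j\}$, the
transition matrix is

$$p_{ij} = \frac{w_{ij}}{\sum_j w_{ij}}, \qquad w_{ij} = a_{ij}\, q_j,$$

and the walk iterates $g^{(n)} = (1-r)\, g^{(n-1)} P + r\, g^{(0)}$ from a
seed vector $g^{(0)}$ uniform over the mapped DRPs, until the L1 step norm
drops below `tol` (default 1e-5). At $r = 0$ this is the plain power
iteration $g^{(n)} = g^{(n-1)} P$.

Three design points deserve explanation:

* **Weight mode.** The default is `one_minus_fdr`:
  $q_j = \max(1 - \mathrm{FDR}_j, w_{\min})$. Taking $q_j$ to be the FDR
  itself would steer the walk *away* from significant genes, the opposite
  of the method's purpose of connecting protein seeds to transcriptional
  change; the literal `fdr` mode is nevertheless retained and recorded in
  output metadata, and neither mode is asserted to be "the" original. For
  the FDR-as-weight reading, unmeasured nodes get weight 1 (no evidence
  against them); for the significance reading they get the floor.
* **Weight floor.** $w_{\min} = 0.01$ on every node. Without it, any
  signaling intermediate that is not itself differentially expressed would
  zero out every path through it, disconnecting precisely the connector
  routes the method exists to find. The floor keeps such nodes reachable
  at low priority.
* **Restart.** The literal update has $r = 0$, but on a connected,
  non-bipartite (hence ergodic) network the $r = 0$ walk converges to the
  stationary distribution of $P$ *regardless of the seeds* - the seed
  proteins then influence nothing, and on a bipartite component the
  iteration oscillates with period 2 and never converges at all. Both
  facts are verified in the tests (seed-independence to within twice the
  tolerance; the K2 oscillation flagged as non-convergence). The restart
  parameter is therefore exposed, and the planted-truth benchmarks run at
  $r = 0.5$, where the walk provably contracts in L1 with factor $1 - r$
  and its fixed point $g^\* = r\, g^{(0)} (I - (1-r)P)^{-1}$ matches a
  direct linear solve to 1e-8. Dangling (degree-0) nodes get a unit
  self-loop: stochasticity is preserved without teleporting mass.

After convergence the top `k_top = 50` genes are taken (probability
descending, symbol ascending on ties; seeds compete on probability by
default, since a connector that does not rank is no connector - a
`force_include_seeds` flag appends them beyond k when wanted). The induced
subgraph's largest component - ties broken by total walk probability, then
lexicographically - is the crosstalk component, and its nodes are classed
as seed DRP, receptor, transcription factor, DEG, or signaling for
plotting and export.

### Numerical conventions

The step norm is L1 (the natural norm for probability vectors; L-infinity
by flag, since the convergence criterion's norm is rarely stated in
publications). Convergence failure at `max_iter` is a warning (pipeline
mode) or an error advising a positive restart (strict mode); it is never
silently accepted. Row-stochasticity is enforced by exact renormalization,
and the suite asserts rows sum to 1 within 1e-12 and iterates stay on the
simplex within 1e-10.

## The CCP signature classifier

To translate a gene signature into patient stratification the package
implements the classical compound covariate predictor. The cited
algorithm's original description leaves the exact variant open, so the
canonical form is fixed here and documented: per signature gene, the
weight is the pooled two-sample t statistic between training classes
(oriented class2 - class1, classes sorted lexicographically); each
sample's compound covariate is the weighted sum
$c_i = \sum_g t_g x_{gi}$; the decision threshold is the midpoint of the
two class-mean covariates. Because
$\bar c_2 - \bar c_1 = \sum_g t_g (\bar x_{g2} - \bar x_{g1}) \ge 0$,
class 2 always lies above the threshold, making the decision rule
orientation-free.

The "probability of membership" is a Gaussian posterior on the compound
covariate with equal priors and a **common pooled within-class sd**. With
a shared sd the posterior crosses 0.5 exactly at the midpoint threshold,
so the probabilistic and threshold rules agree everywhere, including the
boundary (probability exactly 0.5, assigned to the later class by the
deterministic tie rule). Per-class sds are recorded for inspection but
deliberately not used in the posterior: unequal sds would let the two
rules disagree near the boundary, an inconsistency worse than the small
fidelity gain.

Cross-cohort application ("train on one cohort, stratify another") needs a
harmonization choice that published descriptions usually leave implicit.
The default standardizes each signature gene within each cohort (z-scores
against the cohort's own mean and sd) and applies the threshold computed
on the standardized training data; t-statistic weights are themselves
invariant to per-gene affine transforms, so only the threshold scale needs
this care. `"none"` is available when cohorts are already comparable.
Model genes missing from a test cohort contribute at the neutral value
(cohort mean), i.e. z = 0.

Leave-one-out cross-validation refits weights and threshold on every fold
- reusing the full-data weights would leak the held-out label into the
model and understate the error. On label-permuted data the LOOCV error
concentrates near 0.5, and on separable synthetic cohorts (2-sd signature
effect) it is at or near 0; both are asserted in the acceptance tests.

## Survival and the percentile cutoff scan

Kaplan-Meier curves and the two-group log-rank test are delegated to the
`survival` package (the aggregated-risk-set form handles ties). The
percentile cutoff scan dichotomizes a continuous marker at every
percentile in a band - 10th to 90th by 1 by default, which also enforces
at least ~10% of subjects per side - and records the cutpoint with the
smallest log-rank p.

The scan applies **no multiple-testing correction by default**, on
purpose: that is how such cutoffs are typically reported, and the package
reproduces the procedure honestly while measuring its cost. Scanning ~80
correlated cutpoints inflates the chance of a "significant" split far
beyond the nominal 5% - the acceptance suite measures roughly a third of
null replicates flagged at n = 100 - so a min-p permutation adjustment is
provided as a corrective option. A single *pre-specified* cutpoint, by
contrast, holds its nominal level (measured within [0.03, 0.07] at
alpha = 0.05 over 2000 null replicates). Dichotomies use
`marker > quantile(marker, pct)`, which depends on ranks only and is
therefore invariant under strictly monotone transforms of the marker.

## What the synthetic generators emulate - and what they do not

The generators reproduce the *statistical structure* each stage consumes,
with truth recorded alongside:

* `simulate_network()` builds a KEGG-like collection: random connected
  pathways (spanning tree plus extra edges) over a shared symbol pool,
  plus a planted crosstalk axis: seed protein -> signaling chain -> hub ->
  DEG cluster, stored as its own pathway. The seed and chain belong only
  to the planted axis, while the hub and DEG genes are embedded in
  background pathways. This asymmetry is deliberate: the seed models an
  RPPA phospho-protein and the chain signaling intermediates that
  transcript-level pathway projections touch only through this route. It
  is also what keeps the planted truth identifiable - if the seed's walk
  mass immediately dissipated into dozens of background edges, no method
  could recover the planted route and the benchmark would measure the
  instance, not the method.
* `simulate_expression()` / `simulate_rppa()` draw homoscedastic Gaussian
  noise with mean shifts on the planted features (negative by default on
  the protein side, mimicking a dephosphorylation read-out). Gaussian
  noise first: the pipeline's own t/F machinery assumes it, and the tests
  should validate the pipeline under its own model before anything else.
* `simulate_cohorts()` produces train/test cohorts with a 2-sd signature
  effect and a clinical covariate (platelet-count-like, mean 300, sd 80,
  units 1e9/L) shifted by 1 sd in the active class.
* `simulate_survival()` draws a Uniform(0,1) marker, exponential event
  times with the hazard multiplied by the hazard ratio above a marker
  changepoint, and independent exponential censoring calibrated to an
  approximate censoring fraction.

They do **not** emulate platform-specific artifacts (probe effects,
batch structure, heteroscedastic or heavy-tailed noise), realistic KEGG
topology beyond degree heterogeneity, directed or signed regulation, or
correlated gene expression. Consequently a green benchmark demonstrates
that the algorithms do what they claim under their own assumptions - it
does not certify performance on any particular real dataset.

## Benchmark problem sizes and defaults

The planted-recovery benchmark uses a 500-symbol pool, 20 background
pathways of 15 nodes, a 3-node signaling chain and a 10-gene DEG cluster,
with DEG FDRs at or below 0.001 against a Uniform(0.2, 1) background, run
at restart 0.5 and k = 50 over 100 seeded replicates. The demo
(`run_demo()`) uses 10 expression samples per group - enough for a 3-sd
shift to reach the small FDRs the walk weighting expects, whereas a
triplicate design (the generator's default, matching common co-incubation
experiments) cannot push BH FDRs of 10 genes among ~500 below 0.001 - and
a 60-antibody protein panel in which only the seed protein maps into the
transcript-level network. CCP benchmarks use 40 training / 200 test
samples; survival benchmarks 100-200 subjects, hazard ratio 3,
changepoint at the 40th percentile. The analysis defaults are
recorded verbatim in every run summary: DRP alpha 0.05, DEG report
p 0.001, walk tolerance 1e-5, top-50.

## Known limitations

* The walk is undirected; KEGG relations are directed, and direction
  could matter for receptor-to-TF routes. Directed support is out of
  scope here.
* No significance is attached to the crosstalk component itself (no
  permutation null over networks); the component is descriptive.
* The CCP is strictly two-class, and harmonization beyond per-cohort
  z-scoring (e.g. quantile normalization, batch correction) is the
  caller's responsibility.
* The cutoff scan's default output reproduces an uncorrected procedure;
  any confirmatory use should rely on the permutation-adjusted p.
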