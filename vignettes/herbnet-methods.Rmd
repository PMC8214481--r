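---
title: "Mining core and disease-specific herbs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining core and disease-specific herbs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The problem

Hospital electronic medical records for a chronic disease such as
hypertensive nephropathy (HN) contain thousands of herbal prescriptions
("formulae"), each a set of roughly two dozen herbs chosen per visit.  Two
questions drive the analysis: which herb combinations form the *core* of
clinical practice for the disease, and which herbs are *specific* to it
rather than generic tonics; and, downstream, through which compounds,
protein targets and pathways those herbs plausibly act.  `herbnet`
implements this mining pipeline as reusable, tested components, together
with a synthetic-data module that emulates the statistical structure of the
records, which are not publicly distributable.

## Co-prescription network and shell extraction

Prescriptions are transactions; herbs are nodes; the edge weight
$w_{ab}$ is the number of prescriptions containing both $a$ and $b$
(presence-based, so repeated mentions within one formula count once).
`extract_shell()` sorts edges by weight and retains the largest prefix $K$
satisfying

$$S_k \cdot N \;\ge\; k^{\alpha} \cdot S_N ,$$

where $N$ is the number of herbs in the data, $S_N$ the total pair weight,
$S_k$ the cumulative weight of the $k$ heaviest pairs, and $\alpha$ the
degree coefficient (default 2.4).  `extract_hierarchy()` peels layers
iteratively from the residual network; herbs incident to layer-1 edges are
the core herbs.

Three choices deserve comment.

* **Reading of the criterion.**  The inequality is read with $S_k$
  cumulative over weight-sorted pairs and $N$ fixed at the original herb
  count across iterations ($S_N$ shrinks with the residual).  Ties between
  equal-weight edges are broken lexicographically on the herb pair, making
  output deterministic across platforms.
* **A structural ceiling.**  Since $S_k \le S_N$, the criterion can hold
  only while $k^\alpha \le N$, i.e. a layer can never exceed
  $N^{1/\alpha}$ edges (about 12 edges for $N = 425$, $\alpha = 2.4$).
  Layer 1 is therefore always a small set of dominant pairs.  In data where
  formulae are long and weight is spread over many pairs, even $k = 1$ can
  fail the criterion; `extract_shell()` then falls back to the single
  heaviest edge, flags `fallback = TRUE` and warns, so the iteration always
  terminates.
* **Test regime for recovery.**  Because of the ceiling, planted-core
  recovery is exercised on compact formulae (mean 8 herbs, 4 core herbs at
  inclusion 0.8 over a 425-herb Zipf background), a regime chosen from the
  ceiling argument above: there the six core pairs carry the dominant weight
  share and the retained prefix ($K \approx 4\text{–}6$) must cover all
  core herbs.  With realistically long formulae the criterion itself, not
  the implementation, limits what layer 1 can contain.

## Disease-specific herbs: relative risk and chi-square

With case formulae as the exposed group, counts are herb-use frequencies at
prescription level: $n_{ij}$ uses of herb $j$ in case formulae, $n_i$ all
herb uses in case formulae, $n_j$ all uses of herb $j$, $N$ all uses.  The
relative risk is

$$RR \;=\; \frac{n_{ij}/n_i}{(n_j - n_{ij})/(N - n_i)} ,$$

and each herb's $2\times2$ table (cells $n_{ij}$, $n_i-n_{ij}$,
$n_j-n_{ij}$, $N-n_i-n_j+n_{ij}$) is screened with Pearson's chi-square
(df 1, no continuity correction by default — the counts are large; Yates
is available).  A herb is selected when $RR > 1$ and $p < 0.05$, raw
p-values by design: the screen mirrors common practice for this kind of
exploratory contrast, and a Benjamini–Hochberg option is exposed for
stricter use.  Herbs absent from controls give $RR = \infty$; tables with
a zero margin have no defined p-value and are excluded with a warning.

Under the synthetic null the screen is approximately calibrated.  The one
caveat is mechanical: prescriptions have a fixed size, so herb inclusions
within a formula are negatively correlated, deflating the chi-square
slightly when the formula occupies a large fraction of the universe.  The
calibration test therefore uses a wide (200-herb), nearly flat background,
where the empirical false-positive rate sits at the nominal 5% within
Monte-Carlo error; with a 50-herb universe it drops to about 3%, which is
the conservative direction.

## Association rules

`apriori()` is a from-scratch level-wise miner with downward-closure
pruning, checked against exhaustive subset enumeration.  `generate_rules()`
scores every (LHS, single-item RHS) partition of each frequent itemset:

* support $= \mathrm{count}/n$, coverage $=$ LHS support,
  confidence $=$ support/coverage, lift $=$ confidence / RHS support;
* rules are kept when support $> 0.2$ **and** confidence $> 0.5$, strict
  inequalities by default (configurable to $\ge$);
* RHS is restricted to single items by default (every reference rule is
  1-to-1); multi-item RHS sits behind `max_rhs`.

Output is ordered by lift, then support.  `group_rules()` embeds rules as
binary incidence vectors over the LHS and RHS item blocks and runs seeded
k-means with restarts drawn from the distinct vectors, so equal rules
always co-cluster and results are reproducible under the seed.  The number
of groups is a configuration choice with no claimed default.

The package bundles ten published reference rules for HN co-prescriptions
(`hn_reference_rules()`).  Because the printed metrics are rounded to three
decimals but the co-occurrence counts are exact, the underlying integer
margins can be recovered by a small consistency search
(`reconstruct_rule_transactions()`); mining the rebuilt transactions with
the package's own Apriori reproduces every printed cell to print precision
(±0.001; ±0.01 for lift, which compounds two rounded inputs).

## Molecular network, MCODE and random walk with restart

`build_molecular_network()` unions the confidence-filtered protein
interaction edges (STRING-style scores, auto-detected 0–1 or 0–1000 scale,
default cut-off 0.9) with weight-1 compound–target edges; disease genes are
marked, and those absent from the network are kept as isolated seeds with a
warning.

`mcode_cores()` implements the published three-stage MCODE procedure on the
protein-only view: node weight = core number × density of the highest
k-core of the closed neighbourhood (degree < 2 scores 0); greedy growth
from the highest-weighted seed admitting neighbours with weight above
$(1-\mathrm{cutoff}) \times$ seed weight (cutoff 0.2); optional haircut of
singly-connected members.  Parameters are the plug-in's published defaults.

`rwr()` iterates $p \leftarrow (1-c)\,W p + c\,s$ with $W$ the
column-normalised weighted adjacency, $s$ uniform over the disease-gene
seeds and restart probability $c = 0.75$, stopping when the L1 change falls
below $10^{-9}$.  Design choices the procedure leaves open: column
(random-walk) normalisation rather than symmetric; a uniform seed vector;
interaction confidences as walk weights.  The walk runs on the full
heterogeneous graph, so compounds are scored by their diffusion proximity
to the disease genes; `retain_core_compounds()` keeps compounds strictly
above the type-7 third quartile of the compound scores, with deterministic
ID tie-breaks.  On any connected fixture the score vector matches the
closed form $c\,(I-(1-c)W)^{-1}s$ and sums to one; nodes unreachable from
the seeds score exactly zero.

## Enrichment and core pathways

`enrich()` tests a query gene list against a GMT collection with the exact
upper-tail hypergeometric probability $P(X \ge k)$,
$X \sim \mathrm{Hypergeometric}(M, K, n)$, using the collection's own
universe (all annotated genes) as $M$ — not the network node set, which
would entangle enrichment with network coverage.  Terms with zero overlap
are excluded before the Benjamini–Hochberg correction, keeping $q$ values
comparable across query lists; significance is $q < 0.05$.  The separately
named "Q" and "adjusted P" criteria sometimes quoted for this procedure
are treated as one BH quantity — nothing distinguishes their definitions,
and applying two corrections to one test would be arbitrary.

`core_pathways()` applies the retention rule downstream: candidate terms
are the disease-significant ones, and a herb keeps a candidate term when
its enriched-gene count strictly exceeds the type-7 third quartile of that
herb's counts over the candidates.  A herb with equal counts everywhere
keeps nothing (strict inequality), and core sets are by construction
subsets of the disease-significant terms.

The uniformity check of the null planted term uses a large-overlap regime
(universe 4000, sets of 300, query ≈ 1000) so the discrete hypergeometric
p-value is nearly continuous; with small sets the test statistic has few
support atoms and a Kolmogorov–Smirnov comparison against the uniform is
not meaningful.  Detection of the planted term is exercised at fold 5 with
sets of 100 genes (mean overlap ≈ 35 against ≈ 10 under the null), where a
properly implemented test flags it essentially always.

## Profiles and Ward clustering

`build_profile()` produces a herb × feature matrix: binary incidence for
symptom and target levels, counts (enriched genes per pathway) for the
GO/KEGG levels, where the number of enriched genes carries the signal a
0/1 incidence would discard.  Distances are
Euclidean ($D_{ij}^2$ equals the Hamming distance on binary rows).

`ward_cluster()` implements Ward's method directly on the error sum of
squares,
$ESS = \sum_i x_i^2 - \tfrac{1}{n}\bigl(\sum_i x_i\bigr)^2$
per coordinate: at each step it merges the pair of clusters minimising
$\Delta ESS = \frac{n_A n_B}{n_A+n_B}\lVert c_A - c_B\rVert^2$, which is
algebraically the increase in total ESS (for singletons, half the squared
distance).  Fidelity to the printed formula was preferred over the
Lance–Williams `ward.D2` variant, which is available as an option (its
heights are on the $\sqrt{2\,\Delta ESS}$ scale).  Ties are broken on the
smallest pair of cluster labels, a cluster being labelled by its smallest
original row index.  Ward is reducible, so merge costs never decrease; the
implementation is checked merge-by-merge against an oracle that recomputes
every candidate ESS from scratch, and cluster counts per level are
configuration (defaults 4/3/4/4 for symptom/target/GO/KEGG) — they are
deliberately never inferred from the data.

## The synthetic cohort generator

`simulate_cohort()` draws, per prescription: a size from a rounded normal
truncated to $[1, \text{universe}]$ (defaults 23.84 ± 3.88 herbs, the
study-scale summary, over 425 herbs); each core herb independently with a
fixed inclusion probability (default 0.8); each specific herb with
probability $p_{bg}$ in controls and $RR_{target}\cdot p_{bg}$ in cases,
planting the relative risk at the same prescription-level granularity the
RR statistic measures; and Zipf-weighted background herbs without
replacement for the remaining slots (exponent 1 by default — prescription
frequencies are heavy-tailed; the exponent is a parameter so tests can
flatten it).  `simulate_molecular()` adds an Erdős–Rényi or
preferential-attachment interaction network, compound–target edges grouped
into herbs, a disease gene list with a controlled overlap with the herb
targets, and a gene-set collection whose first term samples disease genes
with a weight equal to the planted fold.

What the generator does *not* emulate: longitudinal structure, dosages,
co-prescription correlations beyond the planted core block, symptom
free-text, and the curation noise of real records.  Passing recovery tests
therefore show that each statistic detects the structure it is defined on,
at realistic sample sizes — not that the pipeline is robust to the full
messiness of hospital data.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use: 100 (tests) / 30 (script)
cohort replicates of 1000 + 1000 prescriptions for recovery and
calibration; 50 random 8-item × 30-transaction databases for the Apriori
oracle; 100 random ≤ 8-point instances for the Ward oracle; 100 random
≤ 50-node graphs for the walk; and 200 replicates for the enrichment null.
These sizes give stable Monte-Carlo estimates while keeping a full run in
the low minutes on one CPU.  All randomness flows through explicit integer
seeds: the same configuration reruns byte-identically, and the pipeline
manifest records the configuration hash, seed and input checksums.

## Known limitations

* The shell criterion's $N^{1/\alpha}$ ceiling (above) means layer-1 cores
  are intrinsically small; users wanting larger cores should lower
  $\alpha$, not expect more from the default.
* The RR screen uses raw p-values by design; with hundreds of herbs some
  false positives are expected (and visible in pipeline runs on synthetic
  data).
* MCODE and RWR operate on whatever interaction network they are given;
  confidence filtering changes results materially and the 0.9 default is a
  choice, not a property of the algorithms.
* Reproducing a specific study's absolute compound scores or cluster
  memberships requires its exact database exports, which are not public;
  the package validates the algorithms, not those artefacts.
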