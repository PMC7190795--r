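---
title: "Rich-club analysis of weighted structural connectomes: models and methods"
author: "richconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rich-club analysis of weighted structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richconn)
```

# The scientific problem

Diffusion-tractography studies of clinical populations often ask whether a
disorder preferentially disrupts the *rich club* of a structural brain
network — the small set of high-degree hub regions, and the unusually
strong white-matter connections among them. A typical design compares a
patient group against matched controls: per-subject weighted networks are
built from streamline counts, hub organization is quantified against
degree-preserving random networks, connections are split into rich-club,
feeder and local classes, class strengths are compared between groups by
permutation tests with demographic covariates removed, and within patients
the class strengths are correlated with clinical severity scores.

`richconn` implements that full pipeline, plus a synthetic-cohort
generator that plants the statistical structure the analysis assumes, so
every stage can be exercised and calibrated without any imaging data.

# Network construction

A subject's raw connectome consists of a symmetric streamline-count matrix
$FN$, a symmetric mean-FA matrix with the same support, and per-region
volumes. Edge weights are

$$w_{ij} = \frac{FN_{ij}\, FA_{ij}}{(v_i + v_j)/2},$$

the streamline count scaled by the mean fractional anisotropy along the
bundle and normalized by the *arithmetic mean* volume of the two regions
("average volume" admits several readings; the arithmetic mean is the
plain one and is what `buildNetwork` uses). Edges with $FN$ below a
threshold (1 by default; 2, 3, 5, 10 as sensitivity settings) are removed.

Group-level analysis uses a **consensus backbone**: an edge is kept iff it
is present in at least a fraction $p$ of the subjects (0.50 / 0.75 / 0.90;
0.75 is the primary level). The backbone definition in the literature only
states the support rule; `groupConsensus` assigns each retained edge the
mean weight over the subjects in which it is present, and downstream
rich-club computation uses those weighted values (a binary variant is
trivially obtained by masking).

# Graph metrics and conventions

Where the literature defers to the standard weighted-graph definitions,
several variants exist; `richconn` fixes these conventions:

* **Edge length** is the reciprocal weight $1/w$ (the convention of the
  standard connectome toolboxes); shortest paths are Dijkstra paths.
* **Characteristic path length** $L_p$ averages only *finite*
  ordered-pair distances; disconnected pairs are excluded from $L_p$ but
  contribute $0$ to efficiency, so both remain defined on fragmented
  networks.
* **Global efficiency** $E_g$ is the mean of $1/d_{ij}$ over ordered
  pairs; **nodal efficiency** of $i$ is the mean of $1/d_{ij}$ over
  $j \ne i$; **local efficiency** is the mean over nodes of the global
  efficiency of the subgraph induced by each node's neighbors (nodes with
  fewer than two neighbors contribute 0).
* **Clustering** uses the Onnela form: the geometric mean of triangle
  weights normalized by the network maximum, which reduces to the binary
  triangle fraction on 0/1 weights. Nodes of degree < 2 contribute 0.

Small-world indices are computed against an ensemble of degree-preserving
random networks (`rewireNull`): Maslov–Sneppen double-edge swaps on the
binary topology (10 attempted swaps per edge), followed by random
reassignment of the original weight multiset to the rewired edges. Then
$\gamma = C_p / \overline{C_p^{rand}}$,
$\lambda = L_p / \overline{L_p^{rand}}$, $\sigma = \gamma/\lambda$, using
the arithmetic mean (not median) of the null metrics. The reference
ensemble size is 1000; the package accepts any `nNull`, and the test suite
uses 30–100 so the whole suite stays within minutes. A degenerate ensemble
(zero mean null clustering) yields `NA` indices rather than an error.

Metrics across sparsity are summarized by the trapezoidal area under the
metric-versus-sparsity curve on the grid 0.10–0.40 in steps of 0.01.
`applySparsity` keeps the `round(s * N(N-1)/2)` largest-weight edges
(half-away-from-zero rounding), breaking ties at the cut lexicographically
by edge index so results are deterministic.

# Weighted rich-club coefficient and edge classes

With $S_k$ the set of nodes of binary degree $> k$, $E_{>k}$ the number of
edges inside $S_k$ and $W_{>k}$ their summed weight,

$$\Phi^w(k) = \frac{W_{>k}}{\sum_{l=1}^{E_{>k}} w_l^{ranked}},$$

where the denominator sums the $E_{>k}$ largest edge weights anywhere in
the network — hence $\Phi^w \le 1$, with equality when the club edges are
exactly the strongest ones. $\Phi^w(k)$ is undefined (flagged `NA`, never
coerced to 0) when the club has no edges. The normalized curve
$\Phi_{norm}(k) = \Phi^w(k) / \overline{\Phi^w_{rand}(k)}$ uses the same
rewiring null as the small-world indices; $\Phi_{norm} > 1$ across a
contiguous interval of $k$ is the signature of rich-club organization.

Rich nodes for edge classification are, by default, the **top 32 regions
by backbone degree** at the 75% consensus level (ties broken by strength,
then node index); a strict degree threshold mode (`k = 7` in the emulated
analysis) is also provided. Edges are classified by the standard
definitions — rich–rich = *rich-club*, rich–non-rich = *feeder*,
non-rich–non-rich = *local*. (Some papers' parenthetical glosses swap the
first two; the standard definitions from the rich-club literature are used
here.) Class strengths always partition total strength exactly, and the
rich/feeder and rich/local strength ratios are flagged `NA` on empty
denominators.

Published analyses rarely state which rich set parameterizes the group
comparison of class strengths, so the package exposes three variants.
The default for inference is **"pooled"**: one shared rich set from the
consensus backbone of *all* subjects. This is a deliberate statistical
choice: if each group is classified against its own estimated set
("own"), every patient's value carries the patients' common set-selection
noise and every control the controls', which breaks the exchangeability
the permutation test relies on — in calibration runs the "own" variant
rejects true nulls at ~24% instead of the nominal 5%, while "pooled" is
correctly calibrated. "own" remains available for descriptive per-group
reporting (and the per-group sets and their overlap are always reported),
and "intersection" uses the nodes common to both group sets.

# Inference

Group differences use a permutation test in the **Freedman–Lane** scheme:
pooled values are residualized once by OLS on intercept + age + sex (0/1)
+ education, the observed statistic is the difference of group means of
the residuals, and the null is formed by permuting group labels over those
residuals. The two-tailed p uses the add-one estimator
$p = (1 + \#\{|T^\ast| \ge |T|\})/(1 + n_{perm})$, which is never zero.
The reference permutation count is 10,000; the tests use 199–1000.

Multiple comparisons over the class-strength family {rich, feeder, local}
are corrected by Holm–Bonferroni (FWE) by default; Benjamini–Hochberg
(FDR) is provided as an alternative since both conventions appear in this
literature. Clinical associations use Spearman correlation of
covariate-residualized variables, with a two-tailed p from the $t$
approximation on $n-2$ degrees of freedom. Demographics are compared by
Mann–Whitney U (exact when $\min(n,m) \le 8$ with no ties, tie-corrected
normal approximation otherwise) and the sex contingency by Pearson
$\chi^2$ without continuity correction (the Yates-corrected variant is a
flag).

# The synthetic-cohort generator

`generateCohort` emulates a two-group study (43 patients / 42 controls by
default) on a 90-node atlas labelled with the AAL-90 abbreviations.
Its components, and the reasoning behind each default:

* **Hub block.** The first 32 nodes are planted hubs. Edge *presence*
  probability is block-dependent: hub–hub and hub–nonhub edges have 3 and
  2 times the odds of nonhub–nonhub edges, solved so the expected overall
  density is 0.35 (a typical FN ≥ 1 structural-network density). Presence
  enrichment is what makes hubs identifiable by degree.
* **Anatomical consistency.** Each cohort draws one per-edge presence
  propensity from $\mathrm{Beta}(c\,p,\, c(1-p))$ with concentration
  $c = 1$, shared by all subjects. The U-shaped template means an edge is
  either present in most subjects or few — without it, independent
  per-subject draws leave a 75% consensus backbone almost empty, which is
  neither realistic nor analyzable. With the default, the backbone holds
  roughly 800 edges and the top-32 backbone-degree nodes coincide with the
  planted hubs in essentially every cohort.
* **Streamline counts.** On present edges, $FN = 1 + \mathrm{NB}(\mu - 1)$
  with dispersion 2 — overdispersed counts with $E[FN] = \mu$ exactly.
  Block means are `fnBase` = 8 (local), $8\sqrt{3} \approx 13.9$
  (feeder) and $8 \times 3 = 24$ (hub–hub). In the patient group the
  hub-attached means are multiplied by `groupDeficit` = 0.7, planting a
  30% deficit concentrated on rich-club and feeder connections — the
  effect structure the analysis is designed to detect.
* **FA and volumes.** FA on present edges is Beta(4, 4) rescaled to
  (0.2, 0.9) — tracking masks FA below 0.2, so surviving bundles live
  above it. Volumes are lognormal (median 1500, sdlog 0.4): strictly
  positive and right-skewed like regional voxel counts.
* **Covariates and scores.** Age, sex and education are group-independent
  by default (the emulated design is matched); a `confound` switch shifts
  patient ages for testing covariate removal. Clinical scores use
  group-specific truncated-normal marginals (patients high on PSQI, ISI,
  SAS, SDS; controls low) rounded to integers, and illness duration is
  lognormal (median 24 months) for patients only.
* **Clinical couplings.** Each scale can be rank-coupled to a named
  connection-class strength through a Gaussian copula applied *within each
  group*: normal scores of the within-group strength ranks are mixed with
  independent noise at the Pearson equivalent $r = 2\sin(\pi\rho/6)$ of
  the target Spearman $\rho$, then mapped through the group's marginal.
  Defaults plant ISI ~ rich-club at $+0.58$ and SDS ~ rich-club at
  $-0.31$ within each group. The group deficit and the within-group
  couplings are deliberately independent knobs; the generator does not try
  to reconcile them mechanistically (a weaker rich club *and* a positive
  severity coupling can coexist, as the emulated findings show, but no
  common mechanism is claimed).

What the generator does **not** emulate: anatomical geometry (distance-
dependent connectivity, hemispheric symmetry of weights), measurement
artifacts of tractography (crossing-fiber dropout, motion), site effects,
and any longitudinal structure. Passing tests therefore demonstrate that
the pipeline recovers planted statistical structure of this form — not
that it is robust to every property of real diffusion data.

# Numerical choices and degenerate inputs

* Undefined quantities propagate as `NA` flags (empty rich club, all-null
  undefined $\Phi$, degenerate null ensembles, zero-denominator ratios,
  constant inputs to correlation) — never silent zeros, never exceptions.
* Validity methods on every S4 container enforce symmetry to machine
  precision, zero diagonals, FN/FA support equality and positive volumes
  at construction time.
* All randomness is seeded; one master seed is expanded into per-stage
  and per-replicate child seeds by a Lehmer-style counter scheme
  (`childSeed`), so any stage can be re-run in isolation and a pipeline
  run is bit-reproducible for a fixed configuration.
* Rewiring with fewer than two edges returns the input with a warning
  (nothing to swap) rather than failing.

# Problem sizes in the test suite

The packaged tests run the full statistical calibration at reduced but
honest scales chosen to keep the suite in the minutes range: oracle
equivalence on hundreds of random graphs with up to 10 nodes; null-model
contracts over 1000 rewiring draws; type-I calibration over 500 replicate
null cohorts (40/40 subjects, 1000 permutations); power and rich-club
detection over 200 replicate cohorts with the planted 30% deficit;
correlation recovery over 200 replicates at the study's patient sample
size (n = 43); and the full 5 x 3 threshold-by-prevalence robustness grid
on one cohort. Per-subject small-world indices in the pipeline are
computed on the full FN-thresholded network rather than per sparsity
level, because normalizing every sparsity level of every subject against
its own 1000-network ensemble is disproportionate at desk scale; raw
metric comparisons use sparsity AUCs as is conventional.

# Limitations

The edge template, block model and copula couplings are statistical
stand-ins, not biophysics; absolute metric values (e.g. efficiency in
1/mm-free units) are only meaningful relative to the same pipeline's
nulls; and the rich-node count (32) and degree threshold (7) are analysis
parameters inherited from the emulated design, not estimated quantities.
On very sparse networks the default degree grid for $\Phi^w$ can be
short, and small consensus backbones may make `topN` selection partly
index-determined — both surface as flagged values rather than errors.
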