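---
title: "Methods: subtype-aware drug-sensitivity screening with basalscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype-aware drug-sensitivity screening with basalscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basalscreen)
```

# The scientific setting

Head and neck squamous cell carcinoma (HNSCC) is transcriptomically
heterogeneous, and several independent classifications converge on four
subtypes: basal, classical, mesenchymal and atypical. The basal subtype
(roughly 30% of tumors) over-expresses EGFR-pathway genes, most notably the
EGFR-ligand genes *EREG* (epiregulin) and *AREG* (amphiregulin), suggesting
that basal tumors and cell lines are preferentially sensitive to EGFR
blockade (Cetuximab, Erlotinib, Afatinib), alone or combined with inhibitors
of adjacent pathways (MEK: Cobimetinib; PI3K/mTOR: Gedatolisib; HER2:
Trastuzumab).

basalscreen implements the quantitative machinery needed to test that
hypothesis on a cell-line panel: consensus subtype classification,
dose-response descriptors, Bliss synergy scoring, marker evaluation and the
association statistics — plus seeded generators that simulate every input,
so the full analysis is exercised end to end without any external download.

# Subtype classification

## Differential genes and centroids

Cohorts are first harmonized by `scale_and_aggregate()`: within each
dataset every gene is standardized to mean 0 and SD 1 across samples, which
removes per-dataset multiplicative batch scale and additive offset exactly,
then samples are column-bound over the genes shared by all datasets. We use
the population SD (divisor *n*); at cohort sizes of 30+ the difference from
the sample SD is far below every tolerance used downstream.

`identify_common_de_genes()` finds the genes carrying subtype signal in
*every* cohort. Two per-gene tests are available:

* `method = "moderated_t"` — basal vs all other samples, with
  empirical-Bayes variance shrinkage (below);
* `method = "anova"` — one-way ANOVA across all four subtype groups.

Both control the FDR per dataset with Benjamini–Hochberg before
intersecting, and require the basal-vs-rest effect direction to agree in
every dataset. The pipeline uses the ANOVA variant for centroid
construction, for a structural reason worth spelling out: a nearest-centroid
classifier correlates a sample's profile with each subtype's mean profile
*across genes*. If the gene list contains only basal-up markers of equal
effect, the basal centroid is flat across genes and the Pearson correlation
carries no signal — classification collapses. Genes selected for
between-subtype variation (ANOVA) give every subtype an identifiable shape
across the gene list.

`build_centroids()` is the per-subtype arithmetic mean of member samples on
the standardized scale; `predict_subtypes()` assigns each sample the
subtype with the highest Pearson correlation. Correlation is invariant to
positive affine transforms of the profile, so raw and standardized profiles
yield identical calls. Exact ties are broken by the centroid order and
flagged; with continuous data they essentially never occur.

## Consensus basal calls

A cell line profiled in two reference datasets receives a consensus status:

| dataset 1 | dataset 2 | consensus |
|-----------|-----------|-----------|
| basal | basal | basal |
| non-basal | non-basal | non-basal |
| non-basal | absent (either order) | non-basal |
| basal | non-basal (either order) | unclassified |
| basal | absent (either order) | unclassified |

The first three rows are the established screening rule. The discordant and
basal/absent cases are not covered by it; we assign `"unclassified"` and
exclude such lines downstream rather than guess — a deliberate,
conservative design choice. A line absent from both datasets is an error.

## Markers

`select_markers()` scores each gene by the basal-vs-rest log2 fold change
and by the ROC AUC of its expression as a basal classifier (Mann–Whitney
formulation, midranks, so ties contribute 1/2). A gene is selected when
both thresholds are met. The thresholds behind published signatures are not
standardized, so both are explicit arguments (`fc_threshold = 1`,
`auc_threshold = 0.8` by default).

# Dose-response descriptors

Raw plate signals are normalized as
`(signal - blank) / (control - blank)` and clipped to `[-0.05, 1.2]` to
absorb fluorescence overshoot; technical replicates are averaged before
fitting. `fit_4pl()` fits

$$v(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
  {1 + (c/\mathrm{IC}_{50})^{h}}$$

by Levenberg–Marquardt least squares on the log10 concentration axis, with
deterministic multi-start (Hill slope started at 0.5, 1, 2; IC50 at the
concentration nearest half-range viability; lowest residual wins). A fit is
reported `converged = FALSE` when optimization fails, the viabilities are
flat, or the fitted IC50 lands more than three decades outside the tested
range; the model-free AUC descriptors are still computed.

The response AUC is defined *here* as the trapezoidal integral of the
viability fraction over log10(concentration/M) (`auc_raw`), with a
normalized variant dividing by the log10 span, so an unresponsive curve
scores exactly 1 and lower values mean greater sensitivity. This convention
is stated explicitly because published screen tables rarely define their
AUC scale; the packaged 25-line table's values (1.81–6.22) exceed the log10
span of its printed concentration ranges (≈4.78), so that table cannot have
used this convention, and basalscreen therefore treats it strictly as
fixture data — loaded, checksummed and summarized, never re-derived from
curves.

# Bliss synergy

For a two-drug inhibition matrix with single-agent axes, the Bliss
independence expectation for single-agent inhibitions $y_a, y_b$ (percent)
is $y_a + y_b - y_a y_b / 100$. The synergy score is the arithmetic mean of
observed-minus-expected over all non-missing combination cells: 0 means
independence, positive synergy, negative antagonism. We deliberately do not
smooth the response surface before averaging: the raw-excess mean is fully
specified, linear in any injected excess, and transpose-invariant. Missing
cells are excluded and counted; a result with more than half of its
combination cells missing is flagged unreliable. Inhibition is clipped to
[0, 100] before scoring.

# Association statistics

All tests return one-row tidy tables with a common column set. Standard
tests delegate to the classical implementations (Welch/pooled t, one-way
ANOVA, Yates-corrected chi-squared, Fisher exact, hypergeometric upper
tail, Benjamini–Hochberg). Two choices deserve comment:

* **Yates continuity correction** is the default for 2×2 chi-squared tests.
  On the screen's mutation-enrichment counts (6 of 10 basal lines mutated,
  8 of 25 overall) the corrected statistic gives p = 0.044 while the
  uncorrected one gives p = 0.014, and the corrected value is the one that
  matches the screening literature's reporting; the package treats the
  corrected statistic as the convention.
* **Welch** is the default two-sample t variant because screen arms are
  small and unequal (10 vs 15); the pooled variant is available to probe
  sensitivity.

## Moderated t

`moderated_t()` implements feature-wise two-sample tests with
empirical-Bayes variance shrinkage. Feature variances $s^2_g$ on $d$
residual df are assumed exchangeable around a scaled inverse chi-squared
prior $(d_0, s_0^2)$, estimated by moment matching on $\log s^2_g$ (the
mean and variance of $\log s^2$ have closed forms in digamma/trigamma
functions; $d_0$ solves a trigamma equation by Newton inversion). The
moderated statistic uses
$\tilde s^2_g = (d_0 s_0^2 + d\, s^2_g)/(d_0 + d)$ on $d_0 + d$ df. A
configuration override forces $d_0 = 0$ (ordinary t) or $d_0 = \infty$
(full pooling). With fewer than `min_features` features the prior is not
estimable and the function falls back to ordinary t with a message. The
estimator agrees with the standard empirical-Bayes implementation in limma
to numerical precision on common inputs (verified in the test suite, where
limma serves only as an independent cross-check).

`mutation_association()` applies this machinery per mutated gene, with
moderation pooled across the drug panel (six drugs), which is why its
`min_features` default is lowered to 2. Which set a published "moderated
t" pools over is generally unstated; both the moderated and plain variants
are exposed. Genes with fewer than two mutated or two wild-type lines are
skipped and listed. A negative effect direction means the mutation
sensitizes (lower AUC in mutated lines).

# Validation assays

`ddct_fold_change()` implements relative qPCR quantification: the target Ct
is normalized to the arithmetic mean of the reference-gene Ct values
(identical to geometric-mean normalization of the linear quantities), the
treated-minus-control difference is taken, and the fold change is
$2^{-\Delta\Delta Ct}$, assuming amplification efficiency 2. A
single-reference design (e.g. 18S) is the one-element case of the same
operation. `plating_efficiency()` and `surviving_fraction()` are the
clonogenic-assay quotients — colonies per seeded cell without treatment,
and treated colony yield normalized by the plating efficiency — making the
surviving fraction invariant to seeding density.

# The synthetic-data generators

`sim_config()` fixes the study conditions once; a single root seed spawns
independent named RNG streams (expression, panel, dose, combination,
mutation, qpcr, clonogenic — in that fixed order), so adding one generator
never perturbs another, and repeated combination matrices are separated by
a deterministic salt derived from the cell line and drug pair.

What the generators emulate, and the defaults:

* **Expression** — four subtypes at proportions 0.30/0.25/0.25/0.20 (basal
  ≈ 30%, matching the tumor literature), a shared gene-level biology across
  cohorts, per-dataset batch scale (×0.8–1.25) and offset, Gaussian log2
  noise (SD 1 by default; 0.5 in the pipeline, typical of replicated
  array/RNA-seq panels after preprocessing). Each subtype carries an
  8–10-gene marker block shifted up by 2 log2 units in its own samples;
  the basal block is led by *EREG* and *AREG*. The marker shift is applied
  after the batch scale so that the configured effect is the exact
  within-dataset expectation.
* **Viability plates** — 13-point, 2.5-fold dilution series per drug
  (0.5 nM–30 µM for small molecules; 0.1 nM–6 µM Cetuximab; 0.4 nM–24 µM
  Trastuzumab), triplicate raw signals
  `blank + (control − blank)·4PL + noise` with noise SD 2% of the signal
  window. Basal lines have log10 IC50 lowered by 1 decade for the three
  EGFR-directed drugs.
* **Combination matrices** — 6×6 grids plus single-agent axes; combination
  cells equal the Bliss expectation plus an injected excess (default 10
  percentage points for basal lines, 0 otherwise) plus noise, clipped to
  [0, 100].
* **Mutations** — Bernoulli per (line, gene) with subtype-specific rates;
  the default CDKN2A rates (0.60 basal / 0.13 non-basal) reproduce the
  screen-scale enrichment of 6/10 vs 2/15 in expectation.
* **qPCR and clonogenic** — target Ct `base − log2(fold) + noise` with
  fixed-level reference genes; colony counts Binomial(seeded, pe·sf).

None of the generators simulate probe-level microarray artifacts, RNA-seq
count noise, plate-position effects or colony-image segmentation error, so
a passing test suite demonstrates correctness of the analysis machinery
under the stated statistical model — not robustness to every failure mode
of real instruments.

# The end-to-end pipeline

`run_pipeline()` chains simulate → classify → dose-response → synergy →
associate → assays with stage toggles whose dependencies are validated
before anything runs. The default problem sizes — three 40-sample cohorts
of 150 genes, a 25-line panel (3 lines absent from the second reference
dataset to exercise the consensus rule), six drugs at 13 concentrations in
triplicate, nine combinations — keep a full run in the tens of seconds
while every stage still recovers its injected ground truth. Every run
carries a manifest (seed, configuration hash, package version), and a rerun
with the same configuration is bit-identical.

```{r pipeline, eval = FALSE}
report <- run_pipeline(pipeline_config(seed = 1))
report$auc_by_subtype   # basal vs non-basal AUC per drug
report$synergy_by_group # Bliss score contrast per combination
```

# Known limitations

* The packaged screen table's AUC convention is unrecoverable, so
  cross-scale comparisons between fitted `auc_norm` values and the fixture
  AUCs are not meaningful; only within-scale contrasts are used.
* Synergy scoring averages raw excess; it is not a reimplementation of
  surface-fitting tools, and scores are comparable only within this
  convention.
* The hypergeometric enrichment test is provided as an operation; the
  package does not ship a pathway collection.
* Consensus handling of discordant calls is a documented package choice,
  not an established rule.
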