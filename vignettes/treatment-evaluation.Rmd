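---
title: "Methods: rank-based integrative evaluation of biofertilizer trials"
author: "rhizorank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based integrative evaluation of biofertilizer trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizorank)
```

## The problem

Greenhouse biofertilizer trials produce three loosely coupled data layers:
per-plant growth traits (organ lengths, fresh/dry weights, SPAD chlorophyll),
rhizosphere community profiles from 16S and ITS amplicon OTU tables, and
RT-qPCR expression of a panel of leaf genes. No single layer decides which
treatment "won". rhizorank implements an integrative answer: every parameter
is ranked across treatments, the ranks become scores, and each treatment is
summarized by the total and the mean of its available scores. The package
ships the printed summaries of two such trials — a 12-treatment durum wheat
study and an 8-treatment maize study crossing biochar amendment, two
five-strain microbial consortia (MC-B, MC-C; delivered by seed coating or on
pre-colonized "functionalized" char) and arbuscular mycorrhizal fungi — and
reproduces their published evaluation matrices from the printed trait means.

## The scoring procedure

For one parameter observed on $n$ treatments with values $v_1,\dots,v_n$,
the score of treatment $i$ is

$$s_i = \max\{\,\mathrm{pos}(j) : v_j = v_i\,\}$$

where $\mathrm{pos}(j)$ is the position of $v_j$ in the ascending sort. The
largest value scores $n$, the smallest scores at least 1, and **tied values
all receive the maximum of their tied positions** (`rank(, ties.method =
"max")`). The tie rule is load-bearing: with eight tied smallest root dry
weights out of twelve treatments, all eight score 8 — which is what the
published matrices contain, and what average- or minimum-rank conventions
fail to reproduce. Every parameter is oriented higher-is-better (this holds
for all thirteen packaged columns); `rank_scores(direction = "lower")`
exists for reuse with cost-like parameters.

Parameters not measured for a treatment ("n.t.") are excluded from that
column's ranking, so the column's maximum attainable score is the number of
treatments actually ranked on it, and the treatment's total *and its mean
denominator* shrink accordingly — that is how a treatment scored on 9
parameters remains comparable with one scored on 13. Means are rounded
*half-up* to one decimal (79/9 prints as 8.8), not with banker's rounding;
`round_half_up()` adds a $10^{-9}$ guard against binary-representation
artifacts like $4.85 \times 10 = 48.4999\ldots$.

Ranking is performed on values as supplied. The packaged reproduction ranks
the *printed* means (1–2 decimals), because that is the only public record
of the trials; `run_all(rank_digits = NULL)` ranks full-precision means for
fresh data. One printed wheat cell is internally inconsistent: the MC-C_AMF
shoot-length mean of 31.6 cm ranks 4th among the twelve printed means, but
the published score is 5 (propagating to a printed total of 81 where the
recomputed value is 80). `evaluate_packaged_study()` reports this cell as a
mismatch rather than guessing the intent; all other 179 physiological score
cells across the two crops reproduce exactly.

```{r}
w <- evaluate_packaged_study("wheat")
w$mismatches
tail(w$ranking[order(w$ranking$mean), ], 3)
```

## Group testing

Published trait tables annotate means with compact letters. The summary
methods of the source trials name "ANOVA followed by Dunn's post hoc test",
which is internally inconsistent — Dunn's z-tests are the companion of the
Kruskal–Wallis rank omnibus, and that pairing is what the Past software the
trials used actually computes. `group_test()` therefore runs Kruskal–Wallis
(with midranks and the standard tie correction) followed by Dunn's
all-pairs z-tests, and reports a classical one-way ANOVA p alongside for
transparency. Dunn p-values are unadjusted by default (the Past default);
`adjust = "holm"` or `"bonferroni"` are available. Pairs separate when the
pairwise p is strictly below `alpha` (default 0.05); letters are assembled
with the insert-and-absorb algorithm, so two treatments share a letter
exactly when their pairwise p is at or above `alpha`.

Two practical notes. First, Dunn's test compares mean joint ranks against a
pooled variance, so with 3 groups of 6 observations even completely
disjoint adjacent groups have $z \approx 1.95$ (p ≈ 0.052): full letter
separation of well-separated groups needs roughly 10 replicates per group.
Second, the published letters cannot be regenerated from the printed
summaries (the replicate-level data are unpublished), so letters are
property-tested — internal consistency with the pairwise matrix, and
correct type-I error under the null — never golden-tested. Under the null
with two groups of six (the trials' six pots), exact enumeration of all
$\binom{12}{6}$ rank configurations gives a 4.1% rejection rate at nominal
5%, inside the 5% ± 2% band the calibration test asserts over 1,000
simulations.

## Diversity indices

`shannon()` computes $H = -\sum_i p_i \ln p_i$ in natural-log units by
default. Nats are the reading consistent with the source trials' remark
that their low-diversity fungal communities sit "below 3"; `base = 2`
selects bits. `chao1()` defaults to the bias-corrected estimator
$S_{obs} + F_1(F_1-1) / (2(F_2+1))$, which stays defined when no doubletons
are observed; the classic $S_{obs} + F_1^2/(2F_2)$ form is selectable when
$F_2 > 0$. No rarefaction is applied by default (none is part of the
emulated workflow); `rarefy_otu_table()` provides seeded subsampling for
sensitivity checks. The per-treatment Shannon values entering the
evaluation matrix are means over the duplicate soil samples of each
treatment.

## Relative quantification (2^−ΔΔCt)

Technical replicates are collapsed by arithmetic mean over *determined*
values; a Ct is undetermined when the raw value is strictly above 36 cycles
(36.0 is kept) or missing, applied at read time. Then, per biological
replicate, $\Delta Ct = Ct_{target} - Ct_{18S}$, $\Delta\Delta Ct$ is
referenced to the mean calibrator $\Delta Ct$ of the same gene and
timepoint, and $FC = 2^{-\Delta\Delta Ct}$. Biological replicates are
averaged **on the ΔΔCt (log) scale**, i.e. the reported fold change is a
geometric mean: fold change is a multiplicative quantity, log-scale
averaging is symmetric in up/down noise, and it makes the calibrator's own
fold change exactly 1 by construction. Arithmetic averaging is available by
flag since the emulated workflow does not state its convention. A gene is
`up` when $FC \ge 2$ and `down` when $FC \le 0.5$ — both thresholds
inclusive — and `undetermined` genes are excluded from the upregulated-gene
counts that feed the evaluation matrix. `expression_matrices()` exports the
ΔCt and log2-FC matrices used for heatmap displays.

## Ordination

`pca()` is a thin deterministic wrapper over the singular value
decomposition: column centering, unit scaling by default (the parameters
mix cm, g, percent and SPAD units, so correlation-matrix PCA is the
defensible default; the emulated analyses do not state their scaling), a
fixed sign convention (the largest-magnitude loading of each component is
made positive), and variance fractions $\sigma_k^2 / \sum \sigma^2$. The
published variance-explained percentages are deliberately not reproduction
targets: they were computed from replicate-level matrices that were never
published. In `run_all()` the observations are treatment-level trait means;
for sample-level ordinations call `pca()` on any matrix directly.

## The synthetic-data generator

`sim_config()` + `simulate_study()` generate complete studies with the
statistical structure the pipeline assumes, so every stage is testable
without downloads. Defaults are fixed at the emulated study conditions:

* **Traits** — per treatment, `n_replicates = 6` (six pots) draws from
  Normal(mean, SD) with the packaged printed means/SDs, truncated at zero
  by resampling (clipping would distort the shape near zero). Dry weights
  are not drawn independently: DW = FW × a Beta-distributed dry fraction
  with mean $\mu_{DW}/\mu_{FW}$ and spread from the printed dry-biomass SD
  (method of moments, capped just under the Beta feasibility bound), which
  enforces DW ≤ FW by construction; the dry-biomass percentage is derived,
  never drawn, so its printed mean is redundant in the configuration.
* **Communities** — a Dirichlet-multinomial at phylum profiles matching the
  reported compositions (bacteria: Proteobacteria 0.55, Bacteroidetes 0.11,
  five minor phyla 0.03–0.08; fungi: Ascomycota-dominated, four phyla
  > 90%), each phylum split into 8 OTUs with geometric within-phylum
  weights, duplicate soil samples per treatment, Dirichlet concentration
  200 and library size 20,000 by default. Consortium treatments raise the
  minor phyla by ×1.15 before renormalization (evenness, hence Shannon,
  increases — the reported direction), char alone depresses them ×0.9
  (char-only soils showed the minimum Shannon). Genus-level structure is
  free by design.
* **qPCR** — a 14-gene panel, two timepoints, 2 biological × 3 technical
  replicates, a stable 18S housekeeping gene (Ct ≈ 15 ± 0.2), per-gene
  offsets, planted fold changes (consortium treatments induce part of the
  panel; the char-delivered MC-C + AMF condition plants nine genes at
  FC 4.5 at 21 DAS), and Gaussian biological/technical noise. Ct values
  above 36 are emitted as-is; censoring is the reader's job, so the
  detection ceiling is exercised end to end.

Each table draws from its own stream seeded from `(master seed, table
name)`, so adding a table to a study never perturbs the others, and equal
seeds give byte-identical studies. What the generator does *not* emulate:
spatial/pot effects and block structure, compositional correlations beyond
the Dirichlet, over-dispersed taxon-specific noise, chimeras or
contamination, amplification-efficiency differences between primer pairs.
Passing tests therefore demonstrate the pipeline's algebra and calibration,
not robustness to those real-data artifacts.

## Numerical choices and degenerate inputs

* All-identical group values: omnibus p = 1, one shared letter.
* All-undetermined technical replicates propagate `NA`; a missing
  housekeeping measurement voids every gene of its condition.
* A parameter observed on fewer than two treatments cannot be ranked and is
  an error; `run_all()` drops such columns before scoring.
* Zero-variance columns are an error under standardized PCA, named in the
  message.
* Seeds derived from `(seed, name)` stay below $2^{31}-1$.

## Test and reproduction problem sizes

The suite exercises the generator at 3–6 replicates, library sizes of
2,000–20,000, and 100 seeds for the mean-recovery contract; the
convergence check uses concentration $10^9$ and a $10^6$ library, where
per-phylum multinomial error is ~0.0005, comfortably inside the asserted
0.5%. The null-calibration runs 1,000 two-group simulations. The packaged
reproduction (both crops, all rank cells, totals and means) runs in well
under a second.
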