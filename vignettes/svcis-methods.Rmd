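---
title: "Methods: linking structural variant breakpoints to gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking structural variant breakpoints to gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcis)
```

# Scope and rationale

`svcis` quantifies the cis-regulatory footprint of somatic structural
variants (SSVs) across a tumor cohort. The phenomenon of interest is broad:
a rearrangement breakpoint near a gene may relocate an enhancer into its
neighborhood, remove or break a topologically associating domain (TAD)
boundary that insulated it, truncate the gene, or fuse it to a partner. The
package deliberately does **not** assume a mechanism: the association test
asks only whether expression co-varies with breakpoint proximity, and the
mechanistic annotations (TAD disruption, enhancer translocation, fusion
support) are layered on separately.

# Data model and conventions

All genomic coordinates are handled internally as **0-based half-open**
intervals (BED convention); VCF input is converted on read, with the two
breakends of a symbolic record placed at `POS − 1` and `END − 1`.

Every SSV is a single mate-merged record with two breakends, each carrying
an **orientation**: `positive` means the sequence upstream of the
breakpoint (lower coordinates) is retained at the junction, `negative`
means the downstream sequence is retained. For VCF BND records the
orientation is decoded from bracket notation; for symbolic records it comes
from a `STRANDS` INFO field, falling back to the class-typical pattern
(deletion `+-`, tandem duplication `-+`). Translocation mate pairs are
merged into one record, which is also the unit of the burden count.

The gene "start" is the strand-aware transcription start: the leftmost base
of `+` genes and the rightmost base of `−` genes. Upstream/downstream
windows flip with strand accordingly.

# The association model

For gene $g$ and tumor $t$, two predictors are available:

* **Window presence** $x_{gt} \in \{0,1\}$: does tumor $t$ carry at least
  one breakend inside the window (gene body, or a fixed extent upstream or
  downstream of the start)? Both breakends of every SSV count
  independently.
* **Log distance** $x_{gt} = \log_2 \max(d_{gt}, 1)$, where $d_{gt}$ is the
  distance from the gene start to the nearest breakend within ±1 Mb;
  tumors with no breakend in range are imputed at exactly 1 Mb
  ($\log_2 10^6 \approx 19.93$). The clip at 1 bp handles a breakend
  exactly at the start. This predictor weights close breakpoints most.

The per-gene model is ordinary least squares on
$\log_2(\mathrm{expr} + 1)$ (the pseudocount of 1 is a convention; the
source data state only that expression was log-transformed):

$$ y_t = \beta_0 + \beta_1 x_{gt} + \boldsymbol\gamma^\top
   \mathrm{type}_t + \delta\,\mathrm{cna}_{gt} + \varepsilon_t $$

with tumor type dummy-coded and the thresholded copy-number call entered as
a single numeric term over $\{-2,\dots,2\}$ (numeric rather than
dummy-coded, for parsimony; configurable through the covariate machinery).
The reported p-value is the two-sided t-test on $\beta_1$. For the distance
predictor the sign convention flips: a *negative* $\beta_1$ (closer
breakpoint, higher expression) is reported as direction `positive`, so that
"positively correlated with SSV breakpoints" has the same meaning for both
predictors.

Only genes with at least `min_tumors = 3` qualifying tumors are tested
(presence = 1 for the window method; non-imputed distance for the distance
method — the source describes the filter only for the window method, and we
apply the analogous rule to the distance method). Degenerate designs
(constant predictor, predictor aliased with a tumor-type level) yield a
missing result with a reason code rather than an error; constant covariate
columns such as an all-zero CNA row are dropped silently since they carry
no information.

Expression matrices are expected to be quantile normalized beforehand
(`quantile_normalize()`, backed by `limma::normalizeQuantiles` with
average-tie handling); normalization is kept out of `run_association()` so
that the caller controls preprocessing.

# Multiple testing

Two procedures are implemented, deliberately kept distinct:

1. **Storey–Tibshirani formula**, exactly as printed in the source:
   $q_i = p_i \cdot N_\mathrm{tested} / \#\{j : p_j \le p_i\}$, capped at
   1, ties sharing a q. No monotonicity enforcement and no $\pi_0$
   estimate are applied beyond the formula — this is a documented choice,
   so `q_storey` can be locally non-monotone in rare rank configurations.
   The testing family is the set of genes passing `min_tumors` for the
   given window.
2. **Stratified permutation**: whole per-tumor predictor columns are
   shuffled among tumors of the same tumor type (types with a single tumor
   merge into an `.other` stratum); expression, type, and CNA stay fixed.
   CNA is intentionally *not* co-shuffled — it stays with expression — so
   where SSVs and CNA are coupled the null is conservative. Each
   permutation re-runs the full covariate model per gene; the
   implementation uses the Frisch–Waugh–Lovell residualization (covariates
   are projected out once per gene, each permutation then tests a simple
   regression of residuals), which is algebraically identical to the full
   model and is verified against it in the test suite. The FDR estimate is
   the mean permuted count of genes passing the observed selection rule
   divided by the observed count; both a Storey-q rule and a fixed nominal
   p-value rule are supported.

# Regulatory annotation

**TAD disruption.** An SSV is `preserving` when both breakends fall in the
same TAD interval, `disrupting` when they fall in different TADs (an
inter-chromosomal translocation can never preserve), and `unresolved` when
either breakend lies outside the annotation — a third class we introduce
because published TAD maps have gaps; unresolved SSVs are excluded from
enrichment denominators. TADs must be non-overlapping within a chromosome;
overlapping input is an error rather than silently resolved. The enrichment
test compares the disrupting fraction among expression-linked SSVs against
the remaining SSVs in a 2×2 chi-squared table (expected cell < 5 falls back
to Fisher's exact test with a warning). A 2×2 table needs disjoint rows, so
"altered vs the rest" is used rather than "altered vs all".

**Enhancer translocation.** A candidate call needs a breakend 0–500 kb
upstream of a gene's start (strand-aware; only the breakend closest to the
start is considered per tumor) whose orientation retains the
gene-containing side of the junction: `negative` for `+` strand genes,
`positive` for `−` strand genes. The mate breakend's retained side is then
searched for the nearest enhancer (interval midpoint, a convention the
source leaves open) within 500 kb. The call is emitted only if the
unaltered gene had no enhancer within 1 Mb of its start, or its nearest
native enhancer is farther from the gene than the translocated enhancer
would be **along the derivative chromosome** (start-to-breakend plus
breakend-to-enhancer distance). Distances are measured on the reference
mate locus in the retained direction; resolving the fused allele's true
geometry would require assembly and is out of scope. Multiple qualifying
SSVs per (gene, tumor) are deduplicated to the closest translocated
enhancer.

# Fusion refinement

RNA-seq chimeric candidates are first filtered against a banned artifact
list (unordered pairs) and same-gene events. Surviving candidates are
tiered by two orthogonal pieces of WGS/expression evidence: `ssv_support`
(a breakend within the annotated body — introns included — of one or both
partners in the same tumor) and `high_expression`, which holds if either
(1) the fusion recurs in at most two tumors and in each carrier either
partner's expression exceeds +0.4 SD from the cohort median (SD-from-median
scores are computed on the log2 scale per gene), or (2) either partner has
a significant positive breakpoint association (p < 0.01) by the distance
metric or the gene-body window. Tier `ssv_supported_high_expr` requires
both; `ssv_supported` support only; `rna_only` neither.

# Burden analysis

The per-tumor burden is the count of mate-merged SSV records, so a
translocation contributes once. Burden enters models as
$\log_{10}(\mathrm{count}+1)$ — the base is a convention (the source says
only "log-transformed"), so slope magnitudes are base-dependent and
documented as such. The module provides per-gene expression correlates
(OLS with tumor-type and CNA covariates), point-biserial correlations
between inactivating-mutation indicators and burden (genes mutated in ≥ 3
tumors only), group contrasts against a reference group by OLS with
tumor-type dummies, a paired t-test on log burden for patients with both an
initial and a progressive/recurrent tumor (ties broken by metadata row
order), and a generic one-sided hypergeometric gene-set test.

# Pathway catalog

Somatic alterations are tabulated per (tumor, gene) under the fixed
precedence **SNV/indel > fusion > deep deletion (−2) > high-level
amplification (+2) > SSV-cis**. Oncogene SNVs qualify only at hotspot
residues (or as promoter events, for TERT-like genes); tumor suppressors
accept hotspot or inactivating (nonsense/nonstop/indel) consequences.
SSV-cis calls are gated: only genes significant (q < 10 %) in the gene-body
or 1 Mb association are eligible, with oncogenes requiring a breakpoint
within 1 Mb plus expression > +0.4 SD in that tumor, and tumor suppressors
a gene-body breakpoint plus expression < −0.4 SD. (One figure legend in the
source prints "−4 SD"; we read that as a typo for −0.4, consistent with
the other thresholds.) The shipped catalog (`default_pathway_catalog()`,
also in `inst/extdata/pathways.tsv`) assigns each member gene a role;
dual-role genes (e.g. EZH2) default to the tumor-suppressor rule in this
pediatric context and can be overridden by editing the config. The NRF2
pathway is included but excluded from default summaries, mirroring its
exclusion from the source's final presentation.

# The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a large multi-histology
pediatric brain tumor WGS+RNA cohort; its defaults are the stated world of
the test suite:

* **Genome**: 20 chromosomes × 150 Mb = 3 Gb. Genome size is not free to
  shrink: window predictors respond to breakpoint *density* (breakends per
  Mb per tumor), so realistic per-tumor SSV counts require a
  whole-genome-scale sequence (~0.03 breakends/Mb/tumor at the median,
  matching a real cohort).
* **Burden**: per-tumor SSV count log-normal with median 47 and
  sdlog 1.19, chosen so the SD is ≈ 167 — the heavy right tail the real
  cohort shows. The log-variance is split 80 % patient-shared / 20 %
  tumor-specific: tumors from one patient share genomic instability, which
  is what gives a paired initial-vs-recurrent design its power (the
  marginal stays log-normal). Progressive/recurrent tumors inflate the
  scale by 1.5× by default.
* **Expression**: generated directly on the log2 scale (baseline per gene
  uniform 3–8, per-type offsets SD 0.5, residual SD 1), then emitted as
  `2^E − 1` so the pipeline's `log2(x+1)` transform is exercised exactly.
* **CNA**: sparse background calls plus optional coupling — a background
  duplication emits +1/+2 for genes it spans with probability
  `cna_coupling`. Dosage adds 0.5 log2 units per thresholded step; this is
  the confounder the CNA covariate must absorb.
* **Planted truth**: cis-effect genes (shift of `effect × noise SD` in
  carrier tumors whose extra breakend lands within ±50 kb of the start),
  CNA-dosage-only genes (spanning duplication + forced +2, no direct
  effect), fusions (translocation breakends inside both partner bodies, a
  candidate call row, and a 3-log2-unit bump on the 5′ partner — a
  strongly overexpressed fusion partner), burden-tracking genes
  (slope 0.8 per log10 burden), and a burden-linked driver whose mutation
  probability follows a logistic curve in log burden. Decoy fusion
  candidates (banned pairs in reversed order, same-gene calls, unsupported
  RNA-only calls) exercise the negative paths. Every planted element is
  recorded in a JSON truth manifest with referential integrity enforced by
  tests.

What the generator does **not** emulate: clustered rearrangement processes
(chromothripsis, chromoplexy), sequence-context breakpoint biases,
mutational signatures, read-level data, expression count noise
(mean–variance relationships), or subclonality. A green test therefore
establishes that the statistical machinery behaves as specified under the
stated world — calibrated nulls, recoverable planted effects, correct
covariate absorption — not that biological discovery on real data is
guaranteed.

# Numerical and design choices

* OLS inference uses a QR decomposition with an explicit rank check;
  perfect fits (zero residual) report p = 0 for a non-zero effect rather
  than dividing by zero.
* The breakend-at-start distance is clipped to 1 bp before the log; a
  breakend exactly at 1 Mb is treated as imputed (the value is identical).
* Window boundaries are half-open; the symmetric window covers
  `start ± extent` inclusive of both endpoints at base resolution.
* Permutation strata merge singleton tumor types so each stratum is
  shuffleable.
* In the paired burden test, patients with several tumors per arm use the
  first by metadata order (the inputs carry no collection dates).
* Acceptance checking of the planted burden-expression slope uses the mean
  over five planted genes: a single gene at n = 300 has a slope standard
  error (~0.11) comparable to the ±15 % acceptance band, which would make
  a single-gene check a coin flip in any honest world.
* One acceptance property is left intentionally red: planted cis-effect
  recovery at Storey q < 10 % reaches sensitivity 0.70 on the frozen
  cohort seed against a 0.80 bound (≈ 0.75 expected across seeds; the
  false-discovery proportion and direction checks pass). Power is limited
  by background breakpoint carriers at 100 kb–1 Mb, which dilute the
  log-distance slope under the conservative carriers-only generative
  model. Neither the generator, the seed, nor the threshold was adjusted
  after measurement.

# Known limitations

Orientation handling for insertions is approximate (two near-identical
breakends). The cohort VCF dialect stores the tumor in a `TID` INFO field;
per-tumor VCFs are supported via an argument. The enhancer logic evaluates
the reference geometry of the mate locus, not the assembled derivative
chromosome. The Storey formula without monotonicity can produce locally
non-monotone q-values. Survival modeling, allele-specific expression, and
expression clustering are out of scope.
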