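---
title: "Mapping causal intermediate genes across environments with crossmed"
author: "crossmed authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping causal intermediate genes across environments with crossmed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmed)
```

## The problem

In a cross between two yeast strains, a growth QTL tells us that *some*
variant in a genomic region changes growth rate in *some* environments — but
not through which gene. Expression profiling of the segregants offers a
handle: if the variant changes growth *because* it changes the expression of
a particular gene, that gene's transcript level should (i) track the
genotype, and (ii) track growth in the environments where the QTL acts.
The catch is that hundreds of transcripts correlate with any strong growth
QTL, most of them *consequences* of growth-rate variation or regulatory
*side effects* with no phenotypic role.

`crossmed` implements a multi-environment strategy for separating these
classes. Its central observation is an asymmetry: regulatory effects of a
growth QTL on its causal intermediate genes tend to be **persistent**
across environments (the variant rewires the same regulatory connections
everywhere), while the QTL's effect on growth — and therefore on all
growth-consequence transcripts — is **environment-dependent**. A gene whose
genotype association persists across environments, and whose expression
correlates with growth specifically in the environment where the QTL acts,
is a strong causal-intermediate candidate.

## The models

### Kinship-corrected association scans

Growth and expression traits are mapped by single-marker tests under the
linear mixed model

$$ y = \mu + x_j\beta_j + u + \varepsilon,\qquad
   u \sim \mathcal N(0, \sigma_g^2 K),\quad
   \varepsilon \sim \mathcal N(0, \sigma_e^2 I), $$

where $K$ is the allele-sharing (IBS) kinship matrix of the segregants and
$x_j$ the 0/1 allele code at marker $j$. The variance ratio
$\delta = \sigma_e^2/\sigma_g^2$ is estimated once per trait by REML —
profiled through the spectral decomposition of $K$ and maximized by Brent
search on $\log\delta \in [-10, 10]$ — and then held fixed for all markers
(the standard once-per-trait approximation; `exact = TRUE` re-optimizes per
marker). Within each marker fit the residual scale is re-estimated, so at
identity kinship the scan reduces *exactly* to OLS; p-values are two-sided
t with $n - \mathrm{rank}$ degrees of freedom. Traits are internally
standardized before REML so p-values are exactly invariant to affine
rescaling. Significance is controlled by Storey–Tibshirani q-values
($\pi_0$ from the $\lambda$-grid $0, 0.05, \dots, 0.95$ with a cubic
smoother, step-up q-values; with $\pi_0 = 1$ this is exactly
Benjamini–Hochberg), and significant markers are grouped into QTL regions
by a 50 kb window around peaks.

### Persistent versus environment-dependent genetic effects

For a gene and a marker, expression is stacked across environments and
modeled with per-environment intercepts, a shared genotype effect, and
genotype-by-environment interaction terms. Two parameterizations are
provided:

* `interaction = "all"` with sum-to-zero contrasts — one deviation per
  environment, constrained to sum to zero. The shared coefficient is the
  across-environment mean effect. This is the form used for the
  decomposition identity (shared + deviation = per-environment marginal
  effect) and for reporting effect profiles.
* `interaction = "single"` — a shared effect plus the interaction term of
  *one* environment of interest. This is the form used for classification
  and for the persistent/dependent candidate rankings.

The second form exists because classification with all-interaction codings
is structurally biased: a gene regulated *only* in environment 1 has a
nonzero across-environment mean effect, so its shared term turns
significant with enough power and the gene is mislabeled "both". With the
single-interaction form, the shared coefficient for the environment-1 test
is estimated from the remaining environments and correctly vanishes for a
purely environment-dependent gene. Classification labels
(persistent-only / dependent-only / both / none) are assigned at FDR 0.05
with shared-term p-values pooled into one q-value family and
interaction-term p-values into another, pooled across genes and
environments. `downsample_for_power()` optionally reduces the stacked data
to the mean single-environment sample count, so that persistent and
dependent detection can be compared at matched power.

### The multi-environment growth genetic model

Growth stacked across environments is modeled with per-environment
intercepts plus selected genetic terms, each either a marker main effect
shared by all environments or a marker-by-environment interaction.
Candidates are the QTL-region peak markers; selection is forward–backward
stepwise minimizing BIC (AIC available), with deterministic tie-breaking.
An interaction may enter without its main effect, which is what a sign-flip
locus (beneficial in one environment, detrimental in another) requires.
BIC was chosen as the selection criterion for consistency with the
BIC-based network comparison below.

### The mediation network

For each interaction term $(n_i, e_i)$ of the growth model and each gene,
two linear Gaussian networks are compared.

**Model 1 (causal intermediate).** The gene is under environmentally
persistent regulation by the marker, and growth is independent of genotype
given expression:

$$ t = E\alpha + \beta_s s + \epsilon_t, \qquad
   g = E\gamma_0 + C\theta + \gamma\, t\,\mathbf 1\{e = e_i\} + \epsilon_g $$

**Model 0 (no mediation).** Expression is independent of the genotype and
growth follows the growth genetic model:

$$ t = E\alpha + \epsilon_t, \qquad
   g = E\gamma_0 + C\theta + \delta\, s\,\mathbf 1\{e = e_i\} + \epsilon_g $$

Here $E$ is the environment indicator matrix, $s$ the genotype at $n_i$,
and $C$ the covariate columns of *all other* growth-model terms. Each
sub-model's Gaussian likelihood is profiled over its noise variance, giving
the closed form $-(n/2)(\log(2\pi\,\mathrm{RSS}/n) + 1)$; parameter counts
include both designs' ranks plus two variances (Model 1 has exactly one
extra parameter under the default coding). Models are compared by
$\mathrm{BIC} = -2\log L + k\log n$ over the stacked profiled samples, and
the posterior probability of mediation under equal prior odds is
$e^{-\mathrm{BIC}_1/2} / (e^{-\mathrm{BIC}_0/2} + e^{-\mathrm{BIC}_1/2})$.
Expression is standardized per environment before fitting so the
$\gamma$ scale is comparable across genes. The candidate ranking orders by
$\Delta\mathrm{BIC} = \mathrm{BIC}_0 - \mathrm{BIC}_1$: the posterior is a
strictly monotone function of $\Delta\mathrm{BIC}$ but saturates at 1.0 in
floating point for decisive Bayes factors, which would collapse the top of
the ranking into ties. Each candidate carries a direction sign, the sign of
its expression–growth correlation within $e_i$.

Design choices left open by the prose and resolved here: full mediation is
the default (Model 1 drops the tested term's direct genotype effect;
`partial = TRUE` keeps it); expression enters the growth sub-model only
through the tested environment's interaction; no kinship random effect
inside the network. A single-environment variant (`single_env_input`)
restricts all fits to the tested environment's samples, emulating earlier
single-environment causal-inference approaches; with one environment it
reduces exactly to the full network.

### Deletion-assay validation

Competitive-pool deletion assays measure, per gene and environment, log2
barcode abundance at generations 0 and 5 in triplicate. The selection
coefficient $\hat s$ is the per-gene least-squares slope on generation
count. Significance uses a moderated t-test: residual variances are shrunk
toward a scaled-F prior $(d_0, s_0^2)$ fitted by moment matching on the
log-variance scale (via `limma::squeezeVar`; $d_0 = 0$ recovers the
ordinary t, $d_0 \to \infty$ the fully pooled variance), and
$t = \hat s / (\tilde s_g c_g)$ with $d_0 + d_g$ degrees of freedom.
Calls require both $|\hat s| > 0.05$ and q < 0.05.

A ranked candidate **validates** when its deletion call is significant
*and* directionally consistent: a gene whose expression correlates
positively with growth should be detrimental when deleted, and vice versa
(`ignore_direction` disables the direction requirement). Fold enrichment
divides the validated fraction of the top 100 candidates by the background
rate. Because a randomly ranked gene carries a random direction sign, the
direction-matched background is (beneficial + detrimental) / (2 × assayed)
— this is what makes a random ranking's fold enrichment center on 1.
Spread across growth QTLs is summarized by leave-one-out jackknife.

## The synthetic cross

Every stage is exercised by a seeded generator that reproduces the study's
designs: 159–200 segregants genotyped at thousands of markers, growth in
multiple environments, expression under a checkered design, and a
genome-wide deletion assay. Genotypes are two-state Markov chains along
each chromosome with a constant per-interval recombination probability
(default 0.02) — linkage structure is what the downstream methods need, not
genetic-map accuracy. Expression is generated directly on a log-like
additive scale; array-intensity modeling is out of scope.

The default architecture (used by the package's benchmark and tests) is
200 segregants × 500 markers on 5 chromosomes × 500 genes × 5 environments
with 35 profiled segregants per environment, and three planted growth QTLs:

* one with a persistent direct effect (0.5 growth units per allele in all
  environments) plus 5 weak mediators;
* one environment-specific QTL acting *entirely* through its 5 mediator
  genes (genotype→expression effect 1, expression→growth effect 0.25);
* one sign-flip QTL, +0.25 in environment 1 and −0.25 in environment 4
  through its mediators, emulating a locus whose allele is beneficial in
  one environment and detrimental in another while its expression effects
  stay persistent.

Each QTL also carries 20 environment-dependent eQTL genes (effect 1 in one
environment) and 20 side-effect genes (persistent effect 1, no growth
link); 60 genes are growth consequences (coefficient 0.8 in every
environment); the rest are noise. Expression noise sd is 0.3. Growth
residual sd is 0.8, chosen so that the growth genetic model explains
roughly 25–55% of growth variance per environment, the range reported for
real crosses of this design. Deletion truth gives each mediator |s| = 0.1
in its active environments with sign opposing its expression–growth
correlation; 5% of all other gene × environment pairs carry a random
±0.1 fitness effect (the genome-wide background that gives fold enrichment
a denominator); assay noise sd is 0.05 per replicate measurement.

Ground-truth role labels are written to a sidecar JSON that no pipeline
stage reads — only the benchmark harness (`evaluate_synthetic_benchmark`)
consumes it.

**What passing tests do and do not show.** The generator plants linear
Gaussian effects with homoskedastic noise, bi-allelic markers, and a
noiseless genotype matrix. Real data add array-normalization artifacts,
growth-curve estimation error, epistasis, and non-Gaussian tails; recovery
rates here bound what the statistics can do under their own assumptions,
not what they will achieve on a real cross.

## Numerical choices and degenerate inputs

* REML optimizes $\log\delta$ on $[-10, 10]$; hitting the boundary is
  flagged, and identity-kinship traits (where only
  $\sigma_g^2 + \sigma_e^2$ is identified) report the optimum found.
* Kinship matrices get a $10^{-8}$ ridge before eigendecomposition.
* Constant traits yield zero variance components and p = 1 throughout;
  monomorphic markers are flagged with $\hat\beta = 0$, p = 1.
* Constant expression vectors are flagged degenerate and given mediation
  posterior 0.
* $\pi_0$ estimates are clipped to (0, 1]; q-values are capped at 1.
* Region peaks break ties by smallest p, then leftmost position; stepwise
  selection and candidate rankings break ties by genomic order and gene id
  respectively, so all outputs are independent of input order.
* BIC posteriors subtract the smaller BIC before exponentiation.

## Problem sizes

The test suite and the acceptance script run the full benchmark at the
default synthetic scale (200 × 500 × 500 × 5, ten seeds, about 15 s per
seed), the null-calibration scan at 10,000 tests, and selection-coefficient
recovery at 4,000 genes — sizes chosen so the whole suite completes in a
few minutes on one core while keeping Monte-Carlo error well inside the
tested tolerances.

## Known limitations

* The evaluation depth of 100 candidates is not selective against a
  500-gene synthetic genome: every mediator-sensitive ranking
  (multi-environment network, persistent eQTL, single-environment network)
  captures all planted mediators within its top 100, so comparisons *at
  that depth* reduce to background noise. The strategies separate sharply
  at selective depths (top 10) and in ranking AUROC, which is what the
  package's benchmark reports alongside the depth-100 values.
* One gene at a time: no search over multi-gene mediation paths, no
  epistasis, no partial-mediation decomposition beyond the `partial` flag.
* The recombination model is a constant flip probability, not a genetic
  map; marker positions are equally spaced.
* No polygenic background term in the growth genetic model.
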