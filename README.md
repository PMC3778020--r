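# crossmed

Multi-environment QTL mapping and causal mediation in segregant crosses.

## What problem this solves

A growth QTL in a yeast cross names a genomic region, not a mechanism.
Among the hundreds of transcripts whose levels correlate with such a locus,
most are downstream consequences of growth-rate variation or regulatory
side effects; only a few *causal intermediate* genes actually transmit the
genetic effect to the phenotype. `crossmed` is for geneticists who have (or
simulate) segregant growth rates across environments, expression profiles
from a checkered design (a different random subset of strains profiled in
each environment), and pooled deletion-collection fitness assays — and who
want a ranked, validated list of candidate intermediates per growth QTL.

The package exploits an asymmetry between regulation and phenotype: a
variant's effects on its intermediate genes' expression tend to be
*persistent* across environments, while its effect on growth — and hence on
all growth-consequence transcripts — is *environment-dependent*. For each
growth-model interaction term (marker *n<sub>i</sub>*, environment
*e<sub>i</sub>*) and each gene with expression *t*, growth *g*, genotype
*s* and environment indicators *E*, two linear Gaussian networks are
compared by BIC:

* **Model 1** (causal intermediate): *t* = *E*α + β<sub>s</sub>·*s* + ε
  (persistent regulation), *g* = *E*γ₀ + *C*θ + γ·*t*·1{e = e<sub>i</sub>} + ε
  (growth ⟂ genotype | expression; *C* = all other growth-model terms);
* **Model 0** (no mediation): *t* = *E*α + ε,
  *g* = *E*γ₀ + *C*θ + δ·*s*·1{e = e<sub>i</sub>} + ε.

The posterior probability of mediation under equal prior odds is
exp(−BIC₁/2) / (exp(−BIC₀/2) + exp(−BIC₁/2)); candidates are ranked by
ΔBIC = BIC₀ − BIC₁ with a direction sign from the expression–growth
correlation in *e<sub>i</sub>*. Around this core the package provides
EMMA-style kinship-corrected association scans, Storey–Tibshirani FDR,
persistent/dependent eQTL classification, a stepwise multi-environment
growth genetic model, selection-coefficient estimation from deletion
assays with a moderated t-test, directional validation benchmarking, and a
seeded synthetic-cross generator emulating the full study design.

## Worked example

```r
library(crossmed)

cfg <- pipeline_config(seed = 1L)      # 200 segregants, 500 markers, 500 genes,
ds  <- simulate_dataset(cfg)           # 5 environments, 35 profiled per env
kin <- compute_kinship(ds$genotypes)   # allele-sharing kinship

## growth QTLs in ethanol
assoc <- single_marker_scan(ds$phenotypes$growth[, "ethanol"], ds$genotypes, kin)
call_qtl_regions(assoc, fdr = 0.05, window = 50000)
#>   chrom  start    end peak_marker   peak_p n_markers
#> 1  chr1 484849 505051       m0051 2.34e-06         3
#> 2  chr3 484849 494950       m0249 1.03e-05         2

## multi-environment growth genetic model over all environments' peaks
peaks <- unique(unlist(lapply(ds$phenotypes$environments, function(ev) {
  a <- single_marker_scan(ds$phenotypes$growth[, ev], ds$genotypes, kin)
  call_qtl_regions(a)$peak_marker
})))
model <- stepwise_growth_model(ds$phenotypes$growth, ds$genotypes, peaks)
model$terms
#>   marker      env  coef
#> 1  m0050      all  1.13
#> 2  m0150 low_iron  1.32
#> 3  m0249  ethanol -1.21
#> 4  m0250  glucose  1.21
round(variance_explained(model, ds$phenotypes$growth, ds$genotypes), 2)
#>   glucose  low_iron rapamycin   ethanol   maltose
#>      0.53      0.55      0.27      0.51      0.29

## rank genes as causal intermediates for the ethanol interaction term
calls  <- call_deletion_effects(moderated_t(estimate_selection_coefficients(ds$assay)))
scores <- score_all_genes(ds$phenotypes, ds$genotypes, model,
                          which(model$terms$env == "ethanol")[1])
head(scores[, c("gene", "delta_bic", "posterior", "direction", "rank")], 5)
#>    gene delta_bic posterior direction rank
#> 1 g0091     270.6         1        -1    1
#> 2 g0123     251.3         1        -1    2
#> 3 g0127     236.1         1        -1    3
#> 4 g0133     235.1         1        -1    4
#> 5 g0117     235.0         1        -1    5

validation_rate(scores, calls, "ethanol", top_n = 100)[c("validated", "background", "fold")]
#> $validated [1] 7    $background [1] 0.041    $fold [1] 1.71
```

Reading the output: the scan recovers the two loci affecting ethanol growth
(a persistent QTL on chr1 and the sign-flip locus on chr3, whose clinical
allele is beneficial in glucose but detrimental in ethanol); the stepwise
model assigns the chr1 locus a shared term and the others
environment-interaction terms, explaining 27–55% of growth variance per
environment. The top-ranked intermediate candidate for ethanol (`g0091`) is
a planted mediator; its direction −1 says higher expression predicts slower
growth in ethanol, so its deletion should be (and is) beneficial. Seven of
the top 100 candidates validate directionally in the deletion screen
against a 4.1% background — a 1.7-fold enrichment.

The same analysis runs end-to-end from a config with
`run_pipeline(cfg, "run_dir")`, or from a shell via the thin CLI in
`inst/scripts/crossmed` (`simulate`, `map-qtl`, `map-eqtl`, `classify`,
`growth-model`, `mediate`, `deletions`, `benchmark`, `all`), which persists
every stage as TSV/BED/JSON in the run directory.

## Layout

| path | contents |
| --- | --- |
| `R/cross-sim.R` | synthetic cross: genotypes, phenotypes, checkered design, deletion assay |
| `R/lmm.R`, `R/qvalue.R` | kinship, REML mixed model, scans, Storey FDR, QTL regions |
| `R/gxe.R` | persistent/dependent decomposition and classification |
| `R/growth-model.R` | stepwise multi-environment growth genetic model |
| `R/mediation.R` | Bayesian-network mediation scoring (multi- and single-environment) |
| `R/deletion.R`, `R/benchmark.R` | selection coefficients, moderated t, validation benchmarking |
| `R/pipeline.R`, `R/cli.R`, `R/io.R` | orchestration, config, TSV/BED/JSON I/O, CLI |
| `R/evaluate.R` | truth-labeled benchmark harness over synthetic seeds |
| `vignettes/multienv-mediation.Rmd` | the methods vignette: models, assumptions, design choices |
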