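# Shared fixtures, all generated in code. The expensive multi-seed benchmark
# runs are computed lazily once and cached for the acceptance tests.

tiny_genotypes <- function(n = 50, m = 20, seed = 11, recomb = 0.5) {
  simulate_genotypes(cross_design(
    n_segregants = n, chromosomes = c(chrA = 1e5),
    markers_per_chromosome = m, recomb_prob = recomb, seed = seed))
}

# single-mediator chain dataset used by several mediation tests:
# s -> t (beta_t) -> g in env e1 (gamma), 5 environments, all profiled
chain_dataset <- function(n = 35, n_env = 5, beta_t = 1, gamma = 1,
                          noise = 0.2, seed = 1) {
  set.seed(seed)
  envs <- paste0("env", seq_len(n_env))
  segs <- sprintf("seg%03d", seq_len(n))
  s <- rbinom(n, 1, 0.5)
  expr <- array(rnorm(n * 2 * n_env, sd = noise), dim = c(n, 2, n_env),
                dimnames = list(segs, c("g0001", "g0002"), envs))
  expr[, 1, ] <- expr[, 1, ] + beta_t * s   # mediator
  growth <- matrix(rnorm(n * n_env, sd = noise), n, n_env,
                   dimnames = list(segs, envs))
  growth[, 1] <- growth[, 1] + gamma * expr[, 1, 1]
  phen <- structure(list(growth = growth, expression = expr,
                         mask = matrix(TRUE, n, n_env,
                                       dimnames = list(segs, envs)),
                         environments = envs),
                    class = "MultiEnvPhenotypes")
  alleles <- cbind(mA = s, mB = rbinom(n, 1, 0.5))
  rownames(alleles) <- segs
  geno <- structure(list(alleles = alleles,
                         map = data.frame(marker = c("mA", "mB"),
                                          chrom = "chr1",
                                          pos = c(1000L, 90000L))),
                    class = "GenotypeMatrix")
  model <- structure(list(terms = data.frame(marker = "mA", env = "env1",
                                             coef = gamma,
                                             stringsAsFactors = FALSE),
                          intercepts = stats::setNames(rep(0, n_env), envs),
                          criterion = "BIC",
                          resid_var = noise^2, environments = envs),
                     class = "GrowthGeneticModel")
  list(phen = phen, geno = geno, model = model, s = s)
}

.bench_cache <- new.env(parent = emptyenv())

benchmark_runs <- function(seeds = 1:10) {
  key <- paste0("b", paste(seeds, collapse = "_"))
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- lapply(seeds, evaluate_synthetic_benchmark)
  }
  .bench_cache[[key]]
}

null_fold_runs <- function(seeds = 1:10) {
  key <- paste0("n", paste(seeds, collapse = "_"))
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- lapply(seeds, null_eqtl_folds)
  }
  .bench_cache[[key]]
}
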