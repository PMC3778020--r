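# Benchmark harness over the synthetic cross. These functions consume the
# generator's ground-truth role labels, which no pipeline stage touches:
# they exist to measure how well the ranking strategies recover the wiring
# the generator planted.

#' Run the full pipeline on one synthetic seed and score it against truth
#'
#' Simulates a dataset, maps growth QTLs, builds the stepwise growth genetic
#' model, calls deletion fitness effects, runs the four ranking strategies,
#' and evaluates each environment-interaction term: AUROC of the Bayesian
#' networks for true mediators versus all other genotype-associated genes
#' (other QTLs' mediators, environment-dependent and side-effect genes),
#' validated counts at \code{top_n}, and fold enrichments. A term is
#' attributed to a planted QTL when its marker lies within \code{match_bp}
#' of the QTL marker on the same chromosome (linkage can shift the mapped
#' peak off the causal marker).
#'
#' @param seed Integer master seed.
#' @param config \code{PipelineConfig} overridden with this seed.
#' @param match_bp Marker-to-QTL matching distance (default 50000).
#' @return list: model, calls, bench, metrics (one row per term: marker,
#'   env, auroc_multi, auroc_single, validated counts and folds per
#'   strategy).
#' @export
evaluate_synthetic_benchmark <- function(seed, config = NULL,
                                         match_bp = 50000) {
  if (is.null(config)) config <- pipeline_config(seed = as.integer(seed))
  else config$seed <- as.integer(seed)
  ds <- simulate_dataset(config)
  kin <- compute_kinship(ds$genotypes, method = config$kinship)
  envs <- ds$phenotypes$environments
  peaks <- unique(unlist(lapply(envs, function(ev) {
    a <- single_marker_scan(ds$phenotypes$growth[, ev], ds$genotypes,
                            kinship = kin)
    call_qtl_regions(a, fdr = config$fdr, window = config$window)$peak_marker
  })))
  model <- stepwise_growth_model(ds$phenotypes$growth, ds$genotypes, peaks,
                                 criterion = config$criterion)
  calls <- call_deletion_effects(
    moderated_t(estimate_selection_coefficients(ds$assay)),
    s_cut = config$s_cut, fdr = config$fdr)
  bench <- benchmark_strategies(ds$phenotypes, ds$genotypes, model, calls,
                                top_n = config$top_n)
  map <- ds$genotypes$map
  truth <- ds$truth
  assoc_roles <- c("mediator", "dependent", "side_effect")
  metrics <- do.call(rbind, lapply(bench, function(b) {
    mk <- b$term$marker
    near <- function(m2) {
      i <- match(mk, map$marker); j <- match(m2, map$marker)
      map$chrom[i] == map$chrom[j] & abs(map$pos[i] - map$pos[j]) <= match_bp
    }
    pos_genes <- truth$gene[truth$role == "mediator" & !is.na(truth$marker) &
                              vapply(truth$marker, function(m2)
                                !is.na(m2) && near(m2), TRUE)]
    neg_genes <- setdiff(truth$gene[truth$role %in% assoc_roles], pos_genes)
    auroc_of <- function(rk) {
      sc <- stats::setNames(rk$delta_bic, rk$gene)
      lab <- c(rep(TRUE, length(pos_genes)), rep(FALSE, length(neg_genes)))
      auroc(sc[c(pos_genes, neg_genes)], lab)
    }
    ev <- b$evaluation
    val <- function(s) ev$validated[ev$strategy == s]
    fold <- function(s) ev$fold[ev$strategy == s]
    data.frame(marker = mk, env = b$term$env,
               n_mediators = length(pos_genes),
               auroc_multi = auroc_of(b$rankings$multi_env_bn),
               auroc_single = auroc_of(b$rankings$single_env_bn),
               val_multi = val("multi_env_bn"),
               val_persistent = val("persistent_eqtl"),
               val_single = val("single_env_bn"),
               val_dependent = val("dependent_eqtl"),
               fold_persistent = fold("persistent_eqtl"),
               fold_dependent = fold("dependent_eqtl"),
               stringsAsFactors = FALSE)
  }))
  list(model = model, calls = calls, bench = bench, metrics = metrics,
       truth = truth)
}

#' Persistent and dependent eQTL fold enrichments under the global null
#'
#' Runs the generator with every genetic and growth-coupling effect zeroed,
#' anchors one evaluation term per environment at the strongest growth
#' association, ranks genes by persistent and by environment-dependent eQTL
#' p-value, and returns the two fold enrichments averaged over environments.
#'
#' @param seed Integer master seed.
#' @param config \code{PipelineConfig} (null_effects is forced on).
#' @return list: persistent, dependent (mean folds across environments).
#' @export
null_eqtl_folds <- function(seed, config = NULL) {
  if (is.null(config)) config <- pipeline_config()
  config$seed <- as.integer(seed)
  config$null_effects <- TRUE
  ds <- simulate_dataset(config)
  kin <- compute_kinship(ds$genotypes, method = config$kinship)
  calls <- call_deletion_effects(
    moderated_t(estimate_selection_coefficients(ds$assay)),
    s_cut = config$s_cut, fdr = config$fdr)
  envs <- ds$phenotypes$environments
  folds <- vapply(envs, function(ev) {
    a <- single_marker_scan(ds$phenotypes$growth[, ev], ds$genotypes,
                            kinship = kin)
    mk <- a$marker[which.min(a$p)]
    eq <- eqtl_rankings(ds$phenotypes, ds$genotypes, mk, ev)
    c(validation_rate(eq$persistent, calls, ev, top_n = config$top_n)$fold,
      validation_rate(eq$dependent, calls, ev, top_n = config$top_n)$fold)
  }, numeric(2))
  list(persistent = mean(folds[1, ]), dependent = mean(folds[2, ]))
}
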