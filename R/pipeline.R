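#' Pipeline configuration
#'
#' Validates thresholds and method switches; unknown keys are rejected.
#' Defaults reproduce the package's standard synthetic benchmark: 200
#' segregants, 500 markers on 5 chromosomes, 500 genes, 5 environments with
#' 35 profiled segregants each.
#'
#' @param ... Key-value overrides of the defaults listed below.
#' @return A validated \code{PipelineConfig} list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_segregants = 200L, n_chromosomes = 5L, chromosome_length = 1e6,
    markers_per_chromosome = 100L, recomb_prob = 0.02,
    n_genes = 500L,
    environments = c("glucose", "low_iron", "rapamycin", "ethanol", "maltose"),
    n_per_env = 35L,
    fdr = 0.05, window = 50000, s_cut = 0.05, top_n = 100L,
    kinship = "ibs", contrast = "sum", partial = FALSE, downsample = FALSE,
    criterion = "BIC", eqtl_scan = FALSE, null_effects = FALSE,
    deletion_background = 0.05,
    seed = 1L)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$fdr > 0, cfg$fdr < 1, cfg$window > 0, cfg$s_cut >= 0,
            cfg$top_n >= 1, cfg$kinship %in% c("ibs", "identity"),
            cfg$contrast %in% c("sum", "reference"),
            cfg$criterion %in% c("BIC", "AIC"),
            cfg$recomb_prob >= 0, cfg$recomb_prob <= 0.5)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path (.yaml/.yml or .json).
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(raw)
}

# deterministic sub-seed per named stage, derived from the master seed and
# kept below 2^31
stage_seed <- function(seed, stage) {
  offsets <- c(genotypes = 101L, phenotypes = 211L, checkered = 307L,
               deletion_truth = 401L, deletion_assay = 503L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483647L
}

#' Simulate a full synthetic dataset under a configuration
#'
#' @param config \code{PipelineConfig}.
#' @return list: genotypes, phenotypes (checkered), assay, truth, arch.
#' @export
simulate_dataset <- function(config) {
  chroms <- stats::setNames(rep(config$chromosome_length, config$n_chromosomes),
                            paste0("chr", seq_len(config$n_chromosomes)))
  design <- cross_design(n_segregants = config$n_segregants,
                         chromosomes = chroms,
                         markers_per_chromosome = config$markers_per_chromosome,
                         recomb_prob = config$recomb_prob,
                         seed = stage_seed(config$seed, "genotypes"))
  genotypes <- simulate_genotypes(design)
  arch <- default_architecture(genotypes, config$environments,
                               n_genes = config$n_genes)
  if (isTRUE(config$null_effects)) {
    arch$trait$qtl_terms$effect <- 0
    arch$expr$mediators$beta_t <- 1e-12  # role kept, effect nulled
    arch$expr$mediator_growth$beta_g <- 0
    arch$expr$dependent_genes$effect <- 0
    arch$expr$consequence_genes$coef <- 0
    arch$expr$side_effect_genes$effect <- 0
  }
  phen <- simulate_phenotypes(genotypes, arch$trait, arch$expr,
                              config$environments,
                              seed = stage_seed(config$seed, "phenotypes"))
  phen <- apply_checkered_design(phen, config$n_per_env,
                                 seed = stage_seed(config$seed, "checkered"))
  truth_s <- if (isTRUE(config$null_effects)) {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    s <- matrix(0, length(genes), length(config$environments),
                dimnames = list(genes, config$environments))
    set.seed(stage_seed(config$seed, "deletion_truth"))
    hit <- matrix(stats::runif(length(s)) < config$deletion_background, nrow(s))
    s[hit] <- 0.1 * sample(c(-1, 1), sum(hit), replace = TRUE)
    deletion_truth(s)
  } else {
    default_deletion_truth(arch$expr, config$environments,
                           background_rate = config$deletion_background,
                           seed = stage_seed(config$seed, "deletion_truth"))
  }
  assay <- simulate_deletion_assay(truth_s,
                                   seed = stage_seed(config$seed, "deletion_assay"))
  list(genotypes = genotypes, phenotypes = phen, assay = assay,
       truth = arch$truth, arch = arch, deletion_truth = truth_s)
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> growth QTL mapping -> eQTL mapping (optional
#' genome-wide scan) -> persistent/dependent classification -> stepwise
#' growth genetic model -> mediation scoring (multi- and single-environment
#' Bayesian networks) -> deletion fitness -> benchmark report. All stage
#' outputs are written as TSV/BED/JSON under \code{out_dir}; the JSON report
#' contrasts the four ranking strategies and the persistent vs dependent
#' validation rates.
#'
#' If the growth genetic model contains no environment-interaction term (as
#' under a global null), the benchmark anchors its evaluation at the
#' strongest growth-association marker in each environment so that fold
#' enrichments remain defined.
#'
#' @param config \code{PipelineConfig}.
#' @param out_dir Output directory.
#' @param dataset Optional pre-loaded dataset (list with genotypes,
#'   phenotypes, assay) to analyze instead of simulating.
#' @return The report, invisibly (also written to \code{out_dir/report.json}).
#' @export
run_pipeline <- function(config, out_dir, dataset = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_path <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), sprintf(...), "\n",
        file = log_path, append = TRUE)
  }
  logmsg("pipeline start, seed %d, crossmed %s", config$seed,
         as.character(utils::packageVersion("crossmed")))
  if (is.null(dataset)) {
    logmsg("stage simulate")
    dataset <- simulate_dataset(config)
    write_dataset(out_dir, dataset$genotypes, dataset$phenotypes,
                  assay = dataset$assay, truth = dataset$truth)
  }
  genotypes <- dataset$genotypes
  phen <- dataset$phenotypes
  if (is.null(dataset$assay)) stop("missing upstream output: deletion assay")
  kin <- compute_kinship(genotypes, method = config$kinship)
  envs <- phen$environments

  logmsg("stage map-qtl")
  growth_assoc <- lapply(envs, function(ev) {
    a <- single_marker_scan(phen$growth[, ev], genotypes, kinship = kin)
    write_tsv(a, file.path(out_dir, paste0("assoc_growth_", ev, ".tsv")))
    a
  })
  names(growth_assoc) <- envs
  regions <- lapply(envs, function(ev) {
    call_qtl_regions(growth_assoc[[ev]], fdr = config$fdr,
                     window = config$window)
  })
  names(regions) <- envs
  all_regions <- do.call(rbind, Map(function(r, ev) {
    if (nrow(r) > 0) cbind(r, environment = ev) else NULL
  }, regions, envs))
  if (!is.null(all_regions) && nrow(all_regions) > 0) {
    write_regions_bed(all_regions, file.path(out_dir, "growth_qtl_regions.bed"))
    write_tsv(all_regions, file.path(out_dir, "growth_qtl_regions.tsv"))
  }
  peak_markers <- unique(unlist(lapply(regions, function(r) r$peak_marker)))

  if (isTRUE(config$eqtl_scan)) {
    logmsg("stage map-eqtl")
    for (ev in envs) {
      genes <- dimnames(phen$expression)[[2]]
      rows <- lapply(genes, function(gn) {
        y <- phen$expression[, gn, ev]
        a <- single_marker_scan(y, genotypes, kinship = kin)
        best <- which.min(a$p)
        data.frame(gene = gn, marker = a$marker[best], chrom = a$chrom[best],
                   pos = a$pos[best], beta = a$beta[best], p = a$p[best],
                   stringsAsFactors = FALSE)
      })
      etab <- do.call(rbind, rows)
      etab$q <- storey_qvalues(etab$p)$qvalues
      write_tsv(etab, file.path(out_dir, paste0("eqtl_", ev, ".tsv")))
    }
  }

  logmsg("stage growth-model")
  model <- stepwise_growth_model(phen$growth, genotypes, peak_markers,
                                 criterion = config$criterion)
  r2 <- variance_explained(model, phen$growth, genotypes)
  jsonlite::write_json(list(terms = model$terms,
                            intercepts = as.list(model$intercepts),
                            criterion = model$criterion,
                            trace = model$criterion_trace,
                            resid_var = model$resid_var),
                       file.path(out_dir, "growth_model.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_tsv(data.frame(environment = names(r2), r_squared = as.numeric(r2)),
            file.path(out_dir, "variance_explained.tsv"))

  logmsg("stage classify")
  class_markers <- unique(model$terms$marker)
  if (length(class_markers) == 0) class_markers <- peak_markers
  classification <- do.call(rbind, lapply(class_markers, function(mk) {
    classify_marker(phen, genotypes, mk, fdr = config$fdr,
                    downsample = isTRUE(config$downsample),
                    seed = config$seed)
  }))
  if (!is.null(classification)) {
    write_tsv(classification, file.path(out_dir, "gxe_classification.tsv"))
  }

  logmsg("stage deletions")
  fit <- estimate_selection_coefficients(dataset$assay)
  fit <- moderated_t(fit)
  calls <- call_deletion_effects(fit, s_cut = config$s_cut, fdr = config$fdr)
  write_tsv(calls, file.path(out_dir, "deletion_calls.tsv"))

  logmsg("stage mediate + benchmark")
  bench_model <- model
  if (sum(model$terms$env != "all") == 0) {
    # null fallback: anchor at the strongest growth association per env
    fb <- do.call(rbind, lapply(envs, function(ev) {
      a <- growth_assoc[[ev]]
      data.frame(marker = a$marker[which.min(a$p)], env = ev, coef = 0,
                 stringsAsFactors = FALSE)
    }))
    bench_model <- model
    bench_model$terms <- fb
  }
  bench <- benchmark_strategies(phen, genotypes, bench_model, calls,
                                top_n = config$top_n)
  for (b in bench) {
    for (nm in names(b$rankings)) {
      write_tsv(b$rankings[[nm]],
                file.path(out_dir, sprintf("ranking_%s_%s_%s.tsv",
                                           nm, b$term$marker, b$term$env)))
    }
    curve_tab <- do.call(rbind, Map(function(cv, nm) {
      cbind(strategy = nm, cv)
    }, b$curves, names(b$curves)))
    write_tsv(curve_tab, file.path(out_dir, sprintf("enrichment_curves_%s_%s.tsv",
                                                    b$term$marker, b$term$env)))
  }

  report <- list(
    seed = config$seed,
    n_growth_qtl_regions = if (is.null(all_regions)) 0L else nrow(all_regions),
    growth_model_terms = model$terms,
    variance_explained = as.list(r2),
    terms_evaluated = lapply(bench, function(b) b$term),
    strategy_evaluation = lapply(bench, function(b) b$evaluation),
    curves_at_top_n = lapply(bench, function(b) {
      lapply(b$curves, function(cv) {
        nn <- min(config$top_n, nrow(cv))
        list(n = nn, validated = cv$validated[nn], expected = cv$expected[nn])
      })
    }),
    persistent_vs_dependent = {
      folds <- function(strat) vapply(bench, function(b) {
        b$evaluation$fold[b$evaluation$strategy == strat]
      }, 0)
      list(persistent_fold = folds("persistent_eqtl"),
           dependent_fold = folds("dependent_eqtl"),
           persistent_mean = mean(folds("persistent_eqtl")),
           dependent_mean = mean(folds("dependent_eqtl")))
    })
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  logmsg("pipeline done")
  invisible(report)
}
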