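# Gaussian profile log-likelihood of a least-squares fit:
# maximizing over the noise variance gives -(n/2) (log(2 pi RSS / n) + 1).
profile_loglik <- function(rss, n) {
  if (rss <= 0) rss <- 1e-12  # guard exact fits
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}

# least-squares sub-model fit: log-likelihood, parameter count (rank of the
# design + 1 noise variance), coefficients
lg_fit <- function(X, y) {
  qx <- qr(X)
  rss <- sum(qr.resid(qx, y)^2)
  list(loglik = profile_loglik(rss, length(y)), k = qx$rank + 1L,
       coef = qr.coef(qx, y), rss = rss)
}

#' Assemble the input of the mediation network for one gene and one term
#'
#' Collects the stacked profiled samples for the gene: growth vector g,
#' expression vector t (optionally standardized to zero mean and unit
#' variance within each environment), genotype indicator s at the term's
#' marker, the one-hot environment matrix E, and the growth-model covariates
#' (all terms of the growth genetic model except the one under test).
#'
#' @param phenotypes \code{MultiEnvPhenotypes}.
#' @param gene Gene id.
#' @param genotypes \code{GenotypeMatrix}.
#' @param model \code{GrowthGeneticModel}.
#' @param term_index Row index into \code{model$terms} of the interaction
#'   term (marker n_i, environment e_i) under test.
#' @param standardize Standardize expression per environment (default TRUE).
#' @param stack Optional precomputed \code{\link{stack_expression}} result
#'   for this gene at the term's marker (avoids rebuilding it).
#' @return A \code{MediationInput} list.
#' @export
mediation_input <- function(phenotypes, gene, genotypes, model, term_index,
                            standardize = TRUE, stack = NULL) {
  term <- model$terms[term_index, ]
  if (identical(term$env, "all")) {
    stop("mediation is scored for environment-interaction terms only")
  }
  st <- if (is.null(stack)) stack_expression(phenotypes, gene, genotypes, term$marker)
        else stack
  if (standardize) {
    for (ev in unique(st$env)) {
      i <- st$env == ev
      mu <- mean(st$expression[i])
      sdv <- stats::sd(st$expression[i])
      st$expression[i] <- if (sdv > 1e-12) (st$expression[i] - mu) / sdv
                          else st$expression[i] - mu
    }
  }
  envs <- phenotypes$environments
  E <- matrix(0, nrow(st), length(envs), dimnames = list(NULL, envs))
  E[cbind(seq_len(nrow(st)), match(st$env, envs))] <- 1
  covar <- model_term_matrix(model, genotypes, st$segregant, st$env,
                             exclude = term_index)
  structure(list(g = st$growth, t = st$expression, s = st$genotype, E = E,
                 env = st$env, segregant = st$segregant,
                 term = list(marker = term$marker, env = term$env),
                 covariates = covar, gene = gene),
            class = "MediationInput")
}

#' Fit Model 1 (causal intermediate gene)
#'
#' Two linear Gaussian sub-models: (a) expression under environmentally
#' persistent genetic regulation, t ~ environment intercepts + beta_s * s
#' (one genotype coefficient shared across environments); (b) growth
#' conditionally independent of genotype given expression,
#' g ~ environment intercepts + growth-model covariates +
#' gamma * (t restricted to the tested environment). The joint log-likelihood
#' is the sum of the two profile Gaussian log-likelihoods; the parameter
#' count includes both designs' ranks and two noise variances.
#'
#' @param input \code{MediationInput}.
#' @param partial Also keep the tested term's direct genotype effect in the
#'   growth sub-model (partial mediation; default FALSE).
#' @return list: loglik, k, coefficients of both sub-models.
#' @export
fit_model1 <- function(input, partial = FALSE) {
  e_i <- input$term$env
  if (sum(input$env == e_i) < 3) stop("need >= 3 samples in the tested environment")
  in_env <- as.numeric(input$env == e_i)
  ft <- lg_fit(cbind(input$E, s = input$s), input$t)
  Xg <- cbind(input$E, input$covariates, t_env = input$t * in_env)
  if (partial) Xg <- cbind(Xg, s_env = input$s * in_env)
  fg <- lg_fit(Xg, input$g)
  list(loglik = ft$loglik + fg$loglik, k = ft$k + fg$k,
       coef_t = ft$coef, coef_g = fg$coef)
}

#' Fit Model 0 (no mediation)
#'
#' Sub-models: (a) expression independent of the growth-QTL genotype,
#' t ~ environment intercepts only; (b) growth following the multi-
#' environment growth genetic model, g ~ environment intercepts + covariates
#' + delta * (s restricted to the tested environment).
#'
#' @param input \code{MediationInput}.
#' @return list: loglik, k, coefficients of both sub-models.
#' @export
fit_model0 <- function(input) {
  e_i <- input$term$env
  in_env <- as.numeric(input$env == e_i)
  ft <- lg_fit(input$E, input$t)
  fg <- lg_fit(cbind(input$E, input$covariates, s_env = input$s * in_env),
               input$g)
  list(loglik = ft$loglik + fg$loglik, k = ft$k + fg$k,
       coef_t = ft$coef, coef_g = fg$coef)
}

#' Score one gene as a candidate causal intermediate
#'
#' BIC_m = -2 logLik_m + k_m log(n) for both models, with n the number of
#' stacked profiled samples (shared by both models). The posterior
#' probability of the mediation model under equal prior odds is
#' exp(-BIC_1/2) / (exp(-BIC_0/2) + exp(-BIC_1/2)), computed after
#' subtracting the smaller BIC to avoid overflow. The direction sign is the
#' sign of the expression-growth correlation within the tested environment.
#'
#' @param input \code{MediationInput}.
#' @param partial Passed to \code{\link{fit_model1}}.
#' @return One-row data.frame: gene, marker, env, bic0, bic1, posterior,
#'   direction, degenerate.
#' @export
score_mediation <- function(input, partial = FALSE) {
  n <- length(input$g)
  degenerate <- stats::sd(input$t) < 1e-10
  i_env <- input$env == input$term$env
  dir_cor <- suppressWarnings(stats::cor(input$t[i_env], input$g[i_env]))
  direction <- if (is.na(dir_cor)) 0 else sign(dir_cor)
  if (degenerate) {
    return(data.frame(gene = input$gene, marker = input$term$marker,
                      env = input$term$env, bic0 = NA_real_, bic1 = NA_real_,
                      delta_bic = -Inf, posterior = 0, direction = direction,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  m0 <- fit_model0(input)
  m1 <- fit_model1(input, partial = partial)
  bic0 <- -2 * m0$loglik + m0$k * log(n)
  bic1 <- -2 * m1$loglik + m1$k * log(n)
  b <- min(bic0, bic1)
  posterior <- exp(-(bic1 - b) / 2) /
    (exp(-(bic0 - b) / 2) + exp(-(bic1 - b) / 2))
  data.frame(gene = input$gene, marker = input$term$marker,
             env = input$term$env, bic0 = bic0, bic1 = bic1,
             delta_bic = bic0 - bic1, posterior = posterior,
             direction = direction, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Restrict a mediation input to the tested environment
#'
#' The single-environment variant of the network: only samples profiled in
#' the environment of the tested term are used, and the persistent expression
#' sub-model collapses to a single-environment genotype effect.
#'
#' @param input \code{MediationInput}.
#' @return A \code{MediationInput} over the restricted samples.
#' @export
single_env_input <- function(input) {
  i <- input$env == input$term$env
  covar <- input$covariates[i, , drop = FALSE]
  if (ncol(covar) > 0) {
    keep <- apply(covar, 2, function(x) stats::sd(x) > 1e-12)
    covar <- covar[, keep, drop = FALSE]
  }
  structure(list(g = input$g[i], t = input$t[i], s = input$s[i],
                 E = matrix(1, sum(i), 1, dimnames = list(NULL, input$term$env)),
                 env = input$env[i], segregant = input$segregant[i],
                 term = input$term, covariates = covar, gene = input$gene),
            class = "MediationInput")
}

#' Score all genes for one growth-model interaction term
#'
#' @param phenotypes \code{MultiEnvPhenotypes}.
#' @param genotypes \code{GenotypeMatrix}.
#' @param model \code{GrowthGeneticModel}.
#' @param term_index Row index into \code{model$terms}.
#' @param genes Genes to score (default: all simulated genes).
#' @param single_env Use the single-environment network variant.
#' @param partial Partial mediation (keep the direct genotype effect).
#' @param standardize Standardize expression per environment.
#' @return data.frame of \code{\link{score_mediation}} rows, ranked.
#' @export
score_all_genes <- function(phenotypes, genotypes, model, term_index,
                            genes = NULL, single_env = FALSE, partial = FALSE,
                            standardize = TRUE) {
  if (is.null(genes)) genes <- dimnames(phenotypes$expression)[[2]]
  rows <- lapply(genes, function(gn) {
    inp <- mediation_input(phenotypes, gn, genotypes, model, term_index,
                           standardize = standardize)
    if (single_env) inp <- single_env_input(inp)
    score_mediation(inp, partial = partial)
  })
  rank_candidates(do.call(rbind, rows))
}

#' Rank mediation scores
#'
#' Descending by posterior probability of the mediation model, ties broken
#' deterministically by gene id; attaches a \code{rank} column. The ordering
#' uses the BIC difference when available: the posterior is a strictly
#' monotone function of BIC_0 - BIC_1 but saturates at 1 in floating point
#' for decisive Bayes factors, which would otherwise collapse the top of the
#' ranking into ties.
#'
#' @param scores data.frame with columns gene, posterior (and optionally
#'   delta_bic).
#' @export
rank_candidates <- function(scores) {
  key <- if ("delta_bic" %in% names(scores)) scores$delta_bic
         else scores$posterior
  o <- order(-key, scores$gene)
  scores <- scores[o, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}
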