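#' Background validation rate of the deletion screen
#'
#' The base rate against which candidate rankings are normalized: the chance
#' that a randomly selected assayed gene validates in the given environment.
#' When direction matching is on, a random candidate carries a random
#' direction sign, so the rate is (beneficial + detrimental) / (2 * assayed);
#' with \code{ignore_direction} it is the plain significant fraction.
#'
#' @param calls data.frame from \code{\link{call_deletion_effects}}.
#' @param env Environment.
#' @param ignore_direction Drop the direction-consistency requirement.
#' @export
background_rate <- function(calls, env, ignore_direction = FALSE) {
  cc <- calls$call[calls$environment == env]
  if (length(cc) == 0) stop("no deletion calls for environment ", env)
  n_sig <- sum(cc != "none")
  if (ignore_direction) n_sig / length(cc) else n_sig / (2 * length(cc))
}

# TRUE/FALSE per candidate row: significant call with consistent direction.
# Positive expression-growth correlation predicts the deletion to be
# detrimental, and vice versa.
validates <- function(candidates, calls, env, ignore_direction = FALSE) {
  cc <- calls[calls$environment == env, , drop = FALSE]
  call_of <- stats::setNames(cc$call, cc$gene)[candidates$gene]
  call_of[is.na(call_of)] <- "none"
  if (ignore_direction) {
    call_of != "none"
  } else {
    (candidates$direction > 0 & call_of == "detrimental") |
      (candidates$direction < 0 & call_of == "beneficial")
  }
}

#' Directional validation rate and fold enrichment of a candidate ranking
#'
#' A candidate validates iff its deletion call in the evaluation environment
#' is significant and the call's direction is consistent with the
#' candidate's sign. Fold enrichment is the validated fraction among the top
#' n divided by the background rate over all assayed genes in that
#' environment.
#'
#' @param candidates Ranked data.frame with columns gene, direction (rows in
#'   rank order; restrict to assayed genes beforehand).
#' @param calls data.frame from \code{\link{call_deletion_effects}}.
#' @param env Evaluation environment.
#' @param top_n Number of top candidates evaluated (default 100).
#' @param ignore_direction Drop the direction requirement.
#' @return list: n (candidates used), validated, rate, background, fold.
#' @export
validation_rate <- function(candidates, calls, env, top_n = 100,
                            ignore_direction = FALSE) {
  if (top_n > nrow(candidates)) {
    warning("top_n exceeds number of candidates; using all")
    top_n <- nrow(candidates)
  }
  top <- candidates[seq_len(top_n), , drop = FALSE]
  v <- validates(top, calls, env, ignore_direction)
  bg <- background_rate(calls, env, ignore_direction)
  rate <- sum(v) / top_n
  list(n = top_n, validated = sum(v), rate = rate, background = bg,
       fold = if (bg > 0) rate / bg else NA_real_)
}

#' Jackknife mean and standard deviation of per-QTL rates
#'
#' Leave-one-out resampling over growth QTLs:
#' sd = sqrt((m - 1)/m * sum((theta_(i) - theta_bar)^2)) where theta_(i) is
#' the mean over all QTLs but the i-th.
#'
#' @param rates Numeric vector of per-QTL validation rates (length >= 2).
#' @return list: mean, jackknife_sd, leave_one_out.
#' @export
jackknife_enrichment <- function(rates) {
  m <- length(rates)
  if (m < 2) stop("jackknife requires >= 2 QTLs")
  loo <- vapply(seq_len(m), function(i) mean(rates[-i]), 0)
  list(mean = mean(rates),
       jackknife_sd = sqrt((m - 1) / m * sum((loo - mean(loo))^2)),
       leave_one_out = loo)
}

#' Cumulative enrichment curve of a candidate ranking
#'
#' Walking down the ranking, the cumulative number of validated candidates
#' versus the number predicted, together with the random expectation
#' (background rate times n).
#'
#' @inheritParams validation_rate
#' @return data.frame: n, validated, expected.
#' @export
enrichment_curve <- function(candidates, calls, env, ignore_direction = FALSE) {
  v <- validates(candidates, calls, env, ignore_direction)
  bg <- background_rate(calls, env, ignore_direction)
  data.frame(n = seq_along(v), validated = cumsum(v),
             expected = bg * seq_along(v))
}

#' Area under the ROC curve by the rank-sum formula
#'
#' @param score Numeric predictions (higher = more positive).
#' @param label Logical (or 0/1) truth labels.
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank genes by persistent or environment-dependent eQTL association
#'
#' Fits the joint environment model for every gene at the term's marker and
#' ranks by the shared-effect p-value (persistent) or by the tested
#' environment's interaction p-value (dependent), ascending. Directions are
#' taken from the expression-growth correlation in the tested environment.
#'
#' @param phenotypes \code{MultiEnvPhenotypes}.
#' @param genotypes \code{GenotypeMatrix}.
#' @param marker Marker id of the growth QTL.
#' @param env Tested environment.
#' @param genes Genes to rank (default all).
#' @param kinship Optional \code{KinshipMatrix} for the joint model.
#' @return list of two ranked data.frames (gene, p, direction):
#'   \code{persistent} and \code{dependent}.
#' @export
eqtl_rankings <- function(phenotypes, genotypes, marker, env, genes = NULL,
                          kinship = NULL) {
  if (is.null(genes)) genes <- dimnames(phenotypes$expression)[[2]]
  rows <- lapply(genes, function(gn) {
    st <- stack_expression(phenotypes, gn, genotypes, marker)
    fit <- fit_joint_env_model(st$expression, st$genotype, st$env,
                               kinship = kinship, segregant = st$segregant,
                               interaction = "single", env_of_interest = env)
    i <- st$env == env
    dc <- suppressWarnings(stats::cor(st$expression[i], st$growth[i]))
    data.frame(gene = gn, p_shared = fit$shared$p,
               p_dep = fit$interactions$p[1],
               direction = if (is.na(dc)) 0 else sign(dc),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord_p <- function(p) order(p, tab$gene)
  pers <- tab[ord_p(tab$p_shared), c("gene", "p_shared", "direction")]
  names(pers)[2] <- "p"
  dep <- tab[ord_p(tab$p_dep), c("gene", "p_dep", "direction")]
  names(dep)[2] <- "p"
  rownames(pers) <- rownames(dep) <- NULL
  list(persistent = pers, dependent = dep)
}

#' Compare the four candidate-ranking strategies against deletion fitness
#'
#' For each environment-interaction term of the growth genetic model, ranks
#' all genes by (i) the multi-environment Bayesian network posterior, (ii)
#' persistent eQTL association, (iii) the single-environment Bayesian
#' network, and (iv) environment-dependent eQTL association, then evaluates
#' each ranking against the deletion-screen calls (directional validation,
#' fold enrichment at \code{top_n}, cumulative enrichment curves).
#'
#' @param phenotypes \code{MultiEnvPhenotypes}.
#' @param genotypes \code{GenotypeMatrix}.
#' @param model \code{GrowthGeneticModel}.
#' @param calls Deletion calls from \code{\link{call_deletion_effects}}.
#' @param genes Genes to rank (default all; restrict to assayed genes).
#' @param top_n Evaluation depth (default 100).
#' @param ignore_direction Drop direction matching in validation.
#' @return list with one element per term: term, rankings (named list of
#'   ranked data.frames), evaluation (data.frame strategy, validated, rate,
#'   fold), curves (named list of enrichment curves).
#' @export
benchmark_strategies <- function(phenotypes, genotypes, model, calls,
                                 genes = NULL, top_n = 100,
                                 ignore_direction = FALSE) {
  terms <- model$terms
  term_idx <- which(terms$env != "all")
  if (length(term_idx) == 0) {
    warning("growth model has no environment-interaction terms")
    return(list())
  }
  if (is.null(genes)) genes <- dimnames(phenotypes$expression)[[2]]
  lapply(term_idx, function(ti) {
    marker <- terms$marker[ti]; ev <- terms$env[ti]
    # one pass per gene: the stacked samples feed the two network variants
    # and the joint environment model alike
    per_gene <- lapply(genes, function(gn) {
      st <- stack_expression(phenotypes, gn, genotypes, marker)
      inp <- mediation_input(phenotypes, gn, genotypes, model, ti, stack = st)
      sm <- score_mediation(inp)
      ss <- score_mediation(single_env_input(inp))
      fit <- fit_joint_env_model(st$expression, st$genotype, st$env,
                                 interaction = "single",
                                 env_of_interest = ev)
      i <- st$env == ev
      dc <- suppressWarnings(stats::cor(st$expression[i], st$growth[i]))
      list(multi = sm, single = ss,
           eq = data.frame(gene = gn, p_shared = fit$shared$p,
                           p_dep = fit$interactions$p[1],
                           direction = if (is.na(dc)) 0 else sign(dc),
                           stringsAsFactors = FALSE))
    })
    bn_multi <- rank_candidates(do.call(rbind, lapply(per_gene, `[[`, "multi")))
    bn_single <- rank_candidates(do.call(rbind, lapply(per_gene, `[[`, "single")))
    eqtab <- do.call(rbind, lapply(per_gene, `[[`, "eq"))
    pers <- eqtab[order(eqtab$p_shared, eqtab$gene),
                  c("gene", "p_shared", "direction")]
    dep <- eqtab[order(eqtab$p_dep, eqtab$gene),
                 c("gene", "p_dep", "direction")]
    names(pers)[2] <- names(dep)[2] <- "p"
    rownames(pers) <- rownames(dep) <- NULL
    rankings <- list(multi_env_bn = bn_multi, persistent_eqtl = pers,
                     single_env_bn = bn_single, dependent_eqtl = dep)
    evaluation <- do.call(rbind, lapply(names(rankings), function(nm) {
      vr <- validation_rate(rankings[[nm]], calls, ev, top_n = top_n,
                            ignore_direction = ignore_direction)
      data.frame(strategy = nm, n = vr$n, validated = vr$validated,
                 rate = vr$rate, background = vr$background, fold = vr$fold,
                 stringsAsFactors = FALSE)
    }))
    curves <- lapply(rankings, enrichment_curve, calls = calls, env = ev,
                     ignore_direction = ignore_direction)
    list(term = list(marker = marker, env = ev), rankings = rankings,
         evaluation = evaluation, curves = curves)
  })
}
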