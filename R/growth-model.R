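#' Stepwise multi-environment growth genetic model
#'
#' Growth rates are stacked across environments and modeled with
#' per-environment intercepts (always included). Candidate terms are, for
#' each candidate locus, a main effect shared across environments
#' (env = "all") and one interaction term per environment (the allele code
#' restricted to that environment). Forward-backward selection adds or drops
#' whichever single term most lowers the selection criterion, until no move
#' improves it. An interaction may enter without its main effect, as needed
#' for sign-flip loci. Ties are broken deterministically by (chromosome,
#' position, environment).
#'
#' @param growth Segregant x environment growth matrix.
#' @param genotypes \code{GenotypeMatrix}.
#' @param candidate_markers Character vector of candidate marker ids
#'   (typically QTL-region peaks from \code{\link{call_qtl_regions}}).
#' @param criterion "BIC" (default) or "AIC".
#' @return A \code{GrowthGeneticModel}: list with \code{terms} (data.frame
#'   marker, env, coef), \code{intercepts}, \code{criterion_trace},
#'   \code{resid_var}, \code{environments}.
#' @export
stepwise_growth_model <- function(growth, genotypes, candidate_markers,
                                  criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  envs <- colnames(growth)
  n_seg <- nrow(growth)
  candidate_markers <- unique(candidate_markers)
  if (!all(candidate_markers %in% colnames(genotypes$alleles))) {
    stop("candidate marker not present in genotype matrix")
  }
  y <- as.vector(growth)                       # stacked env-major
  env <- rep(envs, each = n_seg)
  n <- length(y)
  Xenv <- matrix(0, n, length(envs), dimnames = list(NULL, envs))
  Xenv[cbind(seq_len(n), match(env, envs))] <- 1

  map <- genotypes$map
  ord <- candidate_markers[order(match(candidate_markers, map$marker))]
  cand <- if (length(ord) == 0) {
    data.frame(marker = character(0), env = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(
      lapply(ord, function(mk) data.frame(marker = mk, env = "all",
                                          stringsAsFactors = FALSE)),
      lapply(ord, function(mk) data.frame(marker = mk, env = envs,
                                          stringsAsFactors = FALSE))))
  }
  term_col <- function(mk, ev) {
    g <- rep(genotypes$alleles[, mk], times = length(envs))
    if (identical(ev, "all")) g else g * (env == ev)
  }
  penalty <- if (criterion == "BIC") log(n) else 2
  crit_of <- function(cols) {
    X <- cbind(Xenv, cols)
    qx <- qr(X)
    rss <- sum(qr.resid(qx, y)^2)
    n * log(rss / n) + penalty * qx$rank
  }
  selected <- integer(0)
  cols_of <- function(ix) {
    if (length(ix) == 0) return(NULL)
    do.call(cbind, lapply(ix, function(i) term_col(cand$marker[i], cand$env[i])))
  }
  cur <- crit_of(NULL)
  trace <- data.frame(step = 0L, action = "start", marker = NA_character_,
                      env = NA_character_, criterion = cur,
                      stringsAsFactors = FALSE)
  if (nrow(cand) > 0) repeat {
    best <- list(crit = cur, action = "none", idx = NA_integer_)
    for (i in setdiff(seq_len(nrow(cand)), selected)) {
      cr <- crit_of(cols_of(c(selected, i)))
      if (cr < best$crit - 1e-9) best <- list(crit = cr, action = "add", idx = i)
    }
    for (i in selected) {
      cr <- crit_of(cols_of(setdiff(selected, i)))
      if (cr < best$crit - 1e-9) best <- list(crit = cr, action = "drop", idx = i)
    }
    if (best$action == "none") break
    selected <- if (best$action == "add") c(selected, best$idx)
                else setdiff(selected, best$idx)
    cur <- best$crit
    trace <- rbind(trace, data.frame(step = nrow(trace), action = best$action,
                                     marker = cand$marker[best$idx],
                                     env = cand$env[best$idx], criterion = cur,
                                     stringsAsFactors = FALSE))
  }
  selected <- sort(selected)
  X <- cbind(Xenv, cols_of(selected))
  qx <- qr(X)
  cf <- qr.coef(qx, y)
  rss <- sum(qr.resid(qx, y)^2)
  terms <- if (length(selected) > 0) {
    data.frame(marker = cand$marker[selected], env = cand$env[selected],
               coef = cf[length(envs) + seq_along(selected)],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(marker = character(0), env = character(0), coef = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(list(terms = terms,
                 intercepts = cf[seq_along(envs)],
                 criterion = criterion, criterion_trace = trace,
                 resid_var = rss / (n - qx$rank),
                 environments = envs),
            class = "GrowthGeneticModel")
}

#' Design columns of a growth genetic model on arbitrary samples
#'
#' Evaluates each model term (marker main effect or marker-by-environment
#' interaction) on a set of (segregant, environment) rows; used to carry the
#' growth-model terms into the mediation network as covariates.
#'
#' @param model \code{GrowthGeneticModel}.
#' @param genotypes \code{GenotypeMatrix}.
#' @param segregant Segregant ids per row.
#' @param env Environment per row.
#' @param exclude Optional integer index of a term to leave out.
#' @return Numeric matrix with one column per (remaining) term.
#' @export
model_term_matrix <- function(model, genotypes, segregant, env,
                              exclude = NULL) {
  terms <- model$terms
  keep <- setdiff(seq_len(nrow(terms)), exclude)
  if (length(keep) == 0) {
    return(matrix(numeric(0), nrow = length(segregant), ncol = 0))
  }
  cols <- vapply(keep, function(i) {
    g <- genotypes$alleles[segregant, terms$marker[i]]
    if (identical(terms$env[i], "all")) g else g * (env == terms$env[i])
  }, numeric(length(segregant)))
  cols <- matrix(cols, nrow = length(segregant))
  colnames(cols) <- paste0(terms$marker[keep], ":", terms$env[keep])
  cols
}

#' Per-environment variance explained by a growth genetic model
#'
#' For each environment, returns 1 - SS_resid / SS_total of the model's
#' fitted values within that environment. Environments with zero growth
#' variance are reported as NA.
#'
#' @param model \code{GrowthGeneticModel}.
#' @param growth Segregant x environment growth matrix.
#' @param genotypes \code{GenotypeMatrix}.
#' @return Named numeric vector of R-squared per environment.
#' @export
variance_explained <- function(model, growth, genotypes) {
  envs <- model$environments
  out <- stats::setNames(rep(NA_real_, length(envs)), envs)
  segs <- rownames(growth)
  for (ev in envs) {
    y <- growth[, ev]
    sst <- sum((y - mean(y))^2)
    if (sst < 1e-12) next
    tm <- model_term_matrix(model, genotypes, segs, rep(ev, length(segs)))
    fitted <- rep(model$intercepts[[ev]], length(y))
    if (ncol(tm) > 0) fitted <- fitted + as.vector(tm %*% model$terms$coef)
    out[ev] <- 1 - sum((y - fitted)^2) / sst
  }
  out
}
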