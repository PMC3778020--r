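#' Stack one gene's expression across environments
#'
#' Builds the long-format table used by the joint environment model and the
#' mediation network: one row per profiled (segregant, environment) pair with
#' non-missing expression, carrying the segregant's growth rate and its
#' allele at a marker of interest.
#'
#' @param phenotypes \code{MultiEnvPhenotypes}.
#' @param gene Gene id.
#' @param genotypes \code{GenotypeMatrix}.
#' @param marker Marker id.
#' @return data.frame: segregant, env, expression, genotype, growth.
#' @export
stack_expression <- function(phenotypes, gene, genotypes, marker) {
  stopifnot(inherits(phenotypes, "MultiEnvPhenotypes"))
  envs <- phenotypes$environments
  segs <- rownames(phenotypes$growth)
  g <- genotypes$alleles[, marker]
  pieces <- lapply(envs, function(ev) {
    x <- phenotypes$expression[, gene, ev]
    keep <- which(!is.na(x))
    list(segregant = segs[keep], env = rep(ev, length(keep)),
         expression = unname(x[keep]), genotype = unname(g[keep]),
         growth = unname(phenotypes$growth[keep, ev]))
  })
  out <- lapply(stats::setNames(nm = names(pieces[[1]])), function(f) {
    unlist(lapply(pieces, `[[`, f), use.names = FALSE)
  })
  structure(out, class = "data.frame", row.names = seq_along(out$env))
}

#' Joint multi-environment model of a gene's expression at a marker
#'
#' Fits expression ~ environment intercepts + beta_shared * genotype +
#' per-environment genotype-by-environment deviations, on the stacked
#' profiled samples. With sum-to-zero contrasts (default) the deviations sum
#' to zero across environments, so beta_shared is the across-environment mean
#' genetic effect and "persistent in direction and amplitude" is the literal
#' null of all deviations being zero. Tests beta_shared = 0 and each
#' deviation = 0 (two-sided t).
#'
#' An optional kinship matrix is expanded block-wise over the stack (the same
#' segregant profiled in two environments is correlated through the genetic
#' variance component) and the model is fitted by REML-based generalized
#' least squares.
#'
#' @param expression Stacked expression vector.
#' @param genotype Stacked allele codes (0/1).
#' @param env Stacked environment labels.
#' @param kinship Optional segregant-level \code{KinshipMatrix}; requires
#'   \code{segregant} ids.
#' @param segregant Segregant id per stacked row (only used with kinship).
#' @param contrast "sum" (sum-to-zero deviations, default) or "reference",
#'   for the all-interactions parameterization.
#' @param interaction "all" (one deviation per environment, default) or
#'   "single" (a shared main effect plus the interaction term of one
#'   particular environment, \code{env_of_interest}; the parameterization
#'   used for persistent/dependent classification, where the shared effect
#'   is then estimated from the remaining environments).
#' @param env_of_interest Environment of the single interaction term.
#' @return A \code{GxeFit}: list with \code{shared} (beta, se, p),
#'   \code{interactions} (data.frame env, beta, se, p), \code{intercepts},
#'   \code{n}, \code{df}.
#' @export
fit_joint_env_model <- function(expression, genotype, env, kinship = NULL,
                                segregant = NULL,
                                contrast = c("sum", "reference"),
                                interaction = c("all", "single"),
                                env_of_interest = NULL) {
  contrast <- match.arg(contrast)
  interaction <- match.arg(interaction)
  env <- as.character(env)
  envs <- sort(unique(env))
  ne <- length(envs)
  if (ne < 2) stop("decomposition undefined with a single environment")
  counts <- table(env)
  if (any(counts < 3)) stop("need >= 3 profiled samples per environment")
  n <- length(expression)
  ei <- match(env, envs)
  Xenv <- matrix(0, n, ne, dimnames = list(NULL, envs))
  Xenv[cbind(seq_len(n), ei)] <- 1
  if (interaction == "single") {
    if (is.null(env_of_interest) || !env_of_interest %in% envs) {
      stop("env_of_interest must name one of the environments")
    }
    Xint <- matrix(genotype * (env == env_of_interest), ncol = 1,
                   dimnames = list(NULL, paste0("gxe", env_of_interest)))
    C <- matrix(1, 1, 1)
  } else if (contrast == "sum") {
    C <- stats::contr.sum(ne)            # ne x (ne-1)
    Xint <- genotype * Xenv %*% C
    colnames(Xint) <- paste0("gxe", seq_len(ne - 1))
  } else {
    C <- stats::contr.treatment(ne)
    Xint <- genotype * Xenv %*% C
    colnames(Xint) <- paste0("gxe", envs[-1])
  }
  X <- cbind(Xenv, g = genotype, Xint)

  if (!is.null(kinship)) {
    if (is.null(segregant)) stop("segregant ids required with kinship")
    Ks <- unclass(kinship)[segregant, segregant, drop = FALSE]
    nf <- fit_null_lmm(expression, structure(Ks, class = c("KinshipMatrix", "matrix")),
                       X = X)
    sw <- 1 / sqrt(nf$eig$values + nf$delta)
    yt <- sw * crossprod(nf$eig$vectors, expression)
    Xt <- sw * crossprod(nf$eig$vectors, X)
  } else {
    yt <- expression
    Xt <- X
  }
  qx <- qr(Xt)
  cf <- qr.coef(qx, yt)
  res <- qr.resid(qx, yt)
  dfree <- n - qx$rank
  s2 <- sum(res^2) / dfree
  R <- qr.R(qx)
  piv <- qx$pivot[seq_len(qx$rank)]
  XtXinv <- matrix(NA_real_, ncol(X), ncol(X),
                   dimnames = list(colnames(X), colnames(X)))
  XtXinv[piv, piv] <- chol2inv(R[seq_len(qx$rank), seq_len(qx$rank), drop = FALSE])
  V <- s2 * XtXinv
  tp <- function(b, v) {
    b <- unname(b); se <- sqrt(unname(v))
    t <- b / se
    c(beta = b, se = se, p = 2 * stats::pt(-abs(t), dfree))
  }
  shared <- tp(cf["g"], V["g", "g"])
  int_cols <- colnames(Xint)
  if (interaction == "single") {
    x <- tp(cf[int_cols], V[int_cols, int_cols])
    inter <- data.frame(env = env_of_interest, beta = x[["beta"]],
                        se = x[["se"]], p = x[["p"]], stringsAsFactors = FALSE)
  } else {
    # per-environment deviations: rows of the contrast matrix map coefficient
    # space back to environment space (last env = negative sum under contr.sum)
    inter <- do.call(rbind, lapply(seq_len(ne), function(e) {
      if (contrast == "reference" && e == 1) {
        return(data.frame(env = envs[e], beta = 0, se = 0, p = 1,
                          stringsAsFactors = FALSE))
      }
      cvec <- C[e, ]
      b <- sum(cvec * cf[int_cols])
      v <- as.numeric(t(cvec) %*% V[int_cols, int_cols, drop = FALSE] %*% cvec)
      x <- tp(b, v)
      data.frame(env = envs[e], beta = x[["beta"]], se = x[["se"]],
                 p = x[["p"]], stringsAsFactors = FALSE)
    }))
  }
  structure(list(shared = list(beta = shared[["beta"]], se = shared[["se"]],
                               p = shared[["p"]]),
                 interactions = inter,
                 intercepts = cf[envs], n = n, df = dfree,
                 contrast = contrast, interaction = interaction),
            class = "GxeFit")
}

#' Classify eQTLs as persistent, environment-dependent, both or none
#'
#' Shared-term p-values are pooled across genes into one q-value family and
#' interaction-term p-values into another (pooled across genes and
#' environments). A gene-marker pair is persistent-only if the shared q-value
#' is below the threshold and no interaction q-value is; dependent-only in
#' the reverse case; both / none accordingly.
#'
#' @param fits Named list of \code{GxeFit} objects (names = gene ids).
#' @param fdr Threshold applied to both families (default 0.05).
#' @return data.frame: gene, p_shared, q_shared, min_p_int, min_q_int, label.
#' @export
classify_eqtls <- function(fits, fdr = 0.05) {
  if (length(fits) == 0) stop("no fits supplied")
  if (is.null(names(fits))) stop("fits must be named by gene id")
  p_shared <- vapply(fits, function(f) f$shared$p, 0)
  p_int <- lapply(fits, function(f) f$interactions$p)
  if (anyNA(p_shared) || anyNA(unlist(p_int))) stop("missing p-values in fits")
  q_shared <- storey_qvalues(p_shared)$qvalues
  p_int_all <- unlist(p_int, use.names = FALSE)
  q_int_all <- storey_qvalues(p_int_all)$qvalues
  idx <- rep(seq_along(fits), vapply(p_int, length, 0L))
  min_q_int <- vapply(seq_along(fits), function(i) min(q_int_all[idx == i]), 0)
  min_p_int <- vapply(p_int, min, 0)
  pers <- q_shared < fdr
  dep <- min_q_int < fdr
  label <- ifelse(pers & dep, "both",
                  ifelse(pers, "persistent-only",
                         ifelse(dep, "dependent-only", "none")))
  data.frame(gene = names(fits), p_shared = p_shared, q_shared = q_shared,
             min_p_int = min_p_int, min_q_int = min_q_int, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify all genes at a marker across environments
#'
#' For every gene and every requested environment, fits the shared-plus-
#' single-interaction model at the marker and labels each (gene,
#' environment) pair. Shared-term p-values are pooled into one q-value
#' family and interaction-term p-values into another, both across genes and
#' environments.
#'
#' @param phenotypes \code{MultiEnvPhenotypes}.
#' @param genotypes \code{GenotypeMatrix}.
#' @param marker Marker id.
#' @param envs Environments to classify at (default: all profiled).
#' @param fdr Threshold for both families (default 0.05).
#' @param genes Genes to classify (default: all).
#' @param downsample Downsample the stack to single-environment size first.
#' @param seed Seed for downsampling.
#' @return data.frame: gene, marker, env, p_shared, q_shared, p_int, q_int,
#'   label.
#' @export
classify_marker <- function(phenotypes, genotypes, marker, envs = NULL,
                            fdr = 0.05, genes = NULL, downsample = FALSE,
                            seed = 1L) {
  if (is.null(envs)) envs <- phenotypes$environments
  if (is.null(genes)) genes <- dimnames(phenotypes$expression)[[2]]
  per_gene <- lapply(genes, function(gn) {
    st <- stack_expression(phenotypes, gn, genotypes, marker)
    if (downsample) st <- downsample_for_power(st, seed = seed)
    vapply(envs, function(ev) {
      fit <- fit_joint_env_model(st$expression, st$genotype, st$env,
                                 interaction = "single",
                                 env_of_interest = ev)
      c(fit$shared$p, fit$interactions$p[1])
    }, numeric(2))
  })
  rows <- data.frame(gene = rep(genes, each = length(envs)),
                     marker = marker,
                     env = rep(envs, times = length(genes)),
                     p_shared = unlist(lapply(per_gene, function(m) m[1, ])),
                     p_int = unlist(lapply(per_gene, function(m) m[2, ])),
                     stringsAsFactors = FALSE)
  rows$q_shared <- storey_qvalues(rows$p_shared)$qvalues
  rows$q_int <- storey_qvalues(rows$p_int)$qvalues
  pers <- rows$q_shared < fdr
  dep <- rows$q_int < fdr
  rows$label <- ifelse(pers & dep, "both",
                       ifelse(pers, "persistent-only",
                              ifelse(dep, "dependent-only", "none")))
  rows
}

#' Downsample a stacked dataset to single-environment size
#'
#' Draws, uniformly and without replacement across the whole stack, exactly
#' the ceiling of the mean per-environment sample count. Used to compare
#' persistent vs environment-dependent detection at matched statistical
#' power.
#'
#' @param stack data.frame with an \code{env} column (e.g. from
#'   \code{\link{stack_expression}}).
#' @param seed Integer seed.
#' @param target Optional explicit target size.
#' @export
downsample_for_power <- function(stack, seed = 1L, target = NULL) {
  stopifnot(is.data.frame(stack), "env" %in% names(stack))
  if (is.null(target)) target <- ceiling(mean(table(stack$env)))
  if (target > nrow(stack)) stop("downsampling target exceeds available rows")
  if (target == nrow(stack)) return(stack)
  set.seed(seed)
  stack[sort(sample.int(nrow(stack), target)), , drop = FALSE]
}
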