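#' Estimate selection coefficients from a pooled deletion assay
#'
#' Per gene and environment, the selection coefficient s is the least-squares
#' slope of log2 abundance on generation count, with replicates as
#' independent observations. The residual variance and degrees of freedom are
#' retained for empirical-Bayes moderation.
#'
#' @param assay Long data.frame with columns gene, environment, generation,
#'   replicate, log2_abundance (as written by
#'   \code{\link{simulate_deletion_assay}}).
#' @return data.frame: gene, environment, s, se, t_ordinary, df, s2
#'   (residual variance), c2 (unscaled slope variance 1/Sxx).
#' @export
estimate_selection_coefficients <- function(assay) {
  req <- c("gene", "environment", "generation", "log2_abundance")
  stopifnot(all(req %in% names(assay)))
  assay <- assay[!is.na(assay$log2_abundance), , drop = FALSE]
  key <- interaction(assay$gene, assay$environment, drop = TRUE, sep = "\r")
  parts <- split(assay, key)
  rows <- lapply(parts, function(d) {
    if (nrow(d) < 3 || length(unique(d$generation)) < 2) return(NULL)
    x <- d$generation - mean(d$generation)
    sxx <- sum(x^2)
    slope <- sum(x * d$log2_abundance) / sxx
    fitted <- mean(d$log2_abundance) + slope * x
    rss <- sum((d$log2_abundance - fitted)^2)
    df <- nrow(d) - 2L
    s2 <- rss / df
    se <- sqrt(s2 / sxx)
    data.frame(gene = d$gene[1], environment = d$environment[1], s = slope,
               se = se, t_ordinary = slope / se, df = df, s2 = s2,
               c2 = 1 / sxx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$environment, out$gene), , drop = FALSE]
}

#' Moderated t statistics for selection coefficients
#'
#' Empirical-Bayes variance shrinkage: a scaled-F prior (d0, s0^2) is fitted
#' to the per-gene residual variances and each gene's variance is replaced by
#' the posterior mean s2_tilde = (d0 s0^2 + df s2) / (d0 + df). The moderated
#' t is s / (sqrt(s2_tilde) * c) with d0 + df degrees of freedom. The prior
#' is estimated with \code{limma::squeezeVar}; d0 and s0^2 can be fixed
#' explicitly (d0 = 0 reproduces the ordinary t, d0 = Inf the fully pooled
#' variance).
#'
#' @param fit data.frame from \code{\link{estimate_selection_coefficients}}.
#' @param d0,s02 Optional fixed prior degrees of freedom and variance.
#' @return \code{fit} with columns t_moderated, df_total, p, s2_post, and
#'   attributes \code{d0}, \code{s02}.
#' @export
moderated_t <- function(fit, d0 = NULL, s02 = NULL) {
  stopifnot(all(c("s", "s2", "df", "c2") %in% names(fit)))
  if (any(fit$s2 < 0)) stop("negative residual variances")
  if (is.null(d0) || is.null(s02)) {
    if (nrow(fit) < 10) stop("need >= 10 genes to estimate the variance prior")
    sq <- limma::squeezeVar(fit$s2, fit$df)
    if (is.null(d0)) d0 <- sq$df.prior
    if (is.null(s02)) s02 <- sq$var.prior
  }
  s2_post <- if (is.infinite(d0)) rep(s02, nrow(fit))
             else if (d0 == 0) fit$s2
             else (d0 * s02 + fit$df * fit$s2) / (d0 + fit$df)
  fit$s2_post <- s2_post
  fit$t_moderated <- fit$s / sqrt(s2_post * fit$c2)
  fit$df_total <- fit$df + d0
  fit$p <- 2 * stats::pt(-abs(fit$t_moderated), fit$df_total)
  attr(fit, "d0") <- d0
  attr(fit, "s02") <- s02
  fit
}

#' Call beneficial / detrimental deletion effects
#'
#' A deletion is called beneficial if s > s_cut with q < fdr, detrimental if
#' s < -s_cut with q < fdr, and none otherwise. Q-values are computed per
#' environment with \code{\link{storey_qvalues}} if absent.
#'
#' @param fit data.frame from \code{\link{moderated_t}} (needs p).
#' @param s_cut Effect-size cutoff on |s| (default 0.05).
#' @param fdr q-value threshold (default 0.05).
#' @return \code{fit} with columns q and call.
#' @export
call_deletion_effects <- function(fit, s_cut = 0.05, fdr = 0.05) {
  stopifnot("p" %in% names(fit))
  if (!"q" %in% names(fit)) {
    fit$q <- NA_real_
    for (ev in unique(fit$environment)) {
      i <- fit$environment == ev
      fit$q[i] <- storey_qvalues(fit$p[i])$qvalues
    }
  }
  fit$call <- ifelse(fit$q < fdr & fit$s > s_cut, "beneficial",
                     ifelse(fit$q < fdr & fit$s < -s_cut, "detrimental",
                            "none"))
  fit
}
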