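#' Allele-sharing (IBS) kinship matrix
#'
#' Entry (i, j) is the fraction of markers at which segregants i and j carry
#' the same allele; the diagonal is 1. This is the standard genetic-similarity
#' construction for a biparental cross and serves as the random-effect
#' covariance correcting for genotype structure in the mixed model.
#'
#' @param genotypes \code{GenotypeMatrix} or a 0/1 segregant x marker matrix.
#' @param method "ibs" (default) or "identity" (no correction).
#' @return A \code{KinshipMatrix}: symmetric segregant x segregant matrix with
#'   attribute \code{construction}.
#' @export
compute_kinship <- function(genotypes, method = c("ibs", "identity")) {
  method <- match.arg(method)
  A <- if (inherits(genotypes, "GenotypeMatrix")) genotypes$alleles else genotypes
  if (is.null(dim(A)) || ncol(A) == 0) stop("zero markers: cannot compute kinship")
  if (method == "identity") {
    K <- diag(nrow(A))
    dimnames(K) <- list(rownames(A), rownames(A))
  } else {
    # share fraction = 1 - mean |a_i - a_j|; for 0/1 codes this is
    # (AA' + (1-A)(1-A)') / m
    A <- as.matrix(A)
    m <- ncol(A)
    K <- (tcrossprod(A) + tcrossprod(1 - A)) / m
    K <- (K + t(K)) / 2
  }
  structure(K, class = c("KinshipMatrix", "matrix"), construction = method)
}

# Spectral pieces reused across REML evaluations: K = U diag(d) U'.
kinship_eigen <- function(K, ridge = 1e-8) {
  K <- unclass(K)
  e <- eigen(K + diag(ridge, nrow(K)), symmetric = TRUE)
  if (min(e$values) < -1e-6) {
    stop("kinship matrix not positive semidefinite after ridge")
  }
  e$values <- pmax(e$values, 0)
  e
}

#' Fit the null linear mixed model by REML
#'
#' Variance-component model y = X b + u + e with u ~ N(0, sg2 K) and
#' e ~ N(0, se2 I). The restricted likelihood is profiled down to the
#' variance ratio delta = se2 / sg2 using the spectral decomposition of K and
#' maximized by one-dimensional optimization of log(delta) over [-10, 10].
#'
#' @param y Numeric trait vector (missing entries dropped together with the
#'   matching kinship rows).
#' @param kinship \code{KinshipMatrix}.
#' @param X Fixed-effect design matrix (default: intercept).
#' @param eig Optional precomputed \code{kinship_eigen} result for the
#'   non-missing subset.
#' @return list with \code{sigma_g2}, \code{sigma_e2}, \code{delta},
#'   \code{loglik}, \code{boundary} flag, the subset \code{keep}, and the
#'   eigen decomposition used.
#' @export
fit_null_lmm <- function(y, kinship, X = NULL, eig = NULL) {
  keep <- which(!is.na(y))
  y <- y[keep]
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1) else X <- as.matrix(X)[keep, , drop = FALSE]
  K <- unclass(kinship)[keep, keep, drop = FALSE]
  if (n != nrow(K)) stop("trait length does not match kinship dimension")
  if (stats::var(y) < 1e-12) {
    return(list(sigma_g2 = 0, sigma_e2 = 0, delta = NA_real_, loglik = NA_real_,
                boundary = TRUE, degenerate = TRUE, keep = keep, eig = NULL))
  }
  if (is.null(eig)) eig <- kinship_eigen(K)
  # work on the unit-variance scale so the delta estimate (and hence scan
  # p-values) is exactly invariant to affine rescaling of the trait
  y_scale <- stats::sd(y)
  y <- y / y_scale
  U <- eig$vectors; d <- eig$values
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- qr(X)$rank
  ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus

  reml <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    XtW <- Xt * w
    XWX <- crossprod(Xt, XtW)
    beta <- solve(XWX, crossprod(XtW, yt))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    sg2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * sg2) + (n - p) + sum(log(d + delta)) +
              determinant(XWX, logarithm = TRUE)$modulus - ldXX)
  }
  opt <- stats::optimize(reml, interval = c(-10, 10), maximum = TRUE, tol = 1e-8)
  logdelta <- opt$maximum
  delta <- exp(logdelta)
  w <- 1 / (d + delta)
  XtW <- Xt * w
  XWX <- crossprod(Xt, XtW)
  beta <- solve(XWX, crossprod(XtW, yt))
  rss <- sum(w * (yt - Xt %*% beta)^2)
  sg2 <- rss / (n - p) * y_scale^2
  list(sigma_g2 = sg2, sigma_e2 = delta * sg2, delta = delta,
       loglik = opt$objective - (n - p) * log(y_scale),
       boundary = logdelta < -9.5 || logdelta > 9.5,
       degenerate = FALSE, keep = keep, eig = eig)
}

#' Kinship-corrected single-marker association scan
#'
#' For each marker, the trait is regressed on the allele code by generalized
#' least squares with covariance sg2 K + se2 I fixed at the null-model REML
#' estimates (the once-per-trait approximation; set \code{exact = TRUE} to
#' re-optimize the variance ratio per marker). The residual scale is
#' re-estimated within each marker fit, so with an identity kinship the scan
#' reduces exactly to ordinary least squares. Two-sided p-values use a t
#' reference with n - rank(design) degrees of freedom. Monomorphic markers
#' are flagged and given beta = 0, p = 1.
#'
#' @param y Trait vector over segregants (NAs dropped).
#' @param genotypes \code{GenotypeMatrix}.
#' @param kinship \code{KinshipMatrix} (default: IBS from the genotypes).
#' @param covariates Optional covariate matrix (columns added to intercept).
#' @param null_fit Optional result of \code{fit_null_lmm} on the same subset.
#' @param exact Re-fit the variance ratio per marker (slow; default FALSE).
#' @return data.frame: marker, chrom, pos, beta, se, stat, df, p, q plus
#'   attributes \code{sigma_g2}, \code{sigma_e2}, \code{pi0}.
#' @export
single_marker_scan <- function(y, genotypes, kinship = NULL, covariates = NULL,
                               null_fit = NULL, exact = FALSE) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  if (is.null(kinship)) kinship <- compute_kinship(genotypes)
  if (is.null(null_fit)) {
    X0full <- cbind(rep(1, length(y)),
                    if (!is.null(covariates)) as.matrix(covariates))
    null_fit <- fit_null_lmm(y, kinship, X = X0full)
  }
  keep <- null_fit$keep
  yk <- y[keep]
  n <- length(yk)
  G <- genotypes$alleles[keep, , drop = FALSE]
  map <- genotypes$map
  out <- data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                    beta = 0, se = NA_real_, stat = NA_real_,
                    df = NA_real_, p = 1, monomorphic = FALSE,
                    stringsAsFactors = FALSE)
  if (isTRUE(null_fit$degenerate)) {
    out$monomorphic <- apply(G, 2, function(x) length(unique(x)) < 2)
    out$q <- storey_qvalues(out$p)$qvalues
    attr(out, "sigma_g2") <- 0; attr(out, "sigma_e2") <- 0
    return(out)
  }
  X0 <- cbind(`(Intercept)` = rep(1, n),
              if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE])
  scan_fixed <- function(eig, delta) {
    U <- eig$vectors; d <- eig$values
    sw <- 1 / sqrt(d + delta)
    yt <- sw * crossprod(U, yk)
    X0t <- sw * crossprod(U, X0)
    Gt <- sw * crossprod(U, G)
    q0 <- qr(X0t)
    ry <- qr.resid(q0, yt)
    rG <- qr.resid(q0, Gt)
    sxx <- colSums(rG^2)
    sxy <- as.vector(crossprod(rG, ry))
    syy <- sum(ry^2)
    mono <- sxx < 1e-10
    beta <- ifelse(mono, 0, sxy / sxx)
    dfree <- n - q0$rank - 1
    rss <- pmax(syy - beta^2 * sxx, 0)
    s2 <- rss / dfree
    se <- ifelse(mono, NA_real_, sqrt(s2 / sxx))
    tstat <- ifelse(mono, NA_real_, beta / se)
    p <- ifelse(mono, 1, 2 * stats::pt(-abs(tstat), dfree))
    list(beta = beta, se = se, stat = tstat, df = dfree, p = p, mono = mono)
  }
  if (!exact) {
    r <- scan_fixed(null_fit$eig, null_fit$delta)
  } else {
    # re-optimize delta per marker: refit the null with the marker in X
    r <- list(beta = numeric(ncol(G)), se = numeric(ncol(G)),
              stat = numeric(ncol(G)), df = numeric(ncol(G)),
              p = numeric(ncol(G)), mono = logical(ncol(G)))
    for (j in seq_len(ncol(G))) {
      x <- G[, j]
      if (length(unique(x)) < 2) {
        r$beta[j] <- 0; r$se[j] <- NA; r$stat[j] <- NA
        r$p[j] <- 1; r$mono[j] <- TRUE; r$df[j] <- NA
        next
      }
      fitj <- fit_null_lmm(yk, unclass(kinship)[keep, keep],
                           X = cbind(X0, x), eig = null_fit$eig)
      s <- scan_fixed(fitj$eig, fitj$delta)
      r$beta[j] <- s$beta[j]; r$se[j] <- s$se[j]; r$stat[j] <- s$stat[j]
      r$df[j] <- s$df; r$p[j] <- s$p[j]; r$mono[j] <- FALSE
    }
  }
  out$beta <- r$beta; out$se <- r$se; out$stat <- r$stat
  out$df <- r$df; out$p <- r$p; out$monomorphic <- r$mono
  sq <- storey_qvalues(out$p)
  out$q <- sq$qvalues
  attr(out, "sigma_g2") <- null_fit$sigma_g2
  attr(out, "sigma_e2") <- null_fit$sigma_e2
  attr(out, "pi0") <- sq$pi0
  out
}

#' Group significant markers into QTL regions
#'
#' Markers below the q-value threshold are grouped greedily: walking down the
#' significance order, a marker joins an existing region if it lies on the
#' same chromosome within \code{window} bp of the region's peak; otherwise it
#' seeds a new region. Peaks are the minimum-p member (ties broken by
#' leftmost position), and the region span is the range of member positions.
#'
#' @param assoc data.frame from \code{single_marker_scan} (needs q).
#' @param fdr q-value threshold (default 0.05).
#' @param window Grouping window in bp (default 50000).
#' @return data.frame of regions: chrom, start, end, peak_marker, peak_p,
#'   n_markers. Empty (0 rows) when nothing is significant.
#' @export
call_qtl_regions <- function(assoc, fdr = 0.05, window = 50000) {
  stopifnot(all(c("marker", "chrom", "pos", "p", "q") %in% names(assoc)))
  sig <- assoc[assoc$q < fdr & !is.na(assoc$q), , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_marker = character(0),
                      peak_p = numeric(0), n_markers = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  sig <- sig[order(sig$p, sig$chrom, sig$pos, sig$marker), , drop = FALSE]
  regions <- list()
  for (i in seq_len(nrow(sig))) {
    placed <- FALSE
    for (k in seq_along(regions)) {
      rg <- regions[[k]]
      if (identical(rg$chrom, sig$chrom[i]) &&
          abs(sig$pos[i] - rg$peak_pos) <= window) {
        rg$start <- min(rg$start, sig$pos[i])
        rg$end <- max(rg$end, sig$pos[i])
        rg$n_markers <- rg$n_markers + 1L
        regions[[k]] <- rg
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      regions[[length(regions) + 1]] <-
        list(chrom = sig$chrom[i], start = sig$pos[i], end = sig$pos[i],
             peak_marker = sig$marker[i], peak_pos = sig$pos[i],
             peak_p = sig$p[i], n_markers = 1L)
    }
  }
  out <- do.call(rbind, lapply(regions, function(rg) {
    data.frame(chrom = rg$chrom, start = rg$start, end = rg$end,
               peak_marker = rg$peak_marker, peak_p = rg$peak_p,
               n_markers = rg$n_markers, stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}
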