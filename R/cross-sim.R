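#' Describe a biparental cross design
#'
#' A cross design fixes the dimensions of the simulated segregant panel: the
#' number of haploid segregants, the chromosome layout, the marker density and
#' the per-interval recombination probability used by the genotype simulator.
#'
#' @param n_segregants Number of haploid segregants (>= 2).
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param markers_per_chromosome Number of equally spaced markers placed on
#'   each chromosome.
#' @param recomb_prob Probability of recombination between adjacent markers,
#'   in [0, 0.5]. A constant flip probability stands in for a genetic map.
#' @param seed Integer seed controlling the genotype draw.
#' @return An object of class \code{CrossDesign}.
#' @export
cross_design <- function(n_segregants = 200L,
                         chromosomes = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6,
                                         chr4 = 1e6, chr5 = 1e6),
                         markers_per_chromosome = 100L,
                         recomb_prob = 0.02,
                         seed = 1L) {
  if (n_segregants < 2) stop("invalid design: n_segregants must be >= 2")
  if (markers_per_chromosome < 1) stop("invalid design: need >= 1 marker per chromosome")
  if (recomb_prob < 0 || recomb_prob > 0.5) {
    stop("invalid design: recomb_prob must lie in [0, 0.5]")
  }
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes)))) {
    stop("invalid design: chromosomes must be a named vector of lengths")
  }
  if (any(chromosomes <= 0)) stop("invalid design: chromosome lengths must be positive")
  structure(list(n_segregants = as.integer(n_segregants),
                 chromosomes = chromosomes,
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 recomb_prob = recomb_prob,
                 seed = as.integer(seed)),
            class = "CrossDesign")
}

#' Simulate segregant genotypes
#'
#' Each segregant's chromosome is a two-state Markov chain over markers:
#' the first marker is Bernoulli(0.5) and each subsequent marker flips allele
#' with probability \code{recomb_prob}. Allele 0 is the laboratory strain (S)
#' allele, 1 the clinical isolate (Y) allele. Chromosomes are independent.
#'
#' @param design A \code{CrossDesign}.
#' @return A \code{GenotypeMatrix}: list with \code{alleles} (segregant x
#'   marker 0/1 matrix) and \code{map} (data.frame with columns
#'   \code{marker}, \code{chrom}, \code{pos}; positions 1-based).
#' @export
simulate_genotypes <- function(design) {
  stopifnot(inherits(design, "CrossDesign"))
  set.seed(design$seed)
  n <- design$n_segregants
  m_per <- design$markers_per_chromosome
  chroms <- names(design$chromosomes)
  blocks <- vector("list", length(chroms))
  maps <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    len <- design$chromosomes[[ci]]
    pos <- unique(as.integer(round(seq(1, len, length.out = m_per))))
    # equal spacing can collide on short chromosomes; positions must increase
    if (length(pos) < m_per) {
      pos <- seq_len(m_per)
      if (m_per > len) stop("invalid design: more markers than bp on ", chroms[ci])
    }
    first <- matrix(rbinom(n, 1L, 0.5), nrow = n, ncol = 1)
    g <- matrix(0L, nrow = n, ncol = m_per)
    g[, 1] <- first
    if (m_per > 1) {
      flips <- matrix(rbinom(n * (m_per - 1), 1L, design$recomb_prob),
                      nrow = n, ncol = m_per - 1)
      for (j in 2:m_per) g[, j] <- bitwXor(g[, j - 1], flips[, j - 1])
    }
    blocks[[ci]] <- g
    maps[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                             stringsAsFactors = FALSE)
  }
  alleles <- do.call(cbind, blocks)
  map <- do.call(rbind, maps)
  map$marker <- sprintf("m%04d", seq_len(nrow(map)))
  map <- map[, c("marker", "chrom", "pos")]
  rownames(map) <- NULL
  dimnames(alleles) <- list(sprintf("seg%03d", seq_len(n)), map$marker)
  structure(list(alleles = alleles, map = map), class = "GenotypeMatrix")
}

#' Trait (growth) genetic architecture
#'
#' @param qtl_terms data.frame with columns \code{marker}, \code{env}
#'   (an environment name, or "all" for a persistent effect) and \code{effect}
#'   (growth units per Y allele). Sign-flip loci are encoded as two rows for
#'   the same marker with opposite signs.
#' @param residual_sd Growth-rate noise sd.
#' @param env_means Named numeric vector of per-environment baseline growth.
#' @export
trait_architecture <- function(qtl_terms, residual_sd = 0.3, env_means) {
  stopifnot(is.data.frame(qtl_terms),
            all(c("marker", "env", "effect") %in% names(qtl_terms)))
  if (any(!is.finite(qtl_terms$effect))) stop("effect sizes must be finite")
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  structure(list(qtl_terms = qtl_terms, residual_sd = residual_sd,
                 env_means = env_means),
            class = "TraitArchitecture")
}

#' Expression genetic architecture
#'
#' Gene roles follow the causal wiring of the study design: mediators carry a
#' persistent genotype effect and transmit it to growth with environment-
#' specific coefficients; dependent genes have an environment-specific
#' genotype effect and no growth linkage; consequence genes read out realized
#' growth; side-effect genes carry a persistent genotype effect with zero
#' growth linkage.
#'
#' @param n_genes Total number of genes simulated.
#' @param mediators data.frame(gene, marker, beta_t).
#' @param mediator_growth data.frame(gene, env, beta_g).
#' @param dependent_genes data.frame(gene, marker, env, effect).
#' @param consequence_genes data.frame(gene, env, coef).
#' @param side_effect_genes data.frame(gene, marker, effect).
#' @param expr_noise_sd Expression noise sd (log-like additive scale).
#' @export
expression_architecture <- function(n_genes,
                                    mediators = NULL,
                                    mediator_growth = NULL,
                                    dependent_genes = NULL,
                                    consequence_genes = NULL,
                                    side_effect_genes = NULL,
                                    expr_noise_sd = 0.3) {
  empty <- function(...) {
    cols <- c(...)
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  if (is.null(mediators)) mediators <- empty("gene", "marker", "beta_t")
  if (is.null(mediator_growth)) mediator_growth <- empty("gene", "env", "beta_g")
  if (is.null(dependent_genes)) dependent_genes <- empty("gene", "marker", "env", "effect")
  if (is.null(consequence_genes)) consequence_genes <- empty("gene", "env", "coef")
  if (is.null(side_effect_genes)) side_effect_genes <- empty("gene", "marker", "effect")
  roles <- list(mediator = unique(mediators$gene),
                dependent = unique(dependent_genes$gene),
                consequence = unique(consequence_genes$gene),
                side_effect = unique(side_effect_genes$gene))
  all_role_genes <- unlist(roles, use.names = FALSE)
  if (anyDuplicated(all_role_genes)) {
    stop("configuration error: gene roles must be disjoint sets")
  }
  if (nrow(mediators) > 0 && any(mediators$beta_t == 0)) {
    stop("configuration error: mediator beta_t must be non-zero")
  }
  if (expr_noise_sd < 0) stop("expr_noise_sd must be >= 0")
  structure(list(n_genes = as.integer(n_genes), mediators = mediators,
                 mediator_growth = mediator_growth,
                 dependent_genes = dependent_genes,
                 consequence_genes = consequence_genes,
                 side_effect_genes = side_effect_genes,
                 expr_noise_sd = expr_noise_sd),
            class = "ExpressionArchitecture")
}

#' Default synthetic architecture
#'
#' The default emulates the causal wiring used throughout the package's test
#' benchmark: three growth QTLs on distinct chromosomes — one with a
#' persistent direct effect in every environment, one environment-specific
#' and one sign-flip locus (beneficial in one environment, detrimental in
#' another), the latter two acting entirely through their mediator genes —
#' plus, per QTL, 5 mediator genes, 20 environment-dependent eQTL genes,
#' 20 side-effect genes and 20 growth-consequence genes.
#'
#' @param genotypes A \code{GenotypeMatrix} (markers are picked from its map).
#' @param environments Character vector of environment names.
#' @param n_genes Total gene count.
#' @return list with elements \code{trait} (TraitArchitecture), \code{expr}
#'   (ExpressionArchitecture) and \code{truth} (role labels per gene).
#' @export
default_architecture <- function(genotypes, environments, n_genes = 500L) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"), length(environments) >= 5)
  if (n_genes < 3 * 45 + 60) {
    stop("default architecture needs at least 195 genes for its role sets")
  }
  map <- genotypes$map
  chroms <- unique(map$chrom)
  pick_mid <- function(chr) {
    rows <- which(map$chrom == chr)
    map$marker[rows[ceiling(length(rows) / 2)]]
  }
  q1 <- pick_mid(chroms[1]); q2 <- pick_mid(chroms[2]); q3 <- pick_mid(chroms[3])
  e <- environments
  qtl_terms <- data.frame(marker = q1, env = e, effect = 0.5,
                          stringsAsFactors = FALSE)
  trait <- trait_architecture(qtl_terms, residual_sd = 0.8,
                              env_means = stats::setNames(rep(0, length(e)), e))

  genes <- sprintf("g%04d", seq_len(n_genes))
  idx <- 0L
  take <- function(k) { out <- genes[idx + seq_len(k)]; idx <<- idx + k; out }
  med <- list(); medg <- list(); dep <- list(); side <- list()
  qtls <- list(list(marker = q1, envs = e, signs = rep(1, length(e)), beta_g = 0.1),
               list(marker = q2, envs = e[2], signs = 1, beta_g = 0.25),
               list(marker = q3, envs = c(e[1], e[4]), signs = c(1, -1), beta_g = 0.25))
  for (qi in seq_along(qtls)) {
    q <- qtls[[qi]]
    mg <- take(5)
    med[[qi]] <- data.frame(gene = mg, marker = q$marker, beta_t = 1,
                            stringsAsFactors = FALSE)
    medg[[qi]] <- do.call(rbind, lapply(seq_along(q$envs), function(k) {
      data.frame(gene = mg, env = q$envs[k], beta_g = q$beta_g * q$signs[k],
                 stringsAsFactors = FALSE)
    }))
    dg <- take(20)
    dep[[qi]] <- data.frame(gene = dg, marker = q$marker,
                            env = rep(e[seq_len(5)], length.out = 20),
                            effect = 1, stringsAsFactors = FALSE)
    sg <- take(20)
    side[[qi]] <- data.frame(gene = sg, marker = q$marker, effect = 1,
                             stringsAsFactors = FALSE)
  }
  cons_genes <- take(60)
  cons <- do.call(rbind, lapply(e, function(ev) {
    data.frame(gene = cons_genes, env = ev, coef = 0.8, stringsAsFactors = FALSE)
  }))
  expr <- expression_architecture(
    n_genes = n_genes,
    mediators = do.call(rbind, med),
    mediator_growth = do.call(rbind, medg),
    dependent_genes = do.call(rbind, dep),
    consequence_genes = cons,
    side_effect_genes = do.call(rbind, side),
    expr_noise_sd = 0.3)
  role <- rep("none", n_genes); names(role) <- genes
  role[expr$mediators$gene] <- "mediator"
  role[unique(expr$dependent_genes$gene)] <- "dependent"
  role[cons_genes] <- "consequence"
  role[unique(expr$side_effect_genes$gene)] <- "side_effect"
  qtl_of <- rep(NA_character_, n_genes); names(qtl_of) <- genes
  for (qi in seq_along(qtls)) {
    qm <- qtls[[qi]]$marker
    qtl_of[med[[qi]]$gene] <- qm
    qtl_of[unique(dep[[qi]]$gene)] <- qm
    qtl_of[unique(side[[qi]]$gene)] <- qm
  }
  truth <- data.frame(gene = genes, role = unname(role),
                      marker = unname(qtl_of), stringsAsFactors = FALSE)
  list(trait = trait, expr = expr, truth = truth,
       qtl_markers = c(q1, q2, q3))
}

#' Simulate growth and expression phenotypes
#'
#' Generation follows the causal order: (1) mediator, side-effect and
#' dependent-gene expression from genotype plus noise; (2) growth from
#' environment baselines, direct QTL effects and mediator expression plus
#' noise; (3) consequence-gene expression from realized growth plus noise.
#'
#' @param genotypes \code{GenotypeMatrix}.
#' @param trait_arch \code{TraitArchitecture}.
#' @param expr_arch \code{ExpressionArchitecture}.
#' @param environments Character vector of environment names.
#' @param seed Integer seed.
#' @return A \code{MultiEnvPhenotypes}: list with \code{growth} (segregant x
#'   environment matrix), \code{expression} (segregant x gene x environment
#'   array), \code{mask} (segregant x environment logical; all TRUE until
#'   \code{\link{apply_checkered_design}}), and \code{truth} role labels.
#' @export
simulate_phenotypes <- function(genotypes, trait_arch, expr_arch,
                                environments, seed = 1L) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"),
            inherits(trait_arch, "TraitArchitecture"),
            inherits(expr_arch, "ExpressionArchitecture"))
  A <- genotypes$alleles
  n <- nrow(A)
  ne <- length(environments)
  genes <- sprintf("g%04d", seq_len(expr_arch$n_genes))
  arch_markers <- unique(c(trait_arch$qtl_terms$marker,
                           expr_arch$mediators$marker,
                           expr_arch$dependent_genes$marker,
                           expr_arch$side_effect_genes$marker))
  if (!all(arch_markers %in% colnames(A))) {
    stop("configuration error: architecture references unknown markers")
  }
  set.seed(seed)
  expr <- array(rnorm(n * length(genes) * ne, sd = expr_arch$expr_noise_sd),
                dim = c(n, length(genes), ne),
                dimnames = list(rownames(A), genes, environments))
  # (1) genotype-driven expression
  md <- expr_arch$mediators
  for (i in seq_len(nrow(md))) {
    expr[, md$gene[i], ] <- expr[, md$gene[i], ] + md$beta_t[i] * A[, md$marker[i]]
  }
  sd_ <- expr_arch$side_effect_genes
  for (i in seq_len(nrow(sd_))) {
    expr[, sd_$gene[i], ] <- expr[, sd_$gene[i], ] + sd_$effect[i] * A[, sd_$marker[i]]
  }
  dp <- expr_arch$dependent_genes
  for (i in seq_len(nrow(dp))) {
    expr[, dp$gene[i], dp$env[i]] <- expr[, dp$gene[i], dp$env[i]] +
      dp$effect[i] * A[, dp$marker[i]]
  }
  # (2) growth
  growth <- matrix(rnorm(n * ne, sd = trait_arch$residual_sd), n, ne,
                   dimnames = list(rownames(A), environments))
  for (ev in environments) {
    growth[, ev] <- growth[, ev] + trait_arch$env_means[[ev]]
  }
  qt <- trait_arch$qtl_terms
  for (i in seq_len(nrow(qt))) {
    envs <- if (identical(qt$env[i], "all")) environments else qt$env[i]
    for (ev in envs) growth[, ev] <- growth[, ev] + qt$effect[i] * A[, qt$marker[i]]
  }
  mg <- expr_arch$mediator_growth
  for (i in seq_len(nrow(mg))) {
    growth[, mg$env[i]] <- growth[, mg$env[i]] +
      mg$beta_g[i] * expr[, mg$gene[i], mg$env[i]]
  }
  # (3) consequence expression from realized growth
  cg <- expr_arch$consequence_genes
  for (i in seq_len(nrow(cg))) {
    expr[, cg$gene[i], cg$env[i]] <- expr[, cg$gene[i], cg$env[i]] +
      cg$coef[i] * growth[, cg$env[i]]
  }
  mask <- matrix(TRUE, n, ne, dimnames = list(rownames(A), environments))
  structure(list(growth = growth, expression = expr, mask = mask,
                 environments = environments),
            class = "MultiEnvPhenotypes")
}

#' Apply the checkered expression-profiling design
#'
#' In each environment an independent random subset of segregants is retained
#' for expression profiling; expression outside the subset is set missing.
#' Growth is untouched (it is measured for all segregants).
#'
#' @param phenotypes \code{MultiEnvPhenotypes}.
#' @param n_per_env Number of profiled segregants per environment.
#' @param seed Integer seed.
#' @export
apply_checkered_design <- function(phenotypes, n_per_env, seed = 1L) {
  stopifnot(inherits(phenotypes, "MultiEnvPhenotypes"))
  n <- nrow(phenotypes$growth)
  if (n_per_env > n) stop("design error: n_per_env exceeds number of segregants")
  set.seed(seed)
  for (ev in phenotypes$environments) {
    keep <- sort(sample.int(n, n_per_env))
    phenotypes$mask[, ev] <- FALSE
    phenotypes$mask[keep, ev] <- TRUE
    phenotypes$expression[!phenotypes$mask[, ev], , ev] <- NA_real_
  }
  phenotypes
}

#' Deletion-collection assay ground truth
#'
#' @param s_true gene x environment matrix of true selection coefficients
#'   (log2 relative abundance change per generation).
#' @param n_replicates Replicates per generation (default 3).
#' @param generations Generations assayed (default 0 and 5).
#' @param noise_sd Measurement noise sd on log2 abundance.
#' @export
deletion_truth <- function(s_true, n_replicates = 3L, generations = c(0, 5),
                           noise_sd = 0.05) {
  stopifnot(is.matrix(s_true), !is.null(rownames(s_true)),
            !is.null(colnames(s_true)))
  if (any(!is.finite(s_true))) stop("selection coefficients must be finite")
  if (any(generations < 0)) stop("generations must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(s_true = s_true, n_replicates = as.integer(n_replicates),
                 generations = generations, noise_sd = noise_sd),
            class = "DeletionTruth")
}

#' Default deletion truth derived from the expression architecture
#'
#' Mediator deletions have |s| = 0.1 in the environments where the mediator
#' drives growth, with sign opposite to the expression-growth effect
#' (knocking out a growth-promoting gene is detrimental). A random background
#' fraction of all other gene x environment pairs carries |s| = 0.1 with
#' random sign, emulating the genome-wide base rate of fitness-relevant
#' deletions.
#'
#' @param expr_arch \code{ExpressionArchitecture}.
#' @param environments Environment names.
#' @param background_rate Fraction of non-mediator gene x env pairs with a
#'   true fitness effect (default 0.05).
#' @param seed Integer seed.
#' @export
default_deletion_truth <- function(expr_arch, environments,
                                   background_rate = 0.05, seed = 1L) {
  genes <- sprintf("g%04d", seq_len(expr_arch$n_genes))
  s <- matrix(0, length(genes), length(environments),
              dimnames = list(genes, environments))
  mg <- expr_arch$mediator_growth
  for (i in seq_len(nrow(mg))) {
    s[mg$gene[i], mg$env[i]] <- -0.1 * sign(mg$beta_g[i])
  }
  set.seed(seed)
  free <- s == 0
  hit <- free & matrix(stats::runif(length(s)) < background_rate, nrow(s))
  s[hit] <- 0.1 * sample(c(-1, 1), sum(hit), replace = TRUE)
  deletion_truth(s)
}

#' Simulate the pooled deletion-collection assay
#'
#' log2 abundance of a deletion strain after g generations equals its
#' generation-0 abundance plus s_true * g, plus independent Gaussian
#' measurement noise per replicate.
#'
#' @param truth \code{DeletionTruth}.
#' @param seed Integer seed.
#' @return Long data.frame: gene, environment, generation, replicate,
#'   log2_abundance.
#' @export
simulate_deletion_assay <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "DeletionTruth"))
  set.seed(seed)
  genes <- rownames(truth$s_true)
  envs <- colnames(truth$s_true)
  grid <- expand.grid(gene = genes, environment = envs,
                      generation = truth$generations,
                      replicate = seq_len(truth$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- 10  # arbitrary common generation-0 log2 abundance
  s <- truth$s_true[cbind(grid$gene, grid$environment)]
  grid$log2_abundance <- base + s * grid$generation +
    stats::rnorm(nrow(grid), sd = truth$noise_sd)
  grid
}
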