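test_that("genotype simulation respects the recombination model", {
  # no recombination: each chromosome is a single parental block
  g0 <- simulate_genotypes(cross_design(
    n_segregants = 30, chromosomes = c(c1 = 1e5, c2 = 1e5),
    markers_per_chromosome = 10, recomb_prob = 0, seed = 4))
  for (chr in c("c1", "c2")) {
    block <- g0$alleles[, g0$map$marker[g0$map$chrom == chr]]
    expect_true(all(apply(block, 1, function(x) length(unique(x)) == 1)))
  }
  # free recombination: adjacent markers uncorrelated (Monte-Carlo)
  g5 <- simulate_genotypes(cross_design(
    n_segregants = 10000, chromosomes = c(c1 = 1e5),
    markers_per_chromosome = 10, recomb_prob = 0.5, seed = 5))
  for (j in 1:9) {
    r <- cor(g5$alleles[, j], g5$alleles[, j + 1])
    expect_lt(abs(r), 0.05)
  }
  # Mendelian segregation: Y-allele frequency within 5 s.e. of 0.5
  freqs <- colMeans(g5$alleles)
  expect_true(all(abs(freqs - 0.5) < 5 * sqrt(0.25 / 10000)))
})

test_that("genotype simulation is reproducible from the seed", {
  d <- cross_design(n_segregants = 20, chromosomes = c(c1 = 1e5),
                    markers_per_chromosome = 15, recomb_prob = 0.1, seed = 9)
  expect_identical(simulate_genotypes(d), simulate_genotypes(d))
  d2 <- d; d2$seed <- 10L
  expect_false(identical(simulate_genotypes(d)$alleles,
                         simulate_genotypes(d2)$alleles))
})

test_that("invalid cross designs are rejected", {
  expect_error(cross_design(n_segregants = 1), "invalid design")
  expect_error(cross_design(recomb_prob = 0.7), "invalid design")
  expect_error(cross_design(chromosomes = c(100, 200)), "invalid design")
})

test_that("phenotype generation follows the causal order", {
  geno <- tiny_genotypes(n = 80, m = 10, recomb = 0.1)
  envs <- paste0("e", 1:5)
  mk <- geno$map$marker[3]
  trait <- trait_architecture(
    data.frame(marker = mk, env = "all", effect = 1),
    residual_sd = 0.3, env_means = stats::setNames(rep(0, 5), envs))
  base_expr <- function(cons_coef) {
    expression_architecture(
      n_genes = 10,
      mediators = data.frame(gene = "g0001", marker = mk, beta_t = 1),
      mediator_growth = data.frame(gene = "g0001", env = "e1", beta_g = 0.5),
      consequence_genes = data.frame(gene = "g0002", env = envs,
                                     coef = cons_coef),
      expr_noise_sd = 0.2)
  }
  p1 <- simulate_phenotypes(geno, trait, base_expr(0.8), envs, seed = 2)
  p2 <- simulate_phenotypes(geno, trait, base_expr(5.0), envs, seed = 2)
  # growth is upstream of consequence expression: changing the consequence
  # coupling cannot move growth
  expect_identical(p1$growth, p2$growth)
  expect_false(identical(p1$expression[, "g0002", ], p2$expression[, "g0002", ]))
})

test_that("mediator genotype-to-expression effect is recovered by OLS", {
  geno <- tiny_genotypes(n = 200, m = 5, recomb = 0.5, seed = 21)
  envs <- paste0("e", 1:5)
  mk <- geno$map$marker[1]
  trait <- trait_architecture(
    data.frame(marker = mk, env = "all", effect = 0.5),
    residual_sd = 0.3, env_means = stats::setNames(rep(0, 5), envs))
  expr <- expression_architecture(
    n_genes = 5,
    mediators = data.frame(gene = "g0001", marker = mk, beta_t = 1),
    mediator_growth = data.frame(gene = "g0001", env = "e1", beta_g = 0.3),
    expr_noise_sd = 0.1)
  phen <- simulate_phenotypes(geno, trait, expr, envs, seed = 3)
  fit <- summary(lm(phen$expression[, "g0001", "e2"] ~ geno$alleles[, mk]))
  est <- fit$coefficients[2, ]
  expect_lt(abs(est[["Estimate"]] - 1), 3 * est[["Std. Error"]])
})

test_that("checkered design masks expression but not growth", {
  geno <- tiny_genotypes(n = 159, m = 6)
  envs <- paste0("e", 1:5)
  trait <- trait_architecture(
    data.frame(marker = geno$map$marker[1], env = "all", effect = 0),
    residual_sd = 0.5, env_means = stats::setNames(rep(0, 5), envs))
  expr <- expression_architecture(n_genes = 4, expr_noise_sd = 0.3)
  phen <- simulate_phenotypes(geno, trait, expr, envs, seed = 7)
  full <- apply_checkered_design(phen, n_per_env = 159, seed = 1)
  expect_false(anyNA(full$expression))
  chk <- apply_checkered_design(phen, n_per_env = 35, seed = 1)
  expect_equal(unname(colSums(chk$mask)), rep(35, 5))
  for (ev in envs) {
    expect_equal(sum(!is.na(chk$expression[, 1, ev])), 35)
  }
  expect_identical(chk$growth, phen$growth)
  expect_error(apply_checkered_design(phen, n_per_env = 200), "design error")
})

test_that("checkered masks of two environments overlap at the hypergeometric rate", {
  geno <- tiny_genotypes(n = 159, m = 2)
  envs <- paste0("e", 1:2)
  trait <- trait_architecture(
    data.frame(marker = geno$map$marker[1], env = "all", effect = 0),
    residual_sd = 0.5, env_means = stats::setNames(rep(0, 2), envs))
  expr <- expression_architecture(n_genes = 2, expr_noise_sd = 0.3)
  phen <- simulate_phenotypes(geno, trait, expr, envs, seed = 7)
  overlaps <- vapply(1:60, function(s) {
    m <- apply_checkered_design(phen, n_per_env = 35, seed = s)$mask
    sum(m[, 1] & m[, 2])
  }, 0)
  expected <- 35^2 / 159            # = 7.70
  se <- sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - expected), 4 * se + 0.1)
})

test_that("deletion assay follows the selection-coefficient model", {
  s <- matrix(c(0, 0.1), 2, 1, dimnames = list(c("gA", "gB"), "e1"))
  a <- simulate_deletion_assay(deletion_truth(s, noise_sd = 0), seed = 1)
  g0 <- a$log2_abundance[a$gene == "gA" & a$generation == 0]
  g5 <- a$log2_abundance[a$gene == "gA" & a$generation == 5]
  expect_equal(g5, g0)
  d <- a$log2_abundance[a$gene == "gB" & a$generation == 5][1] -
    a$log2_abundance[a$gene == "gB" & a$generation == 0][1]
  expect_equal(d, 0.5)
  expect_error(deletion_truth(s, noise_sd = -1), "noise_sd")
  expect_error(deletion_truth(s, generations = c(-1, 5)), "non-negative")
})

test_that("selection-coefficient signs are recovered from a noisy assay", {
  set.seed(30)
  s_true <- matrix(sample(c(-0.2, 0, 0.2), 300, replace = TRUE), 300, 1,
                   dimnames = list(sprintf("g%03d", 1:300), "e1"))
  a <- simulate_deletion_assay(deletion_truth(s_true, noise_sd = 0.05),
                               seed = 2)
  est <- estimate_selection_coefficients(a)
  est <- est[match(rownames(s_true), est$gene), ]
  nonzero <- s_true[, 1] != 0
  agree <- sign(est$s[nonzero]) == sign(s_true[nonzero, 1])
  expect_gte(mean(agree), 0.99)
})

test_that("gene roles must be disjoint and mediators active", {
  expect_error(expression_architecture(
    n_genes = 5,
    mediators = data.frame(gene = "g0001", marker = "m1", beta_t = 1),
    side_effect_genes = data.frame(gene = "g0001", marker = "m1", effect = 1)),
    "disjoint")
  expect_error(expression_architecture(
    n_genes = 5,
    mediators = data.frame(gene = "g0001", marker = "m1", beta_t = 0)),
    "beta_t")
})
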