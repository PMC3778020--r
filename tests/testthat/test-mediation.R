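# straight transcription of the closed-form Gaussian profile log-likelihood,
# used as the independent oracle for the BIC computations
oracle_loglik <- function(X, y) {
  rss <- sum(lm.fit(X, y)$residuals^2)
  n <- length(y)
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}

test_that("a deterministic mediator chain is fitted exactly", {
  d <- chain_dataset(n = 40, beta_t = 1, gamma = 1, noise = 1e-6, seed = 51)
  inp <- mediation_input(d$phen, "g0001", d$geno, d$model, 1,
                         standardize = FALSE)
  m1 <- fit_model1(inp)
  expect_equal(unname(m1$coef_t["s"]), 1, tolerance = 1e-3)
  expect_equal(unname(m1$coef_g["t_env"]), 1, tolerance = 1e-3)
})

test_that("model BICs match the closed-form profile-likelihood oracle", {
  d <- chain_dataset(n = 20, beta_t = 0.8, gamma = 0.5, noise = 0.3, seed = 52)
  inp <- mediation_input(d$phen, "g0001", d$geno, d$model, 1)
  n <- length(inp$g)
  sc <- score_mediation(inp)
  in_env <- as.numeric(inp$env == "env1")
  # Model 1: t ~ E + s ; g ~ E + covariates + t * 1{env}
  ll1 <- oracle_loglik(cbind(inp$E, inp$s), inp$t) +
    oracle_loglik(cbind(inp$E, inp$covariates, inp$t * in_env), inp$g)
  k1 <- (ncol(inp$E) + 1 + 1) + (ncol(inp$E) + ncol(inp$covariates) + 1 + 1)
  # Model 0: t ~ E ; g ~ E + covariates + s * 1{env}
  ll0 <- oracle_loglik(inp$E, inp$t) +
    oracle_loglik(cbind(inp$E, inp$covariates, inp$s * in_env), inp$g)
  k0 <- (ncol(inp$E) + 1) + (ncol(inp$E) + ncol(inp$covariates) + 1 + 1)
  expect_equal(sc$bic1, -2 * ll1 + k1 * log(n), tolerance = 1e-8)
  expect_equal(sc$bic0, -2 * ll0 + k0 * log(n), tolerance = 1e-8)
  # default coding: Model 1 has exactly one extra parameter
  expect_equal(k1 - k0, 1)
  m0 <- fit_model0(inp); m1 <- fit_model1(inp)
  expect_equal(m1$k - m0$k, 1L)
})

test_that("the Model 0 growth sub-model equals a direct refit", {
  d <- chain_dataset(n = 30, noise = 0.3, seed = 53)
  inp <- mediation_input(d$phen, "g0002", d$geno, d$model, 1)
  m0 <- fit_model0(inp)
  in_env <- as.numeric(inp$env == "env1")
  direct <- lm.fit(cbind(inp$E, inp$covariates, s_env = inp$s * in_env),
                   inp$g)
  expect_equal(unname(m0$coef_g), unname(direct$coefficients),
               tolerance = 1e-8)
})

test_that("posterior follows the BIC comparison and sums to 1", {
  d <- chain_dataset(n = 30, noise = 0.3, seed = 54)
  for (gene in c("g0001", "g0002")) {
    inp <- mediation_input(d$phen, gene, d$geno, d$model, 1)
    sc <- score_mediation(inp)
    expect_equal(sc$posterior,
                 1 / (1 + exp((sc$bic1 - sc$bic0) / 2)), tolerance = 1e-12)
    expect_equal(sc$posterior + 1 / (1 + exp((sc$bic0 - sc$bic1) / 2)), 1)
    expect_equal(sc$delta_bic, sc$bic0 - sc$bic1)
  }
})

test_that("a strong mediator chain yields a decisive posterior", {
  post <- vapply(1:100, function(i) {
    d <- chain_dataset(n = 35, beta_t = 1, gamma = 1, noise = 0.2,
                       seed = 600 + i)
    inp <- mediation_input(d$phen, "g0001", d$geno, d$model, 1)
    score_mediation(inp)$posterior
  }, 0)
  expect_gte(mean(post > 0.9), 0.9)
})

test_that("mediators outrank pure consequence genes", {
  # consequence gene: expression mirrors growth but has no genotype link
  scores <- lapply(1:40, function(i) {
    d <- chain_dataset(n = 35, beta_t = 1, gamma = 1, noise = 0.3,
                       seed = 700 + i)
    d$phen$expression[, "g0002", ] <- d$phen$growth +
      matrix(rnorm(35 * 5, sd = 0.3), 35, 5)
    med <- score_mediation(mediation_input(d$phen, "g0001", d$geno, d$model, 1))
    con <- score_mediation(mediation_input(d$phen, "g0002", d$geno, d$model, 1))
    c(med = med$delta_bic, con = con$delta_bic,
      medp = med$posterior, conp = con$posterior)
  })
  scores <- do.call(rbind, scores)
  expect_gt(median(scores[, "medp"]), median(scores[, "conp"]))
  lab <- c(rep(TRUE, nrow(scores)), rep(FALSE, nrow(scores)))
  expect_gte(auroc(c(scores[, "med"], scores[, "con"]), lab), 0.9)
})

test_that("scores are equivariant to growth shifts and expression scaling", {
  d <- chain_dataset(n = 35, noise = 0.3, seed = 55)
  base <- score_mediation(mediation_input(d$phen, "g0001", d$geno, d$model, 1))
  d2 <- d
  d2$phen$growth <- d2$phen$growth + 100
  d2$phen$expression[, "g0001", ] <- 7 * d2$phen$expression[, "g0001", ]
  shifted <- score_mediation(mediation_input(d2$phen, "g0001", d2$geno,
                                             d2$model, 1))
  expect_equal(shifted$posterior, base$posterior, tolerance = 1e-8)
  expect_equal(shifted$delta_bic, base$delta_bic, tolerance = 1e-6)
  expect_equal(shifted$direction, base$direction)
})

test_that("the single-environment variant equals the full network with one environment", {
  d <- chain_dataset(n = 40, n_env = 1, noise = 0.3, seed = 56)
  inp <- mediation_input(d$phen, "g0001", d$geno, d$model, 1)
  sc_multi <- score_mediation(inp)
  sc_single <- score_mediation(single_env_input(inp))
  expect_equal(sc_single$bic0, sc_multi$bic0, tolerance = 1e-8)
  expect_equal(sc_single$bic1, sc_multi$bic1, tolerance = 1e-8)
})

test_that("a constant gene is flagged degenerate with zero posterior", {
  d <- chain_dataset(n = 20, noise = 0.3, seed = 57)
  d$phen$expression[, "g0002", ] <- 3
  sc <- score_mediation(mediation_input(d$phen, "g0002", d$geno, d$model, 1))
  expect_true(sc$degenerate)
  expect_equal(sc$posterior, 0)
})

test_that("ranking is deterministic and input-order invariant", {
  set.seed(58)
  sc <- data.frame(gene = sprintf("g%02d", 1:8),
                   delta_bic = c(5, 3, 3, 9, -1, 0, 0, 2),
                   posterior = plogis(c(5, 3, 3, 9, -1, 0, 0, 2) / 2))
  r1 <- rank_candidates(sc)
  r2 <- rank_candidates(sc[sample(8), ])
  expect_identical(r1$gene, r2$gene)
  expect_identical(r1$rank, seq_len(8))
  expect_equal(r1$gene[1], "g04")
  # tied delta_bic broken by gene id
  i <- which(r1$delta_bic == 3)
  expect_identical(r1$gene[i], c("g02", "g03"))
})

test_that("mediation refuses main-effect terms", {
  d <- chain_dataset(n = 20, seed = 59)
  d$model$terms <- data.frame(marker = "mA", env = "all", coef = 1)
  expect_error(mediation_input(d$phen, "g0001", d$geno, d$model, 1),
               "interaction terms only")
})
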