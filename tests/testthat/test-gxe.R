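test_that("a purely persistent effect loads on the shared term only", {
  set.seed(101)
  n <- 40; envs <- rep(paste0("e", 1:4), each = n)
  g <- rep(rbinom(n, 1, 0.5), 4)
  y <- 0.7 * g + rep(c(1, 2, 3, 4), each = n)  # identical effect, no noise
  fit <- fit_joint_env_model(y, g, envs)
  expect_equal(fit$shared$beta, 0.7, tolerance = 1e-10)
  expect_true(all(abs(fit$interactions$beta) < 1e-10))
  expect_equal(unname(fit$intercepts), c(1, 2, 3, 4), tolerance = 1e-10)
})

test_that("shared + deviation reproduces the per-environment marginal effect", {
  set.seed(102)
  n <- 30; ne <- 4
  g1 <- rbinom(n, 1, 0.5)
  envs <- rep(paste0("e", 1:ne), each = n)
  g <- rep(g1, ne)                       # balanced: same strains in each env
  slopes <- c(0.5, -1, 0, 2)
  y <- g * slopes[rep(1:ne, each = n)] + rep(seq_len(ne), each = n)
  fit <- fit_joint_env_model(y, g, envs)
  recomposed <- fit$shared$beta + fit$interactions$beta
  marginal <- vapply(1:ne, function(e) {
    i <- envs == paste0("e", e)
    unname(coef(lm(y[i] ~ g[i]))[2])
  }, 0)
  expect_equal(recomposed, marginal, tolerance = 1e-8)
  expect_equal(sum(fit$interactions$beta), 0, tolerance = 1e-8)
})

test_that("single-environment decomposition is rejected", {
  expect_error(fit_joint_env_model(rnorm(10), rbinom(10, 1, 0.5),
                                   rep("e1", 10)),
               "single environment")
})

test_that("an environment-specific effect is detected with high power", {
  set.seed(103)
  hits <- vapply(1:100, function(i) {
    n <- 35; ne <- 5
    g <- rep(rbinom(n, 1, 0.5), ne)
    envs <- rep(paste0("e", 1:ne), each = n)
    y <- rnorm(n * ne, sd = 0.1) + 1.0 * g * (envs == "e1")
    fit <- fit_joint_env_model(y, g, envs)
    fit$interactions$p[fit$interactions$env == "e1"] < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("shared-effect p-values are uniform under the global null", {
  set.seed(104)
  ps <- vapply(1:1000, function(i) {
    n <- 20; ne <- 3
    g <- rep(rbinom(n, 1, 0.5), ne)
    envs <- rep(paste0("e", 1:ne), each = n)
    fit_joint_env_model(rnorm(n * ne), g, envs)$shared$p
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the single-interaction fit isolates one environment's deviation", {
  set.seed(110)
  n <- 40; ne <- 4
  g <- rep(rbinom(n, 1, 0.5), ne)
  envs <- rep(paste0("e", 1:ne), each = n)
  y <- 0.4 * g + 1.0 * g * (envs == "e2") + rep(1:ne, each = n)
  fit <- fit_joint_env_model(y, g, envs, interaction = "single",
                             env_of_interest = "e2")
  expect_equal(fit$shared$beta, 0.4, tolerance = 1e-10)
  expect_equal(fit$interactions$beta, 1.0, tolerance = 1e-10)
  expect_equal(fit$interactions$env, "e2")
  expect_error(fit_joint_env_model(y, g, envs, interaction = "single"),
               "env_of_interest")
})

test_that("eQTL classes are assigned from the pooled q-value families", {
  set.seed(105)
  n <- 35; ne <- 5
  g1 <- rbinom(n, 1, 0.5)
  envs <- rep(paste0("e", 1:ne), each = n)
  g <- rep(g1, ne)
  make_fit <- function(kind) {
    y <- rnorm(n * ne, sd = 0.3) +
      switch(kind,
             persistent = 1.0 * g,
             dependent = 1.0 * g * (envs == "e1"),
             none = 0)
    fit_joint_env_model(y, g, envs, interaction = "single",
                        env_of_interest = "e1")
  }
  kinds <- rep(c("persistent", "dependent", "none"), times = c(30, 30, 140))
  fits <- lapply(kinds, make_fit)
  names(fits) <- sprintf("g%04d", seq_along(fits))
  cl <- classify_eqtls(fits, fdr = 0.05)
  acc_p <- mean(cl$label[kinds == "persistent"] == "persistent-only")
  acc_d <- mean(cl$label[kinds == "dependent"] == "dependent-only")
  expect_gte(acc_p, 0.9)
  expect_gte(acc_d, 0.9)
  # nulls stay mostly unlabeled
  expect_gte(mean(cl$label[kinds == "none"] == "none"), 1 - 2 * 0.05)
  expect_error(classify_eqtls(list()), "no fits")
})

test_that("downsampling matches the mean per-environment size", {
  st <- data.frame(env = rep(paste0("e", 1:5), each = 35),
                   expression = rnorm(175))
  sub <- downsample_for_power(st, seed = 3)
  expect_equal(nrow(sub), 35)
  expect_identical(downsample_for_power(st, target = nrow(st)), st)
  expect_error(downsample_for_power(st, target = 1000), "exceeds")
})

test_that("downsampled detection rates are stable across seeds", {
  set.seed(106)
  n <- 35; ne <- 5
  g1 <- rbinom(n, 1, 0.5)
  envs <- rep(paste0("e", 1:ne), each = n)
  g <- rep(g1, ne)
  y <- 1.0 * g + rnorm(n * ne, sd = 0.5)
  st <- data.frame(env = envs, expression = y, genotype = g)
  rate_for <- function(seed) {
    sub <- downsample_for_power(st, seed = seed)
    summary(lm(expression ~ genotype, sub))$coefficients[2, 4] < 0.05
  }
  means <- vapply(1:20, rate_for, TRUE)
  expect_lt(sd(means) / sqrt(20), 0.15)  # stable mean detection
})
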