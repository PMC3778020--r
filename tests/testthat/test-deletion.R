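test_that("selection coefficients follow the slope definition", {
  grid <- expand.grid(gene = c("gA", "gB"), environment = "e1",
                      generation = c(0, 5), replicate = 1:3,
                      stringsAsFactors = FALSE)
  grid$log2_abundance <- 10
  grid$log2_abundance[grid$gene == "gB" & grid$generation == 5] <- 10.5
  est <- estimate_selection_coefficients(grid)
  expect_equal(est$s[est$gene == "gA"], 0)
  expect_equal(est$s[est$gene == "gB"], 0.1)  # 0.5 over 5 generations
})

test_that("selection coefficients are recovered to tight accuracy", {
  set.seed(61)
  s_true <- matrix(sample(c(-0.2, 0, 0.2), 500, replace = TRUE), 500, 1,
                   dimnames = list(sprintf("g%03d", 1:500), "e1"))
  a <- simulate_deletion_assay(deletion_truth(s_true, noise_sd = 0.05),
                               seed = 3)
  est <- estimate_selection_coefficients(a)
  est <- est[match(rownames(s_true), est$gene), ]
  expect_lt(mean(abs(est$s - s_true[, 1])), 0.02)
})

# independent straight transcription of the empirical-Bayes moment-matching
# on the log-variance scale (scaled-F prior for the sample variances)
oracle_var_prior <- function(s2, df) {
  trigamma_inverse <- function(y) {
    uniroot(function(x) trigamma(x) - y, c(1e-8, 1e8), tol = 1e-12)$root
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

test_that("the moderated-t prior matches an independent transcription", {
  set.seed(62)
  s_true <- matrix(rnorm(20, sd = 0.1), 20, 1,
                   dimnames = list(sprintf("g%02d", 1:20), "e1"))
  a <- simulate_deletion_assay(deletion_truth(s_true, noise_sd = 0.08),
                               seed = 5)
  est <- estimate_selection_coefficients(a)
  mod <- moderated_t(est)
  orc <- oracle_var_prior(est$s2, est$df)
  expect_equal(attr(mod, "d0"), orc$d0, tolerance = 1e-6)
  expect_equal(attr(mod, "s02"), orc$s02, tolerance = 1e-6)
  s2_post <- (orc$d0 * orc$s02 + est$df * est$s2) / (orc$d0 + est$df)
  expect_equal(mod$t_moderated, est$s / sqrt(s2_post * est$c2),
               tolerance = 1e-6)
})

test_that("moderated-t limiting cases reduce as expected", {
  set.seed(63)
  s_true <- matrix(rnorm(15, sd = 0.1), 15, 1,
                   dimnames = list(sprintf("g%02d", 1:15), "e1"))
  a <- simulate_deletion_assay(deletion_truth(s_true, noise_sd = 0.05),
                               seed = 6)
  est <- estimate_selection_coefficients(a)
  # d0 = 0: no shrinkage, ordinary t
  m0 <- moderated_t(est, d0 = 0, s02 = 1)
  expect_equal(m0$t_moderated, est$t_ordinary)
  # d0 -> infinity: fully pooled variance
  mi <- moderated_t(est, d0 = Inf, s02 = 0.02)
  expect_true(all(mi$s2_post == 0.02))
  # moderated p is a monotone transform of |t| at fixed df
  m <- moderated_t(est)
  o <- order(abs(m$t_moderated))
  expect_true(all(diff(m$p[o]) <= 1e-12))
})

test_that("deletion calls apply both the effect-size and FDR cutoffs", {
  fit <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    environment = "e1",
                    s = c(0.10, 0.10, -0.20, 0.04),
                    p = c(1e-4, 0.5, 1e-4, 1e-6))
  fit$q <- c(0.001, 0.20, 0.001, 0.001)
  calls <- call_deletion_effects(fit)
  expect_equal(calls$call, c("beneficial", "none", "detrimental", "none"))
})

test_that("fold enrichment arithmetic and direction matching are correct", {
  genes <- sprintf("g%03d", 1:1000)
  calls <- data.frame(gene = genes, environment = "e1", call = "none",
                      stringsAsFactors = FALSE)
  calls$call[1:100] <- "detrimental"
  calls$call[101:200] <- "beneficial"
  # background: (100+100)/(2*1000) = 0.10
  expect_equal(background_rate(calls, "e1"), 0.10)
  # 20 of the top 100 validated -> fold 2.0
  cand <- data.frame(gene = genes[c(1:20, 300:379)], direction = 1,
                     stringsAsFactors = FALSE)
  vr <- validation_rate(cand, calls, "e1", top_n = 100)
  expect_equal(vr$validated, 20)
  expect_equal(vr$fold, 2.0)
  # wrong direction does not validate
  cand_bad <- data.frame(gene = genes[1:20], direction = -1)
  expect_equal(validation_rate(cand_bad, calls, "e1", top_n = 20)$validated, 0)
  expect_equal(validation_rate(cand_bad, calls, "e1", top_n = 20,
                               ignore_direction = TRUE)$validated, 20)
  expect_warning(validation_rate(cand_bad, calls, "e1", top_n = 50), "top_n")
})

test_that("randomly ranked candidates show fold enrichment near 1", {
  set.seed(64)
  genes <- sprintf("g%03d", 1:1000)
  calls <- data.frame(gene = genes, environment = "e1",
                      call = sample(c("detrimental", "beneficial", "none"),
                                    1000, replace = TRUE,
                                    prob = c(0.1, 0.1, 0.8)),
                      stringsAsFactors = FALSE)
  folds <- vapply(1:100, function(i) {
    cand <- data.frame(gene = sample(genes, 100),
                       direction = sample(c(-1, 1), 100, replace = TRUE))
    validation_rate(cand, calls, "e1", top_n = 100)$fold
  }, 0)
  expect_gte(mean(folds), 0.9)
  expect_lte(mean(folds), 1.1)
})

test_that("jackknife spread matches the closed form", {
  j <- jackknife_enrichment(c(1, 2, 3))
  # leave-one-out means 2.5, 2, 1.5 -> sqrt(2/3 * 0.5) = 1/sqrt(3)
  expect_equal(j$jackknife_sd, 1 / sqrt(3))
  expect_equal(j$mean, 2)
  expect_equal(jackknife_enrichment(rep(1.3, 5))$jackknife_sd, 0)
  expect_error(jackknife_enrichment(1), ">= 2")
})

test_that("enrichment curves are cumulative, monotone and complete", {
  genes <- sprintf("g%02d", 1:20)
  calls <- data.frame(gene = genes, environment = "e1", call = "none",
                      stringsAsFactors = FALSE)
  calls$call[1:5] <- "detrimental"
  cand <- data.frame(gene = genes, direction = 1)  # perfect ranking
  cv <- enrichment_curve(cand, calls, "e1")
  expect_equal(cv$validated[1:5], 1:5)          # slope 1 for k steps
  expect_equal(tail(cv$validated, 1), 5)        # endpoint = total validated
  expect_true(all(diff(cv$validated) >= 0))
  expect_equal(cv$expected, (5 / 40) * seq_len(20))
})

test_that("auroc matches the rank-sum definition on a toy case", {
  expect_equal(auroc(c(3, 2, 1), c(TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(c(1, 2, 3), c(TRUE, FALSE, FALSE)), 0)
  expect_equal(auroc(c(2, 2), c(TRUE, FALSE)), 0.5)
})
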