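test_that("genotype codings build the documented design columns", {
  g <- c(0, 1, 2, 1, 0)
  expect_equal(colnames(genotype_design(g, "general")), c("g", "h"))
  expect_equal(as.numeric(genotype_design(g, "recessive_ref")), c(0, 1, 1, 1, 0))
  expect_equal(ncol(genotype_design(g, "additive")), 1L)
  expect_silent(genotype_design(g, "general"))
  # missing homozygote class: h duplicates g and is dropped with a warning
  expect_warning(X <- genotype_design(c(0, 0, 1, 1), "general"), "degenerate")
  expect_equal(colnames(X), "g")
  expect_error(suppressWarnings(genotype_design(rep(1, 4), "additive")),
               "non-degenerate")
})

test_that("variance components hit the zero boundary without relatedness signal", {
  set.seed(5)
  n <- 150
  y <- rnorm(n, 2, 1.3)
  vc <- estimate_variance_components(y, Phi = diag(0.5, n))
  expect_equal(vc$sigma2_a, 0)
  expect_equal(vc$sigma2_e, mean((y - mean(y))^2), tolerance = 1e-6)
  expect_error(estimate_variance_components(rep(1, 50), Phi = diag(0.5, 50)),
               "zero variance")
})

test_that("heritability is recovered on a simulated pedigree", {
  ped <- simulate_pedigree(pedigree_sim_config(n_generations = 7, n_founders = 40,
                                               max_couples = 40, seed = 21))
  phi <- kinship_matrix(ped)
  sub <- ped$id[(nrow(ped) - 499):nrow(ped)]
  A <- 2 * unclass(phi)[sub, sub]
  eig <- eigen(A, symmetric = TRUE)
  eig$values <- pmax(eig$values, 0)
  L <- chol(A + diag(1e-8, 500))
  h2_true <- 0.3
  set.seed(33)
  h2_hat <- vapply(1:20, function(i) {
    y <- 1 + drop(crossprod(L, rnorm(500))) * sqrt(h2_true) +
      rnorm(500, 0, sqrt(1 - h2_true))
    estimate_variance_components(y, eig = eig)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - h2_true), 0.1)
})

test_that("GLS with identity covariance reproduces OLS exactly", {
  set.seed(8)
  n <- 80
  X <- cbind(a = rnorm(n), b = rnorm(n))
  g <- sample(0:2, n, replace = TRUE)
  y <- 1 + 0.5 * X[, 1] + 0.1 * g + rnorm(n)
  r <- gls_association(y, X, g, "general", Sigma = diag(n))
  # reference OLS F-test for the two genotype columns
  f0 <- lm(y ~ X)
  f1 <- lm(y ~ X + g + I(g == 1))
  an <- anova(f0, f1)
  expect_equal(r$F, an$F[2], tolerance = 1e-10)
  expect_equal(r$p_value, an$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(unname(r$beta[c("a", "b")]), unname(coef(f1)[c("Xa", "Xb")]),
               tolerance = 1e-10)
  # any scalar multiple of I gives the same test
  r2 <- gls_association(y, X, g, "general", Sigma = diag(3.7, n))
  expect_equal(r2$F, r$F, tolerance = 1e-10)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-10)
})

test_that("nested codings satisfy RSS(general) <= RSS(carrier) <= RSS(null)", {
  set.seed(14)
  n <- 120
  X <- cbind(rnorm(n))
  g <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  y <- 0.3 - 0.05 * (g == 0) + rnorm(n, 0, 0.12)
  rg <- gls_association(y, X, g, "general", Sigma = diag(n))
  rr <- gls_association(y, X, g, "recessive_ref", Sigma = diag(n))
  expect_lte(rg$RSS_alt, rr$RSS_alt + 1e-12)
  expect_lte(rr$RSS_alt, rr$RSS_null + 1e-12)
  expect_equal(rg$RSS_null, rr$RSS_null)
})

test_that("percent variance explained matches its algebraic definition", {
  expect_equal(percent_variance(100, 95), 5)
  expect_equal(percent_variance(100, 100), 0)
  expect_error(percent_variance(100, 101), "exceeds")
  set.seed(2)
  rss0 <- runif(1, 5, 10); rss1 <- runif(1, 1, 5)
  expect_equal(percent_variance(rss0, rss1), 100 * (1 - rss1 / rss0))
  # invariant to rescaling y (both RSS scale by the same factor)
  expect_equal(percent_variance(4 * rss0, 4 * rss1),
               percent_variance(rss0, rss1))
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(signif(bonferroni(0.0096, 4), 2), 0.038)
  expect_equal(signif(bonferroni(0.0029, 4), 2), 0.012)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_equal(bonferroni(0, 10), 0)
})

test_that("Wald t with identity covariance equals the OLS t-test", {
  set.seed(19)
  n <- 90
  X <- cbind(rnorm(n))
  g <- sample(0:2, n, replace = TRUE)
  y <- 0.5 + 0.02 * g + rnorm(n, 0, 0.1)
  vc0 <- estimate_variance_components(y, cbind(1, X), Phi = diag(0.5, n))
  # with Phi = I/2 the fitted covariance is a multiple of I: t must match lm
  r <- wald_t_additive(y, X, g, vc = vc0)
  ref <- summary(lm(y ~ X + g))$coefficients["g", ]
  expect_equal(r$t, unname(ref["t value"]), tolerance = 1e-6)
  expect_equal(r$p_value, unname(ref["Pr(>|t|)"]), tolerance = 1e-6)
  expect_equal(unname(r$beta["g"]), unname(ref["Estimate"]), tolerance = 1e-8)
})

test_that("Wald t is centered under the null across seeds", {
  set.seed(44)
  tvals <- vapply(1:60, function(i) {
    n <- 100
    y <- rnorm(n)
    g <- sample(0:2, n, replace = TRUE)
    wald_t_additive(y, NULL, g, Phi = diag(0.5, n))$t
  }, numeric(1))
  expect_lt(abs(mean(tvals)), 3 / sqrt(60))  # mean ~ 0, SD ~ 1
})

test_that("additive effect is recovered at replication-cohort scale", {
  # n = 315 men, derived-allele frequency 0.65, additive beta = 0.03
  set.seed(55)
  reps <- 12
  betas <- vapply(seq_len(reps), function(i) {
    n <- 315
    g <- rbinom(n, 2, 0.65)
    y <- 0.46 + 0.03 * g + rnorm(n, 0, 0.15)
    unname(wald_t_additive(y, NULL, g, Phi = diag(0.5, n))$beta["g"])
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.03), 3 * sd(betas) / sqrt(reps))
})

test_that("effect translates into a births deficit over the reproductive span", {
  expect_equal(effect_summary(0.049, 11.5), 0.56)
  expect_equal(effect_summary(-0.049, 11.5), 0.56)
  expect_equal(effect_summary(0, 27), 0)
  expect_equal(effect_summary(0.1, 10), 1)
})

test_that("association scan reports one calibrated row per locus and coding", {
  ped <- simulate_pedigree(pedigree_sim_config(n_generations = 5, n_founders = 30,
                                               max_couples = 25, seed = 3))
  phi <- kinship_matrix(ped)
  geno <- drop_genotypes(gene_drop(ped, p = 0.3, seed = 4))
  sim <- simulate_fertility(ped, geno, fertility_sim_config(n_men = 120, seed = 9),
                            phi = phi)
  pt <- phenotype_table(sim$histories)
  keep <- !pt$excluded
  sub <- pt$individual_id[keep]
  scan <- association_scan(pt$rate[keep],
                           as.matrix(pt[keep, c("wife_birth_year",
                                                "marriage_to_last_birth")]),
                           list(m470v = sim$dosage[sub]),
                           Phi = kinship_matrix(ped)[sub, sub],
                           n_tests = 4, alleles = list(m470v = c("Met", "Val")))
  expect_equal(nrow(scan), 2L)
  expect_true(all(scan$p_bonferroni >= scan$p_value))
  expect_true(all(scan$pct_variance_explained >= 0 &
                    scan$pct_variance_explained <= 100))
  expect_s3_class(attr(scan, "vc"), "variance_components")
})
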