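geno <- function(id, tg, polyt, m470v, phased = TRUE) {
  list(individual_id = id, tg = as.character(tg), polyt = as.character(polyt),
       m470v = m470v, intron8_phased = phased)
}

test_that("intron 8 cis pairs pass through as observed", {
  g <- geno("x", c("10", "11"), c("7", "9"), c("Met", "Val"))
  p <- phase_intron8(g)
  expect_true(p$phased)
  expect_equal(unname(p$cis[[1]]), c("10", "7"))
  expect_equal(unname(p$cis[[2]]), c("11", "9"))

  hom <- phase_intron8(geno("y", c("11", "11"), c("7", "7"), c("Met", "Met")))
  expect_equal(unname(hom$cis[[1]]), unname(hom$cis[[2]]))

  miss <- phase_intron8(geno("z", c("10", "11"), c("7", "9"), c("Met", "Val"),
                             phased = FALSE))
  expect_false(miss$phased)

  expect_error(phase_intron8(geno("w", c("14", "10"), c("7", "7"),
                                  c("Met", "Met"))), "domain")
})

test_that("homozygosity forces phase; double heterozygotes stay ambiguous", {
  solo_ped <- validate_pedigree(data.frame(id = c("m1", "m2"), father = NA,
                                           mother = NA, sex = "male"))
  hom <- geno("m1", c("10", "11"), c("7", "9"), c("Met", "Met"))
  # the Met/Val + TG11/12 + 7T/7T man whose phase cannot be determined
  amb <- geno("m2", c("11", "12"), c("7", "7"), c("Met", "Val"))
  a <- phase_by_pedigree(list(hom, amb), solo_ped)
  expect_true(a[[1]]$resolved)
  expect_equal(a[[1]]$pair, sort(c("TG10-7T-Met", "TG11-9T-Met")))
  expect_false(a[[2]]$resolved)
  expect_length(a[[2]]$candidates, 2L)
})

test_that("pedigree transmission resolves phase and matches the enumeration oracle", {
  trio_ped <- validate_pedigree(data.frame(
    id = c("dad", "mom", "kid"), father = c(NA, NA, "dad"),
    mother = c(NA, NA, "mom"), sex = c("male", "female", "male")))
  gdad <- geno("dad", c("10", "10"), c("7", "7"), c("Met", "Met"))
  gmom <- geno("mom", c("10", "11"), c("7", "7"), c("Val", "Met"))
  gkid <- geno("kid", c("10", "11"), c("7", "7"), c("Met", "Val"))
  a <- phase_by_pedigree(list(gdad, gmom, gkid), trio_ped)
  kid <- a[[3]]
  expect_true(kid$resolved)
  expect_equal(kid$pair, sort(c("TG10-7T-Met", "TG11-7T-Val")))
  # independent exhaustive enumeration over all candidate assignments
  expect_equal(oracle_trio_phase(gkid, gdad, gmom), list(kid$pair))

  # phase is invariant to the processing order of individuals
  a2 <- phase_by_pedigree(list(gkid, gmom, gdad), trio_ped)
  kid2 <- a2[[which(vapply(a2, `[[`, character(1), "individual_id") == "kid")]]
  expect_equal(kid2$pair, kid$pair)
})

test_that("a newly phased parent phases a child on the next sweep", {
  # gp (homozygous) phases p; p then phases k
  ped <- validate_pedigree(data.frame(
    id = c("gp", "gm", "p", "q", "k"),
    father = c(NA, NA, "gp", NA, "p"),
    mother = c(NA, NA, "gm", NA, "q"),
    sex = c("male", "female", "male", "female", "male")))
  gl <- list(
    geno("gp", c("10", "10"), c("7", "7"), c("Met", "Met")),
    geno("gm", c("11", "11"), c("7", "7"), c("Val", "Val")),
    geno("p", c("10", "11"), c("7", "7"), c("Met", "Val")),
    geno("q", c("12", "12"), c("7", "7"), c("Met", "Met")),
    geno("k", c("11", "12"), c("7", "7"), c("Val", "Met")))
  a <- phase_by_pedigree(gl, ped)
  k <- a[[5]]
  expect_true(k$resolved)
  expect_equal(k$pair, sort(c("TG11-7T-Val", "TG12-7T-Met")))
})

test_that("Mendelian inconsistency names the offending trio", {
  trio_ped <- validate_pedigree(data.frame(
    id = c("dad", "mom", "kid"), father = c(NA, NA, "dad"),
    mother = c(NA, NA, "mom"), sex = c("male", "female", "male")))
  gdad <- geno("dad", c("10", "10"), c("7", "7"), c("Met", "Met"))
  gmom <- geno("mom", c("10", "10"), c("7", "7"), c("Met", "Met"))
  gkid <- geno("kid", c("11", "11"), c("7", "7"), c("Val", "Val"))
  expect_error(phase_by_pedigree(list(gdad, gmom, gkid), trio_ped),
               "Mendelian inconsistency.*(kid|dad|mom)")
})

test_that("resolved assignments regenerate the observed genotypes", {
  set.seed(10)
  sim <- simulate_three_locus_genotypes(cftr_summary$haplotype_freq, 60, seed = 4)
  solo <- validate_pedigree(data.frame(
    id = vapply(sim$genotypes, `[[`, character(1), "individual_id"),
    father = NA_character_, mother = NA_character_, sex = "male"))
  a <- phase_by_pedigree(sim$genotypes, solo)
  for (i in seq_along(a)) {
    if (!a[[i]]$resolved) next
    parts <- strsplit(a[[i]]$pair, "-")
    expect_equal(sort(sub("^TG", "", vapply(parts, `[`, character(1), 1))),
                 sort(sim$genotypes[[i]]$tg))
    expect_equal(sort(vapply(parts, `[`, character(1), 3)),
                 sort(sim$genotypes[[i]]$m470v))
  }
  # and the resolved pair matches the simulated truth
  res <- which(vapply(a, `[[`, logical(1), "resolved"))
  for (i in res) {
    expect_equal(a[[i]]$pair, sort(sim$truth[i, ]))
  }
})

test_that("haplotype frequency estimates are consistent and unbiased", {
  solo1 <- validate_pedigree(data.frame(id = "s", father = NA, mother = NA,
                                        sex = "male"))
  one <- phase_by_pedigree(list(geno("s", c("10", "10"), c("7", "7"),
                                     c("Met", "Met"))), solo1)
  hf1 <- haplotype_frequencies(one)
  expect_equal(unname(hf1$freq), 1)
  expect_equal(names(hf1$freq), "TG10-7T-Met")

  # family information resolves phase; counting then recovers the realized
  # haplotype frequencies of the cohort
  truth <- cftr_summary$haplotype_freq
  ped <- simulate_pedigree(pedigree_sim_config(n_generations = 4,
                                               n_founders = 40,
                                               max_couples = 20, seed = 6))
  devs <- matrix(0, 20, length(truth), dimnames = list(NULL, names(truth)))
  amb_rate <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_three_locus_genotypes(truth, seed = 100 + s, ped = ped)
    hf <- haplotype_frequencies(phase_by_pedigree(sim$genotypes, ped))
    expect_equal(sum(hf$freq), 1)
    realized <- table(factor(c(sim$truth), levels = names(truth))) /
      (2 * nrow(sim$truth))
    est <- stats::setNames(numeric(length(truth)), names(truth))
    est[names(hf$freq)] <- hf$freq
    devs[s, ] <- est - as.numeric(realized)
    amb_rate[s] <- hf$n_ambiguous / length(sim$genotypes)
  }
  # most individuals are phased through their families
  expect_lt(mean(amb_rate), 0.15)
  m <- colMeans(devs)
  se <- apply(devs, 2, sd) / sqrt(nrow(devs))
  for (h in names(truth)) {
    expect_lt(abs(m[h]), max(3 * se[h], 0.02))
  }
})

test_that("D-prime and r2 follow the normalized-D definitions", {
  # the 7T x Val dichotomization of the observed haplotype table
  ld <- d_prime(cftr_summary$haplotype_freq, "polyt", "m470v", "7", "Val")
  expect_equal(ld$D_prime, 1.0)
  expect_equal(ld$pA, 0.91)
  expect_equal(ld$pB, 0.28)

  # independent loci
  tab <- data.frame(a = c("1", "1", "2", "2"), b = c("1", "2", "1", "2"),
                    freq = c(0.12, 0.28, 0.18, 0.42))
  ld0 <- d_prime(tab, "a", "b", "1", "1")
  expect_equal(ld0$D, 0)
  expect_equal(ld0$D_prime, 0)

  # random 2x2 tables vs direct recomputation of the max-normalization
  set.seed(9)
  for (i in 1:50) {
    f <- as.numeric(rmultinom(1, 200, runif(4))) / 200
    if (any(colSums(matrix(f, 2)) %in% c(0, 1)) ||
        any(rowSums(matrix(f, 2)) %in% c(0, 1))) next
    tab <- data.frame(a = c("1", "1", "2", "2"), b = c("1", "2", "1", "2"),
                      freq = f)
    ld <- d_prime(tab, "a", "b", "1", "1")
    pA <- f[1] + f[2]; pB <- f[1] + f[3]; D <- f[1] - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    expect_equal(ld$D_prime, if (dmax == 0) 0 else D / dmax, tolerance = 1e-12)
    expect_gte(ld$r2, 0); expect_lte(ld$r2, 1)
    expect_lte(abs(ld$D_prime), 1 + 1e-12)
  }
  expect_error(d_prime(cftr_summary$haplotype_freq, "polyt", "m470v", "5", "Val"),
               "monomorphic")
})

test_that("three-locus genotype files round-trip", {
  sim <- simulate_three_locus_genotypes(cftr_summary$haplotype_freq, 10, seed = 2)
  f <- tempfile(fileext = ".csv")
  tab <- do.call(rbind, lapply(sim$genotypes, function(g) {
    data.frame(individual_id = g$individual_id, tg1 = g$tg[1], tg2 = g$tg[2],
               polyt1 = g$polyt[1], polyt2 = g$polyt[2],
               m470v1 = g$m470v[1], m470v2 = g$m470v[2],
               intron8_phased = g$intron8_phased)
  }))
  write.csv(tab, f, row.names = FALSE, quote = FALSE)
  back <- read_three_locus_genotypes(f)
  expect_equal(back[[3]]$tg, sim$genotypes[[3]]$tg)
  expect_equal(back[[7]]$m470v, sim$genotypes[[7]]$m470v)
  expect_true(back[[1]]$intron8_phased)
})
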