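test_that("Weir-Cockerham theta matches an independent transcription", {
  th <- weir_cockerham_theta(100, 80, 100, 20)
  expect_equal(th$theta, oracle_wc_theta(100, 80, 100, 20), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:30) {
    n1 <- sample(10:300, 1); n2 <- sample(10:300, 1)
    x1 <- rbinom(1, n1, runif(1, 0.05, 0.95))
    x2 <- rbinom(1, n2, runif(1, 0.05, 0.95))
    expect_equal(weir_cockerham_theta(n1, x1, n2, x2)$theta,
                 oracle_wc_theta(n1, x1, n2, x2), tolerance = 1e-12)
  }
})

test_that("theta is symmetric in population order and allele labelling", {
  a <- weir_cockerham_theta(120, 80, 90, 15)$theta
  expect_equal(weir_cockerham_theta(90, 15, 120, 80)$theta, a)
  expect_equal(weir_cockerham_theta(120, 120 - 80, 90, 90 - 15)$theta, a)
})

test_that("theta spans no-differentiation to fixation", {
  # identical sample frequencies: zero up to the estimator's own
  # sampling correction of -1/(nc - 1)
  th0 <- weir_cockerham_theta(120, 60, 120, 60)
  expect_lte(th0$theta, 0)
  expect_lte(abs(th0$theta), 1 / (th0$nc - 1) + 1e-12)

  th1 <- weir_cockerham_theta(1e4, 1e4, 1e4, 0)
  expect_gt(th1$theta, 1 - 1e-3)

  und <- weir_cockerham_theta(50, 0, 60, 0)
  expect_true(und$undefined)
  expect_true(is.na(und$theta))
})

test_that("the genotype-level theta variant agrees with the allele variant at HWE scale", {
  # with all-heterozygote-free genotypes the two variants use different
  # denominators but both must detect strong differentiation
  th_g <- weir_cockerham_theta(100, 160, 100, 40, h1 = 30, h2 = 30,
                               variant = "genotype")
  th_a <- weir_cockerham_theta(200, 160, 200, 40, variant = "allele")
  expect_equal(th_g$variant, "genotype")
  expect_gt(th_g$theta, 0.2)
  expect_equal(th_g$theta, th_a$theta, tolerance = 0.05)
})

test_that("EHH is 1 at the core, non-increasing, and equals brute-force pair counting", {
  set.seed(21)
  for (i in 1:10) {
    n_hap <- sample(8:64, 1)
    n_snp <- sample(11:41, 1)
    M <- matrix(rbinom(n_hap * n_snp, 1, runif(1, 0.2, 0.8)), n_hap)
    core <- sample(2:(n_snp - 1), 1)
    M[, core] <- rbinom(n_hap, 1, 0.5)
    if (sum(M[, core]) < 2 || sum(1 - M[, core]) < 2) next
    panel <- hap_panel(M, seq_len(n_snp) * 500, core)
    for (dir in c("downstream", "upstream")) {
      cv <- ehh(panel, 1, dir)
      expect_equal(cv$ehh[1], 1)
      expect_true(all(diff(cv$ehh) <= 1e-12))
      expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
      expect_equal(cv$ehh, oracle_ehh(panel, 1, dir), tolerance = 1e-12)
    }
  }
})

test_that("EHH hand examples: all-distinct collapse and two identical pairs", {
  # 4 carriers all distinct at the first flanking SNP -> EHH 0 beyond it
  M <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1))
  panel <- hap_panel(M, c(0, 1000, 2000), 1)
  cv <- ehh(panel, 1, "downstream")
  expect_equal(cv$ehh, c(1, 2 / 6, 0))

  # two identical pairs out to x -> EHH = 2 / C(4,2) = 1/3
  Mp <- rbind(c(1, 0, 1), c(1, 0, 1), c(1, 1, 0), c(1, 1, 0))
  panel2 <- hap_panel(Mp, c(0, 1000, 2000), 1)
  cv2 <- ehh(panel2, 1, "downstream")
  expect_equal(cv2$ehh[3], (1 + 1) / choose(4, 2))
})

test_that("iHH integrates trapezoids with cutoff truncation", {
  flat <- data.frame(distance = c(0, 1000, 2000), ehh = c(1, 1, 1))
  expect_equal(ihh(flat, flat)$ihh, 2 * 2000)
  expect_true(ihh(flat, flat)$edge_truncated)

  drop0 <- data.frame(distance = c(0, 1000), ehh = c(1, 0))
  r <- ihh(drop0, drop0)
  expect_equal(r$ihh, 2 * 0.5 * 1000 * (1 + 0))
  expect_false(r$edge_truncated)

  # halving the cutoff never decreases the area
  set.seed(2)
  e <- sort(runif(30, 0, 1), decreasing = TRUE)
  cv <- data.frame(distance = seq(0, by = 700, length.out = 30), ehh = e)
  a1 <- ihh(cv, cv, cutoff = 0.2)$ihh
  a2 <- ihh(cv, cv, cutoff = 0.1)$ihh
  a3 <- ihh(cv, cv, cutoff = 0.05)$ihh
  expect_lte(a1, a2); expect_lte(a2, a3)
})

test_that("uiHS is antisymmetric under allele-label swap and negative for sweeps", {
  panel <- simulate_sweep_panel(sweep_panel_config(n_hap = 60, n_snp = 201,
                                                   sweep_tract_bp = 1.2e5,
                                                   seed = 5))
  r <- ihs_unstandardized(panel)
  expect_lt(r$uihs, 0)

  flipped <- hap_panel(1 - panel$haplotypes, panel$positions, panel$core_index)
  r2 <- ihs_unstandardized(flipped)
  expect_equal(r2$uihs, -r$uihs, tolerance = 1e-12)

  # symmetric panel: equal-size backgrounds drawn from one distribution
  set.seed(6)
  M <- matrix(rbinom(40 * 41, 1, 0.5), 40)
  M[, 21] <- rep(c(0, 1), each = 20)
  M[21:40, ] <- M[1:20, ]; M[21:40, 21] <- 1   # mirror images
  p <- hap_panel(M, seq_len(41) * 1000, 21)
  expect_equal(ihs_unstandardized(p)$uihs, 0, tolerance = 1e-12)
})

test_that("iHS standardization gives mean 0 / SD 1 per occupied bin", {
  set.seed(30)
  n <- 4000
  freqs <- runif(n, 0.02, 0.98)
  uihs <- rnorm(n, mean = 2 * freqs, sd = 1)   # frequency-dependent means
  st <- standardize_ihs(uihs, freqs, bins = 20)
  for (b in unique(st$bin)) {
    v <- st$ihs[st$bin == b]
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
  # the standardization removed the frequency trend
  expect_lt(abs(cor(st$ihs, freqs)), 0.08)

  # single occupied bin reduces to global z-scoring
  u <- rnorm(50); f <- runif(50, 0.4, 0.45)
  st1 <- standardize_ihs(u, f, bins = 2)
  expect_equal(st1$ihs, as.numeric(scale(u)), tolerance = 1e-12)

  # sparse bins are merged with a neighbor
  u2 <- c(rnorm(40), 0.5)
  f2 <- c(runif(40, 0.1, 0.15), 0.9)
  st2 <- standardize_ihs(u2, f2, bins = 10)
  expect_true(st2$merged)
  expect_length(unique(st2$bin), 1L)
})

test_that("empirical percentiles recover marginal and planted joint tail mass", {
  set.seed(31)
  fst <- rnorm(10000)
  ihs <- rnorm(10000)
  p <- empirical_percentile(fst, ihs, stats::median(fst), Inf)
  expect_equal(p$p_fst, 0.5, tolerance = 0.001)

  # more extreme than every entry
  p0 <- empirical_percentile(fst, ihs, max(fst) + 1, min(ihs) - 1)
  expect_equal(p0$p_fst, 0)
  expect_equal(p0$less_than, 1e-4)

  # plant a joint tail of exactly 300 / 1e5
  n <- 1e5
  fst2 <- runif(n, 0, 0.4); ihs2 <- runif(n, -1.9, 2)
  joint <- sample(n, 300)
  fst2[joint] <- runif(300, 0.43, 0.9)
  ihs2[joint] <- runif(300, -4, -1.93)
  pj <- empirical_percentile(fst2, ihs2, 0.43, -1.93)
  expect_equal(pj$p_joint, 0.003)
})

test_that("hap/legend panels round-trip including ancestral recoding", {
  panel <- simulate_sweep_panel(sweep_panel_config(n_hap = 20, n_snp = 31,
                                                   sweep_tract_bp = 2e4,
                                                   seed = 8))
  hp <- tempfile(); lp <- tempfile()
  write_hap_legend(panel, hp, lp)
  back <- read_hap_legend(hp, lp, sprintf("snp%05d", panel$core_index))
  expect_equal(back$haplotypes, unname(panel$haplotypes))
  expect_equal(back$positions, panel$positions)
  expect_equal(back$core_index, panel$core_index)
  expect_error(hap_panel(matrix(c(0, 1, 2, 0), 2), c(1, 2), 1))
  expect_error(hap_panel(matrix(0:1, 2, 2), c(2, 1), 1))
})
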