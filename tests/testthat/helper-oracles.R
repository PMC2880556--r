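# Small fixed pedigrees used across tests -----------------------------------

ped_trio <- function() {
  validate_pedigree(data.frame(
    id = c("F", "M", "C"), father = c(NA, NA, "F"),
    mother = c(NA, NA, "M"), sex = c("male", "female", "male")))
}

# A, B founders; S1, S2 full sibs; X their child (full-sib mating)
ped_fullsib <- function() {
  validate_pedigree(data.frame(
    id = c("A", "B", "S1", "S2", "X"),
    father = c(NA, NA, "A", "A", "S1"),
    mother = c(NA, NA, "B", "B", "S2"),
    sex = c("male", "female", "male", "female", "male")))
}

# first-cousin mating: GP1 x GP2 -> P1, P2 (sibs); P1 x U1 -> C1; P2 x U2 -> C2;
# C1 x C2 (first cousins) -> K
ped_cousin <- function() {
  validate_pedigree(data.frame(
    id = c("GP1", "GP2", "U1", "U2", "P1", "P2", "C1", "C2", "K"),
    father = c(NA, NA, NA, NA, "GP1", "GP1", "P1", "P2", "C1"),
    mother = c(NA, NA, NA, NA, "GP2", "GP2", "U1", "U2", "C2"),
    sex = c("male", "female", "female", "female", "male", "male",
            "male", "female", "male")))
}

history_rec <- function(id = "h1", marriage = 1990, wife = 1970,
                        births = c(1991, 1993), end = 2007) {
  list(individual_id = id, marriage_year = marriage, wife_birth_year = wife,
       birth_years = births, observation_end = end)
}

# Monte-Carlo IBD probability between two individuals: sample one random
# allele from each per replicate drop and compare founder-origin labels.
# Independent oracle for the kinship recursion.
mc_ibd <- function(ped, id1, id2, n_rep = 1e5, seed = 42) {
  d <- gene_drop(ped, seed = seed, n_rep = n_rep, founder_alleles = "unique")
  i <- match(id1, d$ids); j <- match(id2, d$ids)
  set.seed(seed + 1)
  ai <- ifelse(stats::runif(n_rep) < 0.5, d$paternal[i, ], d$maternal[i, ])
  aj <- ifelse(stats::runif(n_rep) < 0.5, d$paternal[j, ], d$maternal[j, ])
  mean(ai == aj)
}

# Direct transcription of the two-population allele-based Weir-Cockerham
# theta, written as the ANOVA mean squares, independent of the package path.
oracle_wc_theta <- function(n1, x1, n2, x2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  nt <- n1 + n2
  pbar <- (x1 + x2) / nt
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
  nc <- (nt - (n1^2 + n2^2) / nt)
  (msp - msg) / (msp + (nc - 1) * msg)
}

# Brute-force EHH: all-pairs shared-prefix comparison, O(n^2) per marker.
oracle_ehh <- function(panel, core_allele, direction) {
  carriers <- which(panel$haplotypes[, panel$core_index] == core_allele)
  idx <- if (direction == "downstream") {
    seq(panel$core_index, ncol(panel$haplotypes))
  } else {
    seq(panel$core_index, 1L)
  }
  H <- panel$haplotypes[carriers, idx, drop = FALSE]
  n <- length(carriers)
  pairs <- utils::combn(n, 2)
  vapply(seq_along(idx), function(k) {
    same <- apply(pairs, 2, function(pr) {
      all(H[pr[1], 1:k] == H[pr[2], 1:k])
    })
    mean(same)
  }, numeric(1))
}

# Exhaustive consistency enumeration for a trio: all ways to assign the
# child's candidate pairs given parent genotypes, keeping those where the
# child receives one haplotype from each parent's possible pairs.
oracle_trio_phase <- function(gchild, gfather, gmother) {
  child_cands <- fertsel:::candidate_pairs(gchild)
  fa_cands <- fertsel:::candidate_pairs(gfather)
  mo_cands <- fertsel:::candidate_pairs(gmother)
  ok <- vapply(child_cands, function(H) {
    any(vapply(fa_cands, function(FP) {
      any(vapply(mo_cands, function(MP) {
        (H[1] %in% FP && H[2] %in% MP) || (H[2] %in% FP && H[1] %in% MP)
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  child_cands[ok]
}
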