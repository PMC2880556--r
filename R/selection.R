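#' Weir-Cockerham theta (Fst) for two populations
#'
#' Variance-component estimator of allele-frequency differentiation. The
#' default `"allele"` variant uses allele counts only (the form appropriate
#' when only population allele frequencies are available): with mean
#' squares among (`MSP`) and within (`MSG`) populations,
#' `theta = (MSP - MSG) / (MSP + (nc - 1) MSG)`,
#' where `nc` is the variance-corrected average sample size. The
#' `"genotype"` variant implements the full diploid estimator with its
#' among-population (`a`), among-individual (`b`) and within-individual
#' (`c`) components, and requires observed heterozygote counts.
#'
#' @param n1,n2 number of allele copies sampled in each population
#'   (`variant = "allele"`), or number of diploid individuals
#'   (`variant = "genotype"`).
#' @param x1,x2 derived-allele copy counts.
#' @param h1,h2 heterozygote individual counts (genotype variant only).
#' @param variant `"allele"` (default) or `"genotype"`.
#' @return list of class `fst_result`: `theta`, `variant`, per-population
#'   `n` and `p`, and the variance components (`MSP`/`MSG`/`nc` or
#'   `a`/`b`/`c`). When both populations are fixed for the same allele the
#'   estimator is undefined and `theta` is `NA` with `undefined = TRUE`.
#' @export
weir_cockerham_theta <- function(n1, x1, n2, x2, h1 = NULL, h2 = NULL,
                                 variant = c("allele", "genotype")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, x1 >= 0, x2 >= 0, x1 <= if (variant == "allele") n1 else 2 * n1,
            x2 <= if (variant == "allele") n2 else 2 * n2)
  if (variant == "allele") {
    p1 <- x1 / n1; p2 <- x2 / n2
    if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) {
      return(structure(list(theta = NA_real_, undefined = TRUE, variant = variant,
                            n = c(n1, n2), p = c(p1, p2)), class = "fst_result"))
    }
    r <- 2
    nsum <- n1 + n2
    nc <- (nsum - (n1^2 + n2^2) / nsum) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / nsum
    MSP <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
    MSG <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nsum - r)
    theta <- (MSP - MSG) / (MSP + (nc - 1) * MSG)
    structure(list(theta = theta, undefined = FALSE, variant = variant,
                   n = c(n1, n2), p = c(p1, p2),
                   MSP = MSP, MSG = MSG, nc = nc),
              class = "fst_result")
  } else {
    stopifnot(!is.null(h1), !is.null(h2), h1 <= n1, h2 <= n2)
    p1 <- x1 / (2 * n1); p2 <- x2 / (2 * n2)
    if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) {
      return(structure(list(theta = NA_real_, undefined = TRUE, variant = variant,
                            n = c(n1, n2), p = c(p1, p2)), class = "fst_result"))
    }
    r <- 2
    ni <- c(n1, n2); pi <- c(p1, p2); hi <- c(h1 / n1, h2 / n2)
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    pbar <- sum(ni * pi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    structure(list(theta = a / (a + b + cc), undefined = FALSE, variant = variant,
                   n = ni, p = pi, a = a, b = b, c = cc),
              class = "fst_result")
  }
}

#' Construct a phased haplotype panel
#'
#' @param haplotypes binary matrix, rows = haplotypes, columns = SNPs
#'   (0 = ancestral, 1 = derived).
#' @param positions strictly increasing physical positions (bp), one per
#'   SNP column.
#' @param core_index column index of the focal SNP.
#' @param map optional genetic-map positions (cM) for distance weighting.
#' @return list of class `hap_panel`.
#' @export
hap_panel <- function(haplotypes, positions, core_index, map = NULL) {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(all(haplotypes %in% c(0, 1)),
            length(positions) == ncol(haplotypes),
            all(diff(positions) > 0),
            core_index >= 1, core_index <= ncol(haplotypes))
  if (anyNA(haplotypes)) stop("missing alleles are not supported in haplotype panels")
  structure(list(haplotypes = haplotypes, positions = positions,
                 core_index = core_index, map = map,
                 derived_freq = mean(haplotypes[, core_index])),
            class = "hap_panel")
}

#' Extended haplotype homozygosity around a core SNP
#'
#' EHH at distance `x` is the probability that two chromosomes drawn at
#' random (without replacement) from the carriers of the core allele are
#' identical at every SNP between the core and `x`:
#' `EHH(x) = sum_h C(n_h, 2) / C(n_c, 2)`, where the `n_h` are the sizes
#' of the identical-haplotype classes among the `n_c` carriers, extended
#' marker by marker away from the core. By construction EHH is 1 at the
#' core and non-increasing with distance.
#'
#' @param panel a [hap_panel()].
#' @param core_allele 0 (ancestral) or 1 (derived): which carriers to
#'   follow.
#' @param direction `"downstream"` (increasing position) or `"upstream"`.
#' @return data frame of class `ehh_curve`: `distance` (bp from the core,
#'   starting at 0), `ehh`; attribute `n_carriers`.
#' @export
ehh <- function(panel, core_allele, direction = c("downstream", "upstream")) {
  direction <- match.arg(direction)
  stopifnot(inherits(panel, "hap_panel"), core_allele %in% c(0, 1))
  carriers <- which(panel$haplotypes[, panel$core_index] == core_allele)
  nc <- length(carriers)
  if (nc < 2L) stop("need at least two carriers of the core allele")
  idx <- if (direction == "downstream") {
    seq(panel$core_index, ncol(panel$haplotypes))
  } else {
    seq(panel$core_index, 1L)
  }
  H <- panel$haplotypes[carriers, idx, drop = FALSE]
  denom <- choose(nc, 2)
  grp <- rep(1L, nc)
  vals <- numeric(length(idx))
  for (j in seq_along(idx)) {
    grp <- as.integer(interaction(grp, H[, j], drop = TRUE))
    sz <- tabulate(grp)
    vals[j] <- sum(choose(sz, 2)) / denom
  }
  out <- data.frame(distance = abs(panel$positions[idx] - panel$positions[panel$core_index]),
                    ehh = vals)
  attr(out, "n_carriers") <- nc
  attr(out, "direction") <- direction
  class(out) <- c("ehh_curve", "data.frame")
  out
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH decay curve over physical distance,
#' upstream and downstream summed. Each side is truncated at the first
#' marker where EHH drops below `cutoff` (that marker's trapezoid is
#' included); a side whose curve never reaches the cutoff inside the panel
#' is integrated to the panel edge and flagged `edge_truncated`.
#'
#' @param curve_up,curve_down [ehh()] curves for the two directions.
#' @param cutoff EHH truncation threshold in (0, 1); default 0.05.
#' @return list with `ihh` (bp-weighted area), `edge_truncated` (logical).
#' @export
ihh <- function(curve_up, curve_down, cutoff = 0.05) {
  stopifnot(cutoff > 0, cutoff < 1)
  side <- function(cv) {
    d <- cv$distance; e <- cv$ehh
    below <- which(e < cutoff)
    trunc <- length(below) == 0L
    last <- if (trunc) length(e) else below[1]
    keep <- seq_len(last)
    area <- if (last >= 2L) {
      sum(diff(d[keep]) * (utils::head(e[keep], -1) + utils::tail(e[keep], -1)) / 2)
    } else 0
    list(area = area, edge = trunc)
  }
  up <- side(curve_up); dn <- side(curve_down)
  list(ihh = up$area + dn$area, edge_truncated = up$edge || dn$edge)
}

#' Unstandardized integrated haplotype score
#'
#' `ln(iHH_ancestral / iHH_derived)` for the focal SNP of a panel:
#' negative values mean the derived-allele haplotypes are longer (decay
#' more slowly) than the ancestral ones, the signature expected under a
#' recent or ongoing sweep of the derived allele.
#'
#' @param panel a [hap_panel()]; both core alleles need >= 2 carriers.
#' @param cutoff EHH truncation threshold passed to [ihh()].
#' @return list of class `ihs_result`: `uihs`, `ihh_a`, `ihh_d`,
#'   `derived_freq`, `edge_truncated`.
#' @export
ihs_unstandardized <- function(panel, cutoff = 0.05) {
  areas <- lapply(c(a = 0, d = 1), function(allele) {
    ihh(ehh(panel, allele, "upstream"), ehh(panel, allele, "downstream"),
        cutoff = cutoff)
  })
  if (areas$a$ihh <= 0 || areas$d$ihh <= 0) {
    stop("zero integrated EHH on one allelic background; uiHS undefined")
  }
  structure(list(uihs = log(areas$a$ihh / areas$d$ihh),
                 ihh_a = areas$a$ihh, ihh_d = areas$d$ihh,
                 derived_freq = panel$derived_freq,
                 edge_truncated = areas$a$edge_truncated || areas$d$edge_truncated),
            class = "ihs_result")
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Subtracts the bin mean and divides by the bin standard deviation of the
#' unstandardized scores, within equal-width frequency bins on (0, 1), so
#' that the resulting iHS is comparable across allele frequencies (mean
#' ~0, SD ~1 in each bin of the reference distribution). Bins holding
#' fewer than two values (or with zero spread) are merged with their
#' nearest occupied neighbor and reported.
#'
#' @param uihs numeric vector of unstandardized scores.
#' @param derived_freqs matching derived-allele frequencies in (0, 1).
#' @param bins number of equal-width bins (default 20) or a vector of bin
#'   edges covering (0, 1).
#' @return list with `ihs` (standardized scores), `bin` (final bin id per
#'   value), `merged` (logical: did any merging occur).
#' @export
standardize_ihs <- function(uihs, derived_freqs, bins = 20) {
  stopifnot(length(uihs) == length(derived_freqs),
            all(derived_freqs > 0 & derived_freqs < 1))
  edges <- if (length(bins) == 1L) seq(0, 1, length.out = bins + 1L) else bins
  bin <- findInterval(derived_freqs, edges, rightmost.closed = TRUE)
  merged <- FALSE
  repeat {
    tab <- table(bin)
    occupied <- as.integer(names(tab))
    bad <- occupied[vapply(occupied, function(b) {
      v <- uihs[bin == b]
      length(v) < 2L || stats::sd(v) == 0
    }, logical(1))]
    if (length(bad) == 0L || length(occupied) == 1L) break
    b <- bad[1]
    others <- setdiff(occupied, b)
    nb <- others[which.min(abs(others - b))]
    bin[bin == b] <- nb
    merged <- TRUE
  }
  z <- uihs
  for (b in unique(bin)) {
    v <- uihs[bin == b]
    if (length(v) < 2L || stats::sd(v) == 0) {
      z[bin == b] <- NA_real_   # single degenerate bin left: cannot scale
    } else {
      z[bin == b] <- (v - mean(v)) / stats::sd(v)
    }
  }
  list(ihs = z, bin = bin, merged = merged)
}

#' Empirical marginal and joint tail fractions for (Fst, iHS)
#'
#' Given a genome-wide reference distribution of per-SNP (Fst, iHS) pairs,
#' reports the fraction of SNPs at least as differentiated
#' (`Fst >= fst_value`), at least as negative in iHS
#' (`iHS <= ihs_value`), and satisfying both — the empirical p-values of
#' the observed pair. A value more extreme than every entry is reported as
#' 0 with `less_than = 1/N`.
#'
#' @param fst_dist,ihs_dist numeric vectors (the reference distribution;
#'   paired if the joint fraction is wanted).
#' @param fst_value,ihs_value observed values.
#' @return list with `p_fst`, `p_ihs`, `p_joint`, `n`, `less_than`
#'   (resolution bound 1/N).
#' @export
empirical_percentile <- function(fst_dist, ihs_dist, fst_value, ihs_value) {
  stopifnot(length(fst_dist) >= 1L, length(ihs_dist) == length(fst_dist))
  n <- length(fst_dist)
  list(p_fst = mean(fst_dist >= fst_value),
       p_ihs = mean(ihs_dist <= ihs_value),
       p_joint = mean(fst_dist >= fst_value & ihs_dist <= ihs_value),
       n = n, less_than = 1 / n)
}

#' Read an IMPUTE-style hap/legend pair into a panel
#'
#' The legend file has a header and columns `id position allele0 allele1`
#' (optionally `ancestral`); the hap file is a space-separated 0/1 matrix
#' with one row per SNP and one column per haplotype. Alleles are recoded
#' so 0 = ancestral when an `ancestral` column identifies it.
#'
#' @param hap_path,legend_path file paths.
#' @param core_id SNP id (from the legend) of the focal SNP.
#' @return a [hap_panel()].
#' @export
read_hap_legend <- function(hap_path, legend_path, core_id) {
  leg <- utils::read.table(legend_path, header = TRUE, colClasses = "character")
  M <- unname(as.matrix(utils::read.table(hap_path, header = FALSE)))
  if (nrow(M) != nrow(leg)) stop("hap and legend row counts differ")
  if (anyNA(M) || !all(M %in% c(0, 1))) stop("panel must be complete binary 0/1")
  if ("ancestral" %in% names(leg)) {
    flip <- leg$ancestral == leg$allele1
    M[flip, ] <- 1 - M[flip, ]
  }
  core <- match(core_id, leg$id)
  if (is.na(core)) stop(sprintf("core SNP %s not in legend", core_id))
  hap_panel(t(M), as.numeric(leg$position), core)
}
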