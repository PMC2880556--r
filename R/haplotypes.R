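TG_ALLELES <- c("10", "11", "12", "13")
POLYT_ALLELES <- c("5", "7", "9")
M470V_ALLELES <- c("Met", "Val")

hap_label <- function(tg, polyt, m470v) sprintf("TG%s-%sT-%s", tg, polyt, m470v)

check_domains <- function(geno) {
  ok <- all(geno$tg %in% TG_ALLELES) && all(geno$polyt %in% POLYT_ALLELES) &&
    all(geno$m470v %in% M470V_ALLELES)
  if (!ok) stop(sprintf("individual %s: allele outside the (TG)m {10..13} / polyT {5,7,9} / Met,Val domains",
                        geno$individual_id))
  invisible(TRUE)
}

#' Cis pairing of the intron 8 repeat loci
#'
#' The (TG)m and polyT repeats sit on one sequencing amplicon, so each
#' diplotype yields its two cis combinations directly: this operation is a
#' validating pass-through, not an inference. When the amplicon is missing
#' (`intron8_phased = FALSE`) the genotype is flagged unphased at intron 8
#' and downstream phasing must treat the pairing as unknown.
#'
#' @param geno a three-locus genotype record: list with `individual_id`,
#'   `tg` (character pair), `polyt` (character pair), `m470v` (character
#'   pair), `intron8_phased` (logical). When phased, `tg[k]` and
#'   `polyt[k]` are cis.
#' @return list with `phased` (logical) and, when phased, `cis`: a list of
#'   two `c(tg, polyt)` pairs.
#' @export
phase_intron8 <- function(geno) {
  check_domains(geno)
  if (!isTRUE(geno$intron8_phased)) {
    return(list(phased = FALSE, cis = NULL))
  }
  list(phased = TRUE,
       cis = list(c(tg = geno$tg[1], polyt = geno$polyt[1]),
                  c(tg = geno$tg[2], polyt = geno$polyt[2])))
}

# All candidate haplotype-pair assignments consistent with one genotype.
# A pair is an unordered character vector of two "TGx-yT-Z" labels,
# canonicalized by sorting.
candidate_pairs <- function(geno) {
  i8 <- phase_intron8(geno)
  if (i8$phased) {
    cis_options <- list(i8$cis)
  } else {
    # pairing of tg alleles with polyt alleles unknown: enumerate both
    cis_options <- unique(list(
      list(c(tg = geno$tg[1], polyt = geno$polyt[1]),
           c(tg = geno$tg[2], polyt = geno$polyt[2])),
      list(c(tg = geno$tg[1], polyt = geno$polyt[2]),
           c(tg = geno$tg[2], polyt = geno$polyt[1]))))
  }
  out <- list()
  for (cis in cis_options) {
    for (perm in list(c(1L, 2L), c(2L, 1L))) {
      h1 <- hap_label(cis[[1]]["tg"], cis[[1]]["polyt"], geno$m470v[perm[1]])
      h2 <- hap_label(cis[[2]]["tg"], cis[[2]]["polyt"], geno$m470v[perm[2]])
      out[[length(out) + 1L]] <- sort(c(h1, h2))
    }
  }
  unique(out)
}

pair_key <- function(pair) paste(pair, collapse = "|")

# TRUE if candidate pair H of a child can receive one haplotype from a
# parent whose candidate set is `parent_cands` (list of pairs, or NULL =
# unconstrained) and the other from `other_cands`.
transmission_ok <- function(H, parent_cands, other_cands) {
  from <- function(cands, h) {
    is.null(cands) || any(vapply(cands, function(pp) h %in% pp, logical(1)))
  }
  (from(parent_cands, H[1]) && from(other_cands, H[2])) ||
    (from(parent_cands, H[2]) && from(other_cands, H[1]))
}

#' Phase three-locus haplotypes by Mendelian transmission
#'
#' Deterministic, rule-based phasing of the (TG)m-polyT-Met470Val system
#' across a pedigree. Each individual starts with the set of haplotype
#' pairs consistent with its own genotype (homozygosity at Met470Val or
#' identical intron 8 haplotypes force the phase outright). Candidate sets
#' are then pruned by constraint propagation over parent-child links —
#' a candidate is kept only if the trio admits a Mendelian transmission
#' with some candidate of each relative — iterating family-wise until a
#' fixed point. The procedure never guesses: individuals whose candidate
#' set stays larger than one are returned as ambiguous, and a candidate
#' set that empties raises a Mendelian-inconsistency error naming the trio.
#'
#' @param genotypes list of three-locus genotype records (see
#'   [phase_intron8()]); one per individual.
#' @param ped a validated [pedigree][validate_pedigree]. Individuals
#'   without genotypes are simply unconstrained.
#' @return list of class `haplotype_assignments`: per individual a list
#'   with `individual_id`, `resolved` (logical), `pair` (sorted character
#'   pair when resolved), `candidates` (list of consistent pairs).
#' @export
phase_by_pedigree <- function(genotypes, ped) {
  ids <- vapply(genotypes, function(g) as.character(g$individual_id), character(1))
  cands <- lapply(genotypes, candidate_pairs)
  names(cands) <- ids
  fa <- stats::setNames(ped$father, ped$id)
  mo <- stats::setNames(ped$mother, ped$id)
  kids_map <- lapply(stats::setNames(ped$id, ped$id), function(p) {
    ped$id[(!is.na(ped$father) & ped$father == p) |
             (!is.na(ped$mother) & ped$mother == p)]
  })

  get_cands <- function(id) {
    if (is.na(id) || !(id %in% ids)) NULL else cands[[id]]
  }

  repeat {
    changed <- FALSE
    for (i in seq_along(ids)) {
      id <- ids[i]
      kids <- if (id %in% names(kids_map)) kids_map[[id]] else character(0)
      keep <- vapply(cands[[id]], function(H) {
        # as child of its parents
        if (id %in% names(fa) && !transmission_ok(H, get_cands(fa[[id]]), get_cands(mo[[id]]))) {
          return(FALSE)
        }
        # as parent of each genotyped child
        for (k in intersect(kids, ids)) {
          other <- if (!is.na(fa[[k]]) && fa[[k]] == id) mo[[k]] else fa[[k]]
          ok_k <- any(vapply(cands[[k]], function(HK) {
            transmission_ok(HK, list(H), get_cands(other))
          }, logical(1)))
          if (!ok_k) return(FALSE)
        }
        TRUE
      }, logical(1))
      if (!any(keep)) {
        fam <- c(if (id %in% names(fa) && !is.na(fa[[id]])) c(fa[[id]], mo[[id]]),
                 intersect(kids, ids))
        stop(sprintf("Mendelian inconsistency in the family of individual %s%s",
                     id,
                     if (length(fam)) sprintf(" (relatives: %s)", paste(fam, collapse = ", "))
                     else ""))
      }
      if (!all(keep)) {
        cands[[id]] <- cands[[id]][keep]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  # also prune children candidates against now-reduced parents (the loop
  # above already covers this because every individual re-checks its own
  # parent constraint each sweep)
  out <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    cc <- cands[[id]]
    list(individual_id = id,
         resolved = length(cc) == 1L,
         pair = if (length(cc) == 1L) cc[[1]] else NULL,
         candidates = cc)
  })
  class(out) <- "haplotype_assignments"
  out
}

#' @export
print.haplotype_assignments <- function(x, ...) {
  nres <- sum(vapply(x, `[[`, logical(1), "resolved"))
  cat(sprintf("haplotype assignments: %d individuals, %d resolved, %d ambiguous\n",
              length(x), nres, length(x) - nres))
  invisible(x)
}

#' Haplotype frequencies from resolved assignments
#'
#' Counting estimator: each resolved individual contributes two
#' chromosomes; ambiguous individuals are excluded and their count
#' reported.
#'
#' @param assignments output of [phase_by_pedigree()].
#' @return list with `freq` (named numeric, sums to 1), `counts`,
#'   `n_resolved`, `n_ambiguous`.
#' @export
haplotype_frequencies <- function(assignments) {
  resolved <- Filter(function(a) a$resolved, assignments)
  if (length(resolved) == 0L) stop("no resolved haplotype assignments")
  haps <- unlist(lapply(resolved, `[[`, "pair"))
  counts <- table(haps)
  freq <- stats::setNames(as.numeric(counts) / sum(counts), names(counts))
  list(freq = freq,
       counts = counts,
       n_resolved = length(resolved),
       n_ambiguous = length(assignments) - length(resolved))
}

#' Pairwise linkage disequilibrium (D, D', r2) from haplotype frequencies
#'
#' Multi-allelic loci are dichotomized explicitly: the caller states which
#' allele(s) count as "A" at each locus. With `pA`, `pB` the marginal
#' frequencies and `pAB` the haplotype frequency, `D = pAB - pA pB` and
#' `D' = D / Dmax`, where `Dmax = min(pA (1-pB), (1-pA) pB)` for positive
#' `D` and `min(pA pB, (1-pA)(1-pB))` for negative `D`. `|D'| = 1` whenever
#' one of the four dichotomized haplotype classes is absent.
#'
#' @param hap_freqs data frame with one row per haplotype: allele columns
#'   (e.g. `tg`, `polyt`, `m470v`) and a `freq` column, or the `freq`
#'   output of [haplotype_frequencies()] with labels `TGx-yT-Z`.
#' @param locus_a,locus_b column names of the two loci.
#' @param allele_a,allele_b character vectors: the allele value(s)
#'   dichotomized as "A" at each locus.
#' @return list of class `ld_result`: `D`, `D_prime`, `r2`, `pA`, `pB`,
#'   `pAB`, `dichotomization`.
#' @export
d_prime <- function(hap_freqs, locus_a, locus_b, allele_a, allele_b) {
  if (!is.data.frame(hap_freqs)) {
    hap_freqs <- parse_hap_freq(hap_freqs)
  }
  f <- hap_freqs$freq / sum(hap_freqs$freq)
  inA <- hap_freqs[[locus_a]] %in% allele_a
  inB <- hap_freqs[[locus_b]] %in% allele_b
  pA <- sum(f[inA]); pB <- sum(f[inB]); pAB <- sum(f[inA & inB])
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("monomorphic locus under this dichotomization; D' undefined")
  }
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else        min(pA * pB, (1 - pA) * (1 - pB))
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(D = D, D_prime = if (Dmax == 0) 0 else D / Dmax, r2 = r2,
                 pA = pA, pB = pB, pAB = pAB,
                 dichotomization = list(locus_a = allele_a, locus_b = allele_b)),
            class = "ld_result")
}

parse_hap_freq <- function(freq) {
  parts <- strsplit(names(freq), "-")
  data.frame(tg = sub("^TG", "", vapply(parts, `[`, character(1), 1)),
             polyt = sub("T$", "", vapply(parts, `[`, character(1), 2)),
             m470v = vapply(parts, `[`, character(1), 3),
             freq = as.numeric(freq),
             stringsAsFactors = FALSE)
}

#' Read a three-locus genotype CSV
#'
#' Columns: `individual_id, tg1, tg2, polyt1, polyt2, m470v1, m470v2,
#' intron8_phased` (TRUE/FALSE). When `intron8_phased` is TRUE, columns
#' `tg1`/`polyt1` and `tg2`/`polyt2` are cis pairs.
#'
#' @param path CSV path.
#' @return list of genotype records.
#' @export
read_three_locus_genotypes <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         strip.white = TRUE)
  lapply(seq_len(nrow(tab)), function(i) {
    list(individual_id = tab$individual_id[i],
         tg = c(tab$tg1[i], tab$tg2[i]),
         polyt = c(tab$polyt1[i], tab$polyt2[i]),
         m470v = c(tab$m470v1[i], tab$m470v2[i]),
         intron8_phased = toupper(tab$intron8_phased[i]) %in% c("TRUE", "T", "1"))
  })
}
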