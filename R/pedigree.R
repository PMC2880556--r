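#' Validate and topologically sort a pedigree
#'
#' Takes raw pedigree records (one row per individual with parent pointers)
#' and returns a validated `pedigree` object whose individuals are ordered so
#' that every parent precedes all of its children. Founders are individuals
#' with both parent fields missing; an individual with exactly one recorded
#' parent is rejected, as are duplicated ids, parents absent from the table,
#' and ancestry cycles. Each failure mode raises a classed condition so
#' callers can distinguish them (`fertsel_duplicate_id`,
#' `fertsel_missing_parent`, `fertsel_half_founder`, `fertsel_cycle`).
#'
#' @param records data frame with columns `id`, `father`, `mother`, `sex`.
#'   Missing parents are encoded as `NA`, `""` or `"0"`. `sex` uses
#'   `"male"`/`"female"`/`"unknown"` (`1`/`2`/`0` and `"M"`/`"F"` are
#'   accepted and normalized).
#' @return An object of class `pedigree`: a data frame with columns `id`,
#'   `father`, `mother`, `sex`, `founder`, `generation` (1 = founder depth),
#'   sorted in topological order, with attributes `n_founders` and `depth`.
#' @examples
#' trio <- data.frame(id = c("F", "M", "C"), father = c(NA, NA, "F"),
#'                    mother = c(NA, NA, "M"), sex = c("male", "female", "male"))
#' ped <- validate_pedigree(trio)
#' attr(ped, "n_founders") # 2
#' attr(ped, "depth")      # 2
#' @export
validate_pedigree <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("id", "father", "mother")
  if (!all(need %in% names(records))) {
    stop("pedigree records need columns id, father, mother (and optionally sex)")
  }
  id <- as.character(records$id)
  fa <- normalize_parent(records$father)
  mo <- normalize_parent(records$mother)
  sex <- if ("sex" %in% names(records)) normalize_sex(records$sex) else rep("unknown", length(id))

  dup <- id[duplicated(id)]
  if (length(dup) > 0L) {
    stop(condition_ped("fertsel_duplicate_id",
                       sprintf("duplicated individual id(s): %s", paste(unique(dup), collapse = ", "))))
  }
  half <- is.na(fa) != is.na(mo)
  if (any(half)) {
    stop(condition_ped("fertsel_half_founder",
                       sprintf("individual(s) with exactly one recorded parent: %s",
                               paste(id[half], collapse = ", "))))
  }
  known <- c(NA_character_, id)
  bad_fa <- !is.na(fa) & !(fa %in% id)
  bad_mo <- !is.na(mo) & !(mo %in% id)
  if (any(bad_fa | bad_mo)) {
    miss <- unique(c(fa[bad_fa], mo[bad_mo]))
    stop(condition_ped("fertsel_missing_parent",
                       sprintf("parent id(s) not present in pedigree: %s", paste(miss, collapse = ", "))))
  }

  n <- length(id)
  fi <- match(fa, id)          # NA for founders
  mi <- match(mo, id)

  # Kahn's algorithm: peel individuals whose parents are already placed.
  generation <- rep(NA_integer_, n)
  placed <- rep(FALSE, n)
  order_idx <- integer(0)
  repeat {
    ready <- vapply(seq_len(n), function(i) {
      if (placed[i]) return(FALSE)
      okf <- is.na(fi[i]) || placed[fi[i]]
      okm <- is.na(mi[i]) || placed[mi[i]]
      okf && okm
    }, logical(1))
    if (!any(ready)) break
    gen <- vapply(which(ready), function(i) {
      if (is.na(fi[i])) 1L else 1L + max(generation[fi[i]], generation[mi[i]])
    }, integer(1))
    generation[which(ready)] <- gen
    placed[which(ready)] <- TRUE
    order_idx <- c(order_idx, which(ready))
  }
  if (any(!placed)) {
    stop(condition_ped("fertsel_cycle",
                       sprintf("cycle in pedigree involving: %s",
                               paste(id[!placed], collapse = ", "))))
  }

  out <- data.frame(id = id[order_idx],
                    father = fa[order_idx],
                    mother = mo[order_idx],
                    sex = sex[order_idx],
                    founder = is.na(fi[order_idx]),
                    generation = generation[order_idx],
                    stringsAsFactors = FALSE)
  structure(out,
            n_founders = sum(out$founder),
            depth = max(out$generation),
            class = c("pedigree", "data.frame"))
}

condition_ped <- function(class, msg) {
  structure(class = c(class, "fertsel_pedigree_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("", "0", "NA")] <- NA_character_
  x
}

normalize_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("unknown", length(x))
  out[x %in% c("male", "m", "1")] <- "male"
  out[x %in% c("female", "f", "2")] <- "female"
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals, %d founders, depth %d generations\n",
              nrow(x), attr(x, "n_founders"), attr(x, "depth")))
  invisible(x)
}

#' Read / write PED-like pedigree files
#'
#' The accepted dialect is whitespace- or comma-separated columns
#' `id father mother sex` with `0` (or empty) meaning "no parent"; this is
#' the column order of a PLINK `.fam` file after dropping the family id,
#' and files with a header row are detected automatically.
#'
#' @param path file path.
#' @return `read_ped` returns a validated [pedigree][validate_pedigree].
#' @export
read_ped <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("id", first, ignore.case = TRUE)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           colClasses = "character", comment.char = "#",
                           strip.white = TRUE)
  if (!has_header) {
    if (ncol(tab) < 3L) stop("pedigree file needs at least id, father, mother columns")
    names(tab)[seq_len(min(4L, ncol(tab)))] <- c("id", "father", "mother", "sex")[seq_len(min(4L, ncol(tab)))]
  }
  validate_pedigree(tab)
}

#' @param ped a [pedigree][validate_pedigree].
#' @rdname read_ped
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    father = ifelse(is.na(ped$father), "0", ped$father),
                    mother = ifelse(is.na(ped$mother), "0", ped$mother),
                    sex = ped$sex)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Kinship matrix of a pedigree
#'
#' Computes the full matrix of pairwise kinship coefficients
#' \eqn{\phi(i,j)} — the probability that one allele sampled at random from
#' `i` and one from `j` are identical by descent — by the standard recursion
#' over a topological ordering: for a non-founder `i` with parents `f`, `m`
#' and any earlier individual `j`,
#' \eqn{\phi(i,j) = (\phi(f,j) + \phi(m,j))/2}, and
#' \eqn{\phi(i,i) = (1 + \phi(f,m))/2}. Founders are assumed unrelated and
#' non-inbred (\eqn{\phi = 1/2} with themselves, 0 with each other). The
#' additive relationship matrix used by the association covariance is
#' `2 * phi` (diagonal `1 + f`).
#'
#' @param ped a validated [pedigree][validate_pedigree].
#' @return symmetric numeric matrix with dimnames = individual ids, class
#'   `kinship_matrix`.
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      prev <- seq_len(i - 1L)
      row <- 0.5 * (phi[fi[i], prev] + phi[mi[i], prev])
      phi[i, prev] <- row
      phi[prev, i] <- row
      phi[i, i] <- 0.5 * (1 + phi[fi[i], mi[i]])
    }
  }
  structure(phi, class = c("kinship_matrix", class(phi)))
}

#' Inbreeding coefficient of an individual
#'
#' `f_i` is the kinship coefficient of the individual's parents (0 for a
#' founder). Equivalently `phi(i,i) = (1 + f_i)/2`.
#'
#' @param ped a validated pedigree.
#' @param id individual identifier(s); default all.
#' @param phi optional precomputed [kinship_matrix()] to avoid recomputation.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped, id = ped$id, phi = NULL) {
  if (is.null(phi)) phi <- kinship_matrix(ped)
  idx <- match(id, ped$id)
  if (anyNA(idx)) {
    stop(sprintf("unknown individual id(s): %s", paste(id[is.na(idx)], collapse = ", ")))
  }
  stats::setNames(2 * diag(phi)[idx] - 1, id)
}

#' Write a kinship matrix as TSV
#'
#' @param phi a [kinship_matrix()].
#' @param path output file.
#' @param full write the full matrix (default) or the lower triangle in long
#'   form (`id1 id2 phi`).
#' @export
write_kinship <- function(phi, path, full = TRUE) {
  if (full) {
    utils::write.table(cbind(id = rownames(phi), as.data.frame(phi)), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(lower.tri(phi, diag = TRUE), arr.ind = TRUE)
    long <- data.frame(id1 = rownames(phi)[idx[, 1]],
                       id2 = colnames(phi)[idx[, 2]],
                       phi = phi[idx])
    utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Mendelian gene-drop simulation
#'
#' Drops alleles at a single autosomal locus down a fixed pedigree. Founder
#' alleles are either i.i.d. Bernoulli(`p`) draws of allele `1`
#' (`founder_alleles = "binomial"`) or globally unique integer labels
#' (`founder_alleles = "unique"`, useful as a Monte-Carlo oracle for
#' identity-by-descent probabilities: two equal labels are IBD by
#' construction). Each non-founder inherits, independently, one uniformly
#' chosen allele of its father and one of its mother. Allele pairs are kept
#' ordered (paternal, maternal) internally.
#'
#' @param ped a validated pedigree.
#' @param p founder frequency of allele `1` (binomial mode).
#' @param seed integer seed; the drop is reproducible given (`ped`, `p`,
#'   `seed`, `n_rep`).
#' @param n_rep number of independent replicate drops.
#' @param founder_alleles `"binomial"` or `"unique"`.
#' @return object of class `gene_drop`: list with `ids`, `paternal` and
#'   `maternal` (`n x n_rep` matrices of alleles), `p`, `seed`,
#'   `founder_alleles`.
#' @export
gene_drop <- function(ped, p = 0.5, seed = 1L, n_rep = 1L,
                      founder_alleles = c("binomial", "unique")) {
  stopifnot(inherits(ped, "pedigree"), p >= 0, p <= 1, n_rep >= 1)
  founder_alleles <- match.arg(founder_alleles)
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  withr_seed(seed, {
    pat <- matrix(0L, n, n_rep)
    mat <- matrix(0L, n, n_rep)
    founders <- which(is.na(fi))
    if (founder_alleles == "binomial") {
      pat[founders, ] <- stats::rbinom(length(founders) * n_rep, 1L, p)
      mat[founders, ] <- stats::rbinom(length(founders) * n_rep, 1L, p)
    } else {
      lab <- matrix(seq_len(2L * length(founders)), ncol = 2L)
      pat[founders, ] <- lab[, 1L]
      mat[founders, ] <- lab[, 2L]
    }
    for (i in seq_len(n)) {
      if (is.na(fi[i])) next
      pick <- stats::runif(n_rep) < 0.5
      pat[i, ] <- ifelse(pick, pat[fi[i], ], mat[fi[i], ])
      pick <- stats::runif(n_rep) < 0.5
      mat[i, ] <- ifelse(pick, pat[mi[i], ], mat[mi[i], ])
    }
    structure(list(ids = ped$id, paternal = pat, maternal = mat,
                   p = p, seed = seed, founder_alleles = founder_alleles),
              class = "gene_drop")
  })
}

#' Genotype dosage table from a gene drop
#'
#' @param drop a [gene_drop()] in binomial mode.
#' @param rep which replicate to extract.
#' @return data frame `id`, `allele1`, `allele2`, `dosage` (count of allele 1).
#' @export
drop_genotypes <- function(drop, rep = 1L) {
  stopifnot(inherits(drop, "gene_drop"))
  data.frame(id = drop$ids,
             allele1 = drop$paternal[, rep],
             allele2 = drop$maternal[, rep],
             dosage = drop$paternal[, rep] + drop$maternal[, rep],
             stringsAsFactors = FALSE)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
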