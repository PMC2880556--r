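#' Genotype design columns for an association model
#'
#' Builds the design columns implied by a genotype coding scheme from an
#' additive dosage vector `g` (count of the alternate allele, 0/1/2):
#' \describe{
#'   \item{general}{`g` plus heterozygosity indicator `h = 1[g == 1]`
#'     (2 df; all three genotype means free).}
#'   \item{recessive_ref}{carrier indicator `c = 1[g >= 1]` (1 df;
#'     reference-allele homozygotes vs carriers of the alternate allele).}
#'   \item{additive}{`g` alone (1 df).}
#' }
#' Columns that are constant in the sample (e.g. no homozygote class) are
#' dropped with a warning instead of failing: small founder samples
#' routinely lack a genotype class.
#'
#' @param g integer dosage vector in `{0, 1, 2}`.
#' @param scheme one of `"general"`, `"recessive_ref"`, `"additive"`.
#' @return numeric matrix (possibly with fewer columns than the scheme
#'   implies) with attribute `dropped` naming removed columns.
#' @export
genotype_design <- function(g, scheme = c("general", "recessive_ref", "additive")) {
  scheme <- match.arg(scheme)
  stopifnot(all(g %in% 0:2))
  X <- switch(scheme,
              general = cbind(g = g, h = as.numeric(g == 1L)),
              recessive_ref = cbind(c = as.numeric(g >= 1L)),
              additive = cbind(g = g))
  keep <- apply(X, 2L, function(col) stats::var(col) > 0)
  X <- X[, keep, drop = FALSE]
  # with a missing genotype class the h column can duplicate g: drop it too
  if (ncol(X) > 1L && qr(cbind(1, X))$rank < ncol(X) + 1L) {
    X <- X[, 1L, drop = FALSE]
    keep <- c(TRUE, FALSE)
  }
  if (!all(keep)) {
    warning(sprintf("dropping degenerate genotype column(s) under the %s coding",
                    scheme))
  }
  if (ncol(X) == 0L) stop("no non-degenerate genotype column under this coding")
  attr(X, "dropped") <- setdiff(c("g", "h", "c"), colnames(X))
  X
}

#' Polygenic variance components by maximum likelihood
#'
#' Fits the Gaussian model `y ~ N(X beta, 2 Phi sigma2_a + I sigma2_e)` by
#' profiling the likelihood over the variance ratio
#' `gamma = sigma2_a / sigma2_e`. The additive relationship matrix `A = 2
#' Phi` is eigendecomposed once (`A = U D U'`); in the rotated basis the
#' covariance is diagonal, so each candidate `gamma` costs one weighted
#' least-squares fit. The ratio is optimized on the log scale with a
#' boundary check at `gamma = 0` (no polygenic signal).
#'
#' @param y numeric response (complete cases).
#' @param X fixed-effect design matrix (an intercept is added if absent).
#' @param Phi kinship matrix for the same individuals, in the same order.
#' @param eig optional precomputed `eigen(2 * Phi, symmetric = TRUE)`; pass
#'   it when fitting many phenotypes on one pedigree.
#' @return list of class `variance_components`: `sigma2_a`, `sigma2_e`,
#'   `h2` (= sigma2_a / (sigma2_a + sigma2_e)), `loglik`, `converged`,
#'   `eig` (for reuse), `beta` (GLS fixed effects at the optimum).
#' @export
estimate_variance_components <- function(y, X = NULL, Phi = NULL, eig = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (stats::var(y) == 0) stop("response has zero variance; variance components undefined")
  X <- build_design(X, n)
  if (is.null(eig)) {
    stopifnot(!is.null(Phi), nrow(Phi) == n)
    A <- 2 * unclass(Phi)
    eig <- eigen(A, symmetric = TRUE)
    if (min(eig$values) < -1e-8 * max(eig$values)) {
      stop("2*Phi is not positive semidefinite")
    }
    eig$values <- pmax(eig$values, 0)
  }
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  d <- eig$values

  nll <- function(loggamma) {
    g <- exp(loggamma)
    v <- g * d + 1
    fit <- stats::lm.wfit(Xt, yt, w = 1 / v)
    rss <- sum(fit$residuals^2 / v)
    n * log(rss / n) + sum(log(v))
  }
  opt <- stats::optimize(nll, interval = c(-12, 8), tol = 1e-8)
  # boundary: gamma -> 0 (independent residuals)
  nll0 <- {
    fit <- stats::lm.fit(Xt, yt)
    n * log(sum(fit$residuals^2) / n)
  }
  # prefer the boundary on (near-)flat likelihoods: sigma2_a is then
  # unidentifiable and the parsimonious model is no polygenic component
  if (nll0 <= opt$objective + 1e-6 * (abs(nll0) + 1)) {
    gamma <- 0
    obj <- nll0
  } else {
    gamma <- exp(opt$minimum)
    obj <- opt$objective
  }
  v <- gamma * d + 1
  fit <- stats::lm.wfit(Xt, yt, w = 1 / v)
  sigma2_e <- sum(fit$residuals^2 / v) / n
  sigma2_a <- gamma * sigma2_e
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 h2 = sigma2_a / (sigma2_a + sigma2_e),
                 loglik = -0.5 * (obj + n + n * log(2 * pi)),
                 converged = TRUE,
                 gamma = gamma, eig = eig,
                 beta = stats::coef(fit)),
            class = "variance_components")
}

build_design <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  X
}

# Whitening transform W such that W Sigma W' = I, plus transformed y/X.
whiten <- function(y, X, Sigma = NULL, vc = NULL) {
  if (!is.null(Sigma)) {
    R <- chol(Sigma)                      # Sigma = R'R
    list(y = backsolve(R, y, transpose = TRUE),
         X = backsolve(R, X, transpose = TRUE))
  } else {
    stopifnot(inherits(vc, "variance_components"))
    w <- 1 / sqrt(vc$sigma2_a * vc$eig$values + vc$sigma2_e)
    list(y = w * crossprod(vc$eig$vectors, y),
         X = w * crossprod(vc$eig$vectors, as.matrix(X)))
  }
}

#' Relatedness-corrected genotype association by generalized least squares
#'
#' Fits, by GLS under a fixed covariance `Sigma` (or one assembled from
#' estimated [variance components][estimate_variance_components] as
#' `2 Phi sigma2_a + I sigma2_e`), a null model containing the covariates
#' only and an alternative model that adds the genotype design columns of
#' the requested coding. Significance is an F-statistic on the whitened
#' scale,
#' `F = [(RSS0 - RSS1)/q] / [RSS1/(n - p1)]`,
#' with `q` genotype columns and `p1` columns in the alternative design.
#' When `Sigma` is proportional to the identity the fit, F and p-value
#' coincide with ordinary least squares.
#'
#' @param y numeric response.
#' @param X_cov covariate matrix (may be `NULL`; an intercept is always
#'   included). Pass the residualized phenotype with `X_cov = NULL` to
#'   reproduce a residual-first analysis.
#' @param g additive dosage vector (0/1/2 copies of the alternate allele).
#' @param scheme genotype coding, see [genotype_design()].
#' @param Sigma full covariance matrix, or `NULL` to use `vc`.
#' @param vc a `variance_components` object (from the null model) holding
#'   the eigendecomposition of `2 Phi`; preferred for repeated fits.
#' @param n_tests number of tests for the Bonferroni correction report.
#' @param alleles length-2 character vector naming the reference and
#'   alternate allele (used only to label the effect direction).
#' @return object of class `assoc_result`: list with `scheme`, `beta`,
#'   `se`, `F`, `df1`, `df2`, `p_value`, `p_bonferroni`,
#'   `pct_variance_explained`, `RSS_null`, `RSS_alt`, `n`,
#'   `lower_fertility_allele`.
#' @export
gls_association <- function(y, X_cov, g, scheme = "general",
                            Sigma = NULL, vc = NULL, n_tests = 1L,
                            alleles = c("ref", "alt")) {
  y <- as.numeric(y)
  n <- length(y)
  G <- genotype_design(g, scheme)
  X0 <- build_design(X_cov, n)
  X1 <- cbind(X0, G)
  qrX1 <- qr(X1)
  if (qrX1$rank < ncol(X1)) stop("genotype columns collinear with covariates")
  w <- whiten(y, X1, Sigma, vc)
  p0 <- ncol(X0)
  fit0 <- stats::lm.fit(w$X[, seq_len(p0), drop = FALSE], w$y)
  fit1 <- stats::lm.fit(w$X, w$y)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  q <- ncol(G)
  df2 <- n - ncol(X1)
  Fstat <- ((rss0 - rss1) / q) / (rss1 / df2)
  p <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
  XtX_inv <- chol2inv(qr.R(qr(w$X)))
  sigma2 <- rss1 / df2
  se <- sqrt(diag(XtX_inv) * sigma2)
  beta <- stats::setNames(fit1$coefficients, colnames(X1))
  se <- stats::setNames(se, colnames(X1))
  gcol <- colnames(G)[1]
  bdir <- beta[[gcol]]
  lower <- if (is.na(bdir)) NA_character_ else if (bdir > 0) alleles[1] else alleles[2]
  structure(list(scheme = scheme,
                 beta = beta, se = se,
                 F = Fstat, df1 = q, df2 = df2,
                 p_value = p,
                 p_bonferroni = bonferroni(p, n_tests),
                 pct_variance_explained = percent_variance(rss0, rss1),
                 RSS_null = rss0, RSS_alt = rss1, n = n,
                 lower_fertility_allele = lower,
                 dropped_columns = attr(G, "dropped")),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s coding: F(%d, %d) = %.3f, p = %.4g (Bonferroni %.4g), %.2f%% variance\n",
              x$scheme, x$df1, x$df2, x$F, x$p_value, x$p_bonferroni,
              x$pct_variance_explained))
  invisible(x)
}

#' Percent phenotypic variance explained by a locus
#'
#' `100 * (RSS_null - RSS_alt) / RSS_null`, the reduction in residual sum
#' of squares when genotype terms enter the model.
#'
#' @param RSS_null,RSS_alt residual sums of squares of the nested fits.
#' @return percentage in `[0, 100]`.
#' @export
percent_variance <- function(RSS_null, RSS_alt) {
  stopifnot(RSS_null > 0)
  if (RSS_alt > RSS_null * (1 + 1e-12)) stop("RSS_alt exceeds RSS_null: models not nested")
  100 * (RSS_null - min(RSS_alt, RSS_null)) / RSS_null
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param n_tests number of tests.
#' @return `min(1, p * n_tests)`.
#' @export
bonferroni <- function(p, n_tests) {
  stopifnot(all(p >= 0 & p <= 1), n_tests >= 1)
  pmin(1, p * n_tests)
}

#' Measured-genotype additive association with a Wald t-test
#'
#' The replication-style analysis: a polygenic random effect is estimated
#' under the null (covariates-only) model, the additive dosage enters the
#' GLS fit, and significance is the two-sided t-test of its coefficient.
#' With `Sigma = I` (no relatedness) this is the ordinary regression
#' t-test.
#'
#' @inheritParams gls_association
#' @param Phi kinship matrix (ignored when `vc` is supplied).
#' @return `assoc_result` with fields `t`, `df`, `p_value`, `beta`, `se`.
#' @export
wald_t_additive <- function(y, X_cov, g, Phi = NULL, vc = NULL,
                            n_tests = 1L, alleles = c("ref", "alt")) {
  y <- as.numeric(y)
  n <- length(y)
  X0 <- build_design(X_cov, n)
  if (is.null(vc)) {
    vc <- estimate_variance_components(y, X0, Phi)
  }
  X1 <- cbind(X0, g = as.numeric(g))
  w <- whiten(y, X1, vc = vc)
  fit <- stats::lm.fit(w$X, w$y)
  df <- n - ncol(X1)
  rss <- sum(fit$residuals^2)
  XtX_inv <- chol2inv(qr.R(qr(w$X)))
  se <- sqrt(diag(XtX_inv) * rss / df)
  beta <- fit$coefficients
  k <- ncol(X1)
  tstat <- beta[k] / se[k]
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(list(scheme = "additive",
                 beta = stats::setNames(beta, colnames(X1)),
                 se = stats::setNames(se, colnames(X1)),
                 t = unname(tstat), df = df, p_value = unname(p),
                 p_bonferroni = bonferroni(unname(p), n_tests),
                 vc = vc[c("sigma2_a", "sigma2_e", "h2")],
                 n = n,
                 lower_fertility_allele = if (beta[k] > 0) alleles[1] else alleles[2]),
            class = "assoc_result")
}

#' Translate a per-year effect into a births deficit over a reproductive span
#'
#' @param per_year_effect effect size in births per year of marriage (sign
#'   ignored).
#' @param mean_reproductive_years average reproductive span in years.
#' @return absolute births deficit, rounded to 2 decimals.
#' @examples
#' effect_summary(0.049, 11.5)  # 0.56
#' @export
effect_summary <- function(per_year_effect, mean_reproductive_years) {
  stopifnot(is.finite(per_year_effect), is.finite(mean_reproductive_years))
  round(abs(per_year_effect) * mean_reproductive_years, 2)
}

#' Association scan over several loci and codings
#'
#' Runs [gls_association()] for each locus/coding combination on a shared
#' covariance model (variance components estimated once under the null),
#' producing a summary table with one row per test: locus, coding, the
#' allele associated with lower fertility, F, p, Bonferroni-corrected p and
#' percent variance explained.
#'
#' @param y response vector.
#' @param X_cov covariate matrix.
#' @param geno_list named list of dosage vectors (one per locus).
#' @param schemes character vector of codings to run at each locus.
#' @param Phi kinship matrix.
#' @param n_tests total number of tests for the Bonferroni correction
#'   (default: number of rows in the scan).
#' @param alleles named list mapping locus -> c(ref, alt) labels.
#' @param per_locus_correction hook applied to each raw p-value before the
#'   Bonferroni step, for methods that additionally correct within a locus
#'   (e.g. for the number of codings examined there). The default is the
#'   identity: no within-locus correction is applied, and the cross-locus
#'   Bonferroni is the only multiplicity adjustment.
#' @return data frame, plus attribute `vc` (the shared variance components).
#' @export
association_scan <- function(y, X_cov, geno_list, schemes = c("general", "recessive_ref"),
                             Phi, n_tests = NULL, alleles = NULL,
                             per_locus_correction = identity) {
  X0 <- build_design(X_cov, length(y))
  vc <- estimate_variance_components(y, X0, Phi)
  combos <- expand.grid(locus = names(geno_list), scheme = schemes,
                        stringsAsFactors = FALSE)
  if (is.null(n_tests)) n_tests <- nrow(combos)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    loc <- combos$locus[i]
    al <- if (!is.null(alleles) && loc %in% names(alleles)) alleles[[loc]] else c("ref", "alt")
    r <- gls_association(y, X_cov, geno_list[[loc]], combos$scheme[i],
                         vc = vc, n_tests = n_tests, alleles = al)
    p_loc <- per_locus_correction(r$p_value)
    data.frame(locus = loc, scheme = r$scheme,
               lower_fertility_allele = r$lower_fertility_allele,
               F = r$F, df1 = r$df1, df2 = r$df2,
               p_value = p_loc, p_bonferroni = bonferroni(p_loc, n_tests),
               pct_variance_explained = r$pct_variance_explained,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "vc") <- vc
  out
}
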