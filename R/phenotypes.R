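#' Birth-rate phenotype from a reproductive history
#'
#' Birth rate is defined as (number of births - 1) divided by the sum of the
#' interbirth intervals; since consecutive intervals telescope, the
#' denominator equals the span from first to last birth. Only men with at
#' least two births are phenotyped: a history with fewer births (or with all
#' births in the same instant, e.g. a single twin pair) yields an exclusion
#' record rather than an error, so that cohort construction can simply
#' filter on `excluded`.
#'
#' @param history a list or one-row data frame with fields `individual_id`,
#'   `marriage_year`, `wife_birth_year`, `birth_years` (numeric vector of
#'   decimal years, sorted non-decreasing), `observation_end`.
#' @return list of class `birth_rate` with `individual_id`, `n_births`,
#'   `rate` (births per year), `span` (first-to-last-birth years),
#'   `excluded` (logical) and `exclusion_reason`.
#' @examples
#' h <- list(individual_id = "a", marriage_year = 1989, wife_birth_year = 1968,
#'           birth_years = c(1990, 1992, 1996), observation_end = 2005)
#' birth_rate(h)$rate  # (3 - 1) / (1996 - 1990) = 0.333...
#' @export
birth_rate <- function(history) {
  by <- sort(as.numeric(history$birth_years))
  n <- length(by)
  res <- list(individual_id = history$individual_id, n_births = n,
              rate = NA_real_, span = NA_real_,
              excluded = FALSE, exclusion_reason = NA_character_)
  if (n < 2L) {
    res$excluded <- TRUE
    res$exclusion_reason <- "fewer than two births"
  } else {
    span <- sum(diff(by))            # telescopes to last - first
    stopifnot(isTRUE(all.equal(span, by[n] - by[1])))
    if (span <= 0) {
      res$excluded <- TRUE
      res$exclusion_reason <- "zero total interbirth span"
    } else {
      res$rate <- (n - 1) / span
      res$span <- span
    }
  }
  class(res) <- "birth_rate"
  res
}

#' Build the phenotype table for a set of reproductive histories
#'
#' Applies [birth_rate()] to each history and assembles the covariates used
#' downstream: wife's birth year and the number of years from marriage to
#' last birth.
#'
#' @param histories list of histories (see [birth_rate()]).
#' @return data frame with one row per history: `individual_id`, `n_births`,
#'   `rate`, `wife_birth_year`, `marriage_to_last_birth`, `excluded`,
#'   `exclusion_reason`. Rows with `excluded = TRUE` carry `NA` phenotype.
#' @export
phenotype_table <- function(histories) {
  rows <- lapply(histories, function(h) {
    br <- birth_rate(h)
    by <- sort(as.numeric(h$birth_years))
    data.frame(individual_id = as.character(h$individual_id),
               n_births = br$n_births,
               rate = br$rate,
               wife_birth_year = as.numeric(h$wife_birth_year),
               marriage_to_last_birth = if (br$n_births >= 1L)
                 by[length(by)] - as.numeric(h$marriage_year) else NA_real_,
               excluded = br$excluded,
               exclusion_reason = br$exclusion_reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Residualize birth rate on its covariates
#'
#' Ordinary least-squares regression of the rate on wife's birth year and
#' years from marriage to last birth (or any covariate matrix supplied);
#' returns the residuals, which by construction have mean zero and are
#' orthogonal to every covariate column.
#'
#' @param phenos phenotype table from [phenotype_table()], or a numeric
#'   vector of rates when `covariates` is given.
#' @param covariates optional numeric matrix/data frame of covariates; by
#'   default taken from the `wife_birth_year` and `marriage_to_last_birth`
#'   columns of `phenos`.
#' @return list with `residual` (named by individual where available),
#'   `fit` (the `lm` object), `n_used`.
#' @export
residualize <- function(phenos, covariates = NULL) {
  if (is.data.frame(phenos) && is.null(covariates)) {
    keep <- !phenos$excluded & stats::complete.cases(
      phenos[, c("rate", "wife_birth_year", "marriage_to_last_birth")])
    y <- phenos$rate[keep]
    X <- as.matrix(phenos[keep, c("wife_birth_year", "marriage_to_last_birth")])
    ids <- phenos$individual_id[keep]
  } else {
    y <- as.numeric(phenos)
    X <- as.matrix(covariates)
    ids <- names(phenos)
  }
  # constant columns carry no information beyond the intercept: drop them
  informative <- apply(X, 2L, function(col) stats::var(col) > 0)
  X <- X[, informative, drop = FALSE]
  if (ncol(X) > 0L && qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("rank-deficient covariate matrix")
  }
  fit <- if (ncol(X) == 0L) stats::lm(y ~ 1) else stats::lm(y ~ X)
  r <- stats::setNames(stats::residuals(fit), ids)
  list(residual = r, fit = fit, n_used = length(y))
}

#' Normality diagnostics for phenotype residuals
#'
#' Advisory check that the residuals are compatible with the Gaussian
#' working model of the association test: reports moments and a
#' Shapiro-Wilk p-value. Never blocks the pipeline.
#'
#' @param residuals numeric vector, n >= 20 for the test to be meaningful.
#' @return list with `n`, `skewness`, `kurtosis` (excess), `shapiro_p`,
#'   `degenerate` (TRUE when the input has zero variance, in which case the
#'   test statistics are NA).
#' @export
normality_check <- function(residuals) {
  x <- residuals[is.finite(residuals)]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) {
    return(list(n = n, skewness = NA_real_, kurtosis = NA_real_,
                shapiro_p = NA_real_, degenerate = TRUE))
  }
  z <- (x - mean(x)) / stats::sd(x)
  sw <- stats::shapiro.test(if (n > 5000) sample(x, 5000) else x)
  list(n = n,
       skewness = mean(z^3),
       kurtosis = mean(z^4) - 3,
       shapiro_p = sw$p.value,
       degenerate = FALSE)
}

#' Read reproductive histories from CSV
#'
#' Expected columns: `individual_id`, `marriage_year`, `wife_birth_year`,
#' `birth_years` (semicolon-separated decimal years), `observation_end`.
#'
#' @param path CSV file path.
#' @return list of history records suitable for [birth_rate()].
#' @export
read_reproductive_history <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         strip.white = TRUE)
  lapply(seq_len(nrow(tab)), function(i) {
    list(individual_id = tab$individual_id[i],
         marriage_year = as.numeric(tab$marriage_year[i]),
         wife_birth_year = as.numeric(tab$wife_birth_year[i]),
         birth_years = as.numeric(strsplit(tab$birth_years[i], ";")[[1]]),
         observation_end = as.numeric(tab$observation_end[i]))
  })
}

#' @rdname read_reproductive_history
#' @param histories list of history records.
#' @export
write_reproductive_history <- function(histories, path) {
  tab <- do.call(rbind, lapply(histories, function(h) {
    data.frame(individual_id = h$individual_id,
               marriage_year = h$marriage_year,
               wife_birth_year = h$wife_birth_year,
               birth_years = paste(h$birth_years, collapse = ";"),
               observation_end = h$observation_end)
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
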