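#' Time from marriage to the kth birth, with censoring
#'
#' Builds the survival record used for the time-to-kth-birth comparison:
#' men with at least `k` births contribute the interval from marriage to
#' the kth birth as an event; men with fewer births are censored at their
#' last birth. A history with zero births is flagged as excluded.
#'
#' @param history reproductive history record (see [birth_rate()]).
#' @param k birth order of interest (>= 1).
#' @param group optional group label (e.g. genotype) carried through.
#' @return list with `individual_id`, `time`, `event` (1 = reached kth
#'   birth, 0 = censored), `group`, `excluded`.
#' @export
time_to_kth_birth <- function(history, k, group = NA_character_) {
  stopifnot(k >= 1)
  by <- sort(as.numeric(history$birth_years))
  n <- length(by)
  if (n == 0L) {
    return(list(individual_id = history$individual_id, time = NA_real_,
                event = NA_integer_, group = group, excluded = TRUE))
  }
  if (n >= k) {
    time <- by[k] - history$marriage_year
    event <- 1L
  } else {
    time <- by[n] - history$marriage_year
    event <- 0L
  }
  list(individual_id = history$individual_id, time = time, event = event,
       group = group, excluded = FALSE)
}

records_frame <- function(records) {
  if (is.data.frame(records)) return(records)
  do.call(rbind, lapply(records, function(r) {
    data.frame(individual_id = as.character(r$individual_id), time = r$time,
               event = r$event, group = as.character(r$group),
               stringsAsFactors = FALSE)
  }))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate `S(t) = prod over event times <= t of
#' (1 - d_t / n_t)`. The standard tie convention applies: individuals
#' censored at an event time are still at risk at that time.
#'
#' @param records list of [time_to_kth_birth()] records, or a data frame
#'   with columns `time` and `event`.
#' @return data frame of class `survival_curve`: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (one row per distinct observed time).
#' @export
km_curve <- function(records) {
  tab <- records_frame(records)
  stopifnot(nrow(tab) >= 1L, all(tab$time > 0))
  fit <- survival::survfit(survival::Surv(tab$time, tab$event) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Log-rank test between genotype groups
#'
#' Standard log-rank chi-square with hypergeometric variance at each event
#' time; df = number of groups - 1. Observed minus expected event counts
#' sum to zero across groups.
#'
#' @param records records with a `group` field (>= 2 groups).
#' @return list of class `log_rank_result`: `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` (named per group).
#' @export
log_rank <- function(records) {
  tab <- records_frame(records)
  groups <- unique(tab$group)
  if (length(groups) < 2L) stop("log-rank needs at least two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = tab)
  chi <- unname(sd$chisq)
  df <- length(sd$n) - 1L
  structure(list(chi_square = chi, df = df,
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE),
                 observed = stats::setNames(as.numeric(sd$obs), names(sd$n)),
                 expected = stats::setNames(as.numeric(sd$exp), names(sd$n))),
            class = "log_rank_result")
}

#' Wilcoxon rank-sum comparison of completed family sizes
#'
#' Exact enumeration when the combined sample size is at most 12 (and the
#' data are tie-free); otherwise the tie-corrected normal approximation.
#'
#' @param counts_a,counts_b numeric vectors (e.g. numbers of children).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `statistic` (rank-sum W for group A), `p_value`,
#'   `exact` (logical: was the exact distribution used).
#' @export
wilcoxon_rank_sum <- function(counts_a, counts_b, alternative = "two.sided") {
  stopifnot(length(counts_a) >= 1L, length(counts_b) >= 1L)
  n <- length(counts_a) + length(counts_b)
  ties <- anyDuplicated(c(counts_a, counts_b)) > 0L
  use_exact <- n <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(counts_a, counts_b, alternative = alternative,
                       exact = use_exact, correct = !use_exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}

#' Mean years from marriage to each birth, by group
#'
#' Descriptive summary of cumulative reproduction: for each birth order
#' `b <= max_birth` and each group, the mean and standard error of
#' (bth birth year - marriage year) among men with at least `b` births.
#' A group/order cell with a single contributor reports `se = 0` and is
#' flagged degenerate.
#'
#' @param histories list of reproductive histories.
#' @param groups character vector of group labels, one per history.
#' @param max_birth highest birth order summarized.
#' @return data frame `group`, `birth_order`, `n`, `mean_years`, `se`,
#'   `degenerate_se`.
#' @export
cumulative_birth_summary <- function(histories, groups, max_birth) {
  stopifnot(length(histories) == length(groups))
  rows <- list()
  for (g in unique(groups)) {
    hs <- histories[groups == g]
    for (b in seq_len(max_birth)) {
      times <- vapply(hs, function(h) {
        by <- sort(as.numeric(h$birth_years))
        if (length(by) >= b) by[b] - h$marriage_year else NA_real_
      }, numeric(1))
      times <- times[!is.na(times)]
      if (length(times) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, birth_order = b, n = length(times),
        mean_years = mean(times),
        se = if (length(times) > 1L) stats::sd(times) / sqrt(length(times)) else 0,
        degenerate_se = length(times) < 2L)
    }
  }
  do.call(rbind, rows)
}

#' Filter histories to long-married men
#'
#' Keeps histories whose marriage-to-last-birth span is at least the given
#' threshold; by default the threshold is recomputed as the sample mean of
#' that span, the cohort-derived cut used for comparing completed family
#' sizes.
#'
#' @param histories list of reproductive histories.
#' @param threshold years; `NULL` (default) = sample mean span.
#' @return list with `histories` (the kept subset), `threshold`, `kept`
#'   (logical index).
#' @export
filter_long_married <- function(histories, threshold = NULL) {
  spans <- vapply(histories, function(h) {
    by <- sort(as.numeric(h$birth_years))
    if (length(by) >= 1L) by[length(by)] - h$marriage_year else NA_real_
  }, numeric(1))
  if (is.null(threshold)) threshold <- mean(spans, na.rm = TRUE)
  kept <- !is.na(spans) & spans >= threshold
  list(histories = histories[kept], threshold = threshold, kept = kept)
}
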