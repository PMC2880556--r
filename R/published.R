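#' Reference summary statistics for the CFTR Met470Val fertility system
#'
#' Printed cohort-level summaries from the published Hutterite/Amish
#' CFTR Met470Val fertility study, used as simulation targets and worked
#' inputs throughout the package (the individual-level data are private).
#' Components:
#' \describe{
#'   \item{hutterite}{`n` genotyped men; genotype counts at Met470Val
#'     (`n_val_val`, `n_met_val`, `n_met_met`); locus allele frequencies;
#'     association p-values for the general (model 1) and
#'     Met/Met-vs-carrier (model 2) codings with `n_tests` for the
#'     Bonferroni correction and the percent variance explained;
#'     the recessive deficit in births/yr and the mean +/- SD reproductive
#'     span in years.}
#'   \item{haplotype_freq}{three-locus (TG)m-polyT-Met470Val haplotype
#'     frequencies (sum to 1).}
#'   \item{amish}{replication cohort: per-genotype counts and mean (SD)
#'     birth rates; Val allele frequency.}
#'   \item{hapmap}{CEU/YRI derived (Val) allele frequencies, the
#'     CEU-vs-YRI Fst, the CEU iHS at the locus, and the genome-wide joint
#'     tail fraction of SNPs at least as extreme in both.}
#' }
#' @format a named list.
#' @export
cftr_summary <- list(
  hutterite = list(
    n = 204L,
    n_val_val = 14L, n_met_val = 89L, n_met_met = 101L,
    val_freq = 0.29,
    allele_freq = list(tg = c("10" = 0.52, "11" = 0.43, "12" = 0.05),
                       polyt = c("5" = 0.00, "7" = 0.91, "9" = 0.09),
                       m470v = c(Met = 0.71, Val = 0.29)),
    p_model1 = 0.0096, p_model2 = 0.0029,
    pct_var_model1 = 4.59, pct_var_model2 = 4.36,
    n_tests = 4L,
    recessive_deficit = 0.049,
    span_mean = 11.5, span_sd = 5.0,
    median_family_size = 6L
  ),
  haplotype_freq = c("TG10-7T-Met" = 0.45, "TG11-7T-Met" = 0.15,
                     "TG12-7T-Met" = 0.03, "TG10-9T-Met" = 0.08,
                     "TG11-9T-Met" = 0.01, "TG11-7T-Val" = 0.26,
                     "TG12-7T-Val" = 0.02),
  amish = list(
    n = 315L, val_freq = 0.65,
    genotype_n = c(met_met = 37L, met_val = 147L, val_val = 131L),
    mean_rate = c(met_met = 0.46, met_val = 0.50, val_val = 0.49),
    sd_rate = c(met_met = 0.13, met_val = 0.14, val_val = 0.17)
  ),
  hapmap = list(
    ceu_val_freq = 0.51, yri_val_freq = 0.0,
    fst_ceu_yri = 0.43, ihs_ceu = -1.93,
    joint_tail_fraction = 0.003
  )
)
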