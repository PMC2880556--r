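#!/usr/bin/env Rscript
# Stage 5: selection-signature statistics on the haplotype panel and
# two-population allele counts.
#
# EHH decay on each allelic background of the core SNP, integrated EHH and
# the unstandardized iHS (negative = derived haplotypes longer), a
# standardized iHS for the core against a neutral reference distribution,
# Weir-Cockerham theta for simulated two-population counts at the reference
# frequencies (0.51 vs 0), and the empirical (Fst, iHS) percentiles.

library(fertsel)

seed <- 1L
panel <- read_hap_legend("results/inputs/panel.hap", "results/inputs/panel.legend",
                         sprintf("snp%05d", 501))

curves <- do.call(rbind, lapply(c(0, 1), function(allele) {
  do.call(rbind, lapply(c("upstream", "downstream"), function(dir) {
    cv <- ehh(panel, allele, dir)
    data.frame(background = if (allele == 1) "derived" else "ancestral",
               direction = dir, distance = cv$distance, ehh = cv$ehh)
  }))
}))
write_tsv_provenance(curves, "results/ehh_curves.tsv", seed)
half <- subset(curves, background == "derived" & ehh < 0.5)
cat(sprintf("derived EHH drops below 0.5 at ~%d kb; ancestral at ~%d kb\n",
            round(min(half$distance) / 1000),
            round(min(subset(curves, background == "ancestral" &
                               ehh < 0.5)$distance) / 1000)))

core <- ihs_unstandardized(panel)
cat(sprintf("core uiHS = %.2f (iHH ancestral %.0f, derived %.0f)\n",
            core$uihs, core$ihh_a, core$ihh_d))

# neutral reference distribution of uiHS at matched frequency for
# standardization, from exchangeable (tract-free) panels
neut <- vapply(1:60, function(s) {
  p <- simulate_sweep_panel(sweep_panel_config(sweep_tract_bp = 0,
                                               seed = seed + 9000L + s))
  ihs_unstandardized(p)$uihs
}, numeric(1))
st <- standardize_ihs(c(core$uihs, neut),
                      c(core$derived_freq, rep(0.5, 60)), bins = 1)
cat(sprintf("standardized iHS of the core against the neutral reference: %.2f\n",
            st$ihs[1]))

cts <- simulate_two_pop_counts(cftr_summary$hapmap$ceu_val_freq,
                               cftr_summary$hapmap$yri_val_freq,
                               n1 = 120, n2 = 120, seed = seed + 13L)
th <- weir_cockerham_theta(cts$n1, cts$x1, cts$n2, cts$x2)
cat(sprintf("two-population theta at frequencies %.2f vs %.2f (n = 120 + 120 chromosomes): %.2f\n",
            cftr_summary$hapmap$ceu_val_freq, cftr_summary$hapmap$yri_val_freq,
            th$theta))

write_tsv_provenance(
  data.frame(statistic = c("uihs_core", "ihs_standardized", "theta_two_pop",
                           "derived_core_freq"),
             value = c(core$uihs, st$ihs[1], th$theta, core$derived_freq)),
  "results/selection.tsv", seed)
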