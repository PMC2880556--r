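#!/usr/bin/env Rscript
# Stage 1: build the synthetic study cohort.
#
# Generates a 13-generation consanguineous pedigree tracing to 62 founders,
# drops a biallelic locus through it at the cohort's derived-allele
# frequency (0.29), and simulates reproductive histories in which
# reference-allele homozygotes suffer a 0.049 births/yr deficit on top of a
# polygenic background (h2 = 0.3). All downstream stages read the files
# written here.

library(fertsel)

seed <- 1L
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)

ped <- simulate_pedigree(pedigree_sim_config(seed = seed))
cat(sprintf("pedigree: %d individuals, %d founders, depth %d\n",
            nrow(ped), attr(ped, "n_founders"), attr(ped, "depth")))
f <- inbreeding(ped)
cat(sprintf("inbred fraction: %.2f, mean f among inbred: %.4f\n",
            mean(f > 0), mean(f[f > 0])))
write_ped(ped, "results/inputs/cohort.ped")

geno <- drop_genotypes(gene_drop(ped, p = 0.29, seed = seed + 101L))
write.csv(geno, "results/inputs/m470v_dosage.csv", row.names = FALSE,
          quote = FALSE)

sim <- simulate_fertility(ped, geno, fertility_sim_config(seed = seed))
write_reproductive_history(sim$histories, "results/inputs/histories.csv")
cat(sprintf("phenotyped men: %d; mean latent rate %.3f births/yr\n",
            length(sim$histories), mean(sim$truth$latent_rate)))

hap <- simulate_three_locus_genotypes(cftr_summary$haplotype_freq,
                                      seed = seed + 202L, ped = ped)
tab <- do.call(rbind, lapply(hap$genotypes, function(g) {
  data.frame(individual_id = g$individual_id, tg1 = g$tg[1], tg2 = g$tg[2],
             polyt1 = g$polyt[1], polyt2 = g$polyt[2],
             m470v1 = g$m470v[1], m470v2 = g$m470v[2],
             intron8_phased = g$intron8_phased)
}))
write.csv(tab, "results/inputs/three_locus_genotypes.csv", row.names = FALSE,
          quote = FALSE)

panel <- simulate_sweep_panel(sweep_panel_config(seed = seed + 303L))
write_hap_legend(panel, "results/inputs/panel.hap", "results/inputs/panel.legend")
cat(sprintf("sweep panel: %d haplotypes x %d SNPs, derived core freq %.2f\n",
            nrow(panel$haplotypes), ncol(panel$haplotypes), panel$derived_freq))
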