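#' Configuration constructors for the synthetic-data generators
#'
#' Defaults emulate the study population the pipeline is designed for: a
#' deep consanguineous founder population (13 generations tracing to 62
#' founders, with frequent remote-cousin unions), a birth-rate phenotype
#' centred near 0.5 births per year with a recessive deficit of 0.049
#' births/yr at a derived-allele frequency of 0.29, reproductive spans of
#' 11.5 +/- 5 years, and 1 Mb haplotype panels at 1 kb marker spacing.
#'
#' @param n_generations,n_founders pedigree depth and founder count.
#' @param mean_sibship mean number of children per couple (Poisson).
#' @param cousin_mating_prob probability that a mate is deliberately drawn
#'   from related (but not first-degree) candidates; 0 forbids all
#'   consanguinity.
#' @param max_couples cap on couples formed per generation (keeps the
#'   population size in the low thousands at depth 13).
#' @param seed integer seed.
#' @name sim_configs
#' @export
pedigree_sim_config <- function(n_generations = 13, n_founders = 62,
                                mean_sibship = 3, cousin_mating_prob = 0.3,
                                max_couples = 60, seed = 1L) {
  stopifnot(n_generations >= 2, n_founders >= 4,
            cousin_mating_prob >= 0, cousin_mating_prob <= 1)
  list(n_generations = n_generations, n_founders = n_founders,
       mean_sibship = mean_sibship, cousin_mating_prob = cousin_mating_prob,
       max_couples = max_couples, seed = seed)
}

#' @param snp_allele_freq founder frequency of the derived allele.
#' @param effect_model `"recessive"`, `"additive"` or `"general"`.
#' @param deficit recessive deficit (births/yr) suffered by
#'   reference-homozygous men; ignored for other models.
#' @param beta additive per-allele effect (births/yr).
#' @param genotype_means length-3 vector of genotype effects for the
#'   general model (dosage 0, 1, 2).
#' @param mu baseline birth rate (births/yr).
#' @param h2 polygenic heritability of the rate residual.
#' @param residual_sd total SD of the polygenic + environmental residual.
#' @param slope_wife_year,slope_span covariate slopes entering the latent
#'   rate (per year).
#' @param span_mean,span_sd marriage-duration distribution (years).
#' @param gamma_shape shape of the Gamma interbirth-interval distribution
#'   (mean is always 1/rate).
#' @param wife_year_sd SD of wife's birth year around husband's.
#' @param n_men number of phenotyped men sampled from the pedigree.
#' @rdname sim_configs
#' @export
fertility_sim_config <- function(snp_allele_freq = 0.29,
                                 effect_model = c("recessive", "additive", "general"),
                                 deficit = 0.049, beta = 0.03,
                                 genotype_means = c(-0.049, 0, 0),
                                 mu = 0.5, h2 = 0.3, residual_sd = 0.15,
                                 slope_wife_year = 0.002, slope_span = -0.005,
                                 span_mean = 11.5, span_sd = 5,
                                 gamma_shape = 4, wife_year_sd = 2,
                                 n_men = 204, seed = 1L) {
  effect_model <- match.arg(effect_model)
  stopifnot(h2 >= 0, h2 < 1, residual_sd > 0, span_mean > 0)
  list(snp_allele_freq = snp_allele_freq, effect_model = effect_model,
       deficit = deficit, beta = beta, genotype_means = genotype_means,
       mu = mu, h2 = h2, residual_sd = residual_sd,
       slope_wife_year = slope_wife_year, slope_span = slope_span,
       span_mean = span_mean, span_sd = span_sd, gamma_shape = gamma_shape,
       wife_year_sd = wife_year_sd, n_men = n_men, seed = seed)
}

#' @param n_hap,n_snp panel dimensions.
#' @param derived_core_freq frequency of the derived core allele.
#' @param sweep_tract_bp length of the shared tract around the core on the
#'   derived background (0 = neutral panel).
#' @param mutation_noise_per_site per-site probability that a derived
#'   haplotype deviates from the sweep template inside the tract.
#' @param spacing_bp marker spacing.
#' @rdname sim_configs
#' @export
sweep_panel_config <- function(n_hap = 120, n_snp = 1001,
                               derived_core_freq = 0.5,
                               sweep_tract_bp = 6e5,
                               mutation_noise_per_site = 1.2e-3,
                               spacing_bp = 1000, seed = 1L) {
  stopifnot(derived_core_freq > 0, derived_core_freq < 1,
            sweep_tract_bp <= (n_snp - 1) * spacing_bp + 1)
  list(n_hap = n_hap, n_snp = n_snp, derived_core_freq = derived_core_freq,
       sweep_tract_bp = sweep_tract_bp,
       mutation_noise_per_site = mutation_noise_per_site,
       spacing_bp = spacing_bp, seed = seed)
}

#' Simulate a multi-generation consanguineous pedigree
#'
#' Founders form the first generation and are paired at random; every later
#' generation is produced by Poisson sibships and within-generation mate
#' choice. Mate choice tracks the growing kinship matrix: with probability
#' `cousin_mating_prob` a male's wife is drawn from his related candidates
#' (kinship strictly between 0 and 0.25, i.e. remoter than first-degree),
#' otherwise from unrelated candidates, falling back to related ones when
#' no unrelated mate exists (unless `cousin_mating_prob = 0`, in which case
#' consanguineous unions never occur). The generator is deterministic
#' given the config.
#'
#' @param cfg a [pedigree_sim_config()].
#' @return a validated [pedigree][validate_pedigree] with attribute
#'   `truth` (the config).
#' @export
simulate_pedigree <- function(cfg = pedigree_sim_config()) {
  withr_seed(cfg$seed, {
    kids_per_gen <- cfg$max_couples * cfg$mean_sibship
    cap <- cfg$n_founders +
      ceiling((cfg$n_generations - 1) * (kids_per_gen + 6 * sqrt(kids_per_gen) + 10))
    id <- character(cap); fa <- character(cap); mo <- character(cap)
    sex <- character(cap); gen <- integer(cap)
    K <- matrix(0, cap, cap)
    n <- 0L
    add <- function(f, m, s, g) {
      n <<- n + 1L
      id[n] <<- sprintf("I%04d", n)
      fa[n] <<- f; mo[n] <<- m; sex[n] <<- s; gen[n] <<- g
      if (is.na(f)) {
        K[n, n] <<- 0.5
      } else {
        fi <- match(f, id[seq_len(n - 1L)]); mi <- match(m, id[seq_len(n - 1L)])
        prev <- seq_len(n - 1L)
        row <- 0.5 * (K[fi, prev] + K[mi, prev])
        K[n, prev] <<- row; K[prev, n] <<- row
        K[n, n] <<- 0.5 * (1 + K[fi, mi])
      }
      id[n]
    }

    for (i in seq_len(cfg$n_founders)) {
      add(NA_character_, NA_character_, if (i %% 2L == 1L) "male" else "female", 1L)
    }

    current <- seq_len(cfg$n_founders)
    for (g in seq_len(cfg$n_generations - 1L)) {
      males <- current[sex[current] == "male"]
      females <- current[sex[current] == "female"]
      males <- sample(males)
      taken <- rep(FALSE, length(females))
      couples <- list()
      for (m in males) {
        if (length(couples) >= cfg$max_couples) break
        avail <- females[!taken]
        if (length(avail) == 0L) break
        phim <- K[m, avail]
        unrel <- avail[phim == 0]
        related <- avail[phim > 0 & phim < 0.25]
        pick <- NA_integer_
        if (stats::runif(1) < cfg$cousin_mating_prob && length(related) > 0L) {
          pick <- related[sample.int(length(related), 1L)]
        } else if (length(unrel) > 0L) {
          pick <- unrel[sample.int(length(unrel), 1L)]
        } else if (cfg$cousin_mating_prob > 0 && length(related) > 0L) {
          pick <- related[sample.int(length(related), 1L)]
        }
        if (!is.na(pick)) {
          taken[match(pick, females)] <- TRUE
          couples[[length(couples) + 1L]] <- c(m, pick)
        }
      }
      if (length(couples) == 0L) {
        stop(sprintf(paste("synthetic pedigree died out at generation %d:",
                           "no eligible couples; increase mean_sibship,",
                           "n_founders or cousin_mating_prob"), g + 1L))
      }
      kids <- integer(0)
      for (cp in couples) {
        nk <- stats::rpois(1L, cfg$mean_sibship)
        for (k in seq_len(nk)) {
          s <- if (stats::runif(1) < 0.5) "male" else "female"
          add(id[cp[1]], id[cp[2]], s, g + 1L)
          kids <- c(kids, n)
        }
      }
      if (length(kids) == 0L) {
        stop(sprintf(paste("synthetic pedigree died out at generation %d:",
                           "no children born; increase mean_sibship"), g + 1L))
      }
      current <- kids
    }

    rec <- data.frame(id = id[seq_len(n)], father = fa[seq_len(n)],
                      mother = mo[seq_len(n)], sex = sex[seq_len(n)],
                      stringsAsFactors = FALSE)
    ped <- validate_pedigree(rec)
    attr(ped, "truth") <- cfg
    ped
  })
}

genotype_effect <- function(g, cfg) {
  switch(cfg$effect_model,
         recessive = ifelse(g == 0, -cfg$deficit, 0),
         additive = cfg$beta * g,
         general = cfg$genotype_means[g + 1L])
}

#' Simulate reproductive histories with known genetic truth
#'
#' Draws, for a sample of men from the pedigree, a latent birth rate
#' `mu + genotype effect + covariate terms + polygenic + environmental`
#' where the polygenic component has covariance `2 Phi sigma2_a` over the
#' sampled men and the genotype effect follows the configured model; then
#' realizes birth histories by drawing a marriage duration and
#' Gamma-distributed interbirth intervals with mean `1/rate` until the
#' duration is exhausted. All generating parameters and latent components
#' are stored in the returned truth record.
#'
#' @param ped a validated pedigree.
#' @param genotypes data frame `id`, `dosage` (e.g. from
#'   [drop_genotypes()]).
#' @param cfg a [fertility_sim_config()].
#' @param phi optional precomputed kinship matrix for `ped`.
#' @return list with `histories` (see [birth_rate()]), `dosage` (named),
#'   `truth` (config + latent pieces).
#' @export
simulate_fertility <- function(ped, genotypes, cfg = fertility_sim_config(),
                               phi = NULL) {
  if (is.null(phi)) phi <- kinship_matrix(ped)
  withr_seed(cfg$seed + 1L, {
    # phenotype the most recent generations (a field-interview cohort)
    males <- ped$id[ped$sex == "male" & !ped$founder]
    if (length(males) < cfg$n_men) {
      stop(sprintf("pedigree has only %d non-founder males; %d requested",
                   length(males), cfg$n_men))
    }
    male_gen <- ped$generation[match(males, ped$id)]
    ord <- order(-male_gen)
    gmin <- male_gen[ord][cfg$n_men]
    pool <- males[male_gen >= gmin]
    men <- sort(sample(pool, cfg$n_men))
    g <- genotypes$dosage[match(men, genotypes$id)]
    gen_idx <- ped$generation[match(men, ped$id)]

    depth <- max(ped$generation)
    birth_year <- 1950 - 25 * (depth - gen_idx) + stats::runif(cfg$n_men, -3, 3)
    wife_birth_year <- birth_year + stats::rnorm(cfg$n_men, 0, cfg$wife_year_sd)
    marriage_year <- birth_year + stats::rnorm(cfg$n_men, 25, 2)
    duration <- pmax(2, stats::rnorm(cfg$n_men, cfg$span_mean, cfg$span_sd))

    sigma2 <- cfg$residual_sd^2
    A <- 2 * unclass(phi)[men, men]
    polygenic <- if (cfg$h2 > 0) {
      L <- chol(A + diag(1e-8, cfg$n_men))
      drop(crossprod(L, stats::rnorm(cfg$n_men))) * sqrt(cfg$h2 * sigma2)
    } else rep(0, cfg$n_men)
    env <- stats::rnorm(cfg$n_men, 0, sqrt((1 - cfg$h2) * sigma2))
    geff <- genotype_effect(g, cfg)
    latent <- cfg$mu + geff +
      cfg$slope_wife_year * (wife_birth_year - 1950) +
      cfg$slope_span * (duration - cfg$span_mean) +
      polygenic + env
    latent <- pmax(latent, 0.08)

    histories <- lapply(seq_len(cfg$n_men), function(i) {
      gaps <- stats::rgamma(ceiling(duration[i] * latent[i] * 3) + 10,
                            shape = cfg$gamma_shape,
                            rate = cfg$gamma_shape * latent[i])
      first <- marriage_year[i] + stats::runif(1, 0.75, 2)
      births <- first + c(0, cumsum(gaps))
      births <- births[births <= marriage_year[i] + duration[i]]
      if (length(births) == 0L) births <- first
      list(individual_id = men[i],
           marriage_year = marriage_year[i],
           wife_birth_year = wife_birth_year[i],
           birth_years = births,
           observation_end = max(births) + 0.5)
    })
    list(histories = histories,
         dosage = stats::setNames(g, men),
         truth = c(cfg, list(men = men, latent_rate = latent,
                             polygenic = polygenic,
                             genotype_effect = geff)))
  })
}

#' Simulate two-population derived-allele counts
#'
#' Binomial sampling of allele copies at the stated population
#' frequencies; feeds [weir_cockerham_theta()].
#'
#' @param p1,p2 true derived-allele frequencies.
#' @param n1,n2 allele copies sampled per population.
#' @param seed integer seed.
#' @return list `n1`, `x1`, `n2`, `x2`, `truth`.
#' @export
simulate_two_pop_counts <- function(p1, p2, n1 = 120, n2 = 120, seed = 1L) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  withr_seed(seed, {
    list(n1 = n1, x1 = stats::rbinom(1L, n1, p1),
         n2 = n2, x2 = stats::rbinom(1L, n2, p2),
         truth = list(p1 = p1, p2 = p2, seed = seed))
  })
}

#' Simulate a haplotype panel with a partial sweep at the core
#'
#' Ancestral-background haplotypes are drawn site-independently at
#' per-site frequencies; derived-background haplotypes copy a single
#' template over `sweep_tract_bp` around the core (with per-site mutation
#' noise) and are free elsewhere, so derived carriers share a long
#' identical tract — the haplotype structure a recent sweep leaves behind.
#' `sweep_tract_bp = 0` yields an exchangeable (neutral) panel.
#'
#' @param cfg a [sweep_panel_config()].
#' @return a [hap_panel()] with attribute `truth`.
#' @export
simulate_sweep_panel <- function(cfg = sweep_panel_config()) {
  withr_seed(cfg$seed, {
    pos <- cfg$spacing_bp * (seq_len(cfg$n_snp) - 1L)
    core <- (cfg$n_snp + 1L) %/% 2L
    q <- stats::runif(cfg$n_snp, 0.1, 0.9)
    n_der <- max(2L, min(cfg$n_hap - 2L, round(cfg$n_hap * cfg$derived_core_freq)))
    der_rows <- sample(cfg$n_hap, n_der)
    M <- matrix(stats::rbinom(cfg$n_hap * cfg$n_snp, 1L, rep(q, each = cfg$n_hap)),
                nrow = cfg$n_hap)
    if (cfg$sweep_tract_bp > 0) {
      tract <- which(abs(pos - pos[core]) <= cfg$sweep_tract_bp / 2)
      template <- stats::rbinom(length(tract), 1L, q[tract])
      for (r in der_rows) {
        flip <- stats::rbinom(length(tract), 1L, cfg$mutation_noise_per_site)
        M[r, tract] <- (template + flip) %% 2L
      }
    }
    M[, core] <- 0L
    M[der_rows, core] <- 1L
    panel <- hap_panel(M, pos, core)
    attr(panel, "truth") <- c(cfg, list(derived_rows = sort(der_rows)))
    panel
  })
}

#' Simulate three-locus genotypes from population haplotype frequencies
#'
#' Without a pedigree, each individual receives two haplotypes drawn
#' i.i.d. from the supplied frequency table. With a pedigree, founders
#' draw their pairs from the table and every descendant inherits one
#' whole (unrecombined) haplotype from each parent, so that family
#' structure carries phase information the way it does in real data.
#' Genotype records are emitted with the intron 8 cis pairing observed
#' (as single-amplicon sequencing would give it).
#'
#' @param hap_freqs named numeric vector, names `TGx-yT-Z`, summing to 1.
#' @param n number of individuals (ignored when `ped` is given).
#' @param seed integer seed.
#' @param ped optional validated [pedigree][validate_pedigree].
#' @return list with `genotypes` (records for [phase_by_pedigree()]) and
#'   `truth` (the drawn haplotype pairs, one row per individual).
#' @export
simulate_three_locus_genotypes <- function(hap_freqs, n = NULL, seed = 1L,
                                           ped = NULL) {
  stopifnot(abs(sum(hap_freqs) - 1) < 1e-6)
  withr_seed(seed, {
    if (is.null(ped)) {
      stopifnot(!is.null(n))
      ids <- sprintf("S%04d", seq_len(n))
      draws <- matrix(sample(names(hap_freqs), 2L * n, replace = TRUE,
                             prob = hap_freqs), ncol = 2L)
    } else {
      ids <- ped$id
      n <- length(ids)
      fi <- match(ped$father, ped$id); mi <- match(ped$mother, ped$id)
      draws <- matrix(NA_character_, n, 2L)
      for (i in seq_len(n)) {
        if (is.na(fi[i])) {
          draws[i, ] <- sample(names(hap_freqs), 2L, replace = TRUE,
                               prob = hap_freqs)
        } else {
          draws[i, 1L] <- draws[fi[i], sample.int(2L, 1L)]
          draws[i, 2L] <- draws[mi[i], sample.int(2L, 1L)]
        }
      }
    }
    rownames(draws) <- ids
    genotypes <- lapply(seq_len(n), function(i) {
      p <- strsplit(draws[i, ], "-")
      list(individual_id = ids[i],
           tg = c(sub("^TG", "", p[[1]][1]), sub("^TG", "", p[[2]][1])),
           polyt = c(sub("T$", "", p[[1]][2]), sub("T$", "", p[[2]][2])),
           m470v = c(p[[1]][3], p[[2]][3]),
           intron8_phased = TRUE)
    })
    list(genotypes = genotypes, truth = draws)
  })
}

#' Write a haplotype panel as an IMPUTE-style hap/legend pair
#'
#' @param panel a [hap_panel()].
#' @param hap_path,legend_path output paths.
#' @export
write_hap_legend <- function(panel, hap_path, legend_path) {
  leg <- data.frame(id = sprintf("snp%05d", seq_along(panel$positions)),
                    position = panel$positions,
                    allele0 = "A", allele1 = "G", ancestral = "A")
  utils::write.table(leg, legend_path, quote = FALSE, row.names = FALSE)
  utils::write.table(t(panel$haplotypes), hap_path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(hap_path, legend_path))
}
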