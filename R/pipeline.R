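#' Write a TSV with a provenance header
#'
#' Every pipeline output table carries `#`-prefixed header lines recording
#' the package version, the top-level seed and a hash of the run
#' configuration, so any table can be traced to the run that produced it.
#'
#' @param df data frame.
#' @param path output path.
#' @param seed integer seed recorded in the header.
#' @param config_hash short hash string recorded in the header.
#' @export
write_tsv_provenance <- function(df, path, seed = NA_integer_, config_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fertsel %s", as.character(utils::packageVersion("fertsel"))),
               sprintf("# seed: %s", seed),
               sprintf("# config: %s", config_hash)), con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed TSV
#' @param path file path.
#' @return data frame (header lines are skipped).
#' @export
read_tsv_provenance <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

config_hash <- function(config) {
  config$out_dir <- NULL   # where the tables land is not part of the analysis
  s <- paste(deparse(config), collapse = "")
  # small rolling hash; provenance only, no cryptographic intent
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2^28
  sprintf("%07x", h)
}

#' Default pipeline configuration
#'
#' @param seed top-level seed; every stage derives its own substream from
#'   it, so a full rerun with the same config is byte-identical.
#' @param out_dir output directory for the stage tables.
#' @param stages which stages to run.
#' @param inputs optional named list of input paths (`ped`, `histories`,
#'   `genotypes_csv`, `hap`, `legend`); stages fall back to the synthetic
#'   generators when an input is absent.
#' @param pedigree,fertility,panel generator configs used for synthetic
#'   stages (see [sim_configs]).
#' @param n_tests Bonferroni denominator for the association stage.
#' @param kth_birth birth order for the survival stage.
#' @param ehh_cutoff EHH truncation threshold for the selection stage.
#' @return config list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("fertsel_run_"),
                       stages = c("phenotypes", "association", "survival",
                                  "haplotypes", "selection"),
                       inputs = list(),
                       pedigree = NULL, fertility = NULL, panel = NULL,
                       n_tests = 4L, kth_birth = 6L, ehh_cutoff = 0.05) {
  if (is.null(pedigree)) {
    pedigree <- pedigree_sim_config(n_generations = 8, n_founders = 40,
                                    max_couples = 40, seed = seed)
  }
  if (is.null(fertility)) fertility <- fertility_sim_config(seed = seed)
  if (is.null(panel)) panel <- sweep_panel_config(seed = seed)
  structure(list(seed = seed, out_dir = out_dir, stages = stages,
                 inputs = inputs, pedigree = pedigree, fertility = fertility,
                 panel = panel, n_tests = n_tests, kth_birth = kth_birth,
                 ehh_cutoff = ehh_cutoff),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [run_config()] arguments; the nested
#' `pedigree`, `fertility` and `panel` blocks are passed to the
#' corresponding `*_config()` constructors, so the file is validated the
#' same way a programmatic config is.
#'
#' @param path YAML file.
#' @param seed optional override of the file's seed.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, seed = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs needs the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  args <- y[intersect(names(y), c("seed", "out_dir", "stages", "inputs",
                                  "n_tests", "kth_birth", "ehh_cutoff"))]
  if (!is.null(y$pedigree)) args$pedigree <- do.call(pedigree_sim_config, y$pedigree)
  if (!is.null(y$fertility)) args$fertility <- do.call(fertility_sim_config, y$fertility)
  if (!is.null(y$panel)) args$panel <- do.call(sweep_panel_config, y$panel)
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages — phenotype construction, relatedness-
#' corrected association, time-to-kth-birth survival comparison, haplotype
#' phasing with LD, and selection-signature statistics — on either
#' supplied input files or the synthetic generators, writing one
#' provenance-headed TSV per stage into `config$out_dir`. Inputs named in
#' `config$inputs` are validated before any computation; a stage failure
#' aborts with the stage name. No stage mutates its inputs and every
#' stage reseeds from the top-level seed, so the pipeline is re-entrant
#' per stage.
#'
#' @param config a [run_config()].
#' @return list with `outputs` (named file paths), `tables` (the in-memory
#'   results) and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  for (nm in names(config$inputs)) {
    if (!file.exists(config$inputs[[nm]])) {
      stop(sprintf("pre-flight validation: input '%s' not found at %s",
                   nm, config$inputs[[nm]]))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config))
  outputs <- list(); tables <- list()
  emit <- function(name, df) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_tsv_provenance(df, p, config$seed, hash)
    outputs[[name]] <<- p
    tables[[name]] <<- df
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # shared cohort (pedigree + genotypes + histories)
  ped <- if (!is.null(config$inputs$ped)) read_ped(config$inputs$ped)
         else simulate_pedigree(config$pedigree)
  phi <- kinship_matrix(ped)
  drop <- gene_drop(ped, p = config$fertility$snp_allele_freq,
                    seed = config$seed + 101L)
  geno <- drop_genotypes(drop)
  sim <- if (!is.null(config$inputs$histories)) {
    list(histories = read_reproductive_history(config$inputs$histories),
         dosage = stats::setNames(geno$dosage, geno$id))
  } else {
    simulate_fertility(ped, geno, config$fertility, phi = phi)
  }
  histories <- sim$histories
  ids <- vapply(histories, function(h) as.character(h$individual_id), character(1))
  dosage <- sim$dosage[ids]

  phenos <- NULL
  if ("phenotypes" %in% config$stages) {
    run_stage("phenotypes", {
      phenos <- phenotype_table(histories)
      emit("phenotypes", phenos)
    })
  }

  if ("association" %in% config$stages) {
    run_stage("association", {
      if (is.null(phenos)) phenos <- phenotype_table(histories)
      keep <- !phenos$excluded
      y <- phenos$rate[keep]
      X <- as.matrix(phenos[keep, c("wife_birth_year", "marriage_to_last_birth")])
      sub <- phenos$individual_id[keep]
      scan <- association_scan(y, X, list(m470v = dosage[sub]),
                               schemes = c("general", "recessive_ref"),
                               Phi = phi[sub, sub], n_tests = config$n_tests,
                               alleles = list(m470v = c("Met", "Val")))
      vc <- attr(scan, "vc")
      scan$h2_null <- vc$h2
      emit("association", scan)
    })
  }

  if ("survival" %in% config$stages) {
    run_stage("survival", {
      grp <- ifelse(dosage >= 1, "carrier", "ref_hom")
      recs <- lapply(seq_along(histories), function(i) {
        time_to_kth_birth(histories[[i]], config$kth_birth, grp[i])
      })
      recs <- Filter(function(r) !r$excluded && r$time > 0, recs)
      emit("survival_km", km_curve(recs))
      lr <- log_rank(recs)
      emit("survival_logrank",
           data.frame(group = names(lr$observed), observed = lr$observed,
                      expected = lr$expected, chi_square = lr$chi_square,
                      df = lr$df, p_value = lr$p_value))
    })
  }

  if ("haplotypes" %in% config$stages) {
    run_stage("haplotypes", {
      gl <- if (!is.null(config$inputs$genotypes_csv)) {
        read_three_locus_genotypes(config$inputs$genotypes_csv)
      } else {
        simulate_three_locus_genotypes(cftr_summary$haplotype_freq,
                                       n = config$fertility$n_men,
                                       seed = config$seed + 202L)$genotypes
      }
      asg <- phase_by_pedigree(gl, ped)
      hf <- haplotype_frequencies(asg)
      emit("haplotype_freqs",
           data.frame(haplotype = names(hf$freq), frequency = hf$freq,
                      count = as.numeric(hf$counts)))
      ld <- d_prime(hf$freq, "polyt", "m470v", "7", "Val")
      emit("ld", data.frame(locus_pair = "polyT(7) x M470V(Val)",
                            D = ld$D, D_prime = ld$D_prime, r2 = ld$r2))
    })
  }

  if ("selection" %in% config$stages) {
    run_stage("selection", {
      panel <- if (!is.null(config$inputs$hap)) {
        read_hap_legend(config$inputs$hap, config$inputs$legend, "core")
      } else {
        simulate_sweep_panel(config$panel)
      }
      res <- ihs_unstandardized(panel, cutoff = config$ehh_cutoff)
      cts <- simulate_two_pop_counts(cftr_summary$hapmap$ceu_val_freq,
                                     cftr_summary$hapmap$yri_val_freq,
                                     seed = config$seed + 303L)
      th <- weir_cockerham_theta(cts$n1, cts$x1, cts$n2, cts$x2)
      emit("selection",
           data.frame(statistic = c("uihs", "ihh_ancestral", "ihh_derived",
                                    "derived_freq", "theta_two_pop"),
                      value = c(res$uihs, res$ihh_a, res$ihh_d,
                                res$derived_freq, th$theta)))
    })
  }

  list(outputs = outputs, tables = tables, config = config)
}
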