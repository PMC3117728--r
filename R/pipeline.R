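# End-to-end orchestration: io -> diversity -> dN/dS (full / PBS / non-PBS)
# -> site models -> population tests -> recombination scan -> networks, with
# TSV/JSON reports and a provenance log.

#' Run configuration for the full pipeline
#'
#' @param alignment_path FASTA of exon-2 alleles.
#' @param genotype_path optional two-column genotype TSV.
#' @param family_path optional pedigree TSV (four columns per family).
#' @param out_dir output directory (created if needed).
#' @param trim nucleotide trims \code{c(leading, trailing)} (default 2, 1).
#' @param pbs_catalog \code{"reche"} (default) or \code{"brown"}, or an
#'   explicit integer vector of seahorse codon indices.
#' @param reps permutation/bootstrap replicates (default 10000; a warning is
#'   issued below 1000 -- smoke-test grade only).
#' @param rho recombination switch penalties to sweep (default 0.5, 1, 2).
#' @param seed master RNG seed.
#' @param fit_site_models logical; the M7/M8 fits are the slowest stage.
#' @param site_model_K beta discretization classes (default 10).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(alignment_path, genotype_path = NULL,
                       family_path = NULL, out_dir = "mhc2div_out",
                       trim = c(2L, 1L), pbs_catalog = "reche",
                       reps = 10000L, rho = c(0.5, 1, 2), seed = 1L,
                       fit_site_models = TRUE, site_model_K = 10L) {
  if (reps < 1L) stop("config error: reps must be >= 1")
  if (reps < 1000L) {
    warning("reps = ", reps, " is below inference grade (>= 1000); ",
            "results are smoke-test quality")
  }
  structure(list(alignment_path = alignment_path,
                 genotype_path = genotype_path,
                 family_path = family_path,
                 out_dir = out_dir, trim = as.integer(trim),
                 pbs_catalog = pbs_catalog,
                 reps = as.integer(reps), rho = rho, seed = as.integer(seed),
                 fit_site_models = fit_site_models,
                 site_model_K = as.integer(site_model_K)),
            class = "run_config")
}

#' Read a JSON run configuration
#' @param path JSON file whose keys match \code{\link{run_config}} arguments.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, args)
}

#' Run the complete analysis
#'
#' Executes every stage applicable to the supplied inputs and writes a
#' report bundle to \code{config$out_dir}: diversity summary, a
#' substitution-rate table (full / PBS / non-PBS), site-model fits with LRT
#' and selected sites, HWE and allelic-combination tests, a Mendel report,
#' the recombination scan sweep, full and recombinant-pruned networks, and a
#' provenance log (versions, seeds, config).
#'
#' @param config a \code{run_config}.
#' @return invisibly, a list with every stage result.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  log_lines <- c(sprintf("mhc2div %s | R %s", as.character(utils::packageVersion("mhc2div")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed = %d, reps = %d", config$seed, config$reps),
                 sprintf("config: %s", jsonlite::toJSON(config[c(
                   "alignment_path", "genotype_path", "family_path", "trim",
                   "reps", "rho", "seed")], auto_unbox = TRUE)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  results <- list()

  aln <- stage("io", read_alignment(config$alignment_path,
                                    config$trim[1], config$trim[2]))
  results$alignment <- aln

  genotypes <- NULL
  if (!is.null(config$genotype_path)) {
    genotypes <- stage("io", read_genotypes(config$genotype_path))
    missing <- setdiff(unique(c(genotypes$allele1, genotypes$allele2)),
                       aln$allele_ids)
    if (length(missing)) {
      stop("stage 'io' failed: genotype alleles missing from alignment: ",
           paste(missing, collapse = ", "))
    }
  }

  results$diversity <- stage("diversity", diversity_summary(aln, genotypes))
  write_diversity_summary(results$diversity, outp("diversity.tsv"))

  partition <- stage("pbs", {
    if (is.numeric(config$pbs_catalog)) {
      site_partition(config$pbs_catalog, aln$codon_count)
    } else map_pbs_sites(aln, catalog = config$pbs_catalog)
  })
  results$partition <- partition

  results$dnds <- stage("selection", list(
    full = mean_dn_ds(aln, partition_label = "Exon 2"),
    pbs = mean_dn_ds(aln, partition = partition$pbs_codons,
                     partition_label = "Exon 2, PBS"),
    non_pbs = mean_dn_ds(aln, partition = partition$non_pbs_codons,
                         partition_label = "Exon 2, non-PBS")))
  samples <- if (is.null(genotypes)) NA else nrow(genotypes)
  write_dnds_table(results$dnds, outp("substitution_rates.tsv"), samples = samples)

  results$z_tests <- stage("selection", list(
    full = z_test_positive_selection(aln, reps = min(config$reps, 2000L),
                                     seed = config$seed),
    pbs = z_test_positive_selection(aln, partition = partition$pbs_codons,
                                    reps = min(config$reps, 2000L),
                                    seed = config$seed + 1L),
    non_pbs = z_test_positive_selection(aln, partition = partition$non_pbs_codons,
                                        reps = min(config$reps, 2000L),
                                        seed = config$seed + 2L)))

  if (config$fit_site_models && length(aln$sequences) >= 3L) {
    results$site_models <- stage("sitemodels", {
      tree <- build_nj_tree(aln)
      m7 <- fit_site_model(aln, tree, model = "M7", K = config$site_model_K)
      m8 <- fit_site_model(aln, tree, model = "M8", K = config$site_model_K)
      test <- lrt(m7, m8)
      post <- site_posteriors(m8)
      jsonlite::write_json(
        list(M7 = list(lnL = m7$log_likelihood, parameters = m7$parameters),
             M8 = list(lnL = m8$log_likelihood, parameters = m8$parameters),
             LRT = list(statistic = test$statistic, df = test$df, p = test$p),
             selected_sites = post$selected_sites),
        outp("site_models.json"), auto_unbox = TRUE, digits = NA)
      write.table(data.frame(codon = seq_along(post$posterior),
                             posterior_positive = post$posterior),
                  outp("site_posteriors.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      list(m7 = m7, m8 = m8, lrt = test, posteriors = post)
    })
  }

  if (!is.null(genotypes)) {
    results$hwe <- stage("hwe", hwe_exact_test(genotypes,
                                               mc_steps = config$reps,
                                               seed = config$seed))
    results$combos <- stage("combos", allelic_combination_test(
      genotypes, reps = config$reps, seed = config$seed))
    write_combo_table(results$combos, outp("allele_combinations.tsv"))
  }

  if (!is.null(config$family_path)) {
    families <- stage("io", read_families(config$family_path))
    results$mendel <- stage("mendel", mendel_check_all(families))
    per_off <- do.call(rbind, lapply(results$mendel$reports, function(r) {
      cbind(family = r$family_id, r$offspring)
    }))
    write.table(per_off, outp("mendel_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  results$recomb <- stage("recomb", recomb_rho_sweep(
    aln, rhos = config$rho, reps = config$reps, seed = config$seed))
  for (nm in names(results$recomb)) {
    write_recomb_scan(results$recomb[[nm]],
                      outp(paste0("recomb_scan_", gsub("=", "", nm), ".tsv")))
  }

  results$network <- stage("network", {
    aset <- if (is.null(genotypes)) NULL else collapse_alleles(genotypes, aln)
    full <- build_network(aset, aln)
    write_network(full, outp("network_full.tsv"))
    write_network(full, outp("network_full.dot"), format = "dot")
    recombinant <- unique(unlist(lapply(results$recomb, function(s)
      s$table$allele[s$table$p < 0.05])))
    pruned <- if (length(recombinant) > 0 &&
                  length(recombinant) < length(aln$sequences) - 1) {
      pr <- prune_and_rebuild(aset, aln, exclude = recombinant)
      write_network(pr, outp("network_pruned.tsv"))
      pr
    } else NULL
    list(full = full, pruned = pruned, recombinant_alleles = recombinant)
  })

  log_lines <- c(log_lines, sprintf("completed %d stages at %s",
                                    length(results), format(Sys.time())))
  writeLines(log_lines, outp("provenance.log"))
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate} (write a synthetic demo dataset),
#' \code{all} (full pipeline), and the single stages \code{diversity},
#' \code{dnds}, \code{sitemodels}, \code{hwe}, \code{combos}, \code{mendel},
#' \code{recomb}, \code{network}.  Invoked by the installed
#' \code{scripts/mhc2div} wrapper or directly:
#' \code{Rscript -e 'mhc2div::cli_main()' all --config cfg.json}.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: mhc2div <simulate|diversity|dnds|sitemodels|hwe|combos|",
            "mendel|recomb|network|all> [--config cfg.json] [--out dir] [--seed n]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "mhc2div_out")
  if (cmd == "simulate") {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    cfg <- sim_config(seed = seed, n_recombinants = 2L)
    pool <- gen_allele_pool(cfg)
    panel <- gen_panel(pool$alignment, cfg)
    fams <- gen_families(pool$alignment, cfg)
    write_alignment(pool$alignment, file.path(out, "alleles.fasta"))
    write_genotypes(panel$genotypes, file.path(out, "genotypes.tsv"))
    write_families(fams$families, file.path(out, "families.tsv"))
    jsonlite::write_json(pool$truth[c("recombinants", "pbs_codons", "seed")],
                         file.path(out, "truth.json"), auto_unbox = TRUE)
    message("synthetic dataset written to ", out)
    return(invisible(0L))
  }
  cfg_path <- opt("--config")
  config <- if (!is.null(cfg_path)) read_run_config(cfg_path) else {
    run_config(alignment_path = opt("--alignment"),
               genotype_path = opt("--genotypes"),
               family_path = opt("--families"),
               out_dir = out, seed = seed,
               reps = as.integer(opt("--reps", "10000")))
  }
  if (cmd == "all") {
    run_all(config)
    message("report bundle written to ", config$out_dir)
    return(invisible(0L))
  }
  # single stages; the alignment is only read by the stages that need it
  aln_stages <- c("diversity", "dnds", "sitemodels", "recomb", "network")
  aln <- if (cmd %in% aln_stages) {
    read_alignment(config$alignment_path, config$trim[1], config$trim[2])
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(cmd,
    diversity = {
      gt <- if (!is.null(config$genotype_path)) read_genotypes(config$genotype_path)
      print(diversity_summary(aln, gt))
    },
    dnds = {
      part <- if (is.numeric(config$pbs_catalog)) {
        site_partition(config$pbs_catalog, aln$codon_count)
      } else map_pbs_sites(aln, catalog = config$pbs_catalog)
      print(mean_dn_ds(aln, partition_label = "all"))
      print(mean_dn_ds(aln, part$pbs_codons, "PBS"))
      print(mean_dn_ds(aln, part$non_pbs_codons, "non-PBS"))
    },
    sitemodels = {
      m7 <- fit_site_model(aln, model = "M7", K = config$site_model_K)
      m8 <- fit_site_model(aln, model = "M8", K = config$site_model_K)
      print(m7); print(m8); print(lrt(m7, m8))
    },
    hwe = print(hwe_exact_test(read_genotypes(config$genotype_path),
                               mc_steps = config$reps, seed = config$seed)),
    combos = print(allelic_combination_test(read_genotypes(config$genotype_path),
                                            reps = config$reps, seed = config$seed)),
    mendel = {
      rep <- mendel_check_all(read_families(config$family_path))
      for (r in rep$reports) print(r)
      cat(sprintf("total: %d/%d compatible\n", rep$total_compatible,
                  rep$total_offspring))
    },
    recomb = print(recomb_pvalues(aln, rho = config$rho[1],
                                  reps = config$reps, seed = config$seed)),
    network = print(build_network(NULL, aln)),
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
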