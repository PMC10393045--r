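#' Pipeline configuration
#'
#' Nested per-stage parameter list with the published defaults; unknown
#' keys are rejected so typos cannot silently disable a filter.
#'
#' @param simulate named list of [sim_config()] overrides.
#' @param tips list: `zygosity_min`, `presence_cutoff`.
#' @param eqtl list: `window`, `fdr`, `relaxed_p`, `min_sample_frac`.
#' @param pbs list: `percentiles`, `estimator`, `impute_mode`.
#' @param sweep list: `flank`, `pi_window`, `pi_step`, `h12_window`,
#'   `h12_step`, `n_perm`.
#' @return Validated nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), tips = list(),
                            eqtl = list(), pbs = list(), sweep = list()) {
  d <- pipeline_defaults()
  base <- list(
    simulate = as.list(formals(sim_config))[
      setdiff(names(formals(sim_config)), "seed")],
    tips = list(zygosity_min = d$zygosity_min,
                presence_cutoff = d$zygosity_presence_cutoff),
    eqtl = list(window = d$cis_window, fdr = d$fdr,
                relaxed_p = d$relaxed_p,
                min_sample_frac = d$expressed_min_sample_frac),
    pbs = list(percentiles = d$pbs_percentiles, estimator = "hudson",
               impute_mode = "expected"),
    sweep = list(flank = d$sweep_flank, pi_window = d$pi_window,
                 pi_step = d$pi_step, h12_window = d$h12_window,
                 h12_step = d$h12_step, n_perm = d$n_perm)
  )
  base$simulate <- lapply(base$simulate, eval)
  user <- list(simulate = simulate, tips = tips, eqtl = eqtl, pbs = pbs,
               sweep = sweep)
  for (stage in names(user)) {
    unknown <- setdiff(names(user[[stage]]), names(base[[stage]]))
    if (length(unknown) > 0) {
      stop("unknown ", stage, " parameter(s): ",
           paste(unknown, collapse = ", "))
    }
    base[[stage]][names(user[[stage]])] <- user[[stage]]
  }
  structure(base, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> filter/binarize TIPs -> per-population TIP- and SNP-eQTL
#' scans -> TIP/SNP variance comparison -> population frequencies and
#' specificity -> PBS scan with eQTL enrichment -> sweep scans at planted
#' sweep loci -> TSV/JSON reports. Fully deterministic for a fixed
#' (config, seed): result files are byte-identical across runs.
#'
#' @param config [pipeline_config()].
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @param quiet suppress per-stage row-count messages.
#' @return Invisibly, a list with the main in-memory results
#'   (`cohort`, `tip_results`, `snp_results`, `tip_hits`, `snp_hits`,
#'   `pbs`, `enrichment`, `rank_sum`, `sweeps`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  provenance <- sprintf("# tipscan=%s config_md5=%s seed=%d",
                        as.character(utils::packageVersion("tipscan")),
                        cfg_hash, seed)
  write_result <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(provenance, path)
    suppressWarnings(utils::write.table(
      df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA",
      append = TRUE))
    path
  }

  ## 1. simulate ------------------------------------------------------------
  cohort <- run_stage("simulate", {
    sim_args <- config$simulate
    sim_args$seed <- seed
    simulate_cohort(do.call(sim_config, sim_args))
  })
  write_cohort(cohort, file.path(out_dir, "cohort"))
  say("simulate: %d TIP loci, %d SNPs, %d genes, %d accessions",
      nrow(cohort$zygosity$loci), nrow(cohort$snps$loci),
      nrow(cohort$genes), nrow(cohort$accessions))

  ## 2. TIP matrix ----------------------------------------------------------
  pops <- c("pop1", "pop2")
  groups <- stats::setNames(cohort$accessions$population,
                            cohort$accessions$accession)
  tipg <- run_stage("filter-tips", {
    z <- filter_low_zygosity(cohort$zygosity, config$tips$zygosity_min)
    binarize_zygosity(z, config$tips$presence_cutoff)
  })
  say("filter-tips: %d of %d loci past zygosity filter",
      nrow(tipg$loci), nrow(cohort$zygosity$loci))

  ## per-population eQTL marker sets (MAF recomputed per population)
  eqtl_tips <- lapply(pops, function(p) {
    acc <- cohort$accessions$accession[groups[cohort$accessions$accession] == p]
    filter_maf_missing(subset_samples(tipg, acc), preset = "eqtl")
  })
  names(eqtl_tips) <- pops
  eqtl_snps <- lapply(pops, function(p) {
    acc <- cohort$accessions$accession[groups[cohort$accessions$accession] == p]
    filter_maf_missing(subset_samples(cohort$snps, acc), preset = "eqtl")
  })
  names(eqtl_snps) <- pops

  ## 3. eQTL scans ----------------------------------------------------------
  scan_one <- function(markers, pop) {
    run_eqtl_scan(cohort$counts, cohort$genes, markers[[pop]],
                  cohort$samples, pop, window = config$eqtl$window,
                  min_sample_frac = config$eqtl$min_sample_frac)
  }
  tip_results <- run_stage("map-eqtl-tip", {
    do.call(rbind, lapply(pops, function(p) scan_one(eqtl_tips, p)))
  })
  snp_results <- run_stage("map-eqtl-snp", {
    do.call(rbind, lapply(pops, function(p) scan_one(eqtl_snps, p)))
  })
  tip_hits <- consolidate_replicates(tip_results, config$eqtl$fdr)
  snp_hits <- consolidate_replicates(snp_results, config$eqtl$fdr)
  write_result(tip_results, "associations_tip.tsv")
  write_result(snp_results, "associations_snp.tsv")
  write_result(tip_hits$hits, "hits_tip.tsv")
  write_result(snp_hits$hits, "hits_snp.tsv")
  say("map-eqtl: %d TIP and %d SNP tested pairs; %d / %d hit pairs",
      nrow(tip_results), nrow(snp_results),
      nrow(tip_hits$hits), nrow(snp_hits$hits))
  variance_cmp <- run_stage("compare-snp-tip", {
    compare_variance_explained(tip_hits$leading, snp_results,
                               config$eqtl$fdr)
  })
  if (nrow(variance_cmp$genes) > 0) {
    write_result(variance_cmp$genes, "tip_vs_snp_r2.tsv")
  }

  ## 4. frequencies and PBS ---------------------------------------------------
  pbs_res <- run_stage("pbs", {
    g <- filter_maf_missing(tipg, preset = "pbs")
    freq_all <- allele_frequency(g, groups)
    in_all <- freq_all$freq[, "pop1"] > 0 & freq_all$freq[, "pop2"] > 0 &
      freq_all$freq[, "pop3"] > 0
    in_all[is.na(in_all)] <- FALSE
    g <- subset_loci(g, in_all)
    g <- impute_missing(g, mode = config$pbs$impute_mode, seed = seed + 101L)
    freqs <- allele_frequency(g, groups)
    tab <- pbs_scan(freqs, pops = c("pop1", "pop2", "pop3"),
                    percentiles = config$pbs$percentiles,
                    estimator = config$pbs$estimator)
    list(freqs = freqs, table = tab, genotypes = g)
  })
  eqtl_flag_ids <- unique(tip_hits$hits$marker_id)
  enrichment <- eqtl_enrichment_test(pbs_res$table, eqtl_flag_ids,
                                     percentile = max(config$pbs$percentiles))
  is_eqtl <- pbs_res$table$id %in% eqtl_flag_ids
  rank_sum <- if (any(is_eqtl) && any(!is_eqtl)) {
    rank_sum_compare(pbs_res$table$abs_pbs[is_eqtl],
                     pbs_res$table$abs_pbs[!is_eqtl])
  } else list(U = NA_real_, p = NA_real_)
  write_result(pbs_res$table, "pbs.tsv")
  say("pbs: %d loci scanned; %d flagged eQTL", nrow(pbs_res$table),
      sum(is_eqtl))

  spec_tab <- classify_population_specificity(pbs_res$freqs, "pop1", "pop2")
  write_result(spec_tab, "population_specificity.tsv")
  xfreq <- cross_population_frequency_table(pbs_res$freqs,
                                            is_eqtl, "pop1", "pop2")

  ## 5. sweep scans -----------------------------------------------------------
  sweeps <- run_stage("sweep-scan", {
    tip_scan_calls <- impute_missing(tipg, mode = "expected")
    out <- list()
    for (i in seq_len(nrow(cohort$truth$sweep_loci))) {
      tid <- cohort$truth$sweep_loci$tip_id[i]
      sel <- cohort$truth$selected_tips
      focal_pop <- sel$focal_population[match(tid, sel$tip_id)]
      acc <- cohort$accessions$accession[
        cohort$accessions$population == focal_pop]
      out[[tid]] <- scan_locus(
        cohort$snps, tip_scan_calls, tid, samples = acc,
        flank = config$sweep$flank,
        pi_window = config$sweep$pi_window, pi_step = config$sweep$pi_step,
        h12_window = config$sweep$h12_window,
        h12_step = config$sweep$h12_step,
        n_perm = config$sweep$n_perm, seed = seed + 200L + i)
    }
    out
  })
  if (length(sweeps) > 0) {
    sweep_windows <- do.call(rbind, lapply(names(sweeps), function(tid) {
      cbind(focal_tip = tid, sweeps[[tid]]$windows)
    }))
    write_result(sweep_windows, "sweep_windows.tsv")
  }
  say("sweep-scan: %d loci scanned", length(sweeps))

  ## 6. summary ---------------------------------------------------------------
  summary <- list(
    provenance = list(version = as.character(utils::packageVersion("tipscan")),
                      config_md5 = unname(cfg_hash), seed = seed),
    n_tip_loci_raw = nrow(cohort$zygosity$loci),
    n_tip_loci_zygosity = nrow(tipg$loci),
    n_tip_pairs_tested = nrow(tip_results),
    n_snp_pairs_tested = nrow(snp_results),
    n_tip_hits = nrow(tip_hits$hits),
    n_snp_hits = nrow(snp_hits$hits),
    variance_fractions = as.list(variance_cmp$fractions),
    n_pbs_loci = nrow(pbs_res$table),
    enrichment_odds_ratio = enrichment$odds_ratio,
    enrichment_p = enrichment$p,
    rank_sum_p = rank_sum$p,
    equal_frequency_fraction = as.list(xfreq$equal_fraction),
    sweep_focal = lapply(sweeps, function(s) {
      fw <- focal_window(s)
      stats::setNames(as.list(fw$perm_p), paste(fw$group, fw$stat, sep = "_"))
    })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, tip_results = tip_results,
                 snp_results = snp_results, tip_hits = tip_hits,
                 snp_hits = snp_hits, variance = variance_cmp,
                 pbs = pbs_res$table, pbs_freqs = pbs_res$freqs,
                 enrichment = enrichment, rank_sum = rank_sum,
                 specificity = spec_tab, cross_frequency = xfreq,
                 sweeps = sweeps, summary = summary))
}
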