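#' Simulate a full three-population cohort with ground truth
#'
#' Generates, under one seed, everything the downstream pipeline consumes:
#' a TIP zygosity matrix (with low-zygosity decoy loci and concentrated
#' missing data), the true binary TIP genotypes, a genome-wide SNP matrix
#' (background loci, gene-proximal loci, and dense +/- 50 kb regions around
#' planted sweep loci), gene models on a single synthetic chromosome,
#' negative-binomial expression counts for the two crop populations over
#' 2 conditions x 3 replicates, accession metadata with subpopulation
#' structure, and a truth table of planted effects.
#'
#' Layout: gene `i` occupies `[10000 + (i-1)*20000, ... + 2000)` on
#' `chr1`; planted eQTL TIPs are placed 0.1-4.5 kb upstream of their gene
#' (TIP-eQTLs concentrate upstream of genes in rice); three SNPs are placed
#' within the cis window of every gene so the SNP-eQTL scan has material;
#' remaining TIPs and SNPs are uniform over the chromosome.
#'
#' @param cfg [sim_config()].
#' @return list of class `tip_cohort` with elements `zygosity`
#'   ([tip_zygosity]), `tip_truth_calls` ([marker_matrix], pre-missingness
#'   truth), `snps` ([marker_matrix]), `genes`, `accessions`, `counts`,
#'   `samples`, `truth` (list `planted_eqtls`, `selected_tips`,
#'   `sweep_loci`), `frequencies` (drawn per-population frequencies), `cfg`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    chrom <- "chr1"
    chrom_len <- 20000L * cfg$n_genes + 20000L

    ## accessions -----------------------------------------------------------
    accessions <- data.frame(
      accession = c(sprintf("IND%03d", seq_len(cfg$n_pop1)),
                    sprintf("JAP%03d", seq_len(cfg$n_pop2)),
                    sprintf("WLD%03d", seq_len(cfg$n_pop3))),
      population = rep(c("pop1", "pop2", "pop3"),
                       c(cfg$n_pop1, cfg$n_pop2, cfg$n_pop3)),
      stringsAsFactors = FALSE
    )
    accessions$subpopulation <- c(
      sample(c("ind1", "ind2", "aus"), cfg$n_pop1, TRUE, c(0.5, 0.3, 0.2)),
      sample(c("jap_trp", "jap_tmp", "bas"), cfg$n_pop2, TRUE, c(0.5, 0.3, 0.2)),
      sample(c("ruf", "niv"), cfg$n_pop3, TRUE, c(0.88, 0.12))
    )

    ## gene models ----------------------------------------------------------
    genes <- gene_models(data.frame(
      id = sprintf("gene%04d", seq_len(cfg$n_genes)),
      chrom = chrom,
      start = 10000L + 20000L * (seq_len(cfg$n_genes) - 1L),
      end = 12000L + 20000L * (seq_len(cfg$n_genes) - 1L),
      strand = rep_len(c("+", "-"), cfg$n_genes),
      stringsAsFactors = FALSE
    ))

    ## TIP frequencies, selection, genotypes --------------------------------
    fr <- draw_tip_frequencies(cfg, seed = NULL)
    tip_calls <- cbind(
      draw_genotypes(fr$freq[, "pop1"], cfg$n_pop1, seed = NULL),
      draw_genotypes(fr$freq[, "pop2"], cfg$n_pop2, seed = NULL),
      draw_genotypes(fr$freq[, "pop3"], cfg$n_pop3, seed = NULL)
    )
    colnames(tip_calls) <- accessions$accession

    ## choose planted eQTL TIPs: a fixed fraction from the selected set, the
    ## rest from loci segregating at workable frequency in both crop pops
    crop <- accessions$population != "pop3"
    f1 <- rowMeans(tip_calls[, accessions$population == "pop1", drop = FALSE])
    f2 <- rowMeans(tip_calls[, accessions$population == "pop2", drop = FALSE])
    n_sel_eqtl <- min(round(cfg$selected_eqtl_frac * cfg$n_selected_tips),
                      cfg$n_eqtl_tips, nrow(fr$selected))
    sel_eqtl <- if (n_sel_eqtl > 0) {
      sample(fr$selected$tip, n_sel_eqtl)
    } else integer(0)
    cand <- setdiff(which(f1 >= 0.1 & f1 <= 0.9 & f2 >= 0.1 & f2 <= 0.9),
                    fr$selected$tip)
    n_other <- cfg$n_eqtl_tips - length(sel_eqtl)
    if (length(cand) < n_other) {
      stop("too few segregating TIPs to plant ", cfg$n_eqtl_tips, " eQTLs")
    }
    eqtl_tips <- c(sel_eqtl, sample(cand, n_other))

    ## TIP positions: uniform, then planted eQTL TIPs moved upstream of
    ## their (distinct, randomly assigned) genes, within the cis window
    tip_pos <- sort(sample.int(chrom_len, cfg$n_tips)) - 1L
    eqtl_genes <- sample.int(cfg$n_genes, cfg$n_eqtl_tips)
    tip_pos[eqtl_tips] <- genes$start[eqtl_genes] -
      as.integer(round(stats::runif(cfg$n_eqtl_tips, 100, 4500)))
    te_orders <- c("MITE", "TIR", "LTR", "LINE", "Helitron")
    te_fams <- list(MITE = c("Stowaway", "Tourist"),
                    TIR = c("MULE", "hAT", "CACTA"),
                    LTR = c("Gypsy", "Copia"),
                    LINE = "L1", Helitron = "Helitron")
    tip_order <- sample(te_orders, cfg$n_tips, TRUE,
                        prob = c(0.44, 0.40, 0.09, 0.04, 0.03))
    tip_family <- vapply(tip_order, function(o) {
      fams <- te_fams[[o]]
      if (length(fams) == 1) fams else sample(fams, 1)
    }, character(1))
    tip_loci <- data.frame(
      id = sprintf("TIP_%05d", seq_len(cfg$n_tips)),
      chrom = chrom, pos = tip_pos,
      te_family = unname(tip_family), te_order = unname(tip_order),
      stringsAsFactors = FALSE
    )
    tip_truth_calls <- marker_matrix(tip_loci, accessions$accession,
                                     tip_calls, type = "TIP")

    ## truth table ----------------------------------------------------------
    betas <- stats::runif(cfg$n_eqtl_tips, cfg$beta_range[1], cfg$beta_range[2]) *
      sample(c(-1, 1), cfg$n_eqtl_tips, TRUE, prob = c(0.59, 0.41))
    planted_eqtls <- data.frame(
      tip_id = tip_loci$id[eqtl_tips],
      gene_id = genes$id[eqtl_genes],
      beta = betas,
      condition_specific = stats::runif(cfg$n_eqtl_tips) <
        cfg$condition_specific_frac,
      stringsAsFactors = FALSE
    )
    selected_tips <- data.frame(
      tip_id = tip_loci$id[fr$selected$tip],
      focal_population = fr$selected$focal_pop,
      target = fr$selected$target,
      shift = fr$selected$shift,
      stringsAsFactors = FALSE
    )
    ## sweep loci: upward-shifted selected TIPs with enough carriers and
    ## room for the +/- 50 kb region inside the chromosome
    up_ok <- fr$selected$target > 0.5 &
      tip_pos[fr$selected$tip] > 50000L &
      tip_pos[fr$selected$tip] < chrom_len - 50000L
    sweep_pool <- fr$selected$tip[up_ok]
    sweep_pool <- sweep_pool[sample.int(length(sweep_pool))]
    sweep_tips <- utils::head(sweep_pool, cfg$n_sweep_loci)
    sweep_loci <- data.frame(
      tip_id = tip_loci$id[sweep_tips],
      sweep_type = if (cfg$sweep_carrier_haplotypes == 1) "hard" else "soft",
      stringsAsFactors = FALSE
    )
    truth <- list(planted_eqtls = planted_eqtls,
                  selected_tips = selected_tips,
                  sweep_loci = sweep_loci)

    ## SNP matrix -----------------------------------------------------------
    n_near <- 3L * cfg$n_genes
    near_pos <- rep(genes$start, each = 3L) +
      as.integer(round(stats::runif(n_near, -4500, 6500)))
    n_bg <- max(cfg$n_snps - n_near, 0L)
    bg_pos <- sample.int(chrom_len, n_bg) - 1L
    snp_pos <- c(near_pos, bg_pos)
    p0s <- pmin(pmax(stats::rbeta(length(snp_pos), 0.5, 0.5), 0.02), 0.98)
    fds <- cfg$fst_drift
    bn <- function(p) stats::rbeta(length(p), p * (1 - fds) / fds,
                                   (1 - p) * (1 - fds) / fds)
    snp_calls <- cbind(
      draw_genotypes(bn(p0s), cfg$n_pop1, seed = NULL),
      draw_genotypes(bn(p0s), cfg$n_pop2, seed = NULL),
      draw_genotypes(bn(p0s), cfg$n_pop3, seed = NULL)
    )
    snp_loci <- data.frame(
      id = sprintf("snp%06d", seq_along(snp_pos)),
      chrom = chrom, pos = snp_pos, stringsAsFactors = FALSE
    )
    ## tag SNPs in LD with the planted eQTL TIPs (two per TIP, inside the
    ## gene's cis window): copies of the TIP genotype with symmetric flips,
    ## so r ~= 1 - 2e; without them the TIP-vs-SNP variance comparison
    ## would have no linked SNPs at all
    for (k in seq_along(eqtl_tips)) {
      r2_target <- stats::runif(2, 0.2, 0.7)
      e <- (1 - sqrt(r2_target)) / 2
      for (j in 1:2) {
        tag <- tip_calls[eqtl_tips[k], ]
        flips <- stats::rbinom(length(tag), 1L, e[j])
        snp_loci <- rbind(snp_loci, data.frame(
          id = sprintf("snp_tag%03d_%d", k, j), chrom = chrom,
          pos = genes$start[eqtl_genes[k]] +
            as.integer(round(stats::runif(1, -4000, 5500))),
          stringsAsFactors = FALSE
        ))
        snp_calls <- rbind(snp_calls, abs(tag - flips))
      }
    }
    ## dense SNPs inside each sweep region
    for (k in seq_along(sweep_tips)) {
      rpos <- tip_pos[sweep_tips[k]] +
        sort(sample.int(100001L, cfg$sweep_region_snps)) - 50001L
      rfreq <- stats::runif(cfg$sweep_region_snps, 0.05, 0.95)
      snp_loci <- rbind(snp_loci, data.frame(
        id = sprintf("snp_sw%d_%04d", k, seq_len(cfg$sweep_region_snps)),
        chrom = chrom, pos = rpos, stringsAsFactors = FALSE
      ))
      snp_calls <- rbind(snp_calls,
                         draw_genotypes(rfreq, nrow(accessions), seed = NULL))
    }
    ## plant the sweeps: the swept haplotype is the one carrying the
    ## insertion, so carriers' alleles at EVERY SNP of the +/- 50 kb region
    ## (background and dense alike) collapse onto a small number of
    ## template haplotypes, with 1% per-site divergence
    for (k in seq_along(sweep_tips)) {
      tip <- sweep_tips[k]
      carriers <- which(tip_calls[tip, ] == 1L)
      region <- which(snp_loci$pos >= tip_pos[tip] - 50000L &
                        snp_loci$pos <= tip_pos[tip] + 50000L)
      n_templ <- min(cfg$sweep_carrier_haplotypes, length(carriers))
      templ_cols <- snp_calls[region,
                              carriers[sample.int(length(carriers), n_templ)],
                              drop = FALSE]
      assign_t <- sample.int(n_templ, length(carriers), replace = TRUE)
      hap <- templ_cols[, assign_t, drop = FALSE]
      flips <- matrix(stats::rbinom(length(hap), 1L, 0.01), nrow = nrow(hap))
      snp_calls[region, carriers] <- abs(hap - flips)
    }
    ord <- order(snp_loci$pos)
    ## positions can collide across placement passes; drop duplicates so the
    ## locus id remains the unique key
    ord <- ord[!duplicated(snp_loci$pos[ord])]
    snps <- marker_matrix(snp_loci[ord, ], accessions$accession,
                          snp_calls[ord, , drop = FALSE], type = "SNP")

    ## zygosity matrix with decoys and concentrated missingness -------------
    n_decoy <- as.integer(round(cfg$decoy_frac * cfg$n_tips))
    zyg_real <- matrix(0, cfg$n_tips, nrow(accessions))
    present <- tip_calls == 1L
    zyg_real[present] <- stats::runif(sum(present), 0.3, 1)
    faint <- !present & stats::runif(length(zyg_real)) < 0.02
    zyg_real[faint] <- stats::runif(sum(faint), 0, 0.049)
    decoy_loci <- data.frame(
      id = sprintf("TIPdecoy_%04d", seq_len(n_decoy)),
      chrom = chrom,
      pos = sample.int(chrom_len, max(n_decoy, 1L))[seq_len(n_decoy)] - 1L,
      te_family = sample(unname(unlist(te_fams)), n_decoy, TRUE),
      te_order = sample(te_orders, n_decoy, TRUE),
      stringsAsFactors = FALSE
    )
    zyg_decoy <- matrix(stats::runif(n_decoy * nrow(accessions), 0, 0.24),
                        nrow = n_decoy)
    zyg <- rbind(zyg_real, zyg_decoy)
    all_loci <- rbind(tip_loci, decoy_loci)
    if (cfg$missing_frac > 0) {
      hard <- stats::runif(nrow(zyg)) < 0.3
      cell_rate <- min(cfg$missing_frac / 0.3, 1)
      drop <- matrix(FALSE, nrow(zyg), ncol(zyg))
      drop[hard, ] <- stats::runif(sum(hard) * ncol(zyg)) < cell_rate
      zyg[drop] <- NA_real_
    }
    zygosity <- tip_zygosity(all_loci, accessions$accession, zyg)

    ## expression -----------------------------------------------------------
    expr <- simulate_expression(tip_truth_calls, truth, genes,
                                accessions[crop, , drop = FALSE], cfg,
                                seed = NULL)

    structure(list(
      zygosity = zygosity,
      tip_truth_calls = tip_truth_calls,
      snps = snps,
      genes = genes,
      accessions = accessions,
      counts = expr$counts,
      samples = expr$samples,
      truth = truth,
      frequencies = fr,
      cfg = cfg
    ), class = "tip_cohort")
  })
}

#' @export
print.tip_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "<tip_cohort> %d+%d+%d accessions | %d TIP loci (+%d decoys) | ",
    "%d SNPs | %d genes | %d planted eQTLs | %d selected | %d sweeps\n"),
    x$cfg$n_pop1, x$cfg$n_pop2, x$cfg$n_pop3,
    x$cfg$n_tips, nrow(x$zygosity$loci) - x$cfg$n_tips,
    nrow(x$snps$loci), nrow(x$genes),
    nrow(x$truth$planted_eqtls), nrow(x$truth$selected_tips),
    nrow(x$truth$sweep_loci)))
  invisible(x)
}
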