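#' Simulation configuration for synthetic three-population cohorts
#'
#' Defines the study design the generator emulates: two derived crop
#' populations (indica-like, japonica-like) plus one wild ancestral-proxy
#' population, Balding-Nichols frequency differentiation, planted cis
#' expression effects, planted frequency-shifted ("selected") TIPs with
#' optional hard/soft sweeps around them, and negative-binomial 3'-mRNA-seq
#' style counts over 2 conditions x 3 replicates.
#'
#' Default sample sizes follow the published design (126 indica, 82
#' japonica, 82 rufipogon/nivara accessions). Locus counts are desk-scale
#' stand-ins chosen so that every downstream stage has enough loci to be
#' exercised; see the methods vignette for the rationale behind each value.
#'
#' @param n_pop1,n_pop2,n_pop3 sample counts for derived population 1,
#'   derived population 2, and the wild proxy.
#' @param n_tips,n_snps,n_genes locus counts (background SNPs; sweep regions
#'   add their own).
#' @param fst_drift Balding-Nichols differentiation parameter in (0, 1),
#'   applied to each population relative to the shared ancestor.
#' @param n_selected_tips TIPs given a large frequency shift in exactly one
#'   derived population.
#' @param n_eqtl_tips TIPs with planted cis expression effects.
#' @param selected_eqtl_frac fraction of selected TIPs drawn from the
#'   planted-eQTL set (differential selection preferentially hits
#'   expression-associated insertions, as observed in rice).
#' @param beta_range planted effect-size range (natural-log units of
#'   expression mean per presence allele); signs drawn at random.
#' @param condition_specific_frac fraction of planted eQTLs whose effect is
#'   restricted to the drought-like condition.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param n_sweep_loci selected TIPs (shifted upward) that also receive a
#'   planted sweep among carriers.
#' @param sweep_carrier_haplotypes distinct template haplotypes among
#'   carriers at sweep loci (1 = hard sweep, >1 = soft).
#' @param sweep_region_snps SNPs simulated in each +/- 50 kb sweep region.
#' @param missing_frac overall fraction of missing zygosity cells (injected
#'   concentrated in 30% of loci; see vignette).
#' @param decoy_frac extra low-zygosity decoy loci (never above 0.25),
#'   as a fraction of `n_tips`, exercising the zygosity filter.
#' @param seed integer RNG seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_pop1 = 126L, n_pop2 = 82L, n_pop3 = 82L,
                       n_tips = 1500L, n_snps = 3000L, n_genes = 200L,
                       fst_drift = 0.1,
                       n_selected_tips = 16L, n_eqtl_tips = 30L,
                       selected_eqtl_frac = 0.5,
                       beta_range = c(0.5, 1.5),
                       condition_specific_frac = 0.25,
                       nb_dispersion = 0.2,
                       n_sweep_loci = 3L,
                       sweep_carrier_haplotypes = 2L,
                       sweep_region_snps = 250L,
                       missing_frac = 0.02,
                       decoy_frac = 0.05,
                       seed = 1L) {
  if (missing(n_sweep_loci)) {
    n_sweep_loci <- min(n_sweep_loci, n_selected_tips)
  }
  cfg <- list(
    n_pop1 = as.integer(n_pop1), n_pop2 = as.integer(n_pop2),
    n_pop3 = as.integer(n_pop3),
    n_tips = as.integer(n_tips), n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes),
    fst_drift = fst_drift,
    n_selected_tips = as.integer(n_selected_tips),
    n_eqtl_tips = as.integer(n_eqtl_tips),
    selected_eqtl_frac = selected_eqtl_frac,
    beta_range = as.numeric(beta_range),
    condition_specific_frac = condition_specific_frac,
    nb_dispersion = nb_dispersion,
    n_sweep_loci = as.integer(n_sweep_loci),
    sweep_carrier_haplotypes = as.integer(sweep_carrier_haplotypes),
    sweep_region_snps = as.integer(sweep_region_snps),
    missing_frac = missing_frac,
    decoy_frac = decoy_frac,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_pop1 > 0, n_pop2 > 0, n_pop3 > 0,
      n_tips > 0, n_snps > 0, n_genes > 0,
      fst_drift > 0, fst_drift < 1,
      n_selected_tips >= 0, n_selected_tips <= n_tips,
      n_eqtl_tips >= 0, n_eqtl_tips <= n_tips, n_eqtl_tips <= n_genes,
      n_sweep_loci <= n_selected_tips,
      sweep_carrier_haplotypes >= 1,
      length(beta_range) == 2, all(beta_range > 0),
      nb_dispersion >= 0, missing_frac >= 0, missing_frac < 1
    )
  })
  structure(cfg, class = "sim_config")
}

#' Draw per-TIP allele frequencies for three related populations
#'
#' Ancestral frequency `p0 ~ Beta(0.5, 0.5)` truncated to `[0.02, 0.98]`;
#' each population's frequency is then drawn from the Balding-Nichols
#' distribution `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` with `F = fst_drift`.
#' All three populations (the two derived crops and the wild proxy, which
#' has also drifted since the split) receive independent draws, so every
#' pairwise Hudson FST is approximately `F` and neutral loci have mean PBS
#' near zero on every branch. Selected TIPs are additionally shifted in
#' exactly one derived population: their frequency there is replaced by a
#' target drawn from `[0.8, 0.99]` (shift up) or `[0.01, 0.2]` (shift
#' down), the direction chosen away from `p0`.
#'
#' @param cfg [sim_config()].
#' @param seed seed; defaults to `cfg$seed`. Pass `NULL` to draw from the
#'   current RNG stream (used by [simulate_cohort()]).
#' @return list with `freq` (n_tips x 3 matrix, columns `pop1`, `pop2`,
#'   `pop3`), `p0`, and `selected` (data.frame `tip`, `focal_pop`,
#'   `target`, `shift`).
#' @export
draw_tip_frequencies <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    n <- cfg$n_tips
    p0 <- stats::rbeta(n, 0.5, 0.5)
    p0 <- pmin(pmax(p0, 0.02), 0.98)
    f <- cfg$fst_drift
    bn <- function(p) stats::rbeta(length(p), p * (1 - f) / f,
                                   (1 - p) * (1 - f) / f)
    freq <- cbind(pop1 = bn(p0), pop2 = bn(p0), pop3 = bn(p0))
    selected <- data.frame(tip = integer(0), focal_pop = character(0),
                           target = numeric(0), shift = numeric(0))
    if (cfg$n_selected_tips > 0) {
      sel <- sample.int(n, cfg$n_selected_tips)
      focal <- sample(c("pop1", "pop2"), cfg$n_selected_tips, replace = TRUE)
      up <- p0[sel] < 0.5  # shift away from the ancestral frequency
      target <- ifelse(up, stats::runif(cfg$n_selected_tips, 0.8, 0.99),
                       stats::runif(cfg$n_selected_tips, 0.01, 0.2))
      freq[cbind(sel, match(focal, colnames(freq)))] <- target
      selected <- data.frame(tip = sel, focal_pop = focal, target = target,
                             shift = abs(target - p0[sel]))
    }
    list(freq = freq, p0 = p0, selected = selected)
  })
}

#' Draw binary genotypes from per-locus frequencies
#'
#' Each call is an independent Bernoulli draw at the locus frequency
#' (haploid-equivalent presence/absence for inbred material).
#'
#' @param frequencies numeric vector of per-locus frequencies in `[0, 1]`.
#' @param n_samples number of samples (columns).
#' @param seed RNG seed.
#' @return integer matrix, loci x samples.
#' @export
draw_genotypes <- function(frequencies, n_samples, seed = 1L) {
  stopifnot(all(frequencies >= 0 & frequencies <= 1), n_samples >= 1)
  with_seed(seed, {
    matrix(stats::rbinom(length(frequencies) * n_samples, 1L,
                         rep(frequencies, times = n_samples)),
           nrow = length(frequencies), ncol = n_samples)
  })
}

#' Simulate a SNP haplotype region around a focal TIP
#'
#' Under neutrality every SNP allele is drawn independently at a per-SNP
#' frequency ~ Uniform(0.05, 0.95). Under a sweep, carrier samples are
#' copies of `n_templates` template haplotypes (soft sweep if > 1) with
#' per-site mutation probability `mutation_rate`, while non-carriers are
#' drawn as under neutrality. SNP positions are uniform over the
#' `2 * flank + 1` bp interval centred on the focal position.
#'
#' @param n_samples total samples.
#' @param n_snps SNP count in the region.
#' @param carriers integer indices (or logical mask) of carrier samples.
#' @param sweep logical; plant a sweep among carriers?
#' @param n_templates template haplotype count among carriers (default 2).
#' @param mutation_rate per-site divergence from the template, default 0.01.
#' @param focal_pos 0-based focal TIP position, default 50000.
#' @param flank region half-width in bp, default 50000.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return `haplotype_block`: list with `chrom`, `start`, `end`,
#'   `positions` (ascending, 0-based), `alleles` (samples x SNPs, 0/1),
#'   `carriers` (logical per sample).
#' @export
simulate_haplotype_region <- function(n_samples, n_snps, carriers,
                                      sweep = FALSE, n_templates = 2L,
                                      mutation_rate = 0.01,
                                      focal_pos = 50000L, flank = 50000L,
                                      chrom = "chr1", seed = 1L) {
  if (is.logical(carriers)) carriers <- which(carriers)
  if (sweep && length(carriers) == 0) {
    stop("sweep requested but carrier set is empty")
  }
  stopifnot(n_snps >= 1, n_samples >= 2,
            all(carriers >= 1 & carriers <= n_samples))
  with_seed(seed, {
    start <- focal_pos - flank
    span <- 2L * flank + 1L
    positions <- start + sort(sample.int(span, n_snps)) - 1L
    freqs <- stats::runif(n_snps, 0.05, 0.95)
    alleles <- matrix(stats::rbinom(n_samples * n_snps, 1L,
                                    rep(freqs, each = n_samples)),
                      nrow = n_samples, ncol = n_snps)
    is_carrier <- seq_len(n_samples) %in% carriers
    if (sweep) {
      templates <- matrix(stats::rbinom(n_templates * n_snps, 1L,
                                        rep(freqs, each = n_templates)),
                          nrow = n_templates, ncol = n_snps)
      assign_t <- sample.int(n_templates, length(carriers), replace = TRUE)
      hap <- templates[assign_t, , drop = FALSE]
      if (mutation_rate > 0) {
        flips <- matrix(stats::rbinom(length(hap), 1L, mutation_rate),
                        nrow = nrow(hap))
        hap <- abs(hap - flips)
      }
      alleles[carriers, ] <- hap
    }
    structure(list(chrom = chrom, start = start, end = focal_pos + flank + 1L,
                   positions = positions, alleles = alleles,
                   carriers = is_carrier),
              class = "haplotype_block")
  })
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("<haplotype_block> %s:[%d,%d) %d SNPs x %d samples (%d carriers)\n",
              x$chrom, x$start, x$end, length(x$positions),
              nrow(x$alleles), sum(x$carriers)))
  invisible(x)
}

#' Simulate a 3'-mRNA-seq-like expression matrix
#'
#' Per gene and accession, the expected count is
#' `mu = exp(b0 + b_subpop + beta * g (+ beta * g under drought only, for
#' condition-specific effects))` and counts are negative binomial with
#' variance `mu + nb_dispersion * mu^2`. Two conditions (`wet`, `drought`)
#' with three replicates each are emitted per accession.
#'
#' @param genotypes [marker_matrix] of TIP calls for the expression panel
#'   accessions (no missing values among planted eQTL loci).
#' @param truth truth table from [simulate_cohort()]; only `planted_eqtls`
#'   is used (`tip_id`, `gene_id`, `beta`, `condition_specific`).
#' @param genes gene model data.frame (ids define matrix rows).
#' @param metadata accession-level data.frame with `accession`,
#'   `population`, `subpopulation`.
#' @param cfg [sim_config()].
#' @param seed RNG seed.
#' @return list with `counts` (genes x samples integer matrix) and
#'   `samples` (per-column data.frame: `sample`, `accession`, `population`,
#'   `subpopulation`, `condition`, `replicate`).
#' @export
simulate_expression <- function(genotypes, truth, genes, metadata, cfg,
                                seed = 1L) {
  stopifnot(inherits(genotypes, "marker_matrix"),
            all(metadata$accession %in% genotypes$samples))
  planted <- truth$planted_eqtls
  with_seed(seed, {
    conditions <- c("wet", "drought")
    reps <- 1:3
    grid <- expand.grid(replicate = reps, condition = conditions,
                        accession = metadata$accession,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, c("accession", "condition", "replicate")]
    meta_idx <- match(grid$accession, metadata$accession)
    samples <- data.frame(
      sample = sprintf("%s_%s_r%d", grid$accession,
                       substr(grid$condition, 1, 3), grid$replicate),
      accession = grid$accession,
      population = metadata$population[meta_idx],
      subpopulation = metadata$subpopulation[meta_idx],
      condition = grid$condition,
      replicate = grid$replicate,
      stringsAsFactors = FALSE
    )
    ng <- nrow(genes)
    ns <- nrow(samples)
    b0 <- stats::rnorm(ng, mean = log(300), sd = 1)
    subpops <- unique(metadata$subpopulation)
    b_sub <- matrix(stats::rnorm(ng * length(subpops), 0, 0.2),
                    nrow = ng, dimnames = list(genes$id, subpops))
    log_mu <- matrix(b0, ng, ns) + b_sub[, samples$subpopulation, drop = FALSE]
    if (!is.null(planted) && nrow(planted) > 0) {
      g_acc <- genotypes$calls[planted$tip_id, samples$accession, drop = FALSE]
      if (anyNA(g_acc)) stop("planted eQTL genotypes must not be missing")
      gene_rows <- match(planted$gene_id, genes$id)
      for (k in seq_len(nrow(planted))) {
        eff <- planted$beta[k] * g_acc[k, ]
        if (planted$condition_specific[k]) {
          eff <- eff * (samples$condition == "drought")
        }
        log_mu[gene_rows[k], ] <- log_mu[gene_rows[k], ] + eff
      }
    }
    mu <- exp(log_mu)
    counts <- if (cfg$nb_dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
             nrow = ng)
    } else {
      matrix(stats::rpois(length(mu), mu), nrow = ng)
    }
    dimnames(counts) <- list(genes$id, samples$sample)
    list(counts = counts, samples = samples)
  })
}
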