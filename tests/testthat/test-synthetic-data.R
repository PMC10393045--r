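test_that("Balding-Nichols frequencies behave in the no-drift limit", {
  cfg <- sim_config(n_tips = 2000, fst_drift = 1e-4, n_selected_tips = 0,
                    seed = 3)
  fr <- draw_tip_frequencies(cfg)
  expect_lt(mean(abs(fr$freq[, "pop1"] - fr$p0)), 0.01)
  expect_lt(mean(abs(fr$freq[, "pop2"] - fr$p0)), 0.01)
  expect_true(all(fr$p0 >= 0.02 & fr$p0 <= 0.98))
})

test_that("empirical Hudson FST between populations matches fst_drift", {
  cfg <- sim_config(n_tips = 10000, fst_drift = 0.1, n_selected_tips = 0,
                    seed = 5)
  fr <- draw_tip_frequencies(cfg)
  g1 <- draw_genotypes(fr$freq[, "pop1"], 126, seed = 11)
  g3 <- draw_genotypes(fr$freq[, "pop3"], 82, seed = 12)
  p1 <- rowMeans(g1); p3 <- rowMeans(g3)
  hw <- (2 * p1 * (1 - p1) * 126 / 125 + 2 * p3 * (1 - p3) * 82 / 81) / 2
  hb <- p1 * (1 - p3) + p3 * (1 - p1)
  fst <- 1 - sum(hw) / sum(hb)  # ratio-of-sums over loci
  expect_lt(abs(fst - 0.1), 0.02)
})

test_that("selected TIPs are shifted in exactly one derived population", {
  cfg <- sim_config(n_tips = 500, n_selected_tips = 20, seed = 9)
  fr <- draw_tip_frequencies(cfg)
  sel <- fr$selected
  expect_true(all(sel$target >= 0.8 | sel$target <= 0.2))
  for (k in seq_len(nrow(sel))) {
    expect_equal(unname(fr$freq[sel$tip[k], sel$focal_pop[k]]),
                 sel$target[k])
  }
  # the other derived population keeps an un-shifted Balding-Nichols draw:
  # its frequency must not systematically sit at the target
  other <- ifelse(sel$focal_pop == "pop1", "pop2", "pop1")
  other_f <- fr$freq[cbind(sel$tip, match(other, colnames(fr$freq)))]
  expect_gt(mean(abs(other_f - sel$target)), 0.1)
})

test_that("genotype draws respect fixed and intermediate frequencies", {
  g <- draw_genotypes(c(0, 1, 0.5), 1000, seed = 2)
  expect_true(all(g[1, ] == 0L))
  expect_true(all(g[2, ] == 1L))
  expect_gt(mean(g[3, ]), 0.45)
  expect_lt(mean(g[3, ]), 0.55)
  expect_identical(g, draw_genotypes(c(0, 1, 0.5), 1000, seed = 2))
})

test_that("haplotype regions: sweep structure, positions, errors", {
  # one template, zero mutation: all carrier haplotypes identical, H12 = 1
  b <- simulate_haplotype_region(20, 60, carriers = 1:8, sweep = TRUE,
                                 n_templates = 1, mutation_rate = 0,
                                 seed = 4)
  carr <- b$alleles[1:8, ]
  expect_true(all(apply(carr, 2, function(col) length(unique(col)) == 1)))
  h12 <- window_h12(b, 1:8, window_snps = 50, step_snps = 25)
  expect_equal(h12$value[1], 1)
  expect_true(all(diff(b$positions) > 0))
  expect_true(all(b$positions >= b$start & b$positions < b$end))
  expect_error(
    simulate_haplotype_region(10, 30, carriers = integer(0), sweep = TRUE),
    "empty")
})

test_that("neutral-region pi matches its closed-form expectation", {
  # n = 2 samples: per-site diversity is the probability the two samples
  # differ; with per-SNP frequency p ~ U(0.05, 0.95), E[2p(1-p)] =
  # 2 * (E[p] - E[p^2]) = 2 * (0.5 - (0.25 + 0.9^2 / 12)) = 0.365
  expected <- 2 * (0.5 - (0.25 + 0.9^2 / 12))
  set.seed(42)
  vals <- vapply(1:500, function(i) {
    b <- simulate_haplotype_region(2, 25, carriers = 1, sweep = FALSE,
                                   seed = i)
    window_pi(b, 1:2, window_snps = 25, step_snps = 5)$value[1]
  }, numeric(1))
  expect_lt(abs(mean(vals) - expected), 0.02)
})

test_that("sweeps depress carrier diversity relative to neutral regions", {
  set.seed(7)
  pi_pair <- vapply(1:100, function(i) {
    bs <- simulate_haplotype_region(30, 50, carriers = 1:15, sweep = TRUE,
                                    seed = 1000 + i)
    bn <- simulate_haplotype_region(30, 50, carriers = 1:15, sweep = FALSE,
                                    seed = 2000 + i)
    c(mean(window_pi(bs, 1:15)$value), mean(window_pi(bn, 1:15)$value))
  }, numeric(2))
  expect_lt(mean(pi_pair[1, ]), mean(pi_pair[2, ]))
})

test_that("expression simulation: dispersion limit, conditioning, determinism", {
  genes <- gene_models(data.frame(id = c("g1", "g2"), chrom = "chr1",
                                  start = c(1000, 9000),
                                  end = c(3000, 11000), strand = "+"))
  meta <- data.frame(accession = sprintf("A%02d", 1:40),
                     population = "pop1",
                     subpopulation = "s1")
  g <- marker_matrix(
    data.frame(id = "t1", chrom = "chr1", pos = 500),
    meta$accession,
    matrix(rep(c(0L, 1L), 20), 1), type = "TIP")
  truth <- list(planted_eqtls = data.frame(
    tip_id = "t1", gene_id = "g1", beta = 1.0, condition_specific = TRUE))
  cfg <- sim_config(nb_dispersion = 0, seed = 1)
  ex <- simulate_expression(g, truth, genes, meta, cfg, seed = 5)
  # Poisson limit: variance ~ mean for replicate counts of one cell type
  base <- ex$counts["g2", ex$samples$subpopulation == "s1" &
                      ex$samples$condition == "wet"]
  expect_lt(var(base) / mean(base), 2.5)  # Poisson ratio ~ 1, NB(0.2) ~ 60
  # condition-specific effect acts under drought only
  carrier <- ex$samples$accession %in% meta$accession[g$calls[1, ] == 1]
  wet <- ex$samples$condition == "wet"
  lfc_wet <- log(mean(ex$counts["g1", carrier & wet]) /
                   mean(ex$counts["g1", !carrier & wet]))
  lfc_dro <- log(mean(ex$counts["g1", carrier & !wet]) /
                   mean(ex$counts["g1", !carrier & !wet]))
  expect_lt(abs(lfc_wet), 0.3)
  expect_gt(lfc_dro, 0.6)
  ex2 <- simulate_expression(g, truth, genes, meta, cfg, seed = 5)
  expect_identical(ex$counts, ex2$counts)
})

test_that("cohorts are reproducible and consistent with their truth table", {
  cfg <- sim_config(n_pop1 = 40, n_pop2 = 30, n_pop3 = 30, n_tips = 300,
                    n_snps = 800, n_genes = 50, n_eqtl_tips = 10,
                    n_selected_tips = 6, n_sweep_loci = 1, seed = 21)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$counts, co2$counts)
  expect_identical(co1$zygosity$values, co2$zygosity$values)
  expect_identical(co1$snps$calls, co2$snps$calls)
  # every planted eQTL TIP lies within the cis window of its gene
  pairs <- enumerate_cis_pairs(co1$genes, co1$tip_truth_calls)
  planted_keys <- with(co1$truth$planted_eqtls, paste(gene_id, tip_id))
  expect_true(all(planted_keys %in% paste(pairs$gene_id, pairs$marker_id)))
  # truth ids all exist
  expect_true(all(co1$truth$selected_tips$tip_id %in% co1$tip_truth_calls$loci$id))
  expect_true(all(co1$truth$planted_eqtls$gene_id %in% co1$genes$id))
  # binarizing the zygosity matrix recovers the true genotypes on
  # non-missing cells of non-decoy loci
  g <- binarize_zygosity(co1$zygosity)
  real <- g$calls[co1$tip_truth_calls$loci$id, ]
  obs <- !is.na(real)
  expect_equal(real[obs], co1$tip_truth_calls$calls[obs])
})
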