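test_that("expression filter uses a strict fraction threshold", {
  counts <- rbind(c(rep(1, 10), rep(0, 90)),   # 10% exactly -> dropped
                  c(rep(1, 11), rep(0, 89)),   # 11% -> kept
                  rep(0, 100))                 # all-zero -> dropped
  rownames(counts) <- c("a", "b", "c")
  expect_equal(rownames(filter_expressed_genes(counts)), "b")
})

test_that("median-of-ratios normalization equalizes scaled libraries", {
  toy <- matrix(c(10, 50, 100, 400, 800), 5, 1)
  counts <- cbind(s1 = toy[, 1], s2 = 2 * toy[, 1])
  norm <- normalize_counts(counts)
  expect_equal(unname(attr(norm, "size_factors")[2] /
                        attr(norm, "size_factors")[1]), 2)
  expect_equal(norm[, 1], norm[, 2])
  # identical samples: unit size factors
  same <- cbind(a = toy[, 1], b = toy[, 1])
  expect_equal(unname(attr(normalize_counts(same), "size_factors")),
               c(1, 1))
  # monotone in the raw count within a sample
  set.seed(2)
  m <- matrix(rpois(200, 20), 50, 4)
  n <- normalize_counts(m)
  for (j in 1:4) expect_true(all(diff(n[order(m[, j]), j]) >= 0))
  # no all-positive gene: library-size fallback with a warning
  z <- rbind(c(5, 0), c(0, 5))
  expect_warning(nz <- normalize_counts(z), "library-size")
  expect_equal(unname(attr(nz, "size_factors")), c(1, 1))
})

test_that("size factors agree with DESeq2's median-of-ratios", {
  set.seed(8)
  counts <- matrix(rnbinom(300 * 12, mu = 150, size = 5), 300, 12)
  counts <- sweep(counts, 2, exp(runif(12, -0.7, 0.7)), "*")
  counts <- round(counts)
  sf <- attr(normalize_counts(counts), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("cis pair enumeration applies the strict 5 kb boundary", {
  genes <- gene_models(data.frame(id = "g", chrom = "chr1", start = 20000,
                                  end = 22000, strand = "+"))
  pos <- c(15000,  # exactly 5000 bp before start -> excluded
           15001,  # 4999 bp upstream -> included, distance -4999
           20500,  # inside -> distance 0
           26998,  # 4999 bp after end -> included, +4999
           26999)  # 5000 bp after end -> excluded
  markers <- data.frame(id = paste0("m", 1:5), chrom = "chr1", pos = pos)
  pairs <- enumerate_cis_pairs(genes, markers)
  expect_equal(pairs$marker_id, c("m2", "m3", "m4"))
  expect_equal(pairs$distance, c(-4999L, 0L, 4999L))
  # on the minus strand the signed orientation flips
  genes_m <- genes; genes_m$strand <- "-"
  pairs_m <- enumerate_cis_pairs(genes_m, markers)
  expect_equal(pairs_m$distance, c(4999L, 0L, -4999L))
  # different chromosome: no pairs
  markers_chr2 <- markers; markers_chr2$chrom <- "chr2"
  expect_equal(nrow(enumerate_cis_pairs(genes, markers_chr2)), 0)
})

test_that("association fit recovers strong effects and matches lm", {
  set.seed(4)
  g <- rep(c(0, 1), 30)
  y <- 2 * g + rnorm(60, sd = 1e-4)
  fit <- fit_linear_association(y, g)
  expect_equal(fit$beta, 2, tolerance = 1e-4)
  expect_gt(fit$r2, 0.999)
  expect_lt(fit$p, 1e-20)
  # with covariates, against the full lm fit (independent route)
  subpop <- factor(rep(c("a", "b", "c"), each = 20))
  y2 <- 0.8 * g + c(0, 1, -1)[as.integer(subpop)] + rnorm(60, sd = 0.5)
  fit2 <- fit_linear_association(y2, g, subpop)
  lmfit <- summary(lm(y2 ~ subpop + g))
  expect_equal(fit2$beta, lmfit$coefficients["g", 1], tolerance = 1e-10)
  expect_equal(fit2$se, lmfit$coefficients["g", 2], tolerance = 1e-10)
  expect_equal(fit2$p, lmfit$coefficients["g", 4], tolerance = 1e-10)
  expect_error(fit_linear_association(y, rep(1, 60)), "constant")
})

test_that("subpopulation covariates remove stratification confounding", {
  set.seed(12)
  n <- 200
  subpop <- factor(rep(c("a", "b"), each = n / 2))
  # marker frequency differs by subpopulation; expression depends only on
  # subpopulation -> naive fit is confounded, adjusted fit is not
  g <- rbinom(n, 1, ifelse(subpop == "a", 0.8, 0.2))
  y <- ifelse(subpop == "a", 1, 0) + rnorm(n, sd = 0.3)
  naive <- fit_linear_association(y, g)
  adj <- fit_linear_association(y, g, subpop)
  expect_gt(abs(naive$beta), 0.4)
  expect_lt(abs(adj$beta), 0.15)
})

test_that("null association p-values are approximately uniform", {
  set.seed(33)
  ps <- vapply(1:1000, function(i) {
    g <- rbinom(40, 1, 0.5)
    while (var(g) == 0) g <- rbinom(40, 1, 0.5)
    fit_linear_association(rnorm(40), g)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  p <- runif(8)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

make_scan_cohort <- function(seed, n_acc = 60, n_genes = 12, beta = 1.2) {
  withr::with_seed(seed, {
    genes <- gene_models(data.frame(
      id = sprintf("g%02d", 1:n_genes), chrom = "chr1",
      start = 10000 + 20000 * (0:(n_genes - 1)),
      end = 12000 + 20000 * (0:(n_genes - 1)), strand = "+"))
    meta_acc <- data.frame(
      accession = sprintf("A%03d", 1:n_acc), population = "pop1",
      subpopulation = sample(c("s1", "s2"), n_acc, TRUE))
    calls <- matrix(rbinom(n_genes * n_acc, 1, 0.5), n_genes, n_acc)
    markers <- marker_matrix(
      data.frame(id = sprintf("t%02d", 1:n_genes), chrom = "chr1",
                 pos = genes$start - 1000L, te_family = "Stowaway",
                 te_order = "MITE"),
      meta_acc$accession, calls, type = "TIP")
    truth <- list(planted_eqtls = data.frame(
      tip_id = "t01", gene_id = "g01", beta = beta,
      condition_specific = FALSE))
    ex <- simulate_expression(markers, truth, genes, meta_acc,
                              sim_config(seed = 1), seed = seed + 1)
    list(genes = genes, markers = markers, counts = ex$counts,
         samples = ex$samples, truth = truth)
  })
}

test_that("the scan is deterministic and invariant to input order", {
  co <- make_scan_cohort(71)
  r1 <- run_eqtl_scan(co$counts, co$genes, co$markers, co$samples, "pop1")
  r2 <- run_eqtl_scan(co$counts, co$genes, co$markers, co$samples, "pop1")
  expect_identical(r1, r2)
  # shuffle gene and marker input order: same rows modulo sorting
  perm_g <- sample(nrow(co$genes))
  perm_m <- sample(nrow(co$markers$loci))
  r3 <- run_eqtl_scan(co$counts, co$genes[perm_g, ],
                      subset_loci(co$markers, perm_m), co$samples, "pop1")
  key <- function(d) d[order(d$gene_id, d$marker_id, d$condition,
                             d$replicate), ]
  expect_equal(key(r3), key(r1), ignore_attr = TRUE)
  # planted association is found, q < 0.05 in at least one replicate
  expect_lt(min(r1$q[r1$gene_id == "g01" & r1$marker_id == "t01"]), 0.05)
  # mismatched samples produce a structured error
  bad <- co$samples
  bad$accession[1] <- "NOPE"
  expect_error(
    run_eqtl_scan(co$counts, co$genes, co$markers, bad, "pop1"),
    "NOPE")
})

test_that("replicate consolidation applies the one-replicate rule and tie-breaks", {
  base <- data.frame(
    gene_id = "g1", marker_type = "TIP", beta = 1, se = 0.1, t = 10,
    r2 = 0.5, distance = 100L, marker_pos = 500L, condition = "wet",
    population = "pop1", stringsAsFactors = FALSE)
  rows <- rbind(
    cbind(base, marker_id = "m1", p = 0.001, q = 0.04, replicate = 1),
    cbind(base, marker_id = "m1", p = 0.1, q = 0.2, replicate = 2),
    cbind(base, marker_id = "m1", p = 0.2, q = 0.3, replicate = 3),
    cbind(base, marker_id = "m2", p = 0.02, q = 0.06, replicate = 1),
    cbind(base, marker_id = "m2", p = 0.02, q = 0.06, replicate = 2),
    cbind(base, marker_id = "m2", p = 0.02, q = 0.06, replicate = 3))
  cons <- consolidate_replicates(rows)
  expect_equal(cons$hits$marker_id, "m1")   # m2 never reaches q < 0.05
  expect_equal(cons$leading$marker_id, "m1")
  # tie on min_q: smaller |distance| wins, then leftmost position
  rows2 <- rbind(
    cbind(base, marker_id = "mA", p = 0.001, q = 0.01, replicate = 1),
    cbind(base[, setdiff(names(base), c("distance", "marker_pos"))],
          distance = 50L, marker_pos = 300L, marker_id = "mB", p = 0.001,
          q = 0.01, replicate = 1))
  cons2 <- consolidate_replicates(rows2)
  expect_equal(cons2$leading$marker_id, "mB")
})

test_that("variance comparison prefers the causal marker class", {
  set.seed(91)
  n <- 120
  cat_of <- function(causal_tip) {
    meta_acc <- data.frame(accession = sprintf("A%03d", 1:n),
                           population = "pop1", subpopulation = "s1")
    # background genes keep the size factors stable; only g01 is tested
    genes <- gene_models(data.frame(
      id = sprintf("g%02d", 1:10), chrom = "chr1",
      start = 10000 + 50000 * (0:9), end = 12000 + 50000 * (0:9),
      strand = "+"))
    g_causal <- rbinom(n, 1, 0.5)
    flip <- rbinom(n, 1, (1 - sqrt(0.3)) / 2)  # tag with r^2 ~ 0.3
    g_tag <- abs(g_causal - flip)
    tips <- marker_matrix(
      data.frame(id = "t01", chrom = "chr1", pos = 9000,
                 te_family = "f", te_order = "o"),
      meta_acc$accession,
      matrix(if (causal_tip) g_causal else g_tag, 1), type = "TIP")
    snps <- marker_matrix(
      data.frame(id = "s01", chrom = "chr1", pos = 9500),
      meta_acc$accession,
      matrix(if (causal_tip) g_tag else g_causal, 1), type = "SNP")
    truth <- list(planted_eqtls = data.frame(
      tip_id = "t01", gene_id = "g01", beta = 1.5,
      condition_specific = FALSE))
    causal_markers <- if (causal_tip) tips else {
      marker_matrix(tips$loci, meta_acc$accession, matrix(g_causal, 1),
                    type = "TIP")
    }
    ex <- simulate_expression(causal_markers, truth, genes, meta_acc,
                              sim_config(seed = 1), seed = NULL)
    tr <- run_eqtl_scan(ex$counts, genes, tips, ex$samples, "pop1")
    sr <- run_eqtl_scan(ex$counts, genes, snps, ex$samples, "pop1")
    cmp <- compare_variance_explained(consolidate_replicates(tr)$leading, sr)
    if (nrow(cmp$genes) == 0) NA_character_ else cmp$genes$category
  }
  tip_causal <- table(unlist(replicate(12, cat_of(TRUE), simplify = FALSE)))
  snp_causal <- table(unlist(replicate(12, cat_of(FALSE), simplify = FALSE)))
  tip_pref <- sum(tip_causal[c("TIP_gt_SNP", "TIP_only")], na.rm = TRUE)
  expect_gt(tip_pref, sum(tip_causal) / 2)
  expect_gt(sum(snp_causal["SNP_ge_TIP"], na.rm = TRUE),
            sum(snp_causal) / 2)
})

test_that("relaxed-cutoff sharing is reflexive and sign-aware", {
  co <- make_scan_cohort(55)
  res <- run_eqtl_scan(co$counts, co$genes, co$markers, co$samples, "pop1")
  hits <- consolidate_replicates(res)$hits
  expect_gt(nrow(hits), 0)
  sh <- shared_associations(hits, res)
  expect_equal(sh$shared_fraction, 1.0)  # identical datasets share fully
  flipped <- res
  flipped$beta <- -flipped$beta
  sh2 <- shared_associations(hits, flipped)
  expect_equal(sh2$shared_fraction, 0.0)  # opposite sign is never shared
})

test_that("effect-frequency profile bins cover [0,1] without overlap", {
  hits <- data.frame(marker_id = c("a", "b", "c"), beta = c(1, 1, -2))
  freqs <- c(a = 0.5, b = 0.52, c = 0.999)
  prof <- effect_size_frequency_profile(hits, freqs)
  expect_equal(min(prof$bin_low), 0)
  expect_equal(max(prof$bin_high), 1)
  expect_equal(sum(prof$n), 3)
  pos_bin <- prof[prof$sign == "positive" & prof$bin_low == 0.5, ]
  expect_equal(pos_bin$n, 2)
  expect_equal(pos_bin$mean_beta, 1)
  # frequency 0.999 falls in the closing [0.95, 1] bin
  neg_bin <- prof[prof$sign == "negative" & prof$bin_low == 0.95, ]
  expect_equal(neg_bin$n, 1)
  # bins tile [0,1]: widths sum to 1 per sign
  expect_equal(sum(prof$bin_high - prof$bin_low) / 2, 1)
})
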