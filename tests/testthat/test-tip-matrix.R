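test_that("zygosity filter keeps exactly the loci reaching the cutoff", {
  m <- make_zyg(rbind(c(0.10, 0.20, 0.24),   # never reaches 0.25 -> dropped
                      c(0.00, 0.25, 0.10),   # boundary inclusive -> kept
                      c(NA, 0.24, NA),       # max over non-missing only
                      c(0.9, 0.9, 0.9)))
  f <- filter_low_zygosity(m)
  expect_equal(f$loci$id, c("L002", "L004"))
  expect_warning(filter_low_zygosity(make_zyg(rbind(c(0.1, 0.1)))),
                 "all loci removed")
  empty <- make_zyg(matrix(numeric(0), 0, 3))
  expect_equal(nrow(filter_low_zygosity(empty)$values), 0)
})

test_that("binarization uses an inclusive presence cutoff and keeps NA", {
  m <- make_zyg(rbind(c(0.05, 0.049, 0), c(NA, 1, 0.3)))
  g <- binarize_zygosity(m)
  expect_equal(unname(g$calls[1, ]), c(1L, 0L, 0L))
  expect_equal(unname(g$calls[2, ]), c(NA_integer_, 1L, 1L))
  # all-zero matrix is all-absent
  expect_true(all(binarize_zygosity(make_zyg(matrix(0, 2, 4)))$calls == 0L))
  # idempotence: rebinarizing the 0/1 calls as zygosities changes nothing
  z2 <- make_zyg(g$calls * 1.0)
  z2$values[is.na(g$calls)] <- NA
  expect_equal(binarize_zygosity(z2)$calls, g$calls)
})

test_that("MAF/missingness filter honours preset boundary semantics", {
  # 100 samples, 3 present: MAF 0.03 is not > 0.03 -> dropped by eqtl preset
  calls3 <- matrix(0L, 1, 100); calls3[1, 1:3] <- 1L
  calls4 <- matrix(0L, 1, 100); calls4[1, 1:4] <- 1L
  expect_equal(nrow(filter_maf_missing(make_markers(calls3),
                                       preset = "eqtl")$calls), 0)
  expect_equal(nrow(filter_maf_missing(make_markers(calls4),
                                       preset = "eqtl")$calls), 1)
  # any missing call fails the eqtl preset
  calls_na <- calls4; calls_na[1, 99] <- NA
  expect_equal(nrow(filter_maf_missing(make_markers(calls_na),
                                       preset = "eqtl")$calls), 0)
  # 6% missing fails the pbs preset; 5% missing with MAF exactly 0.05 passes
  calls6 <- matrix(rep(c(1L, 0L), 50), 1, 100); calls6[1, 1:6] <- NA
  expect_equal(nrow(filter_maf_missing(make_markers(calls6),
                                       preset = "pbs")$calls), 0)
  calls5 <- matrix(0L, 1, 100)
  calls5[1, 1:5] <- NA          # 5% missing
  calls5[1, 6:10] <- 1L         # MAF 5/95 > 0.05 actually; make exactly 0.05
  calls_eq <- matrix(0L, 1, 100)
  calls_eq[1, 1:5] <- 1L        # MAF exactly 0.05, complete
  expect_equal(nrow(filter_maf_missing(make_markers(calls_eq),
                                       preset = "pbs")$calls), 1)
  expect_error(filter_maf_missing(make_markers(calls4), min_maf = 0.5),
               "min_maf")
})

test_that("imputation fills missing calls and nothing else", {
  calls <- matrix(1L, 1, 10); calls[1, 1] <- NA
  g <- make_markers(calls)
  gi <- impute_missing(g, "expected")
  expect_equal(unname(gi$calls[1, 1]), 1L)  # freq 0.9 -> present
  expect_false(anyNA(gi$calls))
  # no missing values -> identity
  g_full <- make_markers(matrix(c(1L, 0L), 2, 6))
  expect_identical(impute_missing(g_full)$calls, g_full$calls)
  # all-missing locus is an error
  expect_error(impute_missing(make_markers(matrix(NA_integer_, 1, 5))),
               "all calls missing")
  # bernoulli mode matches the locus frequency on many cells
  set.seed(1)
  big <- matrix(rbinom(200 * 100, 1, 0.3), 200, 100)
  big[, 1:50] <- NA  # 10,000 missing cells; observed freq per locus ~0.3
  gb <- make_markers(big)
  gbi <- impute_missing(gb, "bernoulli", seed = 7)
  filled <- gbi$calls[, 1:50]
  obs_freq <- mean(rowMeans(big[, 51:100]))
  expect_lt(abs(mean(filled) - obs_freq), 0.02)
  # deterministic under the seed
  expect_identical(gbi$calls, impute_missing(gb, "bernoulli", seed = 7)$calls)
})

test_that("per-population frequencies count non-missing calls only", {
  calls <- rbind(c(1L, 1L, 1L, 1L, 0L, 0L, 1L, 0L),
                 c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
                 c(NA, NA, NA, NA, 1L, 0L, 1L, 1L))
  g <- make_markers(calls)
  groups <- setNames(rep(c("A", "B"), each = 4), g$samples)
  ft <- allele_frequency(g, groups)
  expect_equal(unname(ft$freq[1, ]), c(1.0, 0.25))
  expect_equal(unname(ft$freq[2, "A"]), 0.5)
  expect_true(is.na(ft$freq[3, "A"]))  # zero non-missing calls in group A
  expect_equal(unname(ft$n[3, ]), c(0L, 4L))
  # permuting sample order leaves frequencies unchanged
  perm <- sample(g$samples)
  ft2 <- allele_frequency(subset_samples(g, perm), groups[perm])
  expect_equal(ft2$freq, ft$freq)
  expect_error(allele_frequency(g, groups[-1]), "unmapped")
})

test_that("population specificity labels follow the frequency rules", {
  calls <- matrix(0L, 4, 20)
  g <- make_markers(calls)
  ft <- allele_frequency(g, setNames(rep(c("A", "B"), each = 10), g$samples))
  ft$freq <- rbind(c(0.4, 0.0), c(0.4, 0.5), c(0.01, 0.02), c(0.4, 0.02))
  colnames(ft$freq) <- c("A", "B")
  lab <- classify_population_specificity(ft, "A", "B")
  expect_equal(lab$label, c("popA_specific", "shared", "rare_both",
                            "popA_specific"))
  expect_equal(lab$strict, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("cross-population table measures the equal-frequency fraction", {
  g <- make_markers(matrix(0L, 4, 20))
  ft <- allele_frequency(g, setNames(rep(c("A", "B"), each = 10), g$samples))
  ft$freq <- rbind(c(0.3, 0.3), c(0.6, 0.6), c(1, 0), c(0.9, 0.05))
  colnames(ft$freq) <- c("A", "B")
  xt <- cross_population_frequency_table(ft, c(FALSE, FALSE, TRUE, TRUE),
                                         "A", "B")
  expect_equal(unname(xt$equal_fraction["non_eqtl"]), 1.0)
  expect_equal(unname(xt$equal_fraction["eqtl"]), 0.0)
  expect_equal(sum(xt$counts$eqtl), 2)
})

test_that("filter order commutes and presets nest as documented", {
  set.seed(11)
  vals <- matrix(runif(50 * 20), 50, 20)
  m <- make_zyg(vals)
  a <- binarize_zygosity(filter_low_zygosity(m))
  b_full <- binarize_zygosity(m)
  keep <- rownames(b_full$calls) %in% rownames(a$calls)
  expect_identical(a$calls, subset_loci(b_full, keep)$calls)
  # eqtl-preset survivors with MAF < 0.05 are removed by the pbs preset
  calls <- matrix(rbinom(2000, 1, 0.04), 100, 20)
  g <- make_markers(cbind(calls, matrix(rbinom(8000, 1, 0.5), 100, 80)))
  ge <- filter_maf_missing(g, preset = "eqtl")
  freq <- rowMeans(ge$calls)
  low <- pmin(freq, 1 - freq) < 0.05
  gp <- filter_maf_missing(ge, preset = "pbs")
  expect_true(all(!ge$loci$id[low] %in% gp$loci$id))
  # and imputation makes every locus/group frequency defined
  vals_na <- vals; vals_na[sample(length(vals), 30)] <- NA
  gna <- binarize_zygosity(make_zyg(vals_na))
  gi <- impute_missing(gna)
  fi <- allele_frequency(gi, setNames(rep(c("A", "B"), each = 10),
                                      gi$samples))
  expect_false(anyNA(fi$freq))
})
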