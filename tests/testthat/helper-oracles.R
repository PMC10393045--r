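# Independent brute-force oracles. These deliberately avoid the package's
# own computation paths: pairwise loops, direct enumeration, closed forms.

# Mean pairwise Hamming distance per site over distinct sample pairs.
brute_pi <- function(alleles) {
  n <- nrow(alleles)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(alleles[i, ] != alleles[j, ])
  }
  tot / choose(n, 2) / ncol(alleles)
}

# H12 by explicit haplotype counting.
brute_h12 <- function(alleles) {
  key <- apply(alleles, 1, paste, collapse = ",")
  p <- sort(as.vector(table(key)) / nrow(alleles), decreasing = TRUE)
  if (length(p) == 1) return(1)
  (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
}

# Hudson FST from explicit genotype vectors: 1 - Hw/Hb with Hw the mean
# fraction of differing distinct pairs within each population and Hb the
# fraction of differing between-population pairs.
brute_fst <- function(g1, g2) {
  pair_diff <- function(g) {
    n <- length(g); tot <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + (g[i] != g[j])
    tot / choose(n, 2)
  }
  hw <- (pair_diff(g1) + pair_diff(g2)) / 2
  hb <- mean(outer(g1, g2, "!="))
  if (hb == 0) return(0)
  min(max(1 - hw / hb, 0), 1 - 1e-9)
}

# Textbook BH step-up, enumerated directly.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins.
brute_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  probs <- vapply(lo:hi, function(x) {
    stats::dhyper(x, m1, m2, n1)
  }, numeric(1))
  p_obs <- stats::dhyper(a, m1, m2, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small zygosity-matrix builder for filter tests.
make_zyg <- function(values, samples = NULL, te_order = "MITE") {
  values <- as.matrix(values)
  samples <- samples %||% sprintf("S%02d", seq_len(ncol(values)))
  nr <- nrow(values)
  loci <- data.frame(
    id = sprintf("L%03d", seq_len(nr)),
    chrom = rep("chr1", nr),
    pos = seq_len(nr) * 100L,
    te_family = rep("Stowaway", nr),
    te_order = rep(te_order, length.out = nr)
  )
  tip_zygosity(loci, samples, values)
}

make_markers <- function(calls, type = "TIP", pos = NULL, chrom = "chr1") {
  calls <- as.matrix(calls)
  loci <- data.frame(
    id = sprintf("M%03d", seq_len(nrow(calls))),
    chrom = chrom,
    pos = pos %||% (seq_len(nrow(calls)) * 100L),
    te_family = "Stowaway",
    te_order = "MITE"
  )
  marker_matrix(loci, sprintf("S%02d", seq_len(ncol(calls))), calls,
                type = type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Desk-scale demo pipeline configuration shared by the pipeline smoke and
# determinism tests (sizes documented in the methods vignette).
demo_pipeline_config <- function() {
  pipeline_config(
    simulate = list(n_pop1 = 60, n_pop2 = 40, n_pop3 = 40, n_tips = 400,
                    n_snps = 1200, n_genes = 60, n_eqtl_tips = 12,
                    n_selected_tips = 8, n_sweep_loci = 2,
                    sweep_region_snps = 150),
    sweep = list(n_perm = 200)
  )
}
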