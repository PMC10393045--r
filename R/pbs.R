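#' Per-locus FST between two populations
#'
#' Default is the Hudson estimator written in heterozygosity form,
#' `fst = 1 - Hw / Hb`, with `Hw` the mean within-population expected
#' heterozygosity using the unbiased `n/(n-1)` correction (equal to the
#' mean pairwise difference among distinct haplotypes within a population)
#' and `Hb = p1 (1 - p2) + p2 (1 - p1)` the between-population
#' heterozygosity. Hudson's estimator is standard for PBS because it is
#' robust to unequal sample sizes. A haploid Weir-Cockerham estimator is
#' available behind `estimator = "wc"`. Estimates are clamped to
#' `[0, 1 - 1e-9]`; a locus with `Hb = 0` (both populations fixed for the
#' same allele) has `fst = 0`.
#'
#' @param p1,p2 presence frequencies (vectors allowed).
#' @param n1,n2 haploid sample sizes (>= 2).
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return FST values in `[0, 1 - 1e-9]`.
#' @export
per_locus_fst <- function(p1, n1, p2, n2, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  if (any(n1 < 2) || any(n2 < 2)) stop("need n >= 2 haploid samples per population")
  if (estimator == "hudson") {
    hw <- (2 * p1 * (1 - p1) * n1 / (n1 - 1) +
             2 * p2 * (1 - p2) * n2 / (n2 - 1)) / 2
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- ifelse(hb == 0, 0, 1 - hw / hb)
  } else {
    ## Weir & Cockerham (1984) theta for haploid allele counts, r = 2 demes
    n_tot <- n1 + n2
    p_bar <- (n1 * p1 + n2 * p2) / n_tot
    msp <- n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2  # / (r - 1) = 1
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n_tot - 2)
    nc <- n_tot - (n1^2 + n2^2) / n_tot
    denom <- msp + (nc - 1) * msg
    fst <- ifelse(denom == 0, 0, (msp - msg) / denom)
  }
  pmin(pmax(fst, 0), 1 - 1e-9)
}

#' Branch-length transform of FST
#'
#' `t = -ln(1 - fst)`, the divergence-time proxy used by the Population
#' Branch Statistic.
#'
#' @param fst FST values in `[0, 1)`.
#' @return Branch lengths `t >= 0`.
#' @export
branch_length <- function(fst) {
  if (any(fst >= 1 | fst < 0)) {
    stop("fst must lie in [0, 1); clamp estimates before transforming")
  }
  -log(1 - fst)
}

#' PBS for both focal branches from three pairwise FSTs
#'
#' `pbs_i = (t_ij + t_iw - t_jw) / 2` and symmetrically for `pbs_j`, with
#' `t = -ln(1 - fst)`. The identity `pbs_i + pbs_j = t_ij` holds by
#' construction, and the wild-proxy branch is recoverable as
#' `(t_iw + t_jw - t_ij) / 2`.
#'
#' @param fst_ij,fst_iw,fst_jw pairwise FSTs between populations i, j and
#'   the wild proxy w.
#' @return data.frame `t_ij`, `t_iw`, `t_jw`, `pbs_i`, `pbs_j`.
#' @export
pbs_from_fst <- function(fst_ij, fst_iw, fst_jw) {
  t_ij <- branch_length(fst_ij)
  t_iw <- branch_length(fst_iw)
  t_jw <- branch_length(fst_jw)
  data.frame(
    t_ij = t_ij, t_iw = t_iw, t_jw = t_jw,
    pbs_i = (t_ij + t_iw - t_jw) / 2,
    pbs_j = (t_ij + t_jw - t_iw) / 2
  )
}

#' Per-TIP Population Branch Statistic scan
#'
#' Computes the three pairwise FSTs per locus, the branch-length
#' transforms, the PBS on both derived-population branches, the maximum
#' absolute PBS, and percentile flags (`top5`, `top1`) over the scanned
#' loci. Loci must have defined frequencies in all three populations.
#'
#' @param freqs `freq_table` from [allele_frequency()] (or a loci x 3
#'   matrix of frequencies; then supply `n` likewise).
#' @param pops names of the three populations, in the order (derived i,
#'   derived j, wild proxy w).
#' @param n optional loci x 3 matrix of haploid sample sizes (taken from
#'   the `freq_table` when omitted).
#' @param percentiles percentile flags to set, default `c(95, 99)`.
#' @param estimator FST estimator, see [per_locus_fst()].
#' @return data.frame with one row per locus: `id`, `fst_ij`, `fst_iw`,
#'   `fst_jw`, `t_ij`, `t_iw`, `t_jw`, `pbs_i`, `pbs_j`, `abs_pbs`,
#'   `pct_flag`.
#' @export
pbs_scan <- function(freqs, pops = c("pop1", "pop2", "pop3"), n = NULL,
                     percentiles = pipeline_defaults()$pbs_percentiles,
                     estimator = "hudson") {
  if (inherits(freqs, "freq_table")) {
    ids <- freqs$loci$id
    n <- freqs$n[, pops, drop = FALSE]
    fm <- freqs$freq[, pops, drop = FALSE]
  } else {
    fm <- as.matrix(freqs)[, pops, drop = FALSE]
    ids <- rownames(fm) %||% sprintf("locus%05d", seq_len(nrow(fm)))
    if (is.null(n)) stop("supply per-population sample sizes via `n`")
    if (is.vector(n)) n <- matrix(rep(n, each = nrow(fm)), ncol = 3,
                                  dimnames = list(NULL, pops))
  }
  if (anyNA(fm)) {
    stop("PBS scan requires loci with frequencies defined in all three ",
         "populations; filter first (", sum(rowSums(is.na(fm)) > 0),
         " offending loci)")
  }
  fst_ij <- per_locus_fst(fm[, 1], n[, 1], fm[, 2], n[, 2], estimator)
  fst_iw <- per_locus_fst(fm[, 1], n[, 1], fm[, 3], n[, 3], estimator)
  fst_jw <- per_locus_fst(fm[, 2], n[, 2], fm[, 3], n[, 3], estimator)
  pbs <- pbs_from_fst(fst_ij, fst_iw, fst_jw)
  abs_pbs <- pmax(abs(pbs$pbs_i), abs(pbs$pbs_j))
  pct_flag <- rep("none", length(abs_pbs))
  for (pc in sort(percentiles)) {
    k <- ceil_frac((1 - pc / 100) * length(abs_pbs))
    if (k < 1) next
    thr <- sort(abs_pbs, decreasing = TRUE)[k]
    pct_flag[abs_pbs >= thr] <- sprintf("top%g", 100 - pc)
  }
  data.frame(id = ids, fst_ij = fst_ij, fst_iw = fst_iw, fst_jw = fst_jw,
             pbs, abs_pbs = abs_pbs, pct_flag = pct_flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Enrichment of eQTL TIPs among extreme-PBS loci
#'
#' Builds the 2x2 table (extreme vs not) x (eQTL vs not) at a given
#' percentile of `abs_pbs` and reports the sample odds ratio `ad/bc`
#' (with a Haldane 0.5 correction when any cell is zero) and the
#' two-sided Fisher exact p-value.
#'
#' @param pbs_table output of [pbs_scan()].
#' @param eqtl_flags logical vector aligned with `pbs_table`, or a vector
#'   of flagged locus ids.
#' @param percentile extremeness percentile, default 95.
#' @return list `table` (2x2 matrix), `odds_ratio`, `p`,
#'   `degenerate` (logical).
#' @export
eqtl_enrichment_test <- function(pbs_table, eqtl_flags, percentile = 95) {
  ids <- pbs_table$id
  if (!is.logical(eqtl_flags)) eqtl_flags <- ids %in% eqtl_flags
  stopifnot(length(eqtl_flags) == nrow(pbs_table))
  k <- ceil_frac((1 - percentile / 100) * nrow(pbs_table))
  thr <- sort(pbs_table$abs_pbs, decreasing = TRUE)[max(k, 1)]
  extreme <- pbs_table$abs_pbs >= thr
  a <- sum(extreme & eqtl_flags)
  b <- sum(extreme & !eqtl_flags)
  c_ <- sum(!extreme & eqtl_flags)
  d <- sum(!extreme & !eqtl_flags)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(extreme = c("yes", "no"),
                                eqtl = c("yes", "no")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(list(table = tab, odds_ratio = NA_real_, p = 1, degenerate = TRUE))
  }
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p = p, degenerate = FALSE)
}

#' Rank-sum comparison of two groups of PBS values
#'
#' Two-sided Mann-Whitney U with normal approximation, tie correction and
#' continuity correction. Degenerate input (every value identical across
#' both groups) returns `p = 1`.
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @return list `U` (statistic for group A), `p`.
#' @export
rank_sum_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  if (length(unique(c(values_a, values_b))) == 1) {
    return(list(U = length(values_a) * length(values_b) / 2, p = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}
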