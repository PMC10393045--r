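#' Keep genes expressed in more than a minimum fraction of samples
#'
#' @param counts genes x samples matrix of raw counts.
#' @param min_sample_frac a gene is kept iff it has a nonzero count in
#'   strictly more than this fraction of samples; default 0.10.
#' @return Filtered counts matrix.
#' @export
filter_expressed_genes <- function(counts,
                                   min_sample_frac = pipeline_defaults()$expressed_min_sample_frac) {
  stopifnot(all(counts >= 0))
  keep <- rowMeans(counts > 0) > min_sample_frac
  counts[keep, , drop = FALSE]
}

#' Normalize raw counts (median-of-ratios + log2)
#'
#' Size factors are DESeq-style median-of-ratios against a geometric-mean
#' reference built from genes with all-positive counts; normalized values
#' are `log2(count / size_factor + 1)`. This is a documented, monotone
#' stand-in for a variance-stabilizing transform: the association model
#' downstream is invariant to any monotone variance-stabilizing choice
#' under the null. If no gene has all-positive counts, size factors fall
#' back to library size over mean library size, with a warning.
#'
#' @param counts genes x samples matrix of raw counts (>= 2 samples).
#' @return Normalized matrix with attribute `size_factors`.
#' @export
normalize_counts <- function(counts) {
  stopifnot(ncol(counts) >= 2, all(counts >= 0))
  log_counts <- log(counts)
  loggm <- rowMeans(log_counts)
  use <- is.finite(loggm)
  if (!any(use)) {
    warning("no gene with all-positive counts; using library-size factors")
    lib <- colSums(counts)
    sf <- lib / mean(lib)
  } else {
    sf <- exp(apply(log_counts[use, , drop = FALSE] - loggm[use], 2,
                    stats::median))
  }
  stopifnot(all(sf > 0))
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Enumerate cis gene-marker pairs
#'
#' A marker is cis to a gene iff it lies inside the gene body or within
#' strictly fewer than `window` bp of the nearer gene edge on either side
#' (the published rule is "less than 5 kb", hence the strict bound).
#' Distance is 0 inside the gene body, otherwise the bp gap to the nearest
#' edge, signed negative when the marker is on the 5' side of the gene
#' (strand-aware).
#'
#' @param genes gene model data.frame ([gene_models()]).
#' @param markers [marker_matrix] or a loci data.frame (`id`, `chrom`, `pos`).
#' @param window cis window in bp, default 5000.
#' @return data.frame `gene_id`, `marker_id`, `distance`.
#' @export
enumerate_cis_pairs <- function(genes, markers,
                                window = pipeline_defaults()$cis_window) {
  genes <- gene_models(genes)
  loci <- if (inherits(markers, "marker_matrix")) markers$loci else markers
  if (nrow(genes) == 0 || nrow(loci) == 0) {
    return(data.frame(gene_id = character(0), marker_id = character(0),
                      distance = integer(0)))
  }
  ## allowed 0-based marker positions: [start - window + 1, end + window - 2]
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start - window + 2L,
                     end = genes$end + window - 1L)
  )
  marker_gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(start = loci$pos + 1L, width = 1L)
  )
  ## disjoint chromosome sets between genes and markers are legitimate
  ## (e.g. per-chromosome marker files); silence the seqlevel notice
  hits <- suppressWarnings(GenomicRanges::findOverlaps(marker_gr, gene_gr))
  mi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  pos <- loci$pos[mi]
  start <- genes$start[gi]
  end <- genes$end[gi]
  gap <- ifelse(pos < start, start - pos,
                ifelse(pos >= end, pos - end + 1L, 0L))
  upstream5 <- ifelse(genes$strand[gi] == "-", pos >= end, pos < start)
  distance <- as.integer(gap * ifelse(gap > 0 & upstream5, -1L, 1L))
  data.frame(gene_id = genes$id[gi], marker_id = loci$id[mi],
             distance = distance, stringsAsFactors = FALSE)
}

#' Linear association of one marker with one expression trait
#'
#' Ordinary least squares of `y` on an intercept, subpopulation dummies and
#' the marker genotype; reports the marker coefficient, its standard error,
#' two-sided t-test p-value, and the squared partial correlation of the
#' marker with `y` given the covariates (the marginal variance explained by
#' the marker after covariates). Collinear covariate columns are dropped
#' with a warning; a constant marker is an error.
#'
#' @param y numeric response (normalized expression).
#' @param g numeric marker genotype (0/1).
#' @param covariates `NULL`, a factor (subpopulation), or a numeric matrix
#'   of covariates (no intercept column).
#' @return One-row data.frame `beta`, `se`, `t`, `p`, `r2`, `df`.
#' @export
fit_linear_association <- function(y, g, covariates = NULL) {
  stopifnot(length(y) == length(g))
  if (stats::var(g) == 0) stop("marker is constant; cannot fit association")
  X <- covariate_matrix(covariates, length(y))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("dropping ", ncol(X) - qx$rank, " collinear covariate column(s)")
  }
  ry <- qr.resid(qx, y)
  rg <- qr.resid(qx, g)
  df <- length(y) - qx$rank - 1L
  if (df < 1) stop("not enough samples for the model (df < 1)")
  fit <- assoc_from_residuals(matrix(ry, nrow = 1), matrix(rg, nrow = 1), df)
  data.frame(beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
             r2 = fit$r2, df = df)
}

# Build the covariate design matrix (intercept + treatment dummies with the
# largest group as reference, for factors).
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  if (is.factor(covariates) || is.character(covariates)) {
    f <- factor(covariates)
    if (nlevels(f) < 2) return(matrix(1, n, 1))
    f <- stats::relevel(f, ref = names(which.max(table(f))))
    return(stats::model.matrix(~f))
  }
  cbind(1, as.matrix(covariates))
}

# Vectorized association stats from covariate-residualized rows.
# ry, rg: matrices with one row per test (paired rows). df: residual df of
# the full model (n - rank(X) - 1). Based on the partial-correlation t:
# t = r * sqrt(df) / sqrt(1 - r^2); identical to full OLS (Frisch-Waugh).
assoc_from_residuals <- function(ry, rg, df) {
  syy <- rowSums(ry^2)
  sgg <- rowSums(rg^2)
  sgy <- rowSums(ry * rg)
  beta <- sgy / sgg
  r <- sgy / sqrt(syy * sgg)
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df)
  se <- ifelse(t != 0, beta / t, sqrt(syy / (df * sgg)))
  data.frame(beta = beta, se = se, t = t, p = p, r2 = r^2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()]). Applied within one replicate x condition x
#' population x marker-type scan over all tested cis pairs.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Run a per-population cis-eQTL scan
#'
#' For each replicate matrix (condition x replicate) of one population:
#' subset raw counts, drop genes expressed in too few samples, normalize,
#' residualize expression and genotypes on subpopulation covariates, fit
#' every cis pair, and BH-adjust within the scan. Markers that are constant
#' within the population subset are skipped (counted in the
#' `n_constant_skipped` attribute).
#'
#' @param counts genes x samples raw count matrix (sample columns named as
#'   in `metadata$sample`).
#' @param genes gene model data.frame.
#' @param markers [marker_matrix] with accession columns.
#' @param metadata per-sample data.frame: `sample`, `accession`,
#'   `population`, `subpopulation`, `condition`, `replicate`.
#' @param population population label to scan.
#' @param window cis window in bp.
#' @param min_sample_frac expression filter threshold.
#' @return data.frame with one row per tested (pair, replicate):
#'   `gene_id`, `marker_id`, `marker_type`, `beta`, `se`, `t`, `p`, `q`,
#'   `r2`, `distance`, `condition`, `replicate`, `population`.
#' @export
run_eqtl_scan <- function(counts, genes, markers, metadata, population,
                          window = pipeline_defaults()$cis_window,
                          min_sample_frac = pipeline_defaults()$expressed_min_sample_frac) {
  stopifnot(inherits(markers, "marker_matrix"))
  meta <- metadata[metadata$population == population, , drop = FALSE]
  if (nrow(meta) == 0) stop("no samples for population ", population)
  missing_expr <- setdiff(meta$sample, colnames(counts))
  missing_geno <- setdiff(unique(meta$accession), markers$samples)
  if (length(missing_expr) || length(missing_geno)) {
    stop("sample sets disagree; missing from expression: [",
         paste(missing_expr, collapse = ", "), "]; missing from genotypes: [",
         paste(missing_geno, collapse = ", "), "]")
  }
  if (anyNA(markers$calls)) {
    stop("markers must be complete (no missing calls) for the eQTL scan")
  }
  pairs_all <- enumerate_cis_pairs(genes, markers, window)
  scans <- list()
  n_constant <- 0L
  for (cond in sort(unique(meta$condition))) {
    for (rep_i in sort(unique(meta$replicate[meta$condition == cond]))) {
      sub <- meta[meta$condition == cond & meta$replicate == rep_i, ,
                  drop = FALSE]
      y_raw <- counts[, sub$sample, drop = FALSE]
      y_raw <- filter_expressed_genes(y_raw, min_sample_frac)
      if (nrow(y_raw) == 0) next
      y <- normalize_counts(y_raw)
      g <- markers$calls[, sub$accession, drop = FALSE]
      keep_marker <- matrixStats_rowVars(g) > 0
      n_constant <- n_constant +
        sum(!keep_marker & rownames(g) %in% pairs_all$marker_id)
      pairs <- pairs_all[pairs_all$gene_id %in% rownames(y) &
                           pairs_all$marker_id %in% rownames(g)[keep_marker], ,
                         drop = FALSE]
      if (nrow(pairs) == 0) next
      X <- covariate_matrix(sub$subpopulation, nrow(sub))
      qx <- qr(X)
      df <- nrow(sub) - qx$rank - 1L
      ry <- t(qr.resid(qx, t(y)))
      rg <- t(qr.resid(qx, t(g)))
      fit <- assoc_from_residuals(ry[pairs$gene_id, , drop = FALSE],
                                  rg[pairs$marker_id, , drop = FALSE], df)
      scans[[length(scans) + 1L]] <- data.frame(
        gene_id = pairs$gene_id, marker_id = pairs$marker_id,
        marker_type = markers$type,
        beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
        q = bh_adjust(fit$p), r2 = fit$r2,
        distance = pairs$distance,
        marker_pos = markers$loci$pos[match(pairs$marker_id,
                                            markers$loci$id)],
        condition = cond, replicate = rep_i, population = population,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(scans)) do.call(rbind, scans) else data.frame()
  rownames(out) <- NULL
  attr(out, "n_constant_skipped") <- n_constant
  out
}

# rowVars without a matrixStats dependency (0/1 and small matrices only).
matrixStats_rowVars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  (rowSums(m^2) - n * mu^2) / (n - 1)
}

#' Consolidate replicate-level associations into eQTL hits
#'
#' A (gene, marker, condition, population) is a hit iff its q-value is
#' below `fdr` in at least one replicate. The leading marker per
#' (gene, condition, population) is the hit marker with the smallest
#' minimum q, ties broken by smaller absolute distance, then leftmost
#' marker id. Effect sign is taken from the best replicate; conflicting
#' signs across significant replicates are flagged.
#'
#' @param results scan table from [run_eqtl_scan()].
#' @param fdr hit threshold on q, default 0.05.
#' @return list with `hits` (all hit pairs) and `leading` (leading marker
#'   per gene), both data.frames.
#' @export
consolidate_replicates <- function(results, fdr = pipeline_defaults()$fdr) {
  if (nrow(results) == 0) {
    empty <- data.frame()
    return(list(hits = empty, leading = empty))
  }
  key <- interaction(results$population, results$condition,
                     results$gene_id, results$marker_id, drop = TRUE)
  best <- lapply(split(seq_len(nrow(results)), key), function(ii) {
    rr <- results[ii, ]
    b <- ii[order(rr$q, rr$p)][1]
    sig <- rr$q < fdr
    data.frame(
      population = rr$population[1], condition = rr$condition[1],
      gene_id = rr$gene_id[1], marker_id = rr$marker_id[1],
      marker_type = rr$marker_type[1],
      min_q = min(rr$q), p_best = results$p[b],
      beta = results$beta[b], r2 = results$r2[b],
      distance = rr$distance[1],
      marker_pos = rr$marker_pos[1],
      n_replicates = nrow(rr), n_significant = sum(sig),
      sign_conflict = length(unique(sign(rr$beta[sig]))) > 1,
      stringsAsFactors = FALSE
    )
  })
  pairs <- do.call(rbind, best)
  rownames(pairs) <- NULL
  hits <- pairs[pairs$min_q < fdr, , drop = FALSE]
  if (nrow(hits) == 0) return(list(hits = hits, leading = hits))
  gkey <- interaction(hits$population, hits$condition, hits$gene_id,
                      drop = TRUE)
  leading <- do.call(rbind, lapply(split(seq_len(nrow(hits)), gkey),
                                   function(ii) {
    hh <- hits[ii, ]
    hh[order(hh$min_q, abs(hh$distance), hh$marker_pos)[1], , drop = FALSE]
  }))
  rownames(leading) <- NULL
  list(hits = hits, leading = leading)
}

#' Compare variance explained by leading TIPs vs leading SNPs
#'
#' For every gene with a TIP hit, compares the marginal r2 of its leading
#' TIP with that of its leading significant SNP (if any): `TIP_only` when
#' no SNP in the cis window reaches significance, `TIP_gt_SNP` when the
#' TIP explains strictly more variance, `SNP_ge_TIP` otherwise.
#'
#' @param tip_hits `leading` table from [consolidate_replicates()] run on
#'   TIP results.
#' @param snp_results full scan table for SNPs (same samples).
#' @param fdr significance threshold for the SNP side.
#' @return list with `genes` (per-gene categories) and `fractions`.
#' @export
compare_variance_explained <- function(tip_hits, snp_results,
                                       fdr = pipeline_defaults()$fdr) {
  if (nrow(tip_hits) == 0) {
    return(list(genes = data.frame(), fractions = c(TIP_only = NA_real_,
                                                    TIP_gt_SNP = NA_real_,
                                                    SNP_ge_TIP = NA_real_)))
  }
  snp_cons <- consolidate_replicates(snp_results, fdr)
  snp_lead <- snp_cons$leading
  rows <- lapply(seq_len(nrow(tip_hits)), function(i) {
    h <- tip_hits[i, ]
    sl <- if (nrow(snp_lead) == 0) snp_lead else
      snp_lead[snp_lead$population == h$population &
                 snp_lead$condition == h$condition &
                 snp_lead$gene_id == h$gene_id, , drop = FALSE]
    if (nrow(sl) == 0) {
      cat_ <- "TIP_only"; snp_r2 <- NA_real_; snp_id <- NA_character_
    } else {
      snp_r2 <- sl$r2[1]; snp_id <- sl$marker_id[1]
      cat_ <- if (h$r2 > snp_r2) "TIP_gt_SNP" else "SNP_ge_TIP"
    }
    data.frame(population = h$population, condition = h$condition,
               gene_id = h$gene_id, tip_id = h$marker_id, tip_r2 = h$r2,
               snp_id = snp_id, snp_r2 = snp_r2, category = cat_,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  fr <- prop.table(table(factor(genes$category,
                                levels = c("TIP_only", "TIP_gt_SNP",
                                           "SNP_ge_TIP"))))
  list(genes = genes, fractions = c(fr))
}

#' Sharing of hits against another scan at a relaxed cutoff
#'
#' A hit from scan A is "shared" iff the same (gene, marker) pair reaches
#' unadjusted `p < relaxed_p` with the same effect sign in at least one
#' replicate of scan B.
#'
#' @param hits_a `hits` table from [consolidate_replicates()].
#' @param results_b full scan table for the comparison scan.
#' @param relaxed_p relaxed cutoff on the unadjusted p, default 0.05.
#' @return list with `table` (per-hit shared flag) and `shared_fraction`,
#'   `sign_concordant` count.
#' @export
shared_associations <- function(hits_a, results_b,
                                relaxed_p = pipeline_defaults()$relaxed_p) {
  if (nrow(hits_a) == 0) {
    return(list(table = data.frame(), shared_fraction = NA_real_,
                sign_concordant = 0L))
  }
  shared <- logical(nrow(hits_a))
  for (i in seq_len(nrow(hits_a))) {
    h <- hits_a[i, ]
    b <- results_b[results_b$gene_id == h$gene_id &
                     results_b$marker_id == h$marker_id, , drop = FALSE]
    shared[i] <- any(b$p < relaxed_p & sign(b$beta) == sign(h$beta))
  }
  tbl <- cbind(hits_a, shared = shared)
  list(table = tbl, shared_fraction = mean(shared),
       sign_concordant = sum(shared))
}

#' Effect size by population-frequency bin
#'
#' Bins hit markers by their presence frequency (`[0,0.05), ...,
#' [0.95,1]`) and reports count and mean effect size per bin, split by
#' effect sign.
#'
#' @param hits hits table with `marker_id` and `beta`.
#' @param frequencies named numeric vector of marker presence frequencies.
#' @param bin_width bin width, default 0.05.
#' @return data.frame `bin_low`, `bin_high`, `sign`, `n`, `mean_beta`.
#' @export
effect_size_frequency_profile <- function(hits, frequencies,
                                          bin_width = 0.05) {
  stopifnot(all(hits$marker_id %in% names(frequencies)))
  breaks <- round(seq(0, 1, by = bin_width), 10)
  f <- frequencies[hits$marker_id]
  bin <- cut(f, breaks = breaks, include.lowest = TRUE, right = FALSE)
  sgn <- ifelse(hits$beta >= 0, "positive", "negative")
  grid <- expand.grid(bin = levels(bin), sign = c("positive", "negative"),
                      KEEP.OUT.ATTRS = FALSE)
  key <- interaction(bin, sgn)
  gkey <- interaction(grid$bin, grid$sign)
  n <- as.integer(table(factor(key, levels = levels(gkey))))
  mean_beta <- vapply(levels(gkey), function(k) {
    v <- hits$beta[key == k]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  data.frame(
    bin_low = breaks[as.integer(grid$bin)],
    bin_high = breaks[as.integer(grid$bin) + 1L],
    sign = grid$sign, n = n, mean_beta = unname(mean_beta),
    stringsAsFactors = FALSE
  )
}
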