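#' Build a haplotype block from a SNP marker matrix
#'
#' Extracts the SNPs of one chromosome region (0-based half-open) into the
#' samples x SNPs allele matrix used by the windowed statistics. Alleles
#' must be complete (impute first).
#'
#' @param snps [marker_matrix] of type `"SNP"` (no missing calls).
#' @param chrom chromosome.
#' @param start,end region bounds, 0-based half-open.
#' @param carriers optional logical/ids marking carrier samples.
#' @param samples optional sample subset (e.g. one population).
#' @return `haplotype_block`.
#' @export
haplotype_block <- function(snps, chrom, start, end, carriers = NULL,
                            samples = NULL) {
  stopifnot(inherits(snps, "marker_matrix"))
  if (!is.null(samples)) snps <- subset_samples(snps, samples)
  sel <- snps$loci$chrom == chrom & snps$loci$pos >= start &
    snps$loci$pos < end
  block_loci <- snps$loci[sel, , drop = FALSE]
  ord <- order(block_loci$pos)
  alleles <- t(snps$calls[sel, , drop = FALSE][ord, , drop = FALSE])
  if (anyNA(alleles)) stop("haplotype block contains missing alleles; impute first")
  if (is.null(carriers)) {
    carriers <- rep(FALSE, nrow(alleles))
  } else if (!is.logical(carriers)) {
    carriers <- rownames(alleles) %in% carriers
  }
  stopifnot(length(carriers) == nrow(alleles))
  structure(list(chrom = chrom, start = start, end = end,
                 positions = block_loci$pos[ord], alleles = alleles,
                 carriers = carriers),
            class = "haplotype_block")
}

# Window start indices over SNP indices; trailing partial window dropped.
window_starts <- function(n_snps, window_snps, step_snps) {
  if (n_snps < window_snps) return(integer(0))
  seq.int(1L, n_snps - window_snps + 1L, by = step_snps)
}

# Resolve a sample subset of a block into row indices.
resolve_subset <- function(block, subset) {
  if (is.logical(subset)) return(which(subset))
  if (is.character(subset)) {
    idx <- match(subset, rownames(block$alleles))
    if (anyNA(idx)) stop("unknown samples in subset")
    return(idx)
  }
  as.integer(subset)
}

# Shared window bookkeeping for the per-window statistics.
window_frame <- function(block, starts, window_snps, stat, group) {
  data.frame(
    window = seq_along(starts),
    snp_from = starts, snp_to = starts + window_snps - 1L,
    pos_from = block$positions[starts],
    pos_to = block$positions[starts + window_snps - 1L],
    stat = rep(stat, length(starts)),
    group = rep(group, length(starts)), stringsAsFactors = FALSE
  )
}

#' Windowed nucleotide diversity over SNP-index windows
#'
#' Per window of `window_snps` consecutive SNPs (sliding by `step_snps`),
#' pi is the mean per-site pairwise diversity of the sample subset:
#' `sum(2 p (1-p) n/(n-1)) / window_snps` with `p` the subset allele
#' frequency, equal to the average pairwise Hamming distance between
#' distinct haplotypes divided by the SNP count. Windows are defined over
#' SNP indices, not bp (the genomic span is reported so per-bp rescaling
#' is possible); the trailing partial window is dropped.
#'
#' @param block `haplotype_block`.
#' @param subset sample subset (logical mask, ids, or indices), size >= 2.
#' @param window_snps,step_snps window size and slide, defaults 25 / 5.
#' @param group label stored in the output, default `"subset"`.
#' @return data.frame of per-window rows (`window`, SNP and bp spans,
#'   `stat`, `group`, `value`); empty with a warning if the block has
#'   fewer SNPs than one window.
#' @export
window_pi <- function(block, subset,
                      window_snps = pipeline_defaults()$pi_window,
                      step_snps = pipeline_defaults()$pi_step,
                      group = "subset") {
  idx <- resolve_subset(block, subset)
  stopifnot(length(idx) >= 2)
  starts <- window_starts(length(block$positions), window_snps, step_snps)
  if (length(starts) == 0) {
    warning("fewer SNPs than one window; empty result")
    return(window_frame(block, integer(0), window_snps, "pi", group))
  }
  n <- length(idx)
  p <- colMeans(block$alleles[idx, , drop = FALSE])
  site_div <- 2 * p * (1 - p) * n / (n - 1)
  cs <- c(0, cumsum(site_div))
  out <- window_frame(block, starts, window_snps, "pi", group)
  out$value <- (cs[starts + window_snps] - cs[starts]) / window_snps
  out
}

#' Windowed H12 haplotype homozygosity
#'
#' Per window of `window_snps` SNPs, each sample's haplotype is its allele
#' string over the window; with sorted haplotype frequencies
#' `p1 >= p2 >= ...`, `H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2`. Pooling the
#' two most frequent haplotypes makes the statistic sensitive to both hard
#' and soft sweeps.
#'
#' @inheritParams window_pi
#' @param window_snps,step_snps window size and slide, defaults 50 / 25.
#' @return data.frame as [window_pi()], `stat = "h12"`.
#' @export
window_h12 <- function(block, subset,
                       window_snps = pipeline_defaults()$h12_window,
                       step_snps = pipeline_defaults()$h12_step,
                       group = "subset") {
  idx <- resolve_subset(block, subset)
  stopifnot(length(idx) >= 2)
  starts <- window_starts(length(block$positions), window_snps, step_snps)
  if (length(starts) == 0) {
    warning("fewer SNPs than one window; empty result")
    return(window_frame(block, integer(0), window_snps, "h12", group))
  }
  hap_ids <- haplotype_ids(block, starts, window_snps)
  out <- window_frame(block, starts, window_snps, "h12", group)
  out$value <- vapply(seq_along(starts), function(w) {
    h12_from_counts(tabulate(hap_ids[idx, w]))
  }, numeric(1))
  out
}

# Integer haplotype id per sample per window (shared by observed and
# permuted computations, so permutations only re-tabulate ids).
haplotype_ids <- function(block, starts, window_snps) {
  n <- nrow(block$alleles)
  ids <- matrix(0L, n, length(starts))
  for (w in seq_along(starts)) {
    cols <- starts[w]:(starts[w] + window_snps - 1L)
    key <- do.call(paste, c(as.data.frame(block$alleles[, cols, drop = FALSE]),
                            sep = ""))
    ids[, w] <- match(key, unique(key))
  }
  ids
}

h12_from_counts <- function(counts) {
  counts <- counts[counts > 0]
  p <- sort(counts / sum(counts), decreasing = TRUE)
  if (length(p) == 1) return(1)
  (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
}

#' Permutation null for a windowed statistic
#'
#' Each of `n_perm` permutations draws `group_size` samples uniformly
#' without replacement from all samples in the block and recomputes the
#' windowed statistic over the same windows. The permutation p-value is
#' one-sided toward the sweep signature by default (low pi, high H12):
#' `perm_p = (1 + #{perm >= obs}) / (n_perm + 1)` for H12 and with `<=`
#' for pi; `alternative = "two.sided"` doubles the smaller tail (capped
#' at 1).
#'
#' @param block `haplotype_block`.
#' @param group_size permuted group size (strictly less than the number of
#'   samples in the block).
#' @param stat `"pi"` or `"h12"`.
#' @param observed data.frame from [window_pi()] / [window_h12()] for the
#'   observed group (its windows define the comparison).
#' @param window_snps,step_snps window parameters (must match `observed`).
#' @param n_perm number of permutations, default 1000.
#' @param seed RNG seed.
#' @param alternative `"sweep"` (one-sided, default) or `"two.sided"`.
#' @return `observed` with columns `perm_mean` and `perm_p` appended.
#' @export
permutation_null <- function(block, group_size, stat = c("pi", "h12"),
                             observed,
                             window_snps = NULL, step_snps = NULL,
                             n_perm = pipeline_defaults()$n_perm,
                             seed = 1L,
                             alternative = c("sweep", "two.sided")) {
  stat <- match.arg(stat)
  alternative <- match.arg(alternative)
  d <- pipeline_defaults()
  window_snps <- window_snps %||%
    if (stat == "pi") d$pi_window else d$h12_window
  step_snps <- step_snps %||% if (stat == "pi") d$pi_step else d$h12_step
  n_total <- nrow(block$alleles)
  if (group_size >= n_total) {
    stop("group_size must be smaller than the number of samples ",
         "(degenerate null)")
  }
  if (group_size < 2) stop("group_size must be >= 2")
  starts <- window_starts(length(block$positions), window_snps, step_snps)
  stopifnot(nrow(observed) == length(starts))
  perm_vals <- matrix(NA_real_, n_perm, length(starts))
  with_seed(seed, {
    if (stat == "h12") {
      hap_ids <- haplotype_ids(block, starts, window_snps)
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n_total, group_size)
        perm_vals[b, ] <- vapply(seq_along(starts), function(w) {
          h12_from_counts(tabulate(hap_ids[idx, w]))
        }, numeric(1))
      }
    } else {
      cs_template <- function(p) {
        site_div <- 2 * p * (1 - p) * group_size / (group_size - 1)
        cs <- c(0, cumsum(site_div))
        (cs[starts + window_snps] - cs[starts]) / window_snps
      }
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n_total, group_size)
        perm_vals[b, ] <- cs_template(
          colMeans(block$alleles[idx, , drop = FALSE]))
      }
    }
  })
  obs <- observed$value
  ge <- colSums(sweep(perm_vals, 2, obs, ">=")) # number of perms >= observed
  le <- colSums(sweep(perm_vals, 2, obs, "<="))
  p_hi <- (1 + ge) / (n_perm + 1)
  p_lo <- (1 + le) / (n_perm + 1)
  perm_p <- if (alternative == "sweep") {
    if (stat == "h12") p_hi else p_lo
  } else {
    pmin(2 * pmin(p_hi, p_lo), 1)
  }
  observed$perm_mean <- colMeans(perm_vals)
  observed$perm_p <- perm_p
  observed
}

#' Sweep scan around a focal TIP
#'
#' Partitions the population's accessions into TIP carriers and
#' non-carriers, builds the +/- `flank` bp haplotype block around the
#' insertion, computes windowed pi and H12 for each group, and tests each
#' against a permutation null that redraws groups of the same size from
#' all accessions of the population (regardless of TIP state, matching
#' the published protocol).
#'
#' @param snps [marker_matrix] of SNPs (complete calls).
#' @param tips [marker_matrix] of TIP calls (complete for the focal TIP).
#' @param focal_tip id of the focal TIP.
#' @param samples optional accession subset (e.g. one population).
#' @param flank region half-width in bp, default 50000.
#' @param pi_window,pi_step,h12_window,h12_step window parameters.
#' @param n_perm permutations, default 1000.
#' @param seed RNG seed.
#' @return list of class `sweep_scan`: `focal_tip`, `chrom`, `focal_pos`,
#'   `n_carriers`, `n_noncarriers`, and `windows` (long data.frame with
#'   per-window `value`, `perm_mean`, `perm_p` for each group x statistic).
#' @export
scan_locus <- function(snps, tips, focal_tip, samples = NULL,
                       flank = pipeline_defaults()$sweep_flank,
                       pi_window = pipeline_defaults()$pi_window,
                       pi_step = pipeline_defaults()$pi_step,
                       h12_window = pipeline_defaults()$h12_window,
                       h12_step = pipeline_defaults()$h12_step,
                       n_perm = pipeline_defaults()$n_perm,
                       seed = 1L) {
  stopifnot(inherits(snps, "marker_matrix"), inherits(tips, "marker_matrix"))
  if (!focal_tip %in% tips$loci$id) stop("unknown focal TIP: ", focal_tip)
  row <- match(focal_tip, tips$loci$id)
  chrom <- tips$loci$chrom[row]
  pos <- tips$loci$pos[row]
  use_samples <- samples %||% intersect(snps$samples, tips$samples)
  calls <- tips$calls[row, use_samples]
  if (anyNA(calls)) stop("focal TIP has missing calls among scan samples")
  carriers <- names(calls)[calls == 1L]
  noncarriers <- names(calls)[calls == 0L]
  if (length(carriers) < 2 || length(noncarriers) < 2) {
    stop(sprintf(
      "focal TIP %s needs >= 2 carriers and >= 2 non-carriers (found %d / %d)",
      focal_tip, length(carriers), length(noncarriers)))
  }
  block <- haplotype_block(snps, chrom, pos - flank, pos + flank + 1L,
                           carriers = carriers, samples = use_samples)
  if (length(block$positions) < max(pi_window, h12_window)) {
    stop(sprintf(
      "region %s:[%d,%d) has %d SNPs; need >= %d for one window",
      chrom, block$start, block$end, length(block$positions),
      max(pi_window, h12_window)))
  }
  groups <- list(carriers = carriers, noncarriers = noncarriers)
  windows <- list()
  k <- 0L
  for (gname in names(groups)) {
    gs <- length(groups[[gname]])
    obs_pi <- window_pi(block, groups[[gname]], pi_window, pi_step,
                        group = gname)
    obs_h12 <- window_h12(block, groups[[gname]], h12_window, h12_step,
                          group = gname)
    windows[[k + 1L]] <- permutation_null(
      block, gs, "pi", obs_pi, pi_window, pi_step, n_perm,
      seed = seed + 2L * k)
    windows[[k + 2L]] <- permutation_null(
      block, gs, "h12", obs_h12, h12_window, h12_step, n_perm,
      seed = seed + 2L * k + 1L)
    k <- k + 2L
  }
  structure(list(
    focal_tip = focal_tip, chrom = chrom, focal_pos = pos,
    n_carriers = length(carriers), n_noncarriers = length(noncarriers),
    windows = do.call(rbind, windows)
  ), class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf(
    "<sweep_scan> %s @ %s:%d | %d carriers vs %d non-carriers | %d windows\n",
    x$focal_tip, x$chrom, x$focal_pos, x$n_carriers, x$n_noncarriers,
    nrow(x$windows)))
  invisible(x)
}

#' Windows at the focal insertion of a sweep scan
#'
#' Picks, per group x statistic, the window whose genomic span covers the
#' focal TIP position (nearest-midpoint tie-break; nearest window if none
#' covers it). Summarizes a [scan_locus()] result at the insertion itself.
#'
#' @param scan `sweep_scan` object.
#' @return Subset of `scan$windows`, one row per group x statistic.
#' @export
focal_window <- function(scan) {
  w <- scan$windows
  mid <- (w$pos_from + w$pos_to) / 2
  keys <- interaction(w$group, w$stat, drop = TRUE)
  picked <- unlist(lapply(split(seq_len(nrow(w)), keys), function(ii) {
    covering <- ii[w$pos_from[ii] <= scan$focal_pos &
                     w$pos_to[ii] >= scan$focal_pos]
    if (length(covering)) covering[which.min(abs(mid[covering] - scan$focal_pos))]
    else ii[which.min(abs(mid[ii] - scan$focal_pos))]
  }))
  w[picked, , drop = FALSE]
}
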