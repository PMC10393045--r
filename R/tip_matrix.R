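#' Drop loci never reaching a minimum zygosity
#'
#' A TIP whose zygosity stays below `min_zygosity` in every sample is treated
#' as a likely false positive and removed. The comparison is against
#' non-missing samples only and the boundary is inclusive (a single sample at
#' exactly `min_zygosity` keeps the locus).
#'
#' @param m [tip_zygosity] matrix.
#' @param min_zygosity minimum zygosity a locus must reach in at least one
#'   sample; default 0.25.
#' @return Filtered [tip_zygosity] matrix.
#' @export
filter_low_zygosity <- function(m, min_zygosity = pipeline_defaults()$zygosity_min) {
  stopifnot(inherits(m, "tip_zygosity"))
  if (nrow(m$values) == 0) return(m)
  max_z <- suppressWarnings(apply(m$values, 1, max, na.rm = TRUE))
  keep <- keep_at_least(ifelse(is.finite(max_z), max_z, NA_real_), min_zygosity)
  if (!any(keep)) warning("all loci removed by zygosity filter")
  subset_loci(m, keep)
}

#' Binarize a zygosity matrix into presence/absence calls
#'
#' Zygosity at or above `cutoff` is called present (1), below is absent (0);
#' missing stays missing. Inbred material is effectively haploid, so the call
#' is per accession, not per chromosome copy.
#'
#' @param m [tip_zygosity] matrix.
#' @param cutoff presence cutoff on zygosity, default 0.05 (inclusive).
#' @return [marker_matrix] of type `"TIP"`.
#' @export
binarize_zygosity <- function(m, cutoff = pipeline_defaults()$zygosity_presence_cutoff) {
  stopifnot(inherits(m, "tip_zygosity"))
  calls <- ifelse(is.na(m$values), NA_integer_,
                  as.integer(keep_at_least(m$values, cutoff)))
  calls <- matrix(calls, nrow = nrow(m$values))
  marker_matrix(m$loci, m$samples, calls, type = "TIP")
}

#' Filter markers on minor allele frequency and missingness
#'
#' A locus is kept iff its missing fraction is at most `max_missing_frac` and
#' its MAF (min of presence frequency and its complement, over non-missing
#' calls) is strictly greater than `min_maf`. Two published presets exist:
#' `"eqtl"` (MAF > 3%, no missing data) and `"pbs"` (MAF > 5% is NOT the
#' rule here -- the PBS preset keeps MAF >= 5%, i.e. removes MAF < 5%, and
#' allows up to 5% missing data).
#'
#' @param g [marker_matrix].
#' @param min_maf strict lower bound on MAF (preset `"eqtl"`: 0.03).
#' @param max_missing_frac maximum tolerated missing fraction.
#' @param preset `"eqtl"` or `"pbs"`; overrides the two thresholds.
#' @return Filtered [marker_matrix].
#' @export
filter_maf_missing <- function(g, min_maf = 0.03, max_missing_frac = 0,
                               preset = NULL) {
  stopifnot(inherits(g, "marker_matrix"))
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("eqtl", "pbs"))
    d <- pipeline_defaults()
    if (preset == "eqtl") {
      min_maf <- d$maf_eqtl; max_missing_frac <- d$missing_eqtl
      strict_maf <- TRUE
    } else {
      min_maf <- d$maf_pbs; max_missing_frac <- d$missing_pbs
      strict_maf <- FALSE  # "MAF < 5%" removed, so MAF = 5% survives
    }
  } else {
    strict_maf <- TRUE
  }
  if (min_maf >= 0.5) stop("min_maf must be < 0.5")
  if (nrow(g$calls) == 0) return(g)
  n_miss <- rowSums(is.na(g$calls))
  n_obs <- ncol(g$calls) - n_miss
  freq <- rowSums(g$calls, na.rm = TRUE) / pmax(n_obs, 1L)
  maf <- pmin(freq, 1 - freq)
  miss_frac <- n_miss / ncol(g$calls)
  maf_ok <- if (strict_maf) keep_above(maf, min_maf) else keep_at_least(maf, min_maf)
  keep <- n_obs > 0 & miss_frac <= max_missing_frac & maf_ok
  subset_loci(g, keep)
}

#' Impute residual missing calls
#'
#' Frequency-based imputation of the remaining missing presence/absence
#' calls after the missingness filter. Mode `"expected"` (default,
#' deterministic) sets a missing call present iff the locus presence
#' frequency among observed calls is at least 0.5; mode `"bernoulli"` draws
#' each missing call from Bernoulli(presence frequency) under a fixed seed.
#' Observed calls are never altered.
#'
#' @param g [marker_matrix].
#' @param mode `"expected"` or `"bernoulli"`.
#' @param seed RNG seed, used by mode `"bernoulli"` only.
#' @return [marker_matrix] with no missing calls.
#' @export
impute_missing <- function(g, mode = c("expected", "bernoulli"), seed = 1L) {
  stopifnot(inherits(g, "marker_matrix"))
  mode <- match.arg(mode)
  calls <- g$calls
  if (!anyNA(calls)) return(g)
  n_obs <- rowSums(!is.na(calls))
  if (any(n_obs == 0)) {
    stop("cannot impute loci with all calls missing: ",
         paste(utils::head(g$loci$id[n_obs == 0], 5), collapse = ", "))
  }
  freq <- rowSums(calls, na.rm = TRUE) / n_obs
  idx <- which(is.na(calls), arr.ind = TRUE)
  fills <- if (mode == "expected") {
    as.integer(freq[idx[, 1]] >= 0.5)
  } else {
    with_seed(seed, as.integer(stats::rbinom(nrow(idx), 1L, freq[idx[, 1]])))
  }
  calls[idx] <- fills
  marker_matrix(g$loci, g$samples, calls, type = g$type)
}

#' Per-locus presence frequencies by population
#'
#' @param g [marker_matrix].
#' @param groups named character vector mapping every sample id to a
#'   population label.
#' @return An object of class `freq_table`: list with `freq` (loci x groups
#'   presence frequencies; `NA` where a group has no non-missing call),
#'   `n` (non-missing counts on the same shape), and `loci`.
#' @export
allele_frequency <- function(g, groups) {
  stopifnot(inherits(g, "marker_matrix"))
  miss <- setdiff(g$samples, names(groups))
  if (length(miss) > 0) {
    stop("unmapped samples: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  groups <- groups[g$samples]
  pops <- unique(unname(groups))
  freq <- matrix(NA_real_, nrow(g$calls), length(pops),
                 dimnames = list(g$loci$id, pops))
  n <- matrix(0L, nrow(g$calls), length(pops),
              dimnames = list(g$loci$id, pops))
  for (p in pops) {
    sub <- g$calls[, groups == p, drop = FALSE]
    nn <- rowSums(!is.na(sub))
    freq[, p] <- ifelse(nn > 0, rowSums(sub, na.rm = TRUE) / nn, NA_real_)
    n[, p] <- nn
  }
  structure(list(freq = freq, n = n, loci = g$loci), class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d loci x %d populations (%s)\n",
              nrow(x$freq), ncol(x$freq),
              paste(colnames(x$freq), collapse = ", ")))
  invisible(x)
}

#' Classify loci by population specificity
#'
#' Relaxed classification between two focal populations at a MAF threshold
#' (default 3%): `popA_specific` if the locus segregates above threshold in A
#' but is at or below it in B (symmetrically `popB_specific`), `shared` if
#' above threshold in both, `rare_both` otherwise. The `strict` flag
#' additionally marks truly specific loci: present in one population and
#' completely absent (frequency exactly 0) in the other.
#'
#' @param freqs `freq_table` from [allele_frequency()].
#' @param pop_a,pop_b names of the two focal populations (columns of `freqs`).
#' @param maf_threshold frequency threshold, default 0.03.
#' @return data.frame with `id`, `freq_a`, `freq_b`, `label`, `strict`.
#' @export
classify_population_specificity <- function(freqs, pop_a, pop_b,
                                            maf_threshold = 0.03) {
  stopifnot(inherits(freqs, "freq_table"),
            all(c(pop_a, pop_b) %in% colnames(freqs$freq)))
  fa <- freqs$freq[, pop_a]
  fb <- freqs$freq[, pop_b]
  label <- rep(NA_character_, length(fa))
  a_seg <- keep_above(fa, maf_threshold)
  b_seg <- keep_above(fb, maf_threshold)
  label[a_seg & b_seg] <- "shared"
  label[a_seg & !b_seg] <- "popA_specific"
  label[!a_seg & b_seg] <- "popB_specific"
  label[!a_seg & !b_seg] <- "rare_both"
  strict <- (label == "popA_specific" & !is.na(fb) & fb == 0) |
    (label == "popB_specific" & !is.na(fa) & fa == 0)
  data.frame(id = freqs$loci$id, freq_a = fa, freq_b = fb,
             label = label, strict = strict, row.names = NULL)
}

#' Cross-population frequency comparison for eQTL vs non-eQTL loci
#'
#' Pairs each locus's frequencies in two populations, bins them on a 2D grid,
#' and reports, per class (eQTL-flagged vs not), the fraction of loci found
#' at approximately equal frequency in both populations.
#'
#' @param freqs `freq_table`.
#' @param eqtl_flags logical vector (or vector of flagged locus ids).
#' @param pop_a,pop_b focal population names.
#' @param bin_width histogram bin width on each axis, default 0.05.
#' @param equal_band loci with `|freq_a - freq_b| <= equal_band` count as
#'   equal-frequency; default 0.1.
#' @return list with `pairs` (per-locus data.frame), `counts` (list of 2D
#'   tables per class), `equal_fraction` (named numeric per class).
#' @export
cross_population_frequency_table <- function(freqs, eqtl_flags, pop_a, pop_b,
                                             bin_width = 0.05,
                                             equal_band = 0.1) {
  stopifnot(inherits(freqs, "freq_table"))
  ids <- freqs$loci$id
  if (!is.logical(eqtl_flags)) eqtl_flags <- ids %in% eqtl_flags
  stopifnot(length(eqtl_flags) == length(ids))
  pairs <- data.frame(
    id = ids,
    freq_a = freqs$freq[, pop_a],
    freq_b = freqs$freq[, pop_b],
    eqtl = eqtl_flags,
    row.names = NULL
  )
  pairs <- pairs[!is.na(pairs$freq_a) & !is.na(pairs$freq_b), ]
  breaks <- seq(0, 1, by = bin_width)
  cut2 <- function(x) cut(x, breaks = breaks, include.lowest = TRUE,
                          right = FALSE)
  # right = FALSE gives [a, b) bins; include.lowest folds 1.0 into the last
  counts <- lapply(split(pairs, pairs$eqtl), function(d) {
    table(freq_a = cut2(d$freq_a), freq_b = cut2(d$freq_b))
  })
  names(counts) <- ifelse(names(counts) == "TRUE", "eqtl", "non_eqtl")
  equal_fraction <- vapply(split(pairs, pairs$eqtl), function(d) {
    if (nrow(d) == 0) NA_real_ else mean(abs(d$freq_a - d$freq_b) <= equal_band)
  }, numeric(1))
  names(equal_fraction) <- ifelse(names(equal_fraction) == "TRUE",
                                  "eqtl", "non_eqtl")
  list(pairs = pairs, counts = counts, equal_fraction = equal_fraction)
}
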