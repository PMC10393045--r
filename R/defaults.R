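#' Published pipeline defaults
#'
#' All tunable thresholds of the pipeline, centralized. Values mirror the
#' published rice TIP analysis protocol: minimum zygosity 0.25 (a TIP must
#' reach it in at least one sample), presence cutoff 0.05 for binarization,
#' MAF > 3% with complete data for the eQTL path, missingness <= 5% and
#' MAF >= 5% for the PBS path, a 5 kb cis window at 5% FDR, pi in 25-SNP
#' windows sliding by 5, H12 in 50-SNP windows sliding by 25, a +/- 50 kb
#' sweep-scan region, 1000 permutations, and 95th/99th PBS percentiles.
#'
#' @return Named list of default parameter values.
#' @export
pipeline_defaults <- function() {
  list(
    zygosity_min            = 0.25,
    zygosity_presence_cutoff = 0.05,
    maf_eqtl                = 0.03,
    missing_eqtl            = 0.0,
    maf_pbs                 = 0.05,
    missing_pbs             = 0.05,
    expressed_min_sample_frac = 0.10,
    cis_window              = 5000L,
    fdr                     = 0.05,
    relaxed_p               = 0.05,
    pi_window               = 25L,
    pi_step                 = 5L,
    h12_window              = 50L,
    h12_step                = 25L,
    sweep_flank             = 50000L,
    n_perm                  = 1000L,
    pbs_percentiles         = c(95, 99)
  )
}

# Boundary semantics, centralized: zygosity-style cutoffs keep on ">=",
# MAF-style cutoffs keep on strict ">" ("MAF higher than 3%").
keep_at_least <- function(x, cutoff) !is.na(x) & x >= cutoff
keep_above <- function(x, cutoff) !is.na(x) & x > cutoff

`%||%` <- function(a, b) if (is.null(a)) b else a

# ceiling() guarded against binary floating-point noise (0.05 * 300 is
# slightly above 15 in double arithmetic; the count must still be 15).
ceil_frac <- function(x) as.integer(ceiling(x - 1e-9))

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
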