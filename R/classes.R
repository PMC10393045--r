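#' TIP zygosity matrix
#'
#' Container for per-locus, per-sample zygosity values in `[0, 1]` (the
#' read-support fraction for an insertion, PoPoolationTE2 sense) together
#' with locus metadata. Missing evidence is encoded as `NA`, distinct from
#' zero (absence evidence is not the same as no evidence).
#'
#' @param loci data.frame with columns `id`, `chrom`, `pos` (0-based),
#'   `te_family`, `te_order`; `id` must be unique, `pos >= 0`.
#' @param samples character vector of sample ids.
#' @param values numeric matrix, loci x samples, entries in `[0, 1]` or `NA`.
#' @return An object of class `tip_zygosity`.
#' @export
tip_zygosity <- function(loci, samples, values) {
  loci <- as.data.frame(loci)
  stopifnot(
    all(c("id", "chrom", "pos") %in% names(loci)),
    !anyDuplicated(loci$id),
    all(loci$pos >= 0)
  )
  if (is.null(loci$te_family)) loci$te_family <- NA_character_
  if (is.null(loci$te_order)) loci$te_order <- NA_character_
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(loci), ncol(values) == length(samples))
  if (length(values) > 0 && !all(is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      stop("zygosity values must lie in [0, 1] or be NA")
    }
  }
  dimnames(values) <- list(loci$id, samples)
  structure(
    list(loci = loci, samples = as.character(samples), values = values),
    class = "tip_zygosity"
  )
}

#' Binary marker matrix (TIPs or SNPs)
#'
#' Presence/absence calls (0/1, possibly `NA` before imputation) for
#' haploid-equivalent inbred material, with genomic coordinates per locus.
#'
#' @param loci data.frame with `id`, `chrom`, `pos` (0-based) and, for TIPs,
#'   `te_family` and `te_order`.
#' @param samples character vector of sample ids.
#' @param calls integer matrix, loci x samples, entries in `{0, 1, NA}`.
#' @param type `"TIP"` or `"SNP"`.
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(loci, samples, calls, type = c("TIP", "SNP")) {
  type <- match.arg(type)
  loci <- as.data.frame(loci)
  stopifnot(
    all(c("id", "chrom", "pos") %in% names(loci)),
    !anyDuplicated(loci$id),
    all(loci$pos >= 0)
  )
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == nrow(loci), ncol(calls) == length(samples))
  if (!all(calls %in% c(0L, 1L, NA_integer_))) {
    stop("marker calls must be 0, 1 or NA")
  }
  dimnames(calls) <- list(loci$id, samples)
  structure(
    list(loci = loci, samples = as.character(samples), calls = calls,
         type = type),
    class = "marker_matrix"
  )
}

#' @export
print.tip_zygosity <- function(x, ...) {
  cat(sprintf("<tip_zygosity> %d loci x %d samples; %.2f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix:%s> %d loci x %d samples; %.2f%% missing\n",
              x$type, nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.tip_zygosity <- function(x) dim(x$values)

#' @export
dim.marker_matrix <- function(x) dim(x$calls)

#' Subset a matrix container by loci or samples
#'
#' `subset_loci` keeps the loci selected by a logical/integer index,
#' keeping the metadata aligned; `subset_samples` reorders/subsets the
#' sample columns by id (unknown ids are an error).
#'
#' @param m [tip_zygosity] or [marker_matrix].
#' @param keep logical or integer locus index.
#' @param samples character vector of sample ids to keep, in order.
#' @return Object of the same class.
#' @export
subset_loci <- function(m, keep) {
  if (inherits(m, "tip_zygosity")) {
    tip_zygosity(m$loci[keep, , drop = FALSE], m$samples,
                 m$values[keep, , drop = FALSE])
  } else {
    marker_matrix(m$loci[keep, , drop = FALSE], m$samples,
                  m$calls[keep, , drop = FALSE], type = m$type)
  }
}

#' @rdname subset_loci
#' @export
subset_samples <- function(m, samples) {
  miss <- setdiff(samples, m$samples)
  if (length(miss) > 0) {
    stop("samples not present in matrix: ", paste(miss, collapse = ", "))
  }
  if (inherits(m, "tip_zygosity")) {
    tip_zygosity(m$loci, samples, m$values[, samples, drop = FALSE])
  } else {
    marker_matrix(m$loci, samples, m$calls[, samples, drop = FALSE],
                  type = m$type)
  }
}

#' Gene model table
#'
#' Validates a data.frame of gene models (0-based half-open coordinates).
#'
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (`+`, `-` or `.`).
#' @return The validated data.frame.
#' @export
gene_models <- function(genes) {
  genes <- as.data.frame(genes)
  stopifnot(
    all(c("id", "chrom", "start", "end") %in% names(genes)),
    !anyDuplicated(genes$id),
    all(genes$start < genes$end)
  )
  if (is.null(genes$strand)) genes$strand <- "+"
  stopifnot(all(genes$strand %in% c("+", "-", ".")))
  genes
}
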