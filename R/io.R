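## File-format boundary. Internal coordinates are 0-based half-open (BED
## native); VCF and GFF3 are 1-based inclusive and are converted here, in
## one place, by the two helpers below.

pos_to_internal <- function(pos_1based) as.integer(pos_1based) - 1L
pos_to_external <- function(pos_0based) as.integer(pos_0based) + 1L

read_checked_tsv <- function(path, required) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

meta_cols <- c("id", "chrom", "pos", "te_family", "te_order")

#' Write / read a TIP matrix as TSV
#'
#' Layout: five metadata columns (`id`, `chrom`, `pos`, `te_family`,
#' `te_order`), then one column per sample; missing values are `NA`.
#' Works for both zygosity values and binary calls.
#'
#' @param m [tip_zygosity] or [marker_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tip_tsv <- function(m, path) {
  vals <- if (inherits(m, "tip_zygosity")) m$values else m$calls
  loci <- m$loci
  for (cc in c("te_family", "te_order")) {
    if (is.null(loci[[cc]])) loci[[cc]] <- NA_character_
  }
  df <- cbind(loci[, meta_cols], as.data.frame(vals))
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_tip_tsv
#' @param type `"zygosity"` or `"genotype"`: how to interpret the value
#'   columns.
#' @export
read_tip_tsv <- function(path, type = c("zygosity", "genotype")) {
  type <- match.arg(type)
  df <- read_checked_tsv(path, meta_cols)
  samples <- setdiff(names(df), meta_cols)
  vals <- as.matrix(df[, samples, drop = FALSE])
  if (type == "zygosity") {
    tip_zygosity(df[, meta_cols], samples, vals)
  } else {
    marker_matrix(df[, meta_cols], samples, vals, type = "TIP")
  }
}

#' Export marker loci as BED
#'
#' Single-base intervals, 0-based half-open, with the TE family in the
#' name column.
#'
#' @param m [marker_matrix] or [tip_zygosity].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_loci <- function(m, path) {
  loci <- m$loci
  name <- if (!is.null(loci$te_family) && !all(is.na(loci$te_family))) {
    paste(loci$id, loci$te_family, sep = "|")
  } else loci$id
  df <- data.frame(chrom = loci$chrom, start = loci$pos,
                   end = loci$pos + 1L, name = name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a binary SNP matrix as minimal VCFv4.2
#'
#' One biallelic record per locus with haploid GT calls (`0`, `1`, or `.`
#' for missing). Internal 0-based positions are converted to the 1-based
#' VCF convention. The writer emits plain text so outputs stay
#' byte-stable across runs.
#'
#' @param snps [marker_matrix] of type `"SNP"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  stopifnot(inherits(snps, "marker_matrix"))
  gt <- matrix(as.character(snps$calls), nrow = nrow(snps$calls))
  gt[is.na(gt)] <- "."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tipscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", snps$samples), collapse = "\t")
  )
  body <- paste(
    snps$loci$chrom, pos_to_external(snps$loci$pos), snps$loci$id,
    "A", "T", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read SNP genotypes from a VCF
#'
#' Collapses GT to binary alt-presence for haploid (`0`/`1`) or
#' homozygous-diploid (`0/0`, `1/1`, `0|0`, `1|1`) calls; `.` becomes
#' missing. Heterozygous calls are rejected with a count report unless a
#' policy is given: `"drop-site"` removes the offending loci,
#' `"drop-call"` sets the offending calls missing. Multiallelic records
#' are skipped with a warning. VCF 1-based positions are converted to the
#' internal 0-based convention.
#'
#' @param path VCF path.
#' @param het_policy `"error"` (default), `"drop-site"` or `"drop-call"`.
#' @return [marker_matrix] of type `"SNP"`.
#' @export
read_vcf_snps <- function(path, het_policy = c("error", "drop-site",
                                               "drop-call")) {
  het_policy <- match.arg(het_policy)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning("skipping ", sum(multi), " multiallelic record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  first <- substr(gt, 1, 1)
  second <- substr(gt, 3, 3)
  het <- !is.na(gt) & second != "" & first != second
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
  ok <- !is.na(gt) & !het & first %in% c("0", "1")
  calls[ok] <- as.integer(first[ok])
  if (any(het)) {
    if (het_policy == "error") {
      bad <- which(rowSums(het) > 0)
      stop("heterozygous calls at ", sum(het), " cell(s) in ", length(bad),
           " site(s) (first: ", fix$ID[bad[1]],
           "); set het_policy to 'drop-site' or 'drop-call'")
    } else if (het_policy == "drop-site") {
      keep <- rowSums(het) == 0
      calls <- calls[keep, , drop = FALSE]
      fix <- fix[keep, , drop = FALSE]
    } # drop-call: already NA
  }
  loci <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos = pos_to_internal(as.integer(fix$POS)),
    stringsAsFactors = FALSE
  )
  marker_matrix(loci, colnames(calls), calls, type = "SNP")
}

#' Write / read gene models as GFF3
#'
#' Gene features only, `ID` attribute carrying the gene id; internal
#' 0-based half-open coordinates are converted to/from the 1-based
#' inclusive GFF3 convention via rtracklayer.
#'
#' @param genes gene model data.frame ([gene_models()]).
#' @param path file path.
#' @return `path` (writer) or the gene data.frame (reader).
#' @export
write_gff_genes <- function(genes, path) {
  genes <- gene_models(genes)
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = ifelse(genes$strand == ".", "*", genes$strand)
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$id
  S4Vectors::mcols(gr)$source <- "tipscan"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff_genes
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  ids <- S4Vectors::mcols(gr)$ID
  drop <- is.na(ids) | ids == ""
  if (any(drop)) {
    warning("skipping ", sum(drop), " gene record(s) without an ID attribute")
    gr <- gr[!drop]
    ids <- ids[!drop]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  gene_models(data.frame(
    id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = ifelse(strand == "*", ".", strand),
    stringsAsFactors = FALSE
  ))
}

#' Write a simulated cohort to a directory
#'
#' Emits the TIP zygosity TSV, the SNP VCF, the gene GFF3, the counts and
#' sample-metadata TSVs, and the three truth tables.
#'
#' @param cohort `tip_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tip_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tip_tsv(cohort$zygosity, file.path(dir, "tip_zygosity.tsv"))
  write_snp_vcf(cohort$snps, file.path(dir, "snps.vcf"))
  write_gff_genes(cohort$genes, file.path(dir, "genes.gff3"))
  counts_df <- cbind(data.frame(gene_id = rownames(cohort$counts)),
                     as.data.frame(cohort$counts))
  write_tsv(counts_df, file.path(dir, "counts.tsv"))
  write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  write_tsv(cohort$accessions, file.path(dir, "accessions.tsv"))
  write_tsv(cohort$truth$planted_eqtls, file.path(dir, "truth_eqtls.tsv"))
  write_tsv(cohort$truth$selected_tips, file.path(dir, "truth_selected.tsv"))
  write_tsv(cohort$truth$sweep_loci, file.path(dir, "truth_sweeps.tsv"))
  invisible(dir)
}

#' Read a counts TSV (gene_id column + one column per sample)
#'
#' @param path TSV path.
#' @return genes x samples integer matrix.
#' @export
read_counts_tsv <- function(path) {
  df <- read_checked_tsv(path, "gene_id")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' Read the per-sample metadata TSV
#'
#' @param path TSV path.
#' @return data.frame with the sample/accession/population/subpopulation/
#'   condition/replicate columns.
#' @export
read_samples_tsv <- function(path) {
  read_checked_tsv(path, c("sample", "accession", "population",
                           "subpopulation", "condition", "replicate"))
}
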