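#' Read a sample metadata table
#'
#' Tab-separated table with one row per sample. Required column: `sample`.
#' Recognised optional columns: `species`, `strain`, `subgroup`, `phenotype`
#' and `homozygous_expected` (logical; `TRUE` for cultures derived from a
#' single haploid cell, which should be homozygous diploid at every locus).
#'
#' @param path Path to a TSV file.
#' @return A data frame with unique sample names and all recognised columns
#'   present (missing ones filled with `NA` / `FALSE`).
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(md)) stop("metadata must contain a 'sample' column")
  if (anyDuplicated(md$sample))
    stop("duplicate sample names in metadata: ",
         paste(unique(md$sample[duplicated(md$sample)]), collapse = ", "))
  for (col in c("species", "strain", "subgroup", "phenotype"))
    if (!col %in% names(md)) md[[col]] <- NA_character_
  if (!"homozygous_expected" %in% names(md)) md$homozygous_expected <- FALSE
  md$homozygous_expected <- as.logical(md$homozygous_expected)
  md
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) and returns the biallelic-SNV
#' genotype matrix. Multiallelic records and non-SNV records (indels,
#' symbolic alleles) are dropped and counted; the counts are carried in the
#' matrix provenance and surfaced again by [filter_genotypes()]'s report.
#'
#' Genotype strings map as: `0/0` to homozygous reference, `0/1` and `1/0`
#' (and phased `0|1`, `1|0`) to heterozygous, `1/1` to homozygous alternate,
#' `./.` to missing. Half-calls such as `./1` are treated as missing.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param metadata Optional data frame as returned by
#'   [read_sample_metadata()]; when given, every VCF sample must appear in it
#'   (a missing sample is a hard error naming the sample).
#' @return A [genotype_matrix()] with GQ attached when the VCF carries a GQ
#'   FORMAT field, and an attribute `read_report` holding the record-level
#'   drop counts.
#' @export
read_multisample_vcf <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0L) stop("VCF contains no records: ", path)

  bases <- c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snv <- !multi & fix$REF %in% bases & fix$ALT %in% bases
  n_multi <- sum(multi)
  n_nonsnv <- sum(!snv & !multi)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  has_gq <- "GQ" %in% unique(unlist(strsplit(unique(vcf@gt[, "FORMAT"]), ":")))
  gq <- if (has_gq) vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE) else NULL

  smp <- colnames(gt)
  if (!is.null(metadata)) {
    missing_md <- setdiff(smp, metadata$sample)
    if (length(missing_md))
      stop("VCF sample(s) absent from metadata: ", paste(missing_md, collapse = ", "))
  }

  gt <- gt[snv, , drop = FALSE]
  if (!is.null(gq)) gq <- gq[snv, , drop = FALSE]
  fix <- fix[snv, , drop = FALSE]

  # GT string -> dose; anything containing "." is missing (incl. half-calls)
  code <- function(g) {
    out <- rep(NA_integer_, length(g))
    g <- gsub("|", "/", g, fixed = TRUE)
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    bad <- !is.na(g) & is.na(out) & !grepl(".", g, fixed = TRUE)
    if (any(bad))
      stop("unrecognised genotype string(s): ",
           paste(unique(g[bad]), collapse = ", "))
    out
  }
  calls <- matrix(code(as.vector(gt)), nrow = nrow(gt), ncol = ncol(gt))
  calls <- t(calls)  # samples x sites
  gq_m <- if (!is.null(gq)) t(matrix(as.integer(gq), nrow = nrow(gq))) else NULL

  m <- genotype_matrix(
    samples = smp,
    sites = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                       ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    calls = calls, gq = gq_m,
    log = sprintf(
      "read %s: %d records, kept %d biallelic SNVs (dropped %d multiallelic, %d non-SNV)",
      path, n_rec, sum(snv), n_multi, n_nonsnv))
  attr(m, "read_report") <- list(n_records = n_rec,
                                 n_sites_dropped_multiallelic = n_multi,
                                 n_sites_dropped_nonsnv = n_nonsnv)
  m
}

new_filter_report <- function(m_in, ...) {
  rr <- attr(m_in, "read_report")
  rep <- list(n_input_sites = nrow(m_in$sites),
              n_sites_dropped_multiallelic =
                if (is.null(rr)) NA_integer_ else rr$n_sites_dropped_multiallelic,
              ...)
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = "=", collapse = ", ")
    cat(sprintf("  %-32s %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Genotype-quality and site-missingness filters
#'
#' Applies, in this fixed order, (1) the per-call GQ filter: calls with
#' `GQ < min_gq` are set to missing; then (2) the site-missingness filter:
#' sites whose missing-call fraction exceeds `max_missing` are dropped
#' (the PLINK `--geno`-style rule). The order matters and is fixed: quality
#' masking feeds the missingness accounting.
#'
#' @param m A [genotype_matrix()].
#' @param min_gq Minimum conditional genotype quality; calls below it are set
#'   missing. Default 20, the conventional caller threshold. Set to 0 to
#'   disable (required when `m` carries no GQ).
#' @param max_missing Maximum tolerated missing-call fraction per site, in
#'   `[0, 1]`. Default 0.1. At `1` no site is dropped.
#' @return A list with elements `matrix` (the filtered [genotype_matrix()])
#'   and `report` (a `filter_report` whose counts reconcile exactly:
#'   `n_output_sites = n_input_sites - n_sites_dropped_missingness`).
#' @export
filter_genotypes <- function(m, min_gq = 20L, max_missing = 0.1) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (max_missing < 0 || max_missing > 1) stop("'max_missing' must be in [0, 1]")
  if (is.null(m$gq) && min_gq > 0)
    stop("matrix has no GQ but min_gq = ", min_gq,
         "; pass min_gq = 0 to disable the GQ filter explicitly")

  n_masked <- 0L
  if (min_gq > 0) {
    low <- !is.na(m$calls) & (is.na(m$gq) | m$gq < min_gq)
    n_masked <- sum(low)
    m$calls[low] <- NA_integer_
  }
  miss_frac <- colMeans(is.na(m$calls))
  keep <- miss_frac <= max_missing
  out <- subset_sites(m, keep,
                      note = sprintf("filter_genotypes(min_gq=%d, max_missing=%g): masked %d calls, dropped %d sites",
                                     min_gq, max_missing, n_masked, sum(!keep)))
  report <- new_filter_report(m,
    n_calls_masked_gq = n_masked,
    n_sites_dropped_missingness = sum(!keep),
    n_output_sites = sum(keep),
    thresholds = list(min_gq = min_gq, max_missing = max_missing))
  list(matrix = out, report = report)
}

#' Remove loci heterozygous in homozygosity-expected samples
#'
#' Doubled-haploid cultures (conchocelis derived from a single haploid cell)
#' should be homozygous diploid at every locus; a heterozygous call in such a
#' sample flags a non-identical repeat, a mis-mapped (e.g. bacterial) region
#' or a genotyping error. This filter drops every site at which any of the
#' designated samples is heterozygous.
#'
#' @param m A [genotype_matrix()].
#' @param homozygous_samples Character vector of sample names expected to be
#'   homozygous; must be a subset of `m$samples`. An empty set warns and
#'   returns the matrix unchanged.
#' @return A list with elements `matrix` and `report` (field
#'   `n_sites_dropped_het`).
#' @export
drop_heterozygous_sites <- function(m, homozygous_samples) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (length(homozygous_samples) == 0L) {
    warning("empty 'homozygous_samples'; no sites dropped")
    report <- new_filter_report(m, n_sites_dropped_het = 0L,
                                n_output_sites = nrow(m$sites))
    return(list(matrix = m, report = report))
  }
  idx <- sample_index(m, homozygous_samples, "homozygous sample")
  any_het <- colSums(m$calls[idx, , drop = FALSE] == 1L, na.rm = TRUE) > 0L
  out <- subset_sites(m, !any_het,
                      note = sprintf("drop_heterozygous_sites(%d samples): dropped %d sites",
                                     length(idx), sum(any_het)))
  report <- new_filter_report(m, n_sites_dropped_het = sum(any_het),
                              n_output_sites = sum(!any_het))
  list(matrix = out, report = report)
}

#' Write a genotype matrix as a VCF v4.2 file
#'
#' Emits unphased diploid `GT` (and `GQ` when present) records, one per site.
#' Mainly useful for exporting filtered call sets to downstream tools.
#'
#' @param m A [genotype_matrix()].
#' @param path Output path.
#' @param contig_lengths Optional named integer vector of chromosome lengths
#'   for the `##contig` header lines; defaults to the maximum site position
#'   seen per chromosome.
#' @param force Overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(m, path, contig_lengths = NULL, force = FALSE) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (file.exists(path) && !force)
    stop("refusing to overwrite existing file (use force = TRUE): ", path)
  chroms <- unique(m$sites$chrom)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(chroms, function(ch) max(m$sites$pos[m$sites$chrom == ch]),
                             integer(1))
  }
  has_gq <- !is.null(m$gq)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chroms, contig_lengths[chroms]),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (has_gq) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Conditional genotype quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", m$samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[m$calls + 1L], nrow = nrow(m$calls))
  gt_str[is.na(m$calls)] <- "./."
  if (has_gq) {
    gq_str <- matrix(as.character(m$gq), nrow = nrow(m$gq))
    gq_str[is.na(m$gq) | is.na(m$calls)] <- "."
    gt_str <- matrix(paste(gt_str, gq_str, sep = ":"), nrow = nrow(gt_str))
  }
  body <- vapply(seq_len(nrow(m$sites)), function(j) {
    paste(c(m$sites$chrom[j], m$sites$pos[j], ".", m$sites$ref[j], m$sites$alt[j],
            ".", ".", ".", if (has_gq) "GT:GQ" else "GT", gt_str[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
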