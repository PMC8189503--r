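#' Genotype matrix of biallelic SNVs
#'
#' The central container consumed by every filter and analysis: an ordered
#' set of samples by an ordered set of biallelic SNV sites, with one genotype
#' class per call and (optionally) the caller's conditional genotype quality
#' (GQ). Genotype classes are stored as allele dose: `0` = homozygous
#' reference, `1` = heterozygous, `2` = homozygous alternate, `NA` = missing.
#'
#' Sites are kept strictly sorted by (chromosome, position); chromosome order
#' is the order of first appearance (natural for `chr1 ... chrN`). Duplicate
#' (chromosome, position) pairs are rejected.
#'
#' @param samples Character vector of unique sample names (matrix row order).
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; `ref`/`alt` must be single distinct bases in `A,C,G,T`.
#' @param calls Integer matrix, `length(samples)` rows by `nrow(sites)`
#'   columns, values in `0:2` or `NA`.
#' @param gq Optional integer matrix of the same shape with per-call GQ
#'   (missing calls may be `NA`).
#' @param log Character vector of provenance lines (source path, applied
#'   filters); appended to by the filter functions.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `sites`, `calls`, `gq`, `log`.
#' @seealso [read_multisample_vcf()], [filter_genotypes()],
#'   [drop_heterozygous_sites()], [apply_region_mask()]
#' @export
genotype_matrix <- function(samples, sites, calls, gq = NULL, log = character()) {
  samples <- as.character(samples)
  if (length(samples) == 0L) stop("at least one sample is required")
  if (anyDuplicated(samples)) stop("duplicate sample names: ",
                                   paste(unique(samples[duplicated(samples)]), collapse = ", "))
  need <- c("chrom", "pos", "ref", "alt")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    stop("'sites' must be a data frame with columns chrom, pos, ref, alt")
  sites <- data.frame(chrom = as.character(sites$chrom), pos = as.integer(sites$pos),
                      ref = as.character(sites$ref), alt = as.character(sites$alt),
                      stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% bases) || !all(sites$alt %in% bases))
    stop("ref and alt must be single bases in A,C,G,T (biallelic SNVs only)")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(sites))
    stop("'calls' must be length(samples) x nrow(sites)")
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls)))
    stop("'calls' values must be 0, 1, 2 or NA")
  if (!is.null(gq)) {
    gq <- as.matrix(gq)
    storage.mode(gq) <- "integer"
    if (!all(dim(gq) == dim(calls))) stop("'gq' dimensions must match 'calls'")
  }
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  if (!is.null(gq)) gq <- gq[, ord, drop = FALSE]
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicate (chrom, pos) sites are not allowed")
  rownames(sites) <- NULL
  dimnames(calls) <- list(samples, paste0(sites$chrom, ":", sites$pos))
  if (!is.null(gq)) dimnames(gq) <- dimnames(calls)
  structure(list(samples = samples, sites = sites, calls = calls, gq = gq,
                 log = as.character(log)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- if (length(x$calls)) mean(is.na(x$calls)) else 0
  cat(sprintf("genotype_matrix: %d samples x %d sites (%.1f%% missing calls, GQ %s)\n",
              length(x$samples), nrow(x$sites), 100 * miss,
              if (is.null(x$gq)) "absent" else "present"))
  if (length(x$log)) cat(paste0("  ", x$log, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# keep: logical or integer site index; preserves site order
subset_sites <- function(m, keep, note = NULL) {
  if (is.logical(keep)) keep <- which(keep)
  keep <- sort(unique(as.integer(keep)))
  out <- m
  out$sites <- m$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$calls <- m$calls[, keep, drop = FALSE]
  if (!is.null(m$gq)) out$gq <- m$gq[, keep, drop = FALSE]
  if (!is.null(note)) out$log <- c(out$log, note)
  out
}

sample_index <- function(m, who, arg = "sample") {
  i <- match(who, m$samples)
  if (anyNA(i))
    stop("unknown ", arg, ": ", paste(who[is.na(i)], collapse = ", "))
  i
}

#' Genomic region mask
#'
#' A set of genomic intervals, 1-based inclusive, used to exclude (or
#' restrict to) regions such as the nuclear rRNA repeats.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive, `start <= end`).
#' @return An object of class `region_mask`.
#' @seealso [read_bed_mask()], [apply_region_mask()]
#' @export
region_mask <- function(intervals) {
  if (!is.data.frame(intervals) || !all(c("chrom", "start", "end") %in% names(intervals)))
    stop("'intervals' must be a data frame with columns chrom, start, end")
  intervals <- data.frame(chrom = as.character(intervals$chrom),
                          start = as.integer(intervals$start),
                          end = as.integer(intervals$end), stringsAsFactors = FALSE)
  if (nrow(intervals) && any(intervals$start > intervals$end))
    stop("mask intervals must have start <= end")
  if (nrow(intervals) && any(intervals$start < 1L))
    stop("mask intervals must have start >= 1")
  structure(list(intervals = intervals), class = "region_mask")
}

#' Read a BED file as a region mask
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path Path to a BED file (first three columns used).
#' @return A [region_mask()].
#' @export
read_bed_mask <- function(path) {
  bed <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file must have at least 3 columns: ", path)
  region_mask(data.frame(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]]))
}

# logical vector over m's sites: TRUE where the site lies in any mask interval
sites_in_mask <- function(m, mask) {
  stopifnot(inherits(mask, "region_mask"))
  iv <- mask$intervals
  bad <- setdiff(unique(iv$chrom), unique(m$sites$chrom))
  if (length(bad))
    stop("mask names chromosomes absent from the genotype matrix: ",
         paste(bad, collapse = ", "))
  hit <- rep(FALSE, nrow(m$sites))
  for (k in seq_len(nrow(iv))) {
    hit <- hit | (m$sites$chrom == iv$chrom[k] &
                    m$sites$pos >= iv$start[k] & m$sites$pos <= iv$end[k])
  }
  hit
}

#' Exclude or restrict a genotype matrix to masked regions
#'
#' @param m A [genotype_matrix()].
#' @param mask A [region_mask()]; chromosomes named by the mask must exist in
#'   `m`.
#' @param mode `"exclude"` drops sites inside the mask intervals;
#'   `"restrict"` keeps only those. The two modes partition the input sites.
#' @return A filtered `genotype_matrix` (site order preserved).
#' @export
apply_region_mask <- function(m, mask, mode = c("exclude", "restrict")) {
  stopifnot(inherits(m, "genotype_matrix"))
  mode <- match.arg(mode)
  hit <- sites_in_mask(m, mask)
  keep <- if (mode == "exclude") !hit else hit
  subset_sites(m, keep,
               note = sprintf("region mask (%s): %d of %d sites kept",
                              mode, sum(keep), length(keep)))
}
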