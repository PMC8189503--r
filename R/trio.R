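#' Parental fixed-difference (trio-informative) sites
#'
#' A site is trio-informative when parent A carries two reference alleles
#' (homozygous reference) and parent B carries two alternate alleles
#' (homozygous alternate), both calls non-missing. At such loci a true
#' allotetraploid F1 — carrying both full parental chromosome sets but
#' genotyped as a diploid — must appear heterozygous.
#'
#' @param m A [genotype_matrix()].
#' @param parent_a,parent_b Sample names of the two parents. Only the
#'   (A homozygous-reference, B homozygous-alternate) orientation is
#'   returned; swap the arguments for the mirrored condition.
#' @return Integer vector of site indices into `m$sites`.
#' @export
informative_trio_sites <- function(m, parent_a, parent_b) {
  stopifnot(inherits(m, "genotype_matrix"))
  ia <- sample_index(m, parent_a, "parent_a")
  ib <- sample_index(m, parent_b, "parent_b")
  a <- m$calls[ia, ]
  b <- m$calls[ib, ]
  unname(which(!is.na(a) & !is.na(b) & a == 0L & b == 2L))
}

#' Classify a putative hybrid at parental fixed-difference loci
#'
#' Conditions on the trio-informative sites (see
#' [informative_trio_sites()]) and tabulates the hybrid's genotype class at
#' each: two reference alleles, one reference/one alternate (heterozygous),
#' two alternate alleles, or unclassified (missing). A predominantly
#' heterozygous hybrid at these loci indicates an allotetraploid genome
#' (both parental chromosome sets retained); a large homozygous class
#' indicates recombination, substitution of chromosomes, or that the tested
#' parent is not the true parent.
#'
#' The reference study-scale anchor, not reproducible without the study's
#' raw reads, is 18,484 / 139,259 / 141 loci in the three classes for its
#' (*P. yezoensis*, *P. tenera*, hybrid) trio, i.e. 88.2% heterozygous.
#'
#' @param m A [genotype_matrix()].
#' @param parent_a,parent_b,hybrid Sample names; `hybrid` must differ from
#'   both parents.
#' @param mask Optional [region_mask()] applied in exclude mode before
#'   classification (e.g. to drop homogenised nuclear rRNA repeats).
#' @return An object of class `trio_class_counts` with fields
#'   `n_informative`, `n_two_ref`, `n_het`, `n_two_alt`, `n_unclassified`,
#'   the class membership `loci` (list of data frames with `chrom`, `pos`)
#'   and the trio sample names. The four class counts always sum to
#'   `n_informative`.
#' @export
classify_trio <- function(m, parent_a, parent_b, hybrid, mask = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (hybrid %in% c(parent_a, parent_b))
    stop("'hybrid' must differ from both parent samples")
  if (!is.null(mask)) m <- apply_region_mask(m, mask, mode = "exclude")
  idx <- informative_trio_sites(m, parent_a, parent_b)
  ih <- sample_index(m, hybrid, "hybrid")
  h <- m$calls[ih, idx]
  cls <- ifelse(is.na(h), "unclassified",
                c("two_ref", "het", "two_alt")[h + 1L])
  loci <- lapply(c(two_ref = "two_ref", het = "het", two_alt = "two_alt",
                   unclassified = "unclassified"),
                 function(k) m$sites[idx[cls == k], c("chrom", "pos")])
  structure(list(n_informative = length(idx),
                 n_two_ref = sum(cls == "two_ref"),
                 n_het = sum(cls == "het"),
                 n_two_alt = sum(cls == "two_alt"),
                 n_unclassified = sum(cls == "unclassified"),
                 loci = loci,
                 trio = c(parent_a = parent_a, parent_b = parent_b, hybrid = hybrid)),
            class = "trio_class_counts")
}

#' Construct trio class counts directly
#'
#' Useful for re-analysing published contingency counts without the
#' underlying call set.
#'
#' @param n_two_ref,n_het,n_two_alt,n_unclassified Non-negative counts of
#'   hybrid genotype classes at parental fixed-difference loci.
#' @return A `trio_class_counts` object (without locus lists).
#' @export
trio_class_counts <- function(n_two_ref, n_het, n_two_alt, n_unclassified = 0L) {
  counts <- c(n_two_ref, n_het, n_two_alt, n_unclassified)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(n_informative = sum(counts),
                 n_two_ref = as.integer(n_two_ref), n_het = as.integer(n_het),
                 n_two_alt = as.integer(n_two_alt),
                 n_unclassified = as.integer(n_unclassified),
                 loci = NULL, trio = NULL),
            class = "trio_class_counts")
}

#' @export
print.trio_class_counts <- function(x, ...) {
  cat("trio_class_counts")
  if (!is.null(x$trio))
    cat(sprintf(" [A=%s, B=%s, hybrid=%s]", x$trio["parent_a"], x$trio["parent_b"],
                x$trio["hybrid"]))
  cat("\n")
  n_cls <- x$n_two_ref + x$n_het + x$n_two_alt
  pct <- function(k) if (n_cls > 0) sprintf(" (%.1f%% of classified)", 100 * k / n_cls) else ""
  cat(sprintf("  informative loci (A hom-ref, B hom-alt): %d\n", x$n_informative))
  cat(sprintf("  two reference alleles : %d%s\n", x$n_two_ref, pct(x$n_two_ref)))
  cat(sprintf("  het (one ref/one alt) : %d%s\n", x$n_het, pct(x$n_het)))
  cat(sprintf("  two alternate alleles : %d%s\n", x$n_two_alt, pct(x$n_two_alt)))
  cat(sprintf("  unclassified (missing): %d\n", x$n_unclassified))
  invisible(x)
}

#' Allotetraploid verdict from trio class counts
#'
#' The heterozygous fraction is computed over classified loci only
#' (unclassified/missing loci are excluded from the denominator). The hybrid
#' is called allotetraploid when the fraction reaches `threshold`
#' (`>=` semantics) and enough loci were classified; with fewer than
#' `min_classified` classified loci the verdict is `NA` ("insufficient
#' data") rather than a boolean guess.
#'
#' @param counts A `trio_class_counts` object.
#' @param threshold Heterozygous-fraction threshold for the allotetraploid
#'   call; default 0.8, chosen to separate a genuine allotetraploid (~0.9
#'   observed in practice) from plausible contamination or wrong-parent
#'   scenarios.
#' @param min_classified Minimum number of classified loci required for a
#'   boolean verdict; default 100.
#' @return An object of class `ploidy_verdict` with `het_fraction`,
#'   `frac_two_ref`, `frac_two_alt`, `n_classified`, `threshold` and
#'   `is_allotetraploid` (logical, `NA` when data are insufficient).
#' @export
allotetraploid_verdict <- function(counts, threshold = 0.8, min_classified = 100L) {
  stopifnot(inherits(counts, "trio_class_counts"))
  n_cls <- counts$n_two_ref + counts$n_het + counts$n_two_alt
  hf <- if (n_cls > 0) counts$n_het / n_cls else NA_real_
  verdict <- if (n_cls < min_classified) NA else hf >= threshold
  structure(list(het_fraction = hf,
                 frac_two_ref = if (n_cls > 0) counts$n_two_ref / n_cls else NA_real_,
                 frac_two_alt = if (n_cls > 0) counts$n_two_alt / n_cls else NA_real_,
                 n_classified = n_cls,
                 threshold = threshold,
                 min_classified = min_classified,
                 is_allotetraploid = verdict),
            class = "ploidy_verdict")
}

#' @export
print.ploidy_verdict <- function(x, ...) {
  cat("ploidy_verdict\n")
  cat(sprintf("  classified loci : %d\n", x$n_classified))
  if (!is.na(x$het_fraction))
    cat(sprintf("  het fraction    : %.4f (%.1f%%); two-ref %.1f%%, two-alt %.1f%%\n",
                x$het_fraction, 100 * x$het_fraction, 100 * x$frac_two_ref,
                100 * x$frac_two_alt))
  v <- if (is.na(x$is_allotetraploid)) "insufficient data"
       else if (x$is_allotetraploid) "ALLOTETRAPLOID" else "not allotetraploid"
  cat(sprintf("  verdict         : %s (threshold %.2f, min %d loci)\n",
              v, x$threshold, x$min_classified))
  invisible(x)
}
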