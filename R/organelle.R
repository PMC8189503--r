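#' Equal-length sequence alignment
#'
#' A light container for per-sample equal-length nucleotide sequences over
#' `A, C, G, T, N, -` — either organelle alignments read from FASTA or
#' variable-site exports derived from a genotype matrix (in which case the
#' original genomic coordinate of every column is retained).
#'
#' @param seqs Character matrix (samples x columns, single characters) or a
#'   named character vector of equal-length strings.
#' @param samples Optional sample names (taken from names/rownames of `seqs`
#'   when absent).
#' @param source_coords Optional data frame with `chrom`, `pos` per column.
#' @return An object of class `seq_alignment` with fields `samples`, `seqs`
#'   (character matrix) and `source_coords`.
#' @export
seq_alignment <- function(seqs, samples = NULL, source_coords = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(samples)) samples <- names(seqs)
    if (length(unique(nchar(seqs))) > 1L)
      stop("all sequences must have equal length")
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  } else {
    seqs <- toupper(as.matrix(seqs))
    if (is.null(samples)) samples <- rownames(seqs)
  }
  if (is.null(samples)) stop("sample names are required")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample names")
  if (nrow(seqs) != length(samples)) stop("one sequence per sample required")
  bad <- setdiff(unique(as.vector(seqs)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) stop("illegal characters in alignment: ", paste(bad, collapse = ", "))
  if (!is.null(source_coords)) {
    if (nrow(source_coords) != ncol(seqs))
      stop("'source_coords' must have one row per alignment column")
    rownames(source_coords) <- NULL
  }
  rownames(seqs) <- samples
  structure(list(samples = samples, seqs = seqs, source_coords = source_coords),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d sequences x %d columns%s\n",
              length(x$samples), ncol(x$seqs),
              if (is.null(x$source_coords)) "" else " (with source coordinates)"))
  invisible(x)
}

#' Export variable sites of a genotype matrix as an alignment
#'
#' Keeps the sites with at least two genotype classes among non-missing
#' calls and emits, per sample, the reference base (homozygous reference),
#' the alternate base (homozygous alternate) or `N` (heterozygous or
#' missing — downstream phylogenetic sets are homozygous-only, so a
#' heterozygous diploid call has no single haploid state). Column order
#' follows site order; original coordinates are kept in `source_coords`.
#'
#' @param m A [genotype_matrix()].
#' @param mask Optional [region_mask()] applied in exclude mode first (e.g.
#'   rRNA regions before chloroplast phylogenetics).
#' @return A [seq_alignment()]; zero variable sites give a valid empty
#'   alignment with a warning.
#' @export
variable_site_alignment <- function(m, mask = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (!is.null(mask)) m <- apply_region_mask(m, mask, mode = "exclude")
  n_class <- apply(m$calls, 2, function(x) length(unique(x[!is.na(x)])))
  keep <- which(n_class >= 2L)
  if (length(keep) == 0L)
    warning("no variable sites; returning an empty alignment")
  seqs <- matrix("N", nrow = length(m$samples), ncol = length(keep))
  for (k in seq_along(keep)) {
    j <- keep[k]
    x <- m$calls[, j]
    seqs[!is.na(x) & x == 0L, k] <- m$sites$ref[j]
    seqs[!is.na(x) & x == 2L, k] <- m$sites$alt[j]
  }
  seq_alignment(seqs, samples = m$samples,
                source_coords = m$sites[keep, c("chrom", "pos"), drop = FALSE])
}

#' Count parsimony-informative columns
#'
#' A column is parsimony informative when it shows at least two distinct
#' states (ignoring `N` and gaps) each present in at least two sequences.
#'
#' @param a A [seq_alignment()].
#' @return Integer count.
#' @export
parsimony_informative_count <- function(a) {
  stopifnot(inherits(a, "seq_alignment"))
  if (ncol(a$seqs) == 0L) return(0L)
  sum(apply(a$seqs, 2, function(col) {
    tab <- table(col[!col %in% c("N", "-")])
    sum(tab >= 2L) >= 2L
  }))
}

pairwise_p_distances <- function(a, pairs) {
  vapply(seq_len(nrow(pairs)), function(k) {
    x <- a$seqs[pairs[k, 1L], ]
    y <- a$seqs[pairs[k, 2L], ]
    ok <- !(x %in% c("N", "-")) & !(y %in% c("N", "-"))
    if (!any(ok))
      stop("no co-called columns for pair ", pairs[k, 1L], " / ", pairs[k, 2L])
    mean(x[ok] != y[ok])
  }, numeric(1))
}

jc69 <- function(p) {
  out <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), Inf)
  if (any(!is.finite(out)))
    warning("p-distance >= 0.75; JC69 correction is infinite for some pairs")
  out
}

#' Mitochondrial-to-chloroplast substitution-rate ratio
#'
#' Compares the rates of evolution of two organelle genomes by the ratio of
#' mean pairwise distances, computed over the sample pairs shared by both
#' alignments (so both means cover identical pairs). Distances are mismatch
#' fractions over co-called columns, optionally Jukes-Cantor corrected —
#' the correction matters once the faster genome approaches saturation,
#' since uncorrected p-distances then bias the ratio downward.
#'
#' @param cp,mt [seq_alignment()] objects for the slower (chloroplast) and
#'   faster (mitochondrial) genome; their sample sets must share at least
#'   two names.
#' @param correction `"p-distance"` (default) or `"JC69"`.
#' @return An object of class `rate_ratio_estimate`: `ratio`
#'   (`mt_mean_distance / cp_mean_distance`), the two means, `n_pairs`,
#'   `correction` and the per-pair distance table `pairs`.
#' @export
pairwise_rate_ratio <- function(cp, mt, correction = c("p-distance", "JC69")) {
  stopifnot(inherits(cp, "seq_alignment"), inherits(mt, "seq_alignment"))
  correction <- match.arg(correction)
  shared <- intersect(cp$samples, mt$samples)
  if (length(shared) < 2L)
    stop("the two alignments share fewer than 2 samples")
  pairs <- t(utils::combn(shared, 2L))
  d_cp <- pairwise_p_distances(cp, pairs)
  d_mt <- pairwise_p_distances(mt, pairs)
  if (correction == "JC69") {
    d_cp <- jc69(d_cp)
    d_mt <- jc69(d_mt)
  }
  cp_mean <- mean(d_cp)
  mt_mean <- mean(d_mt)
  ratio <- if (cp_mean == 0 && mt_mean > 0) {
    warning("chloroplast mean distance is zero; ratio reported as infinite")
    Inf
  } else if (cp_mean == 0) 1 else mt_mean / cp_mean
  structure(list(ratio = ratio, cp_mean_distance = cp_mean,
                 mt_mean_distance = mt_mean, n_pairs = nrow(pairs),
                 correction = correction,
                 pairs = data.frame(sample_i = pairs[, 1L], sample_j = pairs[, 2L],
                                    cp_dist = d_cp, mt_dist = d_mt,
                                    stringsAsFactors = FALSE)),
            class = "rate_ratio_estimate")
}

#' @export
print.rate_ratio_estimate <- function(x, ...) {
  cat(sprintf("rate_ratio_estimate: mt/cp = %.3f (%s over %d shared pairs; cp %.5f, mt %.5f)\n",
              x$ratio, x$correction, x$n_pairs, x$cp_mean_distance, x$mt_mean_distance))
  invisible(x)
}

#' Read / write alignments as multi-FASTA
#'
#' Thin wrappers over \pkg{ape}'s DNAbin FASTA IO. Sequences must be equal
#' length.
#'
#' @param path FASTA file path.
#' @return `read_alignment_fasta()` returns a [seq_alignment()];
#'   `write_alignment_fasta()` returns `path` invisibly.
#' @export
read_alignment_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(unique(lengths(dna))) > 1L)
    stop("sequences in ", path, " have unequal lengths; not an alignment")
  ch <- toupper(do.call(rbind, as.character(dna)))
  seq_alignment(ch, samples = names(dna))
}

#' @rdname read_alignment_fasta
#' @param a A [seq_alignment()].
#' @param force Overwrite an existing file? Default `FALSE`.
#' @export
write_alignment_fasta <- function(a, path, force = FALSE) {
  stopifnot(inherits(a, "seq_alignment"))
  if (file.exists(path) && !force)
    stop("refusing to overwrite existing file (use force = TRUE): ", path)
  dna <- ape::as.DNAbin(matrix(tolower(a$seqs), nrow = nrow(a$seqs),
                               dimnames = list(a$samples, NULL)))
  ape::write.FASTA(dna, path)
  invisible(path)
}
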