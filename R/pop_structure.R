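#' Pairwise identity-by-state distance matrix
#'
#' For each pair of samples and each site non-missing in both, the IBS
#' similarity is `1 - |dose_i - dose_j| / 2` with dose in `{0, 1, 2}` for
#' homozygous reference / heterozygous / homozygous alternate (the
#' allele-dosage convention used by PLINK-style IBS). The pairwise distance
#' is one minus the mean similarity over the co-nonmissing sites, so missing
#' data are handled pairwise rather than by whole-site deletion.
#'
#' @param m A [genotype_matrix()] with at least two samples.
#' @return An object of class `ibs_dist`: list with `samples`, the symmetric
#'   distance matrix `d` (zero diagonal, values in `[0, 1]`) and
#'   `n_sites_used`, the per-pair count of co-nonmissing sites.
#' @export
ibs_distance_matrix <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  n <- length(m$samples)
  if (n < 2L) stop("at least two samples are required")
  d <- matrix(0, n, n, dimnames = list(m$samples, m$samples))
  used <- matrix(ncol(m$calls), n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    xi <- m$calls[i, ]
    for (j in seq.int(i + 1L, n)) {
      xj <- m$calls[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      n_ok <- sum(ok)
      if (n_ok == 0L)
        stop("samples ", m$samples[i], " and ", m$samples[j],
             " share no co-nonmissing sites")
      dij <- 1 - mean(1 - abs(xi[ok] - xj[ok]) / 2)
      d[i, j] <- d[j, i] <- dij
      used[i, j] <- used[j, i] <- n_ok
    }
  }
  structure(list(samples = m$samples, d = d, n_sites_used = used),
            class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  cat(sprintf("ibs_dist: %d samples, mean distance %.4f (range %.4f-%.4f)\n",
              length(x$samples), mean(x$d[upper.tri(x$d)]),
              min(x$d[upper.tri(x$d)]), max(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distances, eigendecomposes, and builds
#' coordinates from the top-`k` eigenpairs. Negative eigenvalues (present
#' whenever the distances are not Euclidean-embeddable) are truncated to
#' zero for coordinate construction and reported via the eigenvalue vector;
#' no additive correction constant is applied. Coordinates are determined
#' only up to translation, rotation and reflection, so downstream
#' comparisons should use reconstructed distances, not raw coordinates.
#'
#' @param d An `ibs_dist`, a symmetric numeric matrix, or a [stats::dist]
#'   object.
#' @param k Number of dimensions, `1 <= k <= n - 1`. Default 2.
#' @return An object of class `ordination_result`: `coordinates`
#'   (`n x k`, rownames = samples), `eigenvalues` (all `n`, descending) and
#'   `goodness` (fraction of positive-eigenvalue mass captured by the first
#'   `k` axes).
#' @export
classical_mds <- function(d, k = 2L) {
  if (inherits(d, "ibs_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("'d' must be a square matrix")
  if (max(abs(d - t(d))) > 1e-12) stop("'d' must be symmetric")
  n <- nrow(d)
  if (k < 1L || k > n - 1L) stop("'k' must be between 1 and n - 1")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eg$values                      # already descending
  pos <- pmax(ev, 0)
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(k)]), nrow = k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("axis", seq_len(k))
  goodness <- if (sum(pos) > 0) sum(pos[seq_len(k)]) / sum(pos) else 1
  structure(list(coordinates = coords, eigenvalues = ev, goodness = goodness),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination_result: %d samples x %d axes, %.1f%% of positive eigenvalue mass\n",
              nrow(x$coordinates), ncol(x$coordinates), 100 * x$goodness))
  invisible(x)
}

#' Position of a hybrid relative to its parents in ordination space
#'
#' Projects the hybrid onto the segment joining its two parents. `t = 0` at
#' parent A, `t = 1` at parent B, `t = 0.5` exactly midway — the expected
#' position of an allotetraploid, whose allele dose at every parental
#' fixed-difference site is the parental mean. `off_axis` is the distance
#' from the hybrid to the A-B line, scaled by the A-B distance.
#'
#' @param o An `ordination_result`.
#' @param a,b,h Sample names of the two parents and the hybrid.
#' @return A list with `t` and `off_axis`.
#' @export
hybrid_midpoint <- function(o, a, b, h) {
  stopifnot(inherits(o, "ordination_result"))
  co <- o$coordinates
  for (s in c(a, b, h)) if (!s %in% rownames(co)) stop("unknown sample: ", s)
  A <- co[a, ]; B <- co[b, ]; H <- co[h, ]
  ab <- B - A
  len2 <- sum(ab^2)
  if (len2 == 0) stop("parents ", a, " and ", b, " coincide in ordination space")
  t <- sum((H - A) * ab) / len2
  perp <- (H - A) - t * ab
  list(t = t, off_axis = sqrt(sum(perp^2) / len2))
}
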