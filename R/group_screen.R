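#' Screen for variants specific to a phenotype-defined group
#'
#' A locus is a candidate when (1) all non-missing case samples share one
#' genotype class, (2) that class is observed in zero non-missing control
#' samples, and (3) the number of missing calls in each group is within its
#' tolerance. A locus at which every case is missing is never a candidate.
#' This is the automatable core of a case/control presence-absence screen
#' (e.g. variants specific to abnormal-budding cultures or to a green
#' mutant); any subsequent manual review is replaced here by the exported
#' per-locus evidence columns.
#'
#' @param m A [genotype_matrix()].
#' @param cases,controls Disjoint, non-empty character vectors of sample
#'   names present in `m`.
#' @param max_missing_cases,max_missing_controls Maximum tolerated count of
#'   missing calls per locus in each group (defaults 0). Candidate sets are
#'   monotone non-decreasing in these tolerances.
#' @return An object of class `screen_result`: `candidates` (data frame with
#'   `chrom`, `pos`, `case_class`, `n_case_nonmissing`,
#'   `n_control_nonmissing`), `n_case`, `n_control` and the tolerances used.
#' @export
group_specific_variants <- function(m, cases, controls,
                                    max_missing_cases = 0L,
                                    max_missing_controls = 0L) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (length(cases) == 0L || length(controls) == 0L)
    stop("'cases' and 'controls' must both be non-empty")
  if (length(intersect(cases, controls)))
    stop("'cases' and 'controls' overlap: ",
         paste(intersect(cases, controls), collapse = ", "))
  ic <- sample_index(m, cases, "case sample")
  it <- sample_index(m, controls, "control sample")

  cc <- m$calls[ic, , drop = FALSE]
  ct <- m$calls[it, , drop = FALSE]
  miss_c <- colSums(is.na(cc))
  miss_t <- colSums(is.na(ct))
  lo <- suppressWarnings(apply(cc, 2, min, na.rm = TRUE))  # Inf when all NA
  hi <- suppressWarnings(apply(cc, 2, max, na.rm = TRUE))
  shared <- is.finite(lo) & lo == hi                        # >=1 non-missing case, one class
  ok_miss <- miss_c <= max_missing_cases & miss_t <= max_missing_controls
  cand <- which(shared & ok_miss)
  # the shared case class must be absent from all non-missing controls
  if (length(cand)) {
    absent <- vapply(cand, function(j) {
      !any(ct[, j] == lo[j], na.rm = TRUE)
    }, logical(1))
    cand <- cand[absent]
  }
  candidates <- data.frame(
    chrom = m$sites$chrom[cand], pos = m$sites$pos[cand],
    case_class = gt_label(as.integer(lo[cand])),
    n_case_nonmissing = length(ic) - miss_c[cand],
    n_control_nonmissing = length(it) - miss_t[cand],
    stringsAsFactors = FALSE)
  rownames(candidates) <- NULL
  structure(list(candidates = candidates,
                 n_case = length(ic), n_control = length(it),
                 parameters = list(max_missing_cases = max_missing_cases,
                                   max_missing_controls = max_missing_controls)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d candidate loci (%d cases vs %d controls; tolerances %d/%d missing)\n",
              nrow(x$candidates), x$n_case, x$n_control,
              x$parameters$max_missing_cases, x$parameters$max_missing_controls))
  if (nrow(x$candidates)) print(utils::head(x$candidates, 10))
  invisible(x)
}
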