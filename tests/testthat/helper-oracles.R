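# Fixture builders and independent brute-force oracles used across tests.

# small genotype matrix with random classes (incl. missing)
random_gm <- function(seed, n_samples = 4L, n_sites = 30L, p_missing = 0.15) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
                  nrow = n_samples)
  calls[matrix(runif(n_samples * n_sites) < p_missing, nrow = n_samples)] <- NA
  ra <- t(replicate(n_sites, sample(c("A", "C", "G", "T"), 2L)))
  genotype_matrix(samples = sprintf("s%02d", seq_len(n_samples)),
                  sites = data.frame(chrom = "chr1",
                                     pos = sort(sample.int(10 * n_sites, n_sites)),
                                     ref = ra[, 1], alt = ra[, 2]),
                  calls = calls)
}

# genotype matrix from a dose matrix with fabricated site annotation
gm_from_doses <- function(calls, samples = NULL) {
  n_sites <- ncol(calls)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(calls)))
  genotype_matrix(samples = samples,
                  sites = data.frame(chrom = "chr1", pos = seq_len(n_sites) * 10L,
                                     ref = "A", alt = "G"),
                  calls = calls)
}

# brute-force per-site trio classification, written over character classes
# (independent of the dose-coded implementation path)
oracle_classify_trio <- function(m, a, b, h) {
  lab <- function(x) ifelse(is.na(x), "MISSING", c("HOM_REF", "HET", "HOM_ALT")[x + 1])
  counts <- c(n_informative = 0L, n_two_ref = 0L, n_het = 0L,
              n_two_alt = 0L, n_unclassified = 0L)
  for (j in seq_len(ncol(m$calls))) {
    ca <- lab(m$calls[a, j]); cb <- lab(m$calls[b, j]); ch <- lab(m$calls[h, j])
    if (ca == "HOM_REF" && cb == "HOM_ALT") {
      counts["n_informative"] <- counts["n_informative"] + 1L
      key <- switch(ch, HOM_REF = "n_two_ref", HET = "n_het",
                    HOM_ALT = "n_two_alt", MISSING = "n_unclassified")
      counts[key] <- counts[key] + 1L
    }
  }
  counts
}

# brute-force group-specificity predicate, evaluated site by site
oracle_screen <- function(m, cases, controls, max_miss_ca = 0L, max_miss_co = 0L) {
  hits <- integer()
  for (j in seq_len(ncol(m$calls))) {
    xc <- m$calls[cases, j]
    xt <- m$calls[controls, j]
    n_miss_c <- sum(is.na(xc)); n_miss_t <- sum(is.na(xt))
    obs_c <- unique(xc[!is.na(xc)])
    if (length(obs_c) != 1L) next                  # all-missing or mixed cases
    if (n_miss_c > max_miss_ca || n_miss_t > max_miss_co) next
    if (any(xt[!is.na(xt)] == obs_c)) next
    hits <- c(hits, j)
  }
  hits
}

# brute-force parsimony-informative column count
oracle_pis <- function(seq_mat) {
  n <- 0L
  for (j in seq_len(ncol(seq_mat))) {
    col <- seq_mat[, j]
    col <- col[!col %in% c("N", "-")]
    states <- unique(col)
    n_deep <- sum(vapply(states, function(s) sum(col == s) >= 2L, logical(1)))
    if (n_deep >= 2L) n <- n + 1L
  }
  n
}

# write a toy VCF in code; rows are raw record strings
write_toy_vcf <- function(path, samples, records, format = "GT:GQ") {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=100000>",
           "##contig=<ID=chr2,length=100000>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, ..., format = "GT:GQ") {
  paste(c(chrom, pos, ".", ref, alt, ".", ".", ".", format, ...), collapse = "\t")
}
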