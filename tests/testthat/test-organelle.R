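test_that("variable-site export follows the per-call emission rule", {
  # sites: (HOM_REF/HOM_ALT), (HOM_REF/HOM_REF), (HET/HOM_ALT), ref/alt A/G
  m <- gm_from_doses(rbind(s1 = c(0L, 0L, 1L), s2 = c(2L, 0L, 2L)),
                     samples = c("s1", "s2"))
  a <- variable_site_alignment(m)
  expect_equal(ncol(a$seqs), 2L)                     # monomorphic site 2 dropped
  expect_equal(paste(a$seqs["s1", ], collapse = ""), "AN")
  expect_equal(paste(a$seqs["s2", ], collapse = ""), "GG")
  expect_equal(a$source_coords$pos, c(10L, 30L))

  mono <- gm_from_doses(matrix(0L, 2, 4))
  expect_warning(a0 <- variable_site_alignment(mono), "no variable sites")
  expect_equal(ncol(a0$seqs), 0L)
})

test_that("alignment width equals the post-mask variable-site count", {
  for (s in 1:10) {
    m <- random_gm(3000 + s, n_samples = 5L, n_sites = 40L)
    mask <- region_mask(data.frame(chrom = "chr1", start = 1L, end = 100L))
    mm <- apply_region_mask(m, mask, "exclude")
    n_var <- sum(apply(mm$calls, 2,
                       function(x) length(unique(x[!is.na(x)])) >= 2))
    a <- suppressWarnings(variable_site_alignment(m, mask = mask))
    expect_equal(ncol(a$seqs), n_var)
  }
})

test_that("parsimony-informative counting matches hand counts and the oracle", {
  a <- seq_alignment(c(q1 = "AAC", q2 = "AAT", q3 = "GGC", q4 = "GGT"))
  expect_equal(parsimony_informative_count(a), 3L)

  # singleton state is not informative; identical sequences give zero
  b <- seq_alignment(c(x = "A", y = "A", z = "G"))
  expect_equal(parsimony_informative_count(b), 0L)
  expect_equal(parsimony_informative_count(seq_alignment(c(x = "ACGT", y = "ACGT"))), 0L)

  # N and gaps are ignored as states
  d <- seq_alignment(c(w = "AN-A", x = "AN-A", y = "GNNG", z = "GNNG"))
  expect_equal(parsimony_informative_count(d), 2L)

  set.seed(500)
  for (rep in 1:20) {
    n_seq <- sample(4:10, 1); n_col <- sample(10:50, 1)
    mat <- matrix(sample(c("A", "C", "G", "T", "N", "-"), n_seq * n_col,
                         replace = TRUE, prob = c(rep(0.2, 4), 0.1, 0.1)),
                  nrow = n_seq, dimnames = list(sprintf("t%d", 1:n_seq), NULL))
    expect_equal(parsimony_informative_count(seq_alignment(mat)), oracle_pis(mat))
  }
})

test_that("pairwise distances match ape::dist.dna with pairwise deletion", {
  set.seed(77)
  mat <- matrix(sample(c("A", "C", "G", "T", "N"), 6 * 200, replace = TRUE,
                       prob = c(rep(0.23, 4), 0.08)),
                nrow = 6, dimnames = list(sprintf("t%d", 1:6), NULL))
  a <- seq_alignment(mat)
  pairs <- t(combn(a$samples, 2))
  mine <- allotrio:::pairwise_p_distances(a, pairs)
  dna <- ape::as.DNAbin(matrix(tolower(mat), nrow = 6,
                               dimnames = list(rownames(mat), NULL)))
  ref <- as.matrix(ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE))
  expect_equal(mine, ref[pairs], tolerance = 1e-12)
})

test_that("rate ratio arithmetic on constructed alignments", {
  base <- strrep("A", 100)
  flip <- function(k) paste0(strrep("C", k), strrep("A", 100 - k))
  cp <- seq_alignment(c(p = base, q = flip(1)))    # p-distance 0.01
  mt <- seq_alignment(c(p = base, q = flip(10)))   # p-distance 0.10
  rr <- pairwise_rate_ratio(cp, mt)
  expect_equal(rr$ratio, 10)
  expect_equal(rr$cp_mean_distance, 0.01)
  expect_equal(rr$n_pairs, 1L)

  # identical alignments -> ratio 1
  expect_equal(pairwise_rate_ratio(cp, cp)$ratio, 1)

  # zero chloroplast divergence with mitochondrial divergence -> infinite
  cp0 <- seq_alignment(c(p = base, q = base))
  expect_warning(rr0 <- pairwise_rate_ratio(cp0, mt), "infinite")
  expect_equal(rr0$ratio, Inf)

  # fewer than two shared samples
  other <- seq_alignment(c(r = base, s = base))
  expect_error(pairwise_rate_ratio(cp, other), "fewer than 2")
})

test_that("JC69 correction is at least the p-distance and restores rate ratios", {
  p <- seq(0.01, 0.7, by = 0.05)
  expect_true(all(allotrio:::jc69(p) >= p))

  org <- simulate_organelles(sprintf("s%d", 1:8), organelle_length = 20000L,
                             cp_rate = 0.01, mt_cp_ratio = 10, seed = 11)
  jc <- pairwise_rate_ratio(org$cp, org$mt, correction = "JC69")$ratio
  pd <- pairwise_rate_ratio(org$cp, org$mt, correction = "p-distance")$ratio
  expect_lt(pd, jc)    # saturation biases the uncorrected ratio downward
})

test_that("rate-ratio estimation is invariant to a common rate rescaling", {
  r1 <- sapply(1:5, function(s) {
    org <- simulate_organelles(sprintf("s%d", 1:8), 10000L, cp_rate = 0.005,
                               mt_cp_ratio = 8, seed = s)
    pairwise_rate_ratio(org$cp, org$mt, "JC69")$ratio
  })
  r2 <- sapply(1:5, function(s) {
    org <- simulate_organelles(sprintf("s%d", 1:8), 10000L, cp_rate = 0.015,
                               mt_cp_ratio = 8, seed = s)
    pairwise_rate_ratio(org$cp, org$mt, "JC69")$ratio
  })
  expect_lt(abs(mean(r1) - mean(r2)), 0.15 * 8)
})

test_that("FASTA IO round-trips alignments", {
  a <- seq_alignment(c(s1 = "ACGTN-", s2 = "ACGAAC"))
  path <- tempfile(fileext = ".fasta")
  write_alignment_fasta(a, path)
  expect_error(write_alignment_fasta(a, path), "refusing to overwrite")
  back <- read_alignment_fasta(path)
  expect_equal(back$seqs, a$seqs)
  expect_equal(back$samples, a$samples)
})
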