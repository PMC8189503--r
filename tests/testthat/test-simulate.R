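test_that("identical config and seed reproduce identical output", {
  cfg <- sim_config(seed = 42, n_chrom = 1L, chrom_length = 20000L)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)

  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  observe_vcf(t1, noise_model(), seed = 5, path = p1)
  observe_vcf(t2, noise_model(), seed = 5, path = p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("non-hybrid truth genotypes are homozygous everywhere; hybrid follows its sources", {
  tr <- simulate_truth(sim_config(seed = 2))
  hc <- tr$hybrid_composition
  non_hybrid <- setdiff(rownames(tr$genotypes), hc$hybrid)
  expect_false(any(tr$genotypes[non_hybrid, ] == 1L))

  hapA <- tr$haplotypes[hc$parent_a, ]
  hapB <- tr$haplotypes[hc$parent_b, ]
  in_mask <- rep(FALSE, nrow(tr$sites))
  iv <- tr$rrna_mask$intervals
  for (k in seq_len(nrow(iv)))
    in_mask <- in_mask | (tr$sites$chrom == iv$chrom[k] &
                            tr$sites$pos >= iv$start[k] & tr$sites$pos <= iv$end[k])
  expected <- hapA + hapB
  expected[in_mask] <- 2L * hapB[in_mask]
  expect_equal(unname(tr$genotypes[hc$hybrid, ]), unname(expected))
})

test_that("zero species divergence leaves no parental fixed differences", {
  tr <- simulate_truth(sim_config(seed = 8, species_divergence = 0))
  m <- truth_genotype_matrix(tr)
  hc <- tr$hybrid_composition
  expect_length(informative_trio_sites(m, hc$parent_a, hc$parent_b), 0L)
})

test_that("sister-species divergence site count matches the binomial expectation", {
  counts <- vapply(1:20, function(s) {
    tr <- simulate_truth(sim_config(seed = s, n_chrom = 1L, chrom_length = 100000L,
                                    species_divergence = 0.01))
    sum(tr$haplotypes["T01", ] == 1L)
  }, numeric(1))
  expected <- 100000 * 0.01
  se_mean <- sqrt(100000 * 0.01 * 0.99 / 20)
  expect_lt(abs(mean(counts) - expected), 3 * se_mean)
})

test_that("planted mutations beyond the monomorphic pool are rejected", {
  cfg <- sim_config(seed = 1, n_chrom = 1L, chrom_length = 200L,
                    shared_mutations_per_subgroup = 500L)
  expect_error(simulate_truth(cfg), "exceed available monomorphic sites")
})

test_that("zero-noise observation reproduces the truth exactly", {
  tr <- simulate_truth(sim_config(seed = 3, n_chrom = 1L, chrom_length = 20000L))
  path <- tempfile(fileext = ".vcf")
  observe_vcf(tr, noise_model(error_rate = 0, missing_rate = 0), seed = 1,
              path = path)
  m <- read_multisample_vcf(path, metadata = tr$sample_table)
  expect_equal(m$calls, truth_genotype_matrix(tr)$calls)
  expect_equal(m$sites, tr$sites)
})

test_that("missingness draws match their configured rate", {
  tr <- simulate_truth(sim_config(seed = 4, n_chrom = 1L, chrom_length = 20000L))
  path <- tempfile(fileext = ".vcf")
  observe_vcf(tr, noise_model(error_rate = 0, missing_rate = 0.5), seed = 2,
              path = path)
  m <- read_multisample_vcf(path)
  frac <- mean(is.na(m$calls))
  expect_gt(length(m$calls), 1000L)
  expect_true(frac > 0.45 && frac < 0.55)
})

test_that("hybrid organelles are identical to the donor parent's", {
  tr <- simulate_truth(sim_config(seed = 6))
  hc <- tr$hybrid_composition
  expect_identical(tr$organelle_truth$cp$seqs[hc$hybrid, ],
                   tr$organelle_truth$cp$seqs[hc$organelle_donor, ])
  expect_identical(tr$organelle_truth$mt$seqs[hc$hybrid, ],
                   tr$organelle_truth$mt$seqs[hc$organelle_donor, ])
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(mt_cp_ratio = 0), "mt_cp_ratio")
  expect_error(sim_config(error_rate = 1.2), "error_rate")
  expect_error(sim_config(rrna_mask = data.frame(chrom = "chr9", start = 1, end = 10)),
               "chromosomes")
  expect_error(sim_config(rrna_mask = data.frame(chrom = "chr1", start = 1,
                                                 end = 1e6)),
               "within")
})
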