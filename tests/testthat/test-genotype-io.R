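test_that("VCF reading maps genotype strings and drops multiallelic/non-SNV records", {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(path, c("s1", "s2"), c(
    vcf_rec("chr1", 100, "A", "G", "0/0:50", "0/1:44"),
    vcf_rec("chr1", 200, "C", "T", "1|0:31", "1/1:60"),
    vcf_rec("chr1", 250, "G", "A,T", "0/1:40", "0/0:40"),   # multiallelic -> dropped
    vcf_rec("chr1", 300, "G", "GA", "0/0:40", "0/0:40"),    # indel -> dropped
    vcf_rec("chr2", 10, "T", "C", "./.:.", "./1:12")))      # missing + half-call
  m <- read_multisample_vcf(path)
  expect_equal(m$samples, c("s1", "s2"))
  expect_equal(nrow(m$sites), 3L)
  expect_equal(m$sites$pos, c(100L, 200L, 10L))
  expect_equal(unname(m$calls["s1", ]), c(0L, 1L, NA))      # phased 1|0 -> HET
  expect_equal(unname(m$calls["s2", ]), c(1L, 2L, NA))      # half-call -> MISSING
  expect_equal(unname(m$gq["s2", 1:2]), c(44L, 60L))
  expect_equal(attr(m, "read_report")$n_sites_dropped_multiallelic, 1L)
  expect_equal(attr(m, "read_report")$n_sites_dropped_nonsnv, 1L)

  md <- data.frame(sample = "s1", homozygous_expected = TRUE)
  expect_error(read_multisample_vcf(path, metadata = md), "s2")
})

test_that("GQ filter precedes the missingness filter and counts reconcile", {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(path, c("s1", "s2"), c(
    vcf_rec("chr1", 100, "A", "G", "0/0:19", "1/1:50"),  # one low-GQ call
    vcf_rec("chr1", 200, "C", "T", "0/1:30", "0/0:35")))
  m <- read_multisample_vcf(path)

  res <- filter_genotypes(m, min_gq = 20L, max_missing = 0.1)
  # GQ 19 call set missing -> site missingness 0.5 > 0.1 -> site dropped
  expect_equal(res$report$n_calls_masked_gq, 1L)
  expect_equal(res$report$n_sites_dropped_missingness, 1L)
  expect_equal(res$report$n_output_sites, 1L)
  expect_equal(res$matrix$sites$pos, 200L)
  expect_equal(res$report$n_input_sites - res$report$n_sites_dropped_missingness,
               res$report$n_output_sites)

  # no-op case: thresholds that nothing violates
  res2 <- filter_genotypes(m, min_gq = 0L, max_missing = 1)
  expect_equal(res2$matrix$calls, m$calls)
  expect_equal(res2$report$n_sites_dropped_missingness, 0L)
  expect_equal(res2$report$n_calls_masked_gq, 0L)

  # max_missing = 1 never drops a site, whatever the missingness
  m3 <- gm_from_doses(matrix(NA_integer_, 2, 3))
  expect_equal(nrow(filter_genotypes(m3, min_gq = 0L, max_missing = 1)$matrix$sites), 3L)

  # absent GQ demands an explicit opt-out
  expect_error(filter_genotypes(m3, min_gq = 20L), "min_gq = 0")
})

test_that("heterozygous-site removal applies only to the designated samples", {
  calls <- rbind(c(0L, 1L, 0L, 2L),
                 c(0L, 0L, 0L, 2L),
                 c(0L, 0L, 1L, 1L))   # s3 is the non-designated (hybrid-like) row
  m <- gm_from_doses(calls)
  res <- drop_heterozygous_sites(m, c("s01", "s02"))
  # site 2 dropped (s01 HET); sites 3 and 4 retained (only s03 is HET there)
  expect_equal(res$matrix$sites$pos, c(10L, 30L, 40L))
  expect_equal(res$report$n_sites_dropped_het, 1L)

  res_noop <- drop_heterozygous_sites(res$matrix, c("s01", "s02"))
  expect_equal(res_noop$matrix$calls, res$matrix$calls)
  expect_warning(drop_heterozygous_sites(m, character()), "empty")
  expect_error(drop_heterozygous_sites(m, "nope"), "nope")
})

test_that("filters commute with sample reordering and preserve site order", {
  m <- random_gm(11, n_samples = 5L, n_sites = 40L)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  mp <- genotype_matrix(m$samples[perm], m$sites, m$calls[perm, ],
                        gq = NULL)
  a <- drop_heterozygous_sites(m, c("s01", "s02"))$matrix
  b <- drop_heterozygous_sites(mp, c("s01", "s02"))$matrix
  expect_equal(a$sites, b$sites)
  expect_equal(a$calls["s04", ], b$calls["s04", ])
  expect_true(!is.unsorted(a$sites$pos))
})

test_that("VCF writing round-trips a genotype matrix", {
  m <- random_gm(5, n_samples = 3L, n_sites = 12L)
  path <- tempfile(fileext = ".vcf")
  write_genotype_vcf(m, path)
  expect_error(write_genotype_vcf(m, path), "refusing to overwrite")
  back <- read_multisample_vcf(path)
  expect_equal(back$calls, m$calls)
  expect_equal(back$sites, m$sites)
})
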