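# doses: 0 = HOM_REF, 1 = HET, 2 = HOM_ALT, NA = MISSING

test_that("informative sites are exactly the (A hom-ref, B hom-alt) loci", {
  m <- gm_from_doses(rbind(A = c(0L, 0L, 0L, 2L, 0L),
                           B = c(2L, 2L, 0L, 2L, 2L)),
                     samples = c("A", "B"))
  expect_equal(informative_trio_sites(m, "A", "B"), c(1L, 2L, 5L))

  # parents identical everywhere -> no fixed differences
  m2 <- gm_from_doses(rbind(A = c(0L, 2L, 1L), B = c(0L, 2L, 1L)),
                      samples = c("A", "B"))
  expect_length(informative_trio_sites(m2, "A", "B"), 0L)

  # a missing parent call is never informative
  m3 <- gm_from_doses(rbind(A = c(NA, 0L), B = c(2L, 2L)), samples = c("A", "B"))
  expect_equal(informative_trio_sites(m3, "A", "B"), 2L)

  expect_error(informative_trio_sites(m3, "A", "nope"), "nope")
})

test_that("trio classification tabulates the hybrid classes (5-site toy)", {
  m <- gm_from_doses(rbind(A = c(0L, 0L, 0L, 2L, 0L),
                           B = c(2L, 2L, 0L, 2L, 2L),
                           H = c(1L, 2L, 1L, 1L, NA)),
                     samples = c("A", "B", "H"))
  cc <- classify_trio(m, "A", "B", "H")
  expect_equal(cc$n_informative, 3L)
  expect_equal(cc$n_two_ref, 0L)
  expect_equal(cc$n_het, 1L)
  expect_equal(cc$n_two_alt, 1L)
  expect_equal(cc$n_unclassified, 1L)
  expect_equal(cc$loci$het$pos, 10L)
  expect_equal(cc$loci$unclassified$pos, 50L)

  expect_error(classify_trio(m, "A", "B", "A"), "differ")
})

test_that("a hybrid identical to parent A lands entirely in the two-ref class", {
  m <- gm_from_doses(rbind(A = rep(0L, 6), B = rep(2L, 6), H = rep(0L, 6)),
                     samples = c("A", "B", "H"))
  cc <- classify_trio(m, "A", "B", "H")
  expect_equal(cc$n_two_ref, cc$n_informative)
  expect_equal(cc$n_het + cc$n_two_alt + cc$n_unclassified, 0L)
})

test_that("class counts partition the informative loci (random matrices)", {
  for (s in 1:25) {
    m <- random_gm(s, n_samples = 3L, n_sites = 40L)
    cc <- classify_trio(m, "s01", "s02", "s03")
    expect_equal(cc$n_two_ref + cc$n_het + cc$n_two_alt + cc$n_unclassified,
                 cc$n_informative)
  }
})

test_that("classifier agrees with the brute-force per-site oracle", {
  for (s in 1:200) {
    m <- random_gm(s, n_samples = 3L, n_sites = 25L, p_missing = 0.2)
    cc <- classify_trio(m, "s01", "s02", "s03")
    oc <- oracle_classify_trio(m, "s01", "s02", "s03")
    expect_identical(unlist(cc[names(oc)]), oc)
  }
})

test_that("verdict uses classified loci only, with >= threshold semantics", {
  # published-scale contingency: 18,484 / 139,259 / 141
  v <- allotetraploid_verdict(trio_class_counts(18484L, 139259L, 141L))
  expect_equal(v$het_fraction, 139259 / (18484 + 139259 + 141))
  expect_lt(abs(v$het_fraction - 0.882), 0.001)
  expect_true(v$is_allotetraploid)

  # unclassified loci are excluded from the denominator
  v2 <- allotetraploid_verdict(trio_class_counts(10L, 90L, 0L, n_unclassified = 900L))
  expect_equal(v2$het_fraction, 0.9)

  # fraction exactly at the threshold -> allotetraploid (>= semantics)
  v3 <- allotetraploid_verdict(trio_class_counts(20L, 80L, 0L), threshold = 0.8)
  expect_true(v3$is_allotetraploid)

  # no heterozygous loci -> firmly not allotetraploid
  v4 <- allotetraploid_verdict(trio_class_counts(500L, 0L, 0L))
  expect_equal(v4$het_fraction, 0)
  expect_false(v4$is_allotetraploid)

  # too few classified loci -> NA verdict, not a guess
  v5 <- allotetraploid_verdict(trio_class_counts(2L, 8L, 0L), min_classified = 100L)
  expect_true(is.na(v5$is_allotetraploid))
})

test_that("parent-role swap classifies the mirrored condition symmetrically", {
  tr <- simulate_truth(sim_config(seed = 12))
  m <- truth_genotype_matrix(tr)
  hc <- tr$hybrid_composition
  fwd <- classify_trio(m, hc$parent_a, hc$parent_b, hc$hybrid, mask = tr$rrna_mask)
  rev <- classify_trio(m, hc$parent_b, hc$parent_a, hc$hybrid, mask = tr$rrna_mask)
  hf <- function(cc) cc$n_het / (cc$n_two_ref + cc$n_het + cc$n_two_alt)
  # noiseless allotetraploid: both orientations fully heterozygous
  expect_equal(hf(fwd), 1)
  expect_equal(hf(rev), 1)
  expect_gt(rev$n_informative, 0L)
})
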