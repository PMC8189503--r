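#' Simulation configuration
#'
#' Bundles and validates every knob of the ground-truth simulator. The
#' defaults emulate the study design the package targets: several clusters
#' of doubled-haploid (homozygous diploid) cultures of a focal species, a
#' diverged sister species, an allotetraploid F1 between the two observed as
#' a heterozygous diploid, an aquaculture strain split into subgroups that
#' accumulated shared and private mutations, a nuclear rRNA region
#' homogenised to the second parent in the hybrid, and uniparentally
#' inherited organelles whose mitochondrial genome evolves about ten times
#' faster than the chloroplast genome.
#'
#' @param seed Integer master seed; stage-specific streams are derived from
#'   it by fixed offsets so stages are independently reproducible.
#' @param n_chrom,chrom_length Number of chromosomes and length of each (bp).
#' @param n_clusters Number of population clusters of the focal species.
#' @param fst Cluster differentiation in `[0, 1)` (Balding-Nichols).
#' @param n_samples_per_cluster Doubled-haploid samples per cluster.
#' @param n_admixed Admixed samples drawing per-site ancestry from the first
#'   two clusters.
#' @param species_divergence Per-site substitution probability separating
#'   the sister species from the reference.
#' @param strain_subgroups Number of subgroups the first cluster (the
#'   "strain") is split into.
#' @param shared_mutations_per_subgroup Allele flips shared exclusively by
#'   all members of a subgroup.
#' @param private_mutations_per_sample Additional private flips per strain
#'   member.
#' @param rrna_mask Data frame `chrom`, `start`, `end` (1-based inclusive)
#'   of nuclear rRNA-like intervals, inside which the hybrid genome is
#'   homogenised to the second parent; `NULL` (default) places one interval
#'   spanning the 80-90% stretch of chromosome 1.
#' @param organelle_length Length (bp) of each organelle alignment.
#' @param cp_rate Expected root-to-tip substitutions/site of the chloroplast
#'   genome along the sample genealogy.
#' @param mt_cp_ratio Mitochondrial-to-chloroplast rate ratio (> 0);
#'   default 10.
#' @param error_rate,missing_rate Default per-call probabilities used by the
#'   default [noise_model()].
#' @param min_polymorphic_fraction Fraction of genomic sites seeded as
#'   within-species polymorphisms.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_length = 50000L,
                       n_clusters = 3L, fst = 0.2,
                       n_samples_per_cluster = 5L, n_admixed = 2L,
                       species_divergence = 0.01,
                       strain_subgroups = 2L,
                       shared_mutations_per_subgroup = 20L,
                       private_mutations_per_sample = 5L,
                       rrna_mask = NULL,
                       organelle_length = 10000L,
                       cp_rate = 0.01, mt_cp_ratio = 10,
                       error_rate = 0.002, missing_rate = 0.02,
                       min_polymorphic_fraction = 0.01) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              n_clusters = as.integer(n_clusters), fst = fst,
              n_samples_per_cluster = as.integer(n_samples_per_cluster),
              n_admixed = as.integer(n_admixed),
              species_divergence = species_divergence,
              strain_subgroups = as.integer(strain_subgroups),
              shared_mutations_per_subgroup = as.integer(shared_mutations_per_subgroup),
              private_mutations_per_sample = as.integer(private_mutations_per_sample),
              rrna_mask = rrna_mask,
              organelle_length = as.integer(organelle_length),
              cp_rate = cp_rate, mt_cp_ratio = mt_cp_ratio,
              error_rate = error_rate, missing_rate = missing_rate,
              min_polymorphic_fraction = min_polymorphic_fraction)
  if (is.null(cfg$rrna_mask)) {
    cfg$rrna_mask <- data.frame(chrom = "chr1",
                                start = floor(0.8 * cfg$chrom_length) + 1L,
                                end = floor(0.9 * cfg$chrom_length),
                                stringsAsFactors = FALSE)
  }
  if (cfg$fst < 0 || cfg$fst >= 1) stop("'fst' must be in [0, 1)")
  if (cfg$species_divergence < 0 || cfg$species_divergence >= 1)
    stop("'species_divergence' must be in [0, 1)")
  for (p in c("error_rate", "missing_rate", "min_polymorphic_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("'", p, "' must be a probability in [0, 1]")
  if (cfg$mt_cp_ratio <= 0) stop("'mt_cp_ratio' must be positive")
  if (cfg$n_chrom < 1L || cfg$chrom_length < 1L) stop("genome dimensions must be positive")
  if (cfg$n_clusters < 1L || cfg$n_samples_per_cluster < 1L)
    stop("at least one cluster with one sample is required")
  if (cfg$strain_subgroups < 1L) stop("'strain_subgroups' must be >= 1")
  msk <- cfg$rrna_mask
  if (!all(c("chrom", "start", "end") %in% names(msk)))
    stop("'rrna_mask' must have columns chrom, start, end")
  if (!all(msk$chrom %in% paste0("chr", seq_len(cfg$n_chrom))))
    stop("'rrna_mask' chromosomes must be chr1..chr", cfg$n_chrom)
  if (any(msk$start < 1L) || any(msk$end > cfg$chrom_length) || any(msk$start > msk$end))
    stop("'rrna_mask' intervals must lie within [1, chrom_length]")
  structure(cfg, class = "sim_config")
}

#' Per-call observation noise model
#'
#' With probability `missing_rate` a call becomes missing; otherwise, with
#' probability `error_rate`, it is replaced by a uniformly chosen different
#' genotype class (so an error on a homozygous truth call lands on the
#' heterozygous class with probability 1/2). GQ is drawn uniformly from
#' `gq_correct` for faithful calls and from `gq_error` for erroneous ones,
#' which makes a `GQ < 20` filter preferentially remove errors.
#'
#' @param error_rate,missing_rate Per-call probabilities in `[0, 1]`.
#' @param gq_correct,gq_error Inclusive integer GQ ranges (within 0-99) for
#'   correct and erroneous calls.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(error_rate = 0.002, missing_rate = 0.02,
                        gq_correct = c(30L, 99L), gq_error = c(2L, 40L)) {
  if (error_rate < 0 || error_rate > 1 || missing_rate < 0 || missing_rate > 1)
    stop("rates must be probabilities in [0, 1]")
  for (r in list(gq_correct, gq_error))
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > 99)
      stop("GQ ranges must be length-2, increasing, within [0, 99]")
  structure(list(error_rate = error_rate, missing_rate = missing_rate,
                 gq_correct = as.integer(gq_correct), gq_error = as.integer(gq_error)),
            class = "noise_model")
}

lin_to_site <- function(idx, chrom_length) {
  chrom <- (idx - 1L) %/% chrom_length + 1L
  pos <- (idx - 1L) %% chrom_length + 1L
  data.frame(chrom = paste0("chr", chrom), pos = pos, stringsAsFactors = FALSE)
}

#' Simulate a ground-truth dataset
#'
#' Generates reference sequences, per-sample haploid allele vectors, truth
#' diploid genotypes, sample metadata and organelle alignments under the
#' design described in [sim_config()]:
#'
#' * within-species polymorphism is drawn per cluster from a
#'   Balding-Nichols model (`ancestral frequency ~ U(0.1, 0.9)`, cluster
#'   frequency `~ Beta(p(1-F)/F, (1-p)(1-F)/F)`);
#' * the sister species differs from the reference by independent per-site
#'   substitutions with probability `species_divergence`;
#' * the first cluster is the "strain": its samples are partitioned into
#'   `strain_subgroups` subgroups, each sharing exclusive planted allele
#'   flips at previously monomorphic sites, each member carrying further
#'   private flips;
#' * the hybrid's two source haplotypes are the first strain sample
#'   (parent A) and the sister-species sample (parent B); its truth
#'   genotype is the unordered pair of the two source alleles, except
#'   inside the rRNA mask where it is the doubled parent-B allele
#'   (rRNA homogenisation);
#' * organelles are uniparentally inherited from parent B and evolve along
#'   a shared seeded Yule genealogy at rates `cp_rate` and
#'   `cp_rate * mt_cp_ratio`.
#'
#' All non-hybrid truth genotypes are homozygous at every site (doubled
#' haploids). The same configuration and seed always reproduce identical
#' output.
#'
#' @param config A [sim_config()].
#' @return An object of class `truth_dataset`; see the fields
#'   `reference`, `haplotypes`, `sites`, `genotypes`, `sample_table`,
#'   `hybrid_composition`, `planted_group_loci`, `organelle_truth`,
#'   `rrna_mask`, `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  L <- cfg$n_chrom * cfg$chrom_length

  # --- stage 1: reference + within-species polymorphism -------------------
  set.seed(cfg$seed + 1L)
  reference <- vapply(seq_len(cfg$n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
          collapse = ""), character(1))
  names(reference) <- paste0("chr", seq_len(cfg$n_chrom))

  n_focal <- cfg$n_clusters * cfg$n_samples_per_cluster
  focal_names <- sprintf("Y%02d", seq_len(n_focal))
  admixed_names <- if (cfg$n_admixed > 0) sprintf("X%02d", seq_len(cfg$n_admixed)) else character()
  sister_name <- "T01"
  hybrid_name <- "H01"
  hap_names <- c(focal_names, admixed_names, sister_name)
  cluster_of <- rep(seq_len(cfg$n_clusters), each = cfg$n_samples_per_cluster)

  n_poly <- max(1L, round(cfg$min_polymorphic_fraction * L))
  poly_idx <- sort(sample.int(L, n_poly))
  p_anc <- runif(n_poly, 0.1, 0.9)
  freq <- matrix(NA_real_, n_poly, cfg$n_clusters)
  for (cl in seq_len(cfg$n_clusters)) {
    freq[, cl] <- if (cfg$fst > 0) {
      rbeta(n_poly, p_anc * (1 - cfg$fst) / cfg$fst,
            (1 - p_anc) * (1 - cfg$fst) / cfg$fst)
    } else p_anc
  }
  hap_poly <- matrix(0L, length(hap_names), n_poly,
                     dimnames = list(hap_names, NULL))
  for (s in seq_len(n_focal))
    hap_poly[s, ] <- rbinom(n_poly, 1L, freq[, cluster_of[s]])
  if (cfg$n_admixed > 0) {
    cl2 <- min(2L, cfg$n_clusters)
    for (s in seq_len(cfg$n_admixed)) {
      src <- ifelse(rbinom(n_poly, 1L, 0.5) == 1L, 1L, cl2)
      f <- ifelse(src == 1L, freq[, 1L], freq[, cl2])
      hap_poly[n_focal + s, ] <- rbinom(n_poly, 1L, f)
    }
  }

  # --- stage 2: sister-species divergence ---------------------------------
  set.seed(cfg$seed + 2L)
  div_idx <- which(runif(L) < cfg$species_divergence)

  # --- stage 3: strain subgroup + private mutations -----------------------
  set.seed(cfg$seed + 3L)
  strain_members <- focal_names[cluster_of == 1L]
  subgroup_of <- rep(seq_len(cfg$strain_subgroups), length.out = length(strain_members))
  n_shared <- cfg$strain_subgroups * cfg$shared_mutations_per_subgroup
  n_private <- length(strain_members) * cfg$private_mutations_per_sample
  pool <- setdiff(seq_len(L), union(poly_idx, div_idx))
  if (length(pool) < n_shared + n_private)
    stop("requested planted mutations (", n_shared + n_private,
         ") exceed available monomorphic sites (", length(pool), ")")
  planted <- sample(pool, n_shared + n_private)
  shared_sites <- if (n_shared > 0)
    split(planted[seq_len(n_shared)],
          rep(seq_len(cfg$strain_subgroups), each = cfg$shared_mutations_per_subgroup))
  else list()
  private_sites <- if (n_private > 0)
    split(planted[n_shared + seq_len(n_private)],
          rep(seq_along(strain_members), each = cfg$private_mutations_per_sample))
  else list()

  # --- assemble haplotypes over all candidate sites -----------------------
  cand <- sort(unique(c(poly_idx, div_idx, planted)))
  n_cand <- length(cand)
  H <- matrix(0L, length(hap_names), n_cand, dimnames = list(hap_names, NULL))
  H[seq_len(nrow(hap_poly)), match(poly_idx, cand)] <- hap_poly
  H[sister_name, match(div_idx, cand)] <- 1L
  for (g in seq_along(shared_sites)) {
    members <- strain_members[subgroup_of == g]
    H[members, match(shared_sites[[g]], cand)] <- 1L
  }
  for (s in seq_along(private_sites))
    H[strain_members[s], match(private_sites[[s]], cand)] <- 1L

  # --- truth genotypes (doubled haploids + hybrid) ------------------------
  sites <- lin_to_site(cand, cfg$chrom_length)
  parent_a <- strain_members[1L]
  hapA <- H[parent_a, ]
  hapB <- H[sister_name, ]
  in_mask <- rep(FALSE, n_cand)
  for (k in seq_len(nrow(cfg$rrna_mask))) {
    in_mask <- in_mask | (sites$chrom == cfg$rrna_mask$chrom[k] &
                            sites$pos >= cfg$rrna_mask$start[k] &
                            sites$pos <= cfg$rrna_mask$end[k])
  }
  g_hybrid <- hapA + hapB
  g_hybrid[in_mask] <- 2L * hapB[in_mask]
  G <- rbind(2L * H, g_hybrid)
  rownames(G) <- c(hap_names, hybrid_name)

  # keep only truth-polymorphic sites (some seeded frequencies draw all-ref)
  variant <- colSums(G != 0L) > 0L
  cand <- cand[variant]
  sites <- sites[variant, , drop = FALSE]
  rownames(sites) <- NULL
  H <- H[, variant, drop = FALSE]
  G <- G[, variant, drop = FALSE]

  ref_base <- substring(reference[sites$chrom],
                        sites$pos, sites$pos)
  alt_base <- vapply(ref_base, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1), USE.NAMES = FALSE)
  sites$ref <- ref_base
  sites$alt <- alt_base

  keep_planted <- function(ids) {
    df <- lin_to_site(sort(ids), cfg$chrom_length)
    df[paste(df$chrom, df$pos) %in% paste(sites$chrom, sites$pos), , drop = FALSE]
  }
  planted_group_loci <- do.call(rbind, c(list(
    data.frame(subgroup = character(), chrom = character(), pos = integer())),
    lapply(seq_along(shared_sites), function(g) {
      df <- keep_planted(shared_sites[[g]])
      if (nrow(df)) cbind(subgroup = paste0("sg", g), df) else NULL
    })))
  rownames(planted_group_loci) <- NULL

  # --- sample metadata -----------------------------------------------------
  all_names <- c(hap_names, hybrid_name)
  sample_table <- data.frame(
    sample = all_names,
    species = c(rep("A", n_focal + cfg$n_admixed), "B", "AxB"),
    strain = ifelse(all_names %in% strain_members, "strain1", NA_character_),
    subgroup = NA_character_,
    phenotype = "normal",
    cluster = c(paste0("cluster", cluster_of),
                rep("admixed", cfg$n_admixed), "sister", "hybrid"),
    homozygous_expected = c(rep(TRUE, length(hap_names)), FALSE),
    stringsAsFactors = FALSE)
  sample_table$subgroup[match(strain_members, sample_table$sample)] <-
    paste0("sg", subgroup_of)
  sample_table$phenotype[sample_table$subgroup %in% "sg1"] <- "abnormal"

  # --- organelles: uniparental inheritance from parent B ------------------
  org <- simulate_organelles(samples = hap_names,
                             organelle_length = cfg$organelle_length,
                             cp_rate = cfg$cp_rate,
                             mt_cp_ratio = cfg$mt_cp_ratio,
                             seed = cfg$seed + 4L,
                             hybrid = hybrid_name, donor = sister_name)

  structure(list(reference = reference, haplotypes = H, sites = sites,
                 genotypes = G, sample_table = sample_table,
                 hybrid_composition = list(hybrid = hybrid_name,
                                           parent_a = parent_a,
                                           parent_b = sister_name,
                                           organelle_donor = sister_name),
                 planted_group_loci = planted_group_loci,
                 organelle_truth = org,
                 rrna_mask = region_mask(cfg$rrna_mask),
                 config = cfg),
            class = "truth_dataset")
}

#' @export
print.truth_dataset <- function(x, ...) {
  cat(sprintf("truth_dataset: %d samples, %d variant sites, %d planted group loci\n",
              nrow(x$genotypes), nrow(x$sites), nrow(x$planted_group_loci)))
  invisible(x)
}

#' Simulate organelle alignments along a shared genealogy
#'
#' Draws a seeded Yule genealogy over the (non-hybrid) samples
#' (`ape::rphylo`, scaled to unit mean root-to-tip depth), then evolves two
#' sequence alignments along it under Jukes-Cantor substitution
#' (`phangorn::simSeq`): the chloroplast at `cp_rate` expected root-to-tip
#' substitutions/site, the mitochondrion at `cp_rate * mt_cp_ratio`. When a
#' hybrid and a donor are given, the hybrid's sequences are copies of the
#' donor's (uniparental organelle inheritance).
#'
#' @param samples Character vector of sample names evolving on the tree.
#' @param organelle_length Alignment length (bp).
#' @param cp_rate Chloroplast expected root-to-tip substitutions/site.
#' @param mt_cp_ratio Mitochondrial/chloroplast rate ratio.
#' @param seed Integer seed.
#' @param hybrid,donor Optional: name of a hybrid sample to append, and the
#'   parent (must be in `samples`) whose organelles it inherits.
#' @return A list with `cp` and `mt` ([seq_alignment()] objects), the
#'   genealogy `tree` (class `phylo`) and the two rates.
#' @export
simulate_organelles <- function(samples, organelle_length = 10000L,
                                cp_rate = 0.01, mt_cp_ratio = 10,
                                seed = 1L, hybrid = NULL, donor = NULL) {
  if (length(samples) < 2L) stop("at least two samples are required")
  if (!is.null(hybrid) && is.null(donor))
    stop("a 'donor' parent is required when simulating a hybrid")
  if (!is.null(donor) && !donor %in% samples)
    stop("'donor' must be one of 'samples'")
  set.seed(seed)
  tree <- ape::rphylo(length(samples), birth = 1, death = 0)
  tree$tip.label <- samples
  depth <- mean(ape::node.depth.edgelength(tree)[seq_along(samples)])
  tree$edge.length <- tree$edge.length / depth   # unit mean root-to-tip depth

  sim_one <- function(rate) {
    ch <- toupper(as.character(phangorn::simSeq(tree, l = organelle_length,
                                                rate = rate)))
    ch <- ch[samples, , drop = FALSE]
    if (!is.null(hybrid)) {
      ch <- rbind(ch, ch[donor, , drop = FALSE])
      rownames(ch) <- c(samples, hybrid)
    }
    seq_alignment(ch)
  }
  cp <- sim_one(cp_rate)
  mt <- sim_one(cp_rate * mt_cp_ratio)
  list(cp = cp, mt = mt, tree = tree,
       cp_rate = cp_rate, mt_rate = cp_rate * mt_cp_ratio)
}

#' Truth genotype matrix of a simulated dataset
#'
#' @param truth A `truth_dataset`.
#' @return A [genotype_matrix()] of the noiseless truth genotypes (no GQ).
#' @export
truth_genotype_matrix <- function(truth) {
  stopifnot(inherits(truth, "truth_dataset"))
  genotype_matrix(samples = rownames(truth$genotypes), sites = truth$sites,
                  calls = truth$genotypes,
                  log = "truth genotypes (noiseless)")
}

#' Write the observed (noisy) multi-sample VCF of a simulated dataset
#'
#' Applies the [noise_model()] to the truth genotypes and writes a VCF v4.2
#' file with `GT:GQ` FORMAT, one record per truth-polymorphic site,
#' unphased diploid calls, biallelic SNVs only. With both rates zero the
#' observed matrix reproduces the truth exactly.
#'
#' @param truth A `truth_dataset`.
#' @param noise A [noise_model()]; defaults to the rates stored in the
#'   simulation config.
#' @param seed Integer seed for the observation draws.
#' @param path Output VCF path.
#' @param force Overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
observe_vcf <- function(truth, noise = NULL, seed, path, force = FALSE) {
  stopifnot(inherits(truth, "truth_dataset"))
  if (is.null(noise))
    noise <- noise_model(error_rate = truth$config$error_rate,
                         missing_rate = truth$config$missing_rate)
  stopifnot(inherits(noise, "noise_model"))
  if (file.exists(path) && !force)
    stop("refusing to overwrite existing file (use force = TRUE): ", path)

  set.seed(seed)
  G <- truth$genotypes
  n <- length(G)
  miss <- matrix(runif(n) < noise$missing_rate, nrow = nrow(G))
  err <- matrix(runif(n) < noise$error_rate, nrow = nrow(G)) & !miss
  # uniform among the two wrong classes: add 1 or 2 mod 3
  shift <- matrix(sample(c(1L, 2L), n, replace = TRUE), nrow = nrow(G))
  obs <- G
  obs[err] <- (G[err] + shift[err]) %% 3L
  gq <- matrix(sample(seq(noise$gq_correct[1], noise$gq_correct[2]), n,
                      replace = TRUE), nrow = nrow(G))
  gq_err <- matrix(sample(seq(noise$gq_error[1], noise$gq_error[2]), n,
                          replace = TRUE), nrow = nrow(G))
  gq[err] <- gq_err[err]
  obs[miss] <- NA_integer_
  gq[miss] <- NA_integer_

  m <- genotype_matrix(samples = rownames(G), sites = truth$sites,
                       calls = obs, gq = gq,
                       log = sprintf("observed from truth (error=%g, missing=%g, seed=%d)",
                                     noise$error_rate, noise$missing_rate, seed))
  contigs <- setNames(rep(truth$config$chrom_length, truth$config$n_chrom),
                      paste0("chr", seq_len(truth$config$n_chrom)))
  write_genotype_vcf(m, path, contig_lengths = contigs, force = force)
  invisible(path)
}

#' Write the sample metadata table of a simulated dataset as TSV
#'
#' @param truth A `truth_dataset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(truth, path) {
  stopifnot(inherits(truth, "truth_dataset"))
  write.table(truth$sample_table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
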