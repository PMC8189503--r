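#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates the stages in fixed order — simulate (or load), filter,
#' trio classification, population structure, group screen, organelle
#' rate comparison — writing every artifact beneath one output directory
#' and returning a machine-readable report. With a fixed seed the run is
#' fully deterministic.
#'
#' The configuration is a named list (or a path to a JSON file with the
#' same structure). Recognised entries, all optional:
#' \describe{
#'   \item{`seed`}{Master seed (default 1). Seeds every stage.}
#'   \item{`sim`}{List of [sim_config()] arguments; used when no `vcf` is
#'     given. The simulation also supplies metadata, trio roles, screen
#'     groups and organelle alignments.}
#'   \item{`vcf`, `metadata`}{Paths to an existing multi-sample VCF and its
#'     sample metadata TSV; disables the simulation stage.}
#'   \item{`noise`}{List of [noise_model()] arguments for the observation
#'     layer (simulation runs only).}
#'   \item{`min_gq`, `max_missing`}{Filter thresholds (defaults 20, 0.1).}
#'   \item{`trio`}{List with `parent_a`, `parent_b`, `hybrid` and optional
#'     `threshold`; auto-filled from the simulation truth.}
#'   \item{`screen`}{List with `cases` and `controls` (sample names), or a
#'     `case_phenotype` label resolved against the metadata (default
#'     `"abnormal"` among homozygosity-expected samples).}
#'   \item{`mds_k`}{Ordination dimensions (default 2).}
#'   \item{`correction`}{Distance correction for the organelle rate ratio,
#'     `"p-distance"` or `"JC69"`.}
#' }
#'
#' A stage that cannot run for lack of configuration is marked `"skipped"`
#' in the report; a stage that fails aborts the run with the stage name in
#' the error and leaves a `FAILED` marker file in the output directory.
#'
#' @param config Named list or path to a JSON configuration file.
#' @param out_dir Output directory (created if needed).
#' @return An object of class `report_bundle` (also written as
#'   `report.json`): per-stage sections plus `seed`, `config_hash` and the
#'   package version.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("allotrio_")) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("'config' must be a named list or a JSON path")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  report <- list(seed = seed,
                 config_hash = rlang::hash(config),
                 package_version = as.character(utils::packageVersion("allotrio")))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  truth <- NULL
  trio_cfg <- config$trio
  screen_cfg <- config$screen

  # --- simulate / load ----------------------------------------------------
  if (is.null(config$vcf)) {
    truth <- stage("simulate", {
      cfg <- do.call(sim_config, c(list(seed = seed), config$sim))
      simulate_truth(cfg)
    })
    vcf_path <- file.path(out_dir, "observed.vcf")
    md_path <- file.path(out_dir, "metadata.tsv")
    stage("observe", {
      noise <- if (is.null(config$noise)) NULL else do.call(noise_model, config$noise)
      observe_vcf(truth, noise = noise, seed = seed + 10L, path = vcf_path,
                  force = TRUE)
      write_sample_metadata(truth, md_path)
    })
    metadata <- truth$sample_table
    report$simulate <- list(n_samples = nrow(truth$genotypes),
                            n_truth_sites = nrow(truth$sites),
                            vcf = vcf_path, metadata = md_path)
    if (is.null(trio_cfg))
      trio_cfg <- list(parent_a = truth$hybrid_composition$parent_a,
                       parent_b = truth$hybrid_composition$parent_b,
                       hybrid = truth$hybrid_composition$hybrid)
  } else {
    vcf_path <- config$vcf
    metadata <- if (is.null(config$metadata)) NULL else
      read_sample_metadata(config$metadata)
    report$simulate <- "skipped"
  }

  # --- read + filter ------------------------------------------------------
  filt <- stage("filter", {
    m <- read_multisample_vcf(vcf_path, metadata = metadata)
    min_gq <- if (is.null(config$min_gq)) 20L else as.integer(config$min_gq)
    max_missing <- if (is.null(config$max_missing)) 0.1 else config$max_missing
    filter_genotypes(m, min_gq = min_gq, max_missing = max_missing)
  })
  m <- filt$matrix
  report$filter <- unclass(filt$report)
  jsonlite::write_json(report$filter, file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  homoz <- if (!is.null(metadata))
    intersect(metadata$sample[metadata$homozygous_expected %in% TRUE], m$samples)
  else character()

  # --- trio ---------------------------------------------------------------
  if (!is.null(trio_cfg)) {
    trio_res <- stage("trio", {
      counts <- classify_trio(m, trio_cfg$parent_a, trio_cfg$parent_b,
                              trio_cfg$hybrid)
      thr <- if (is.null(trio_cfg$threshold)) 0.8 else trio_cfg$threshold
      list(counts = counts, verdict = allotetraploid_verdict(counts, threshold = thr))
    })
    report$trio <- list(
      counts = trio_res$counts[c("n_informative", "n_two_ref", "n_het",
                                 "n_two_alt", "n_unclassified")],
      het_fraction = trio_res$verdict$het_fraction,
      frac_two_ref = trio_res$verdict$frac_two_ref,
      is_allotetraploid = trio_res$verdict$is_allotetraploid)
    jsonlite::write_json(report$trio, file.path(out_dir, "trio.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else report$trio <- "skipped"

  # --- population structure ----------------------------------------------
  struct <- stage("structure", {
    k <- if (is.null(config$mds_k)) 2L else as.integer(config$mds_k)
    dm <- ibs_distance_matrix(m)
    ord <- classical_mds(dm, k = min(k, length(m$samples) - 1L))
    write.table(data.frame(sample = rownames(ord$coordinates),
                           ord$coordinates, check.names = FALSE),
                file.path(out_dir, "mds_coordinates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mp <- if (!is.null(trio_cfg))
      hybrid_midpoint(ord, trio_cfg$parent_a, trio_cfg$parent_b, trio_cfg$hybrid)
    else NULL
    list(ord = ord, midpoint = mp)
  })
  report$structure <- list(coordinates = file.path(out_dir, "mds_coordinates.tsv"),
                           eigenvalue_mass = struct$ord$goodness,
                           midpoint = struct$midpoint)

  # --- group screen ---------------------------------------------------------
  if (is.null(screen_cfg) && !is.null(metadata)) {
    pheno <- if (is.null(config$screen$case_phenotype)) "abnormal"
             else config$screen$case_phenotype
    dh <- metadata$sample[metadata$homozygous_expected %in% TRUE]
    cases <- intersect(dh[metadata$phenotype[match(dh, metadata$sample)] == pheno],
                       m$samples)
    controls <- setdiff(intersect(dh, m$samples), cases)
    if (length(cases) && length(controls))
      screen_cfg <- list(cases = cases, controls = controls)
  }
  if (!is.null(screen_cfg)) {
    scr <- stage("screen", {
      group_specific_variants(m, screen_cfg$cases, screen_cfg$controls)
    })
    write.table(scr$candidates, file.path(out_dir, "screen_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$screen <- list(n_candidates = nrow(scr$candidates),
                          n_case = scr$n_case, n_control = scr$n_control,
                          table = file.path(out_dir, "screen_candidates.tsv"))
  } else report$screen <- "skipped"

  # --- organelle rate ratio -------------------------------------------------
  if (!is.null(truth)) {
    rr <- stage("organelle", {
      corr <- if (is.null(config$correction)) "p-distance" else config$correction
      write_alignment_fasta(truth$organelle_truth$cp,
                            file.path(out_dir, "cp_alignment.fasta"), force = TRUE)
      write_alignment_fasta(truth$organelle_truth$mt,
                            file.path(out_dir, "mt_alignment.fasta"), force = TRUE)
      pairwise_rate_ratio(truth$organelle_truth$cp, truth$organelle_truth$mt,
                          correction = corr)
    })
    report$organelle <- list(ratio = rr$ratio,
                             cp_mean_distance = rr$cp_mean_distance,
                             mt_mean_distance = rr$mt_mean_distance,
                             correction = rr$correction, n_pairs = rr$n_pairs)
  } else report$organelle <- "skipped"

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  report$out_dir <- out_dir
  class(report) <- "report_bundle"
  report
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle (seed", x$seed, ")\n")
  for (s in c("simulate", "filter", "trio", "structure", "screen", "organelle")) {
    v <- x[[s]]
    cat(sprintf("  %-10s %s\n", s,
                if (identical(v, "skipped")) "skipped" else "done"))
  }
  cat("  artifacts in", x$out_dir, "\n")
  invisible(x)
}
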