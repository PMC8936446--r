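#' Build a pipeline run configuration
#'
#' @param genotypes genotype presets to simulate and analyse.
#' @param timepoint repair timepoint (hours) analysed against 0 hr.
#' @param scaling `"gel"` (anchor fractions to the simulated bulk-repair
#'   curve), `"intergenic_median"` (only meaningful for the contrast pair)
#'   or `"none"`.
#' @param contrast optional character pair `c(test, reference)` of
#'   genotypes for a difference matrix and SRAT contrast (e.g.
#'   `c("rad16set2", "rad16")`).
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param seed master seed for the run.
#' @param smooth TSS-profile smoothing width (odd, 1 = off).
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(genotypes = c("WT", "set2"), timepoint = 2,
                       scaling = c("gel", "intergenic_median", "none"),
                       contrast = NULL, sim = sim_config(), seed = 1L,
                       smooth = 11L, out_dir = tempfile("strandrepair_run")) {
  scaling <- match.arg(scaling)
  cfg <- list(genotypes = genotypes, timepoint = timepoint, scaling = scaling,
              contrast = contrast, sim = sim, seed = as.integer(seed),
              smooth = as.integer(smooth), out_dir = out_dir)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any of the [run_config()] fields; `sim` may
#'   be a mapping of [sim_config()] arguments.
#' @param out_dir optional override of the output directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$gene_length_range)) {
    sim_args$gene_length_range <- unlist(sim_args$gene_length_range)
  }
  if (!is.null(sim_args$base_composition)) {
    sim_args$base_composition <- unlist(sim_args$base_composition)
  }
  if (!is.null(sim_args$induction_prob)) {
    sim_args$induction_prob <- unlist(sim_args$induction_prob)
  }
  args <- list(
    genotypes = y$genotypes %||% c("WT", "set2"),
    timepoint = y$timepoint %||% 2,
    scaling = y$scaling %||% "gel",
    contrast = y$contrast,
    sim = do.call(sim_config, sim_args),
    seed = y$seed %||% 1L,
    smooth = y$smooth %||% 11L)
  if (!is.null(out_dir)) args$out_dir <- out_dir
  else if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  do.call(run_config, args)
}

validate_run_config <- function(cfg) {
  presets <- names(cfg$sim$genotype_presets)
  bad <- setdiff(cfg$genotypes, presets)
  if (length(bad)) {
    stop("unknown genotype(s) ", paste(bad, collapse = ", "),
         "; available presets: ", paste(presets, collapse = ", "))
  }
  if (!is.null(cfg$contrast)) {
    if (length(cfg$contrast) != 2L || !all(cfg$contrast %in% cfg$genotypes)) {
      stop("contrast must name two genotypes included in the run")
    }
  }
  stopifnot(length(cfg$timepoint) == 1L, cfg$timepoint > 0,
            cfg$smooth >= 1L, cfg$smooth %% 2L == 1L)
  invisible(cfg)
}

#' Run the end-to-end simulation and analysis pipeline
#'
#' Simulates one genome, runs a CPD-seq experiment per genotype, analyses
#' each (bin profile, asymmetry, TSS profile, gene matrix, bulk-repair
#' curve) and, when a contrast pair is configured, the
#' intergenic-median-scaled comparison with its SRAT stratification.
#' All tables are written as TSV (matrices additionally as CDT) together
#' with a JSON manifest recording seeds, scale factors, gene counts and
#' every file written. Deterministic given the seed.
#'
#' @param config a `run_config` from [run_config()] or
#'   [read_run_config()].
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genome_and_genes(local({
    s <- config$sim
    s$seed <- config$seed
    s
  }))
  sim_paths <- write_simulation(sim, file.path(out, "simulation"))
  tp <- config$timepoint
  tp_key <- as.character(tp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("strandrepair")),
    seed = config$seed, timepoint = tp, scaling = config$scaling,
    n_genes = nrow(sim$genes),
    n_srat_genes = sum(sim$genes$srat_class != "none"),
    genotypes = list(), files = as.list(sim_paths))

  experiments <- list()
  profiles <- list()
  for (i in seq_along(config$genotypes)) {
    gt <- config$genotypes[i]
    exp_seed <- derive_seed(config$seed, 1000L + i)
    ex <- simulate_experiment(sim, genotype = gt, timepoints = tp,
                              seed = exp_seed)
    experiments[[gt]] <- ex
    gel <- simulate_gel_curve(ex, seed = derive_seed(exp_seed, 7L))
    gel_fraction <- mean(gel$fraction_remaining[gel$timepoint == tp])

    prof <- bin_profile(ex$observed_t[[tp_key]], ex$observed_0, sim$genes)
    if (config$scaling == "gel") {
      prof <- gel_scale(prof, ex$observed_t[[tp_key]], ex$observed_0,
                        gel_fraction)
    }
    profiles[[gt]] <- prof
    asym <- asymmetry(prof)
    tssp <- tss_profile(ex$observed_t[[tp_key]], ex$observed_0, sim$genes,
                        smooth = config$smooth, dyads = sim$dyads,
                        scale_factor = prof$scale_factor)
    gm <- gene_matrix(ex$observed_t[[tp_key]], ex$observed_0, sim$genes,
                      order_by = "transcription_rate",
                      scale_factor = prof$scale_factor)
    files <- c(
      bins = write_table_tsv(prof, file.path(out, sprintf("%s_bins.tsv", gt))),
      asymmetry = write_table_tsv(asym, file.path(out, sprintf("%s_asymmetry.tsv", gt))),
      tss = write_table_tsv(tssp, file.path(out, sprintf("%s_tss_profile.tsv", gt))),
      matrix_cdt = write_cdt(gm, file.path(out, sprintf("%s_matrix.cdt", gt))),
      gel = {
        p <- file.path(out, sprintf("%s_gel_curve.tsv", gt))
        data.table::fwrite(gel, p, sep = "\t"); p
      },
      qc = {
        p <- file.path(out, sprintf("%s_qc.tsv", gt))
        qc <- data.frame(metric = c("lesions_0hr_true", "lesions_t_true",
                                    "reads_0hr", "reads_t"),
                         value = c(total_count(ex$lesions_0),
                                   total_count(ex$lesions_t[[tp_key]]),
                                   total_count(ex$observed_0),
                                   total_count(ex$observed_t[[tp_key]])))
        data.table::fwrite(qc, p, sep = "\t"); p
      })
    manifest$genotypes[[gt]] <- list(
      seed = exp_seed, scale_factor = prof$scale_factor,
      gel_fraction_remaining = gel_fraction,
      n_genes_binned = prof$n_genes, n_genes_excluded = prof$n_excluded)
    manifest$files <- c(manifest$files, as.list(files))
    message(sprintf("[%s] %d lesions at 0 hr; scale factor %.4g",
                    gt, total_count(ex$lesions_0), prof$scale_factor))
  }

  if (!is.null(config$contrast)) {
    test_gt <- config$contrast[1]
    ref_gt <- config$contrast[2]
    prof_scaled <- intergenic_median_scale(
      bin_profile(experiments[[test_gt]]$observed_t[[tp_key]],
                  experiments[[test_gt]]$observed_0, sim$genes),
      bin_profile(experiments[[ref_gt]]$observed_t[[tp_key]],
                  experiments[[ref_gt]]$observed_0, sim$genes))
    gmd <- gene_matrix(
      experiments[[test_gt]]$observed_t[[tp_key]],
      experiments[[test_gt]]$observed_0, sim$genes,
      order_by = "srat_first",
      reference = list(track_t = experiments[[ref_gt]]$observed_t[[tp_key]],
                       track_0 = experiments[[ref_gt]]$observed_0),
      scale_factor = prof_scaled$scale_factor)
    sc <- srat_contrast(gmd, seed = derive_seed(config$seed, 77L))
    files <- c(
      contrast_bins = write_table_tsv(
        prof_scaled, file.path(out, sprintf("%s_vs_%s_bins.tsv", test_gt, ref_gt))),
      contrast_matrix = write_cdt(
        gmd, file.path(out, sprintf("%s_vs_%s_matrix.cdt", test_gt, ref_gt))),
      srat_contrast = {
        p <- file.path(out, sprintf("%s_vs_%s_srat_contrast.tsv", test_gt, ref_gt))
        data.table::fwrite(sc, p, sep = "\t"); p
      })
    manifest$contrast <- list(
      test = test_gt, reference = ref_gt,
      scale_factor = prof_scaled$scale_factor,
      mean_nts_srat_contrast = mean(sc$contrast))
    manifest$files <- c(manifest$files, as.list(files))
  }

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$files$manifest <- manifest_path
  invisible(manifest)
}

#' Summarise a UV colony-survival assay with tests against a reference
#'
#' Survival per replicate is `100 * colonies_uv / colonies_control`
#' (percent). Replicates with a zero control count are excluded (with a
#' message). Per strain and dose the mean and SEM are reported, plus a
#' two-sided Welch t-test of each strain against the reference strain at
#' the same dose. No multiple-testing correction is applied by default;
#' `correct = "holm"` is available.
#'
#' @param assay data.frame with columns `strain`, `dose`, `replicate`,
#'   `colonies_uv`, `colonies_control` (e.g. from
#'   [simulate_survival_assay()]).
#' @param reference reference strain name.
#' @param correct `"none"` (default) or `"holm"`.
#' @return list with `$summary` (strain, dose, n, mean_survival,
#'   sem_survival) and `$tests` (strain, dose, t, df, p, p_adj).
#' @export
survival_stats <- function(assay, reference = "WT",
                           correct = c("none", "holm")) {
  correct <- match.arg(correct)
  dt <- data.table::as.data.table(assay)
  if (!reference %in% dt$strain) stop("reference strain not present: ", reference)
  n_zero <- sum(dt$colonies_control <= 0)
  if (n_zero > 0L) {
    message(n_zero, " replicate(s) with zero control count excluded")
    dt <- dt[colonies_control > 0]
  }
  dt[, survival := 100 * colonies_uv / colonies_control]
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  summ <- dt[, list(n = .N, mean_survival = mean(survival),
                    sem_survival = sem(survival)),
             by = list(strain, dose)]
  tests <- dt[strain != reference, {
    ref_vals <- dt[strain == reference & dose == .BY$dose, survival]
    if (length(ref_vals) >= 2L && .N >= 2L) {
      res <- repair_ttest(survival, ref_vals)
      list(t = res$t, df = res$df, p = res$p)
    } else {
      list(t = NA_real_, df = NA_real_, p = NA_real_)
    }
  }, by = list(strain, dose)]
  tests[, p_adj := if (correct == "holm") stats::p.adjust(p, "holm") else p]
  list(summary = as.data.frame(summ), tests = as.data.frame(tests))
}
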