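#' Genotype presets for the repair simulator
#'
#' Each preset is a set of three multipliers applied to the base repair
#' rates: `gg` scales the global genomic NER rate (`k_gg`), `tc` scales
#' transcription-coupled NER of the transcribed strand (`k_tc`) and `anti`
#' gates antisense TC-NER of the non-transcribed strand of SRAT genes
#' (`k_anti`). The defaults encode the qualitative genetics: SET2 loss
#' impairs (but does not abolish) TC-NER of the TS and de-represses
#' antisense TC-NER of the NTS; RAD16 loss abolishes GG-NER; RAD26 loss
#' abolishes TC-NER.
#'
#' @param gamma_tc residual TS TC-NER efficiency in set2-like genotypes,
#'   in (0, 1]. Default 0.4.
#' @return named list of numeric vectors `c(gg, tc, anti)`.
#' @export
genotype_presets <- function(gamma_tc = 0.4) {
  list(
    WT        = c(gg = 1, tc = 1,        anti = 0),
    set2      = c(gg = 1, tc = gamma_tc, anti = 1),
    rad16     = c(gg = 0, tc = 1,        anti = 0),
    rad16set2 = c(gg = 0, tc = gamma_tc, anti = 1),
    rad26     = c(gg = 1, tc = 0,        anti = 0)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic UV-lesion induction and repair model. The
#' defaults describe a compact yeast-like study condition: a 200 kb genome
#' at yeast base composition, ~55 non-overlapping genes of 1-3 kb,
#' nucleosomes every 165 bp starting 75 bp downstream of the TSS, and
#' first-order repair kinetics in which the transcribed strand of a gene
#' gains TC-NER on top of nucleosome-modulated GG-NER.
#'
#' @param seed master integer seed; all randomness derives from it.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes to place across the genome.
#' @param gene_length_range min/max gene body length (bp).
#' @param intergenic_min minimum intergenic spacer (bp); spacers are drawn
#'   uniformly from `[intergenic_min, intergenic_min + 200]`.
#' @param base_composition probabilities for A, C, G, T (must sum to 1).
#' @param induction_prob per-site lesion probability for each dipyrimidine
#'   (TT, TC, CT, CC), on the damaged strand.
#' @param k_gg GG-NER rate (per hour) at linker DNA.
#' @param k_tc additional TC-NER rate (per hour) on the transcribed strand.
#' @param k_anti antisense TC-NER rate (per hour) on the non-transcribed
#'   strand of SRAT genes, active only in set2-like genotypes.
#' @param nuc_amplitude depth of nucleosomal suppression of GG-NER, in
#'   `[0, 1]` (0 = no modulation; 1 = complete block at the dyad).
#' @param nuc_repeat nucleosome repeat length (bp).
#' @param first_dyad_offset distance from TSS to the +1 nucleosome dyad (bp).
#' @param srat_fraction fraction of genes flagged as carrying a
#'   Set2-repressed antisense transcript; exactly
#'   `floor(srat_fraction * n_genes)` genes are flagged.
#' @param depth expected sampled reads per library (binomial thinning).
#' @param genotype_presets named list of rate multipliers, see
#'   [genotype_presets()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L,
                       chrom_length = 200000L,
                       n_genes = 55L,
                       gene_length_range = c(1000L, 3000L),
                       intergenic_min = 300L,
                       base_composition = c(A = 0.31, C = 0.19, G = 0.19, T = 0.31),
                       induction_prob = c(TT = 0.12, TC = 0.06, CT = 0.06, CC = 0.03),
                       k_gg = 0.35,
                       k_tc = 0.55,
                       k_anti = 0.35,
                       nuc_amplitude = 0.4,
                       nuc_repeat = 165L,
                       first_dyad_offset = 75L,
                       srat_fraction = 0.15,
                       depth = 2e5,
                       genotype_presets = strandrepair::genotype_presets()) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              intergenic_min = as.integer(intergenic_min),
              base_composition = base_composition,
              induction_prob = induction_prob,
              k_gg = k_gg, k_tc = k_tc, k_anti = k_anti,
              nuc_amplitude = nuc_amplitude,
              nuc_repeat = as.integer(nuc_repeat),
              first_dyad_offset = as.integer(first_dyad_offset),
              srat_fraction = srat_fraction, depth = depth,
              genotype_presets = genotype_presets)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$n_chroms >= 1L, cfg$chrom_length >= 1L, cfg$n_genes >= 0L,
    length(cfg$gene_length_range) == 2L,
    cfg$gene_length_range[1] >= 1L,
    cfg$gene_length_range[1] <= cfg$gene_length_range[2],
    cfg$intergenic_min >= 0L
  )
  if (!setequal(names(cfg$base_composition), c("A", "C", "G", "T")) ||
      abs(sum(cfg$base_composition) - 1) > 1e-8 ||
      any(cfg$base_composition < 0)) {
    stop("base_composition must be probabilities over A, C, G, T summing to 1")
  }
  if (!setequal(names(cfg$induction_prob), PYRIMIDINE_DINUCS) ||
      any(cfg$induction_prob < 0) || any(cfg$induction_prob > 1)) {
    stop("induction_prob must map TT, TC, CT, CC to probabilities in [0, 1]")
  }
  if (cfg$k_gg < 0 || cfg$k_tc < 0 || cfg$k_anti < 0) {
    stop("repair rates must be non-negative")
  }
  if (cfg$nuc_amplitude < 0 || cfg$nuc_amplitude > 1) {
    stop("nuc_amplitude must be in [0, 1]")
  }
  if (cfg$srat_fraction < 0 || cfg$srat_fraction > 1) {
    stop("srat_fraction must be in [0, 1]")
  }
  if (cfg$depth <= 0) stop("depth must be positive")
  if (is.null(names(cfg$genotype_presets)) ||
      !all(vapply(cfg$genotype_presets,
                  function(p) all(c("gg", "tc", "anti") %in% names(p)),
                  logical(1)))) {
    stop("genotype_presets must be a named list of c(gg, tc, anti) vectors")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d chrom x %d bp, %d genes, seed %d\n",
              x$n_chroms, x$chrom_length, x$n_genes, x$seed))
  cat(sprintf(" rates/hr: k_gg %.3g, k_tc %.3g, k_anti %.3g; nucleosome amp %.2f, repeat %d bp\n",
              x$k_gg, x$k_tc, x$k_anti, x$nuc_amplitude, x$nuc_repeat))
  cat(" genotypes:", paste(names(x$genotype_presets), collapse = ", "), "\n")
  invisible(x)
}
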