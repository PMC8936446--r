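#' Generate a synthetic genome, gene annotation and nucleosome dyads
#'
#' Draws a random genome at the configured base composition, packs
#' non-overlapping genes onto it left to right with random intergenic
#' spacers, assigns each gene a strand uniformly at random, covariates
#' (transcription rate, expression log2 fold-change) and an SRAT flag for
#' exactly `floor(srat_fraction * n_genes)` genes, and places nucleosome
#' dyads inside each gene body starting `first_dyad_offset` bp downstream
#' of the TSS and repeating every `nuc_repeat` bp.
#'
#' Coordinates are 0-based. For a plus-strand gene occupying `[start, end)`
#' the TSS is `start` and the TES `end - 1` + 1 convention: we store
#' `tss = start`, `tes = end`, so the body is `[tss, tes)` read left to
#' right. For a minus-strand gene `tss = end - 1` and `tes = start - 1`,
#' so the body read in gene orientation is positions `tss, tss - 1, ...,
#' tes + 1` (genomic `[start, end)`).
#'
#' @param config a [sim_config()].
#' @return an object of class `repair_simulation` with elements `genome`
#'   (a [Biostrings::DNAStringSet]), `genes` (data.frame), `dyads`
#'   (data.table of dyad positions), `seqlengths` and `config`.
#' @export
generate_genome_and_genes <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    seqs <- vapply(chroms, function(ch) {
      paste(sample(names(config$base_composition), config$chrom_length,
                   replace = TRUE, prob = config$base_composition),
            collapse = "")
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms

    genes <- pack_genes(config, chroms)
    dyads <- place_dyads(genes, config)
    structure(
      list(genome = genome, genes = genes, dyads = dyads,
           seqlengths = stats::setNames(rep(config$chrom_length,
                                            config$n_chroms), chroms),
           config = config),
      class = "repair_simulation")
  })
}

# Sequential left-to-right packing; errors when the requested genes do not
# fit in the genome.
pack_genes <- function(config, chroms) {
  empty <- data.frame(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), tss = integer(), tes = integer(),
    transcription_rate = numeric(), expr_log2fc = numeric(),
    srat_class = character(), stringsAsFactors = FALSE)
  if (config$n_genes == 0L) return(empty)
  rows <- vector("list", config$n_genes)
  placed <- 0L
  for (ch in chroms) {
    pos <- sample(seq(config$intergenic_min, config$intergenic_min + 200L), 1L)
    while (placed < config$n_genes) {
      len <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]), 1L)
      spacer <- sample(seq(config$intergenic_min, config$intergenic_min + 200L), 1L)
      if (pos + len + config$intergenic_min > config$chrom_length) break
      placed <- placed + 1L
      strand <- sample(c("+", "-"), 1L)
      rows[[placed]] <- data.frame(
        gene_id = sprintf("gene%03d", placed), chrom = ch,
        start = pos, end = pos + len, strand = strand,
        tss = if (strand == "+") pos else pos + len - 1L,
        tes = if (strand == "+") pos + len else pos - 1L,
        transcription_rate = NA_real_, expr_log2fc = NA_real_,
        srat_class = "none", stringsAsFactors = FALSE)
      pos <- pos + len + spacer
    }
    if (placed >= config$n_genes) break
  }
  if (placed < config$n_genes) {
    stop(sprintf("infeasible packing: only %d of %d genes fit in %d chrom(s) of %d bp",
                 placed, config$n_genes, config$n_chroms, config$chrom_length))
  }
  genes <- do.call(rbind, rows)
  genes$transcription_rate <- stats::rlnorm(nrow(genes), meanlog = log(8), sdlog = 1)
  genes$expr_log2fc <- stats::rnorm(nrow(genes), 0, 0.5)
  n_srat <- floor(config$srat_fraction * config$n_genes)
  if (n_srat > 0L) {
    genes$srat_class[sample.int(nrow(genes), n_srat)] <- "polyA"
  }
  genes
}

place_dyads <- function(genes, config) {
  if (nrow(genes) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  count = integer()))
  }
  parts <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    len <- g$end - g$start
    offs <- seq(config$first_dyad_offset, len - 1L, by = config$nuc_repeat)
    if (length(offs) == 0L) return(NULL)
    pos <- if (g$strand == "+") g$tss + offs else g$tss - offs
    data.table::data.table(chrom = g$chrom, pos = as.integer(pos), count = 1L)
  })
  out <- data.table::rbindlist(Filter(Negate(is.null), parts))
  if (nrow(out) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  count = integer()))
  }
  data.table::setkeyv(out, c("chrom", "pos"))
  out[]
}

#' Induce UV lesions at dipyrimidine sites
#'
#' Every dipyrimidine site on each strand independently carries a lesion
#' with its dinucleotide's induction probability. Lesions are recorded at
#' the 5'-most base of the dinucleotide on the damaged strand: position
#' `x` for a plus-strand dipyrimidine at `(x, x + 1)`, position `x + 1`
#' for a minus-strand dipyrimidine at the same genomic span (a
#' purine-purine dinucleotide on the reference).
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector.
#' @param config a [sim_config()] (only `induction_prob` is used).
#' @param seed integer seed.
#' @return a [lesion_track()] at t = 0 hr.
#' @export
induce_lesions <- function(genome, config, seed = config$seed) {
  g <- as_genome_chars(genome)
  if (any(nchar(g) == 0L)) stop("genome must be non-empty")
  sl <- genome_seqlengths(genome)
  withr::with_seed(seed, {
    parts <- lapply(names(g), function(ch) {
      s <- strsplit(g[[ch]], "", fixed = TRUE)[[1]]
      L <- length(s)
      if (L < 2L) return(NULL)
      dinuc <- paste0(s[-L], s[-1L])           # dinuc starting at 0-based x = i-1
      out <- list()
      # plus strand: dipyrimidine as written
      ip <- match(dinuc, PYRIMIDINE_DINUCS)
      idx <- which(!is.na(ip))
      if (length(idx)) {
        p <- config$induction_prob[PYRIMIDINE_DINUCS[ip[idx]]]
        hit <- stats::runif(length(idx)) < p
        if (any(hit)) {
          out$plus <- data.table::data.table(
            chrom = ch, pos = idx[hit] - 1L, strand = "+", count = 1L)
        }
      }
      # minus strand: reference purine-purine; lesion stored at x + 1
      im <- match(dinuc, PURINE_DINUCS)
      idx <- which(!is.na(im))
      if (length(idx)) {
        p <- config$induction_prob[names(PURINE_DINUCS)[im[idx]]]
        hit <- stats::runif(length(idx)) < p
        if (any(hit)) {
          out$minus <- data.table::data.table(
            chrom = ch, pos = idx[hit], strand = "-", count = 1L)
        }
      }
      if (length(out)) data.table::rbindlist(out) else NULL
    })
    counts <- data.table::rbindlist(Filter(Negate(is.null), parts))
    lesion_track(counts, sl, sample_id = "simulated", timepoint = 0,
                 provenance = sprintf("simulated seed=%d", seed))
  })
}

# Per-position per-strand repair rate under a genotype preset.
# k(x, s) = m_nuc(x) k_gg g_gg + k_tc g_tc [s is TS] + k_anti g_anti [s is
# NTS of an SRAT gene], with m_nuc(x) = 1 - A c(x) and c(x) the
# cosine-interpolated dyad proximity (1 at the dyad, 0 at the linker
# midpoint and beyond).
lesion_rates <- function(counts, genes, dyads, config, genotype) {
  presets <- config$genotype_presets
  if (!genotype %in% names(presets)) {
    stop("unknown genotype '", genotype, "'; available presets: ",
         paste(names(presets), collapse = ", "))
  }
  gmul <- presets[[genotype]]
  n <- nrow(counts)
  if (n == 0L) return(numeric(0))
  is_ts <- logical(n)
  is_srat_nts <- logical(n)
  cprox <- numeric(n)
  for (ch in unique(counts$chrom)) {
    sel <- which(counts$chrom == ch)
    pos <- counts$pos[sel]
    gsub <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(gsub) > 0L) {
      ord <- order(gsub$start)
      gsub <- gsub[ord, , drop = FALSE]
      gi <- findInterval(pos, gsub$start)
      inside <- gi >= 1L & pos < gsub$end[pmax(gi, 1L)]
      gi[!inside] <- NA_integer_
      gstrand <- gsub$strand[gi]
      is_ts[sel] <- !is.na(gi) & counts$strand[sel] != gstrand
      is_srat_nts[sel] <- !is.na(gi) & counts$strand[sel] == gstrand &
        gsub$srat_class[gi] != "none"
    }
    dsub <- dyads[dyads$chrom == ch]
    if (nrow(dsub) > 0L && config$nuc_amplitude > 0) {
      dp <- sort(dsub$pos)
      j <- findInterval(pos, dp)
      d_lo <- ifelse(j >= 1L, pos - dp[pmax(j, 1L)], Inf)
      d_hi <- ifelse(j < length(dp), dp[pmin(j + 1L, length(dp))] - pos, Inf)
      d <- pmin(d_lo, d_hi)
      half <- config$nuc_repeat / 2
      cprox[sel] <- ifelse(d <= half,
                           (1 + cos(2 * pi * d / config$nuc_repeat)) / 2, 0)
    }
  }
  m_nuc <- 1 - config$nuc_amplitude * cprox
  m_nuc * config$k_gg * gmul[["gg"]] +
    config$k_tc * gmul[["tc"]] * is_ts +
    config$k_anti * gmul[["anti"]] * is_srat_nts
}

#' Simulate repair of a lesion track for a given genotype and time
#'
#' Each lesion survives independently to time `t` with probability
#' `exp(-k(x, s) t)` where the rate `k(x, s)` combines
#' nucleosome-modulated GG-NER, TC-NER of the transcribed strand and
#' (in set2-like genotypes) antisense TC-NER of the non-transcribed strand
#' of SRAT genes; see [genotype_presets()].
#'
#' @param lesions_0 a [lesion_track()] at the earlier time.
#' @param genes gene annotation data.frame (see
#'   [generate_genome_and_genes()]).
#' @param dyads data.table of nucleosome dyad positions (`chrom`, `pos`).
#' @param config a [sim_config()].
#' @param genotype preset name, one of `names(config$genotype_presets)`.
#' @param t elapsed repair time in hours (from the state of `lesions_0`).
#' @param seed integer seed.
#' @return a [lesion_track()] with `timepoint` advanced by `t`.
#' @export
simulate_repair <- function(lesions_0, genes, dyads, config, genotype, t,
                            seed = config$seed) {
  stopifnot(inherits(lesions_0, "lesion_track"), t >= 0)
  k <- lesion_rates(lesions_0$counts, genes, dyads, config, genotype)
  if (t == 0 || nrow(lesions_0$counts) == 0L) {
    out <- lesions_0
    out$timepoint <- (lesions_0$timepoint %||% 0) + t
    return(out)
  }
  withr::with_seed(seed, {
    surv <- exp(-k * t)
    new_count <- stats::rbinom(nrow(lesions_0$counts),
                               lesions_0$counts$count, surv)
    counts <- data.table::copy(lesions_0$counts)
    counts[, count := new_count]
    tp <- if (is.na(lesions_0$timepoint)) t else lesions_0$timepoint + t
    lesion_track(counts[count > 0L], lesions_0$seqlengths,
                 sample_id = sprintf("%s_%ghr", genotype, tp),
                 timepoint = tp,
                 provenance = sprintf("%s; repaired genotype=%s t=%g seed=%d",
                                      lesions_0$provenance, genotype, t, seed))
  })
}

#' Thin a lesion track to a target sequencing depth
#'
#' Binomial thinning: every lesion is observed independently with
#' probability `min(1, depth / total)`, so the expected observed total is
#' `min(depth, total)`. Mimics finite library depth; absolute lesion
#' numbers are no longer comparable between libraries after thinning,
#' which is why bulk-repair (gel) rescaling exists.
#'
#' @param track a [lesion_track()].
#' @param depth expected number of sampled reads.
#' @param seed integer seed.
#' @return a thinned [lesion_track()].
#' @export
sample_reads <- function(track, depth, seed = 1L) {
  stopifnot(inherits(track, "lesion_track"), depth > 0)
  tot <- total_count(track)
  if (tot == 0L) return(track)
  p <- min(1, depth / tot)
  if (p >= 1) {
    out <- track
    out$provenance <- paste0(track$provenance, "; thinned p=1 (depth >= total)")
    return(out)
  }
  withr::with_seed(seed, {
    counts <- data.table::copy(track$counts)
    counts[, count := stats::rbinom(.N, count, p)]
    lesion_track(counts[count > 0L], track$seqlengths,
                 sample_id = track$sample_id, timepoint = track$timepoint,
                 provenance = sprintf("%s; thinned depth=%g p=%.4g seed=%d",
                                      track$provenance, depth, p, seed))
  })
}

#' Simulate a full CPD-seq experiment for one genotype
#'
#' Induces lesions on the simulated genome, repairs them through the
#' sorted timepoints with a nested survival construction (each timepoint's
#' lesions are a thinning of the previous timepoint's, so totals are
#' monotone non-increasing in time per seed), and binomially thins every
#' library to the configured depth.
#'
#' @param sim a `repair_simulation` from [generate_genome_and_genes()].
#' @param genotype preset name.
#' @param timepoints repair timepoints in hours (0 is implicit).
#' @param seed integer seed for induction, repair and thinning.
#' @param depth per-library sequencing depth; default from the config.
#' @return an object of class `cpd_experiment`: `lesions_0` / `lesions_t`
#'   (true tracks), `observed_0` / `observed_t` (depth-thinned tracks),
#'   `bulk_fraction_remaining` (true genome-wide totals ratio per
#'   timepoint), plus the genotype and seed.
#' @export
simulate_experiment <- function(sim, genotype = "WT", timepoints = 2,
                                seed = 1L, depth = sim$config$depth) {
  stopifnot(inherits(sim, "repair_simulation"), all(timepoints >= 0))
  timepoints <- sort(unique(timepoints[timepoints > 0]))
  lesions_0 <- induce_lesions(sim$genome, sim$config, seed = derive_seed(seed, 1L))
  lesions_t <- list()
  prev <- lesions_0
  prev_t <- 0
  for (i in seq_along(timepoints)) {
    tp <- timepoints[i]
    prev <- simulate_repair(prev, sim$genes, sim$dyads, sim$config, genotype,
                            t = tp - prev_t, seed = derive_seed(seed, 10L + i))
    lesions_t[[as.character(tp)]] <- prev
    prev_t <- tp
  }
  tot0 <- total_count(lesions_0)
  bulk <- vapply(lesions_t, function(tr) total_count(tr) / tot0, numeric(1))
  observed_0 <- sample_reads(lesions_0, depth, seed = derive_seed(seed, 100L))
  observed_t <- lapply(seq_along(lesions_t), function(i) {
    sample_reads(lesions_t[[i]], depth, seed = derive_seed(seed, 100L + i))
  })
  names(observed_t) <- names(lesions_t)
  structure(
    list(genotype = genotype, seed = seed,
         lesions_0 = lesions_0, lesions_t = lesions_t,
         observed_0 = observed_0, observed_t = observed_t,
         bulk_fraction_remaining = bulk),
    class = "cpd_experiment")
}

#' @export
print.cpd_experiment <- function(x, ...) {
  cat(sprintf("cpd_experiment genotype=%s: %d lesions at 0 hr; timepoints %s hr\n",
              x$genotype, total_count(x$lesions_0),
              paste(names(x$lesions_t), collapse = ", ")))
  cat(" true bulk fraction remaining:",
      paste(sprintf("%s hr = %.3f", names(x$bulk_fraction_remaining),
                    x$bulk_fraction_remaining), collapse = "; "), "\n")
  invisible(x)
}

#' Simulate a bulk-repair (alkaline gel) curve from a CPD-seq experiment
#'
#' The true fraction of lesions remaining at each timepoint (total true
#' lesions at t over the 0 hr total) plus Gaussian replicate noise on the
#' fraction scale, truncated to `[0, 1]`. Percent repair is
#' `100 * (1 - fraction remaining)`.
#'
#' @param experiment a `cpd_experiment` from [simulate_experiment()].
#' @param noise_sd replicate noise standard deviation on the fraction
#'   scale (0 for a deterministic curve).
#' @param n_replicates replicates per timepoint.
#' @param seed integer seed.
#' @return data.frame with columns `timepoint`, `replicate`,
#'   `fraction_remaining`, `percent_repair`.
#' @export
simulate_gel_curve <- function(experiment, noise_sd = 0.02, n_replicates = 3,
                               seed = 1L) {
  stopifnot(inherits(experiment, "cpd_experiment"))
  if (total_count(experiment$lesions_0) == 0L) {
    stop("no lesions at 0 hr; cannot form a repair curve")
  }
  tps <- c(0, as.numeric(names(experiment$bulk_fraction_remaining)))
  truth <- c(1, unname(experiment$bulk_fraction_remaining))
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_along(tps), function(i) {
      fr <- truth[i] + stats::rnorm(n_replicates, 0, noise_sd)
      fr <- pmin(pmax(fr, 0), 1)
      if (tps[i] == 0) fr <- rep(1, n_replicates)  # 0 hr anchors the curve
      data.frame(timepoint = tps[i], replicate = seq_len(n_replicates),
                 fraction_remaining = fr, percent_repair = 100 * (1 - fr))
    }))
    out
  })
}

#' Fabricate read 5'-end records from a lesion track
#'
#' Inverts the lesion-calling offset convention: a lesion on the minus
#' strand stored at position `x` is reported by a plus-strand read with 5'
#' end `x + 1`; a plus-strand lesion at `x` by a minus-strand read with 5'
#' end `x - 1`. Lesions at the extreme chromosome edges (plus strand
#' position 0, minus strand position `L - 1`) have no representable read
#' and are dropped; the number dropped is attached as attribute
#' `n_undetectable`.
#'
#' @param track a [lesion_track()].
#' @return data.frame of read records (`chrom`, `five_prime_pos`,
#'   `strand`, `count`) suitable for [infer_lesions()].
#' @export
lesions_to_reads <- function(track) {
  stopifnot(inherits(track, "lesion_track"))
  dt <- track$counts
  if (nrow(dt) == 0L) {
    out <- data.frame(chrom = character(), five_prime_pos = integer(),
                      strand = character(), count = integer())
    attr(out, "n_undetectable") <- 0L
    return(out)
  }
  L <- track$seqlengths[dt$chrom]
  read_strand <- ifelse(dt$strand == "-", "+", "-")
  five <- ifelse(dt$strand == "-", dt$pos + 1L, dt$pos - 1L)
  ok <- five >= 0L & five < L
  out <- data.frame(chrom = dt$chrom[ok], five_prime_pos = as.integer(five[ok]),
                    strand = read_strand[ok], count = dt$count[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_undetectable") <- as.integer(sum(dt$count[!ok]))
  out
}

#' Simulate a Poisson-fragmented gel lane length profile
#'
#' Cuts `n_molecules` molecules of `molecule_kb` kb at Poisson-distributed
#' positions (`cuts_per_kb` expected cuts per kb) and returns the fragment
#' length distribution as an intensity profile with intensity proportional
#' to fragment mass, as a stained gel lane would report.
#'
#' @param n_molecules number of molecules.
#' @param molecule_kb molecule length in kb.
#' @param cuts_per_kb expected cut density (per kb).
#' @param seed integer seed.
#' @return data.frame with columns `length_kb` and `intensity`
#'   (mass-proportional), one row per distinct fragment length, plus
#'   attribute `true_number_average_kb` (total length / fragment count).
#' @export
simulate_fragment_lane <- function(n_molecules, molecule_kb, cuts_per_kb,
                                   seed = 1L) {
  stopifnot(n_molecules >= 1, molecule_kb > 0, cuts_per_kb >= 0)
  withr::with_seed(seed, {
    n_cuts <- stats::rpois(n_molecules, cuts_per_kb * molecule_kb)
    frags <- unlist(lapply(n_cuts, function(k) {
      if (k == 0L) return(molecule_kb)
      cuts <- sort(stats::runif(k, 0, molecule_kb))
      diff(c(0, cuts, molecule_kb))
    }))
    # bin to limit profile size; mass-weighted intensities
    br <- seq(0, molecule_kb, length.out = 513L)
    mid <- (br[-1L] + br[-length(br)]) / 2
    bin <- findInterval(frags, br, rightmost.closed = TRUE)
    mass <- tapply(frags, factor(bin, levels = seq_along(mid)), sum)
    mass[is.na(mass)] <- 0
    keep <- mass > 0
    out <- data.frame(length_kb = mid[keep], intensity = as.numeric(mass[keep]))
    attr(out, "true_number_average_kb") <- sum(frags) / length(frags)
    out
  })
}

#' Simulate a UV colony-survival assay
#'
#' Plates `cells_per_plate` cells per replicate; survivors are binomial
#' with the strain- and dose-specific survival probability. Control
#' (unirradiated) plates report the plated cell number.
#'
#' @param survival_prob named list: strain -> named numeric vector of
#'   survival probabilities per dose (names are dose labels).
#' @param n_trials replicate trials per strain and dose.
#' @param cells_per_plate cells plated per replicate.
#' @param seed integer seed.
#' @return data.frame with columns `strain`, `dose`, `replicate`,
#'   `colonies_uv`, `colonies_control`.
#' @export
simulate_survival_assay <- function(survival_prob, n_trials = 3,
                                    cells_per_plate = 300, seed = 1L) {
  withr::with_seed(seed, {
    rows <- list()
    for (strain in names(survival_prob)) {
      for (dose in names(survival_prob[[strain]])) {
        p <- survival_prob[[strain]][[dose]]
        rows[[length(rows) + 1L]] <- data.frame(
          strain = strain, dose = dose, replicate = seq_len(n_trials),
          colonies_uv = stats::rbinom(n_trials, cells_per_plate, p),
          colonies_control = rep(cells_per_plate, n_trials))
      }
    }
    do.call(rbind, rows)
  })
}

#' Write simulator outputs in standard formats
#'
#' Writes the genome as FASTA, genes as BED6 plus a covariate TSV, dyads
#' as bedGraph and the configuration as YAML.
#'
#' @param sim a `repair_simulation`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "repair_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes_bed = file.path(dir, "genes.bed"),
             covariates = file.path(dir, "gene_covariates.tsv"),
             dyads = file.path(dir, "dyads.bedgraph"),
             config = file.path(dir, "sim_config.yaml"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  bed <- data.frame(chrom = sim$genes$chrom, start = sim$genes$start,
                    end = sim$genes$end, name = sim$genes$gene_id,
                    score = 0L, strand = sim$genes$strand)
  data.table::fwrite(bed, paths[["genes_bed"]], sep = "\t", col.names = FALSE)
  data.table::fwrite(sim$genes, paths[["covariates"]], sep = "\t")
  if (nrow(sim$dyads) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = sim$dyads$chrom,
      ranges = IRanges::IRanges(start = sim$dyads$pos + 1L, width = 1L),
      score = as.numeric(sim$dyads$count), seqlengths = sim$seqlengths)
    rtracklayer::export(gr, paths[["dyads"]], format = "bedGraph")
  } else {
    writeLines(character(), paths[["dyads"]])
  }
  cfg <- sim$config
  cfg$genotype_presets <- lapply(cfg$genotype_presets, as.list)
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    paths[["config"]])
  invisible(paths)
}
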