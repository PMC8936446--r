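#' Fraction of CPDs remaining in strand-qualified regions
#'
#' For each region, the pooled lesion count at the repair timepoint
#' divided by the pooled count at 0 hr. Regions whose 0 hr count is zero
#' get `NA` (undefined), never 0 or Inf.
#'
#' @param track_t,track_0 [lesion_track()]s at the repair timepoint and at
#'   0 hr, on the same genome.
#' @param regions data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand`.
#' @return `regions` with added columns `counts_0`, `counts_t`, `fraction`.
#' @export
fraction_remaining <- function(track_t, track_0, regions) {
  stopifnot(inherits(track_t, "lesion_track"), inherits(track_0, "lesion_track"))
  if (!setequal(names(track_t$seqlengths), names(track_0$seqlengths))) {
    stop("tracks cover different chromosome sets")
  }
  ct <- track_cumsum(track_t)
  c0 <- track_cumsum(track_0)
  n <- nrow(regions)
  counts_0 <- counts_t <- numeric(n)
  for (i in seq_len(n)) {
    counts_0[i] <- interval_sum(c0, regions$chrom[i], regions$strand[i],
                                regions$start[i], regions$end[i])
    counts_t[i] <- interval_sum(ct, regions$chrom[i], regions$strand[i],
                                regions$start[i], regions$end[i])
  }
  regions$counts_0 <- counts_0
  regions$counts_t <- counts_t
  regions$fraction <- ifelse(counts_0 > 0, counts_t / counts_0, NA_real_)
  regions
}

#' Metagene bin intervals for one or more genes
#'
#' The gene body `[TSS, TES)` (in gene orientation) is split into
#' `n_body_bins` contiguous bins of equal size; when the body length is
#' not divisible by `n_body_bins`, the first `length %% n_body_bins` bins
#' (counted from the TSS) receive one extra bp. Three flanking bins of
#' `flank_bin_bp` each tile outward from the TSS (upstream, bins 1-3 with
#' bin 1 furthest) and from the TES (downstream, bins 10-12 with bin 10
#' nearest), flush against the TSS/TES. Intervals are clipped to the
#' chromosome.
#'
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `strand`,
#'   `tss`, `tes`).
#' @param seqlengths named integer vector of chromosome lengths.
#' @param flank_bin_bp width of each flanking bin (bp).
#' @param n_body_bins number of gene-body bins.
#' @return data.table with columns `gene_id`, `bin` (1..12 for the
#'   defaults), `region` (`"upstream"`, `"body"`, `"downstream"`),
#'   `chrom`, `start`, `end`, `gene_strand` (genomic, 0-based half-open).
#' @export
gene_bins <- function(genes, seqlengths, flank_bin_bp = 167L, n_body_bins = 6L) {
  stopifnot(n_body_bins >= 1L, flank_bin_bp >= 1L)
  n_flank <- 3L
  parts <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- abs(g$tes - g$tss)
    if (len < n_body_bins) next   # too short to split; caller logs exclusions
    # local coordinates: 0 at TSS, increasing in gene orientation
    q <- len %/% n_body_bins
    r <- len %% n_body_bins
    sizes <- rep(q, n_body_bins) + c(rep(1L, r), rep(0L, n_body_bins - r))
    body_bounds <- c(0L, cumsum(sizes))
    lo <- c(-(n_flank:1) * flank_bin_bp,                    # upstream bins 1-3
            body_bounds[-(n_body_bins + 1L)],               # body bins
            len + (0:(n_flank - 1L)) * flank_bin_bp)        # downstream bins
    hi <- c(-((n_flank - 1L):0) * flank_bin_bp,
            body_bounds[-1L],
            len + (1:n_flank) * flank_bin_bp)
    if (g$strand == "+") {
      start <- g$tss + lo
      end <- g$tss + hi
    } else {
      start <- g$tss - hi + 1L
      end <- g$tss - lo + 1L
    }
    L <- seqlengths[[g$chrom]]
    start <- pmax(start, 0L)
    end <- pmin(end, L)
    parts[[i]] <- data.table::data.table(
      gene_id = g$gene_id,
      bin = seq_len(n_flank * 2L + n_body_bins),
      region = rep(c("upstream", "body", "downstream"),
                   c(n_flank, n_body_bins, n_flank)),
      chrom = g$chrom, start = as.integer(start), end = as.integer(end),
      gene_strand = g$strand)
  }
  out <- data.table::rbindlist(Filter(Negate(is.null), parts))
  if (nrow(out) == 0L) stop("no genes passed the minimum-length filter")
  out[]
}

bin_count_table <- function(track_t, track_0, genes, flank_bin_bp, n_body_bins) {
  bins <- gene_bins(genes, track_0$seqlengths, flank_bin_bp, n_body_bins)
  ct <- track_cumsum(track_t)
  c0 <- track_cumsum(track_0)
  # TS is the strand opposite the gene's (mRNA-coding) strand
  res <- data.table::rbindlist(lapply(c("TS", "NTS"), function(role) {
    strand <- if (role == "TS") {
      ifelse(bins$gene_strand == "+", "-", "+")
    } else {
      bins$gene_strand
    }
    counts_0 <- counts_t <- numeric(nrow(bins))
    for (ch in unique(bins$chrom)) {
      for (s in c("+", "-")) {
        sel <- which(bins$chrom == ch & strand == s)
        if (!length(sel)) next
        counts_0[sel] <- interval_sum(c0, ch, s, bins$start[sel], bins$end[sel])
        counts_t[sel] <- interval_sum(ct, ch, s, bins$start[sel], bins$end[sel])
      }
    }
    data.table::data.table(gene_id = bins$gene_id, bin = bins$bin,
                           region = bins$region, strand_role = role,
                           counts_0 = counts_0, counts_t = counts_t)
  }))
  res
}

#' Metagene bin profile of the fraction of CPDs remaining
#'
#' Pools lesion counts across genes in each of the 12 metagene bins (3
#' upstream flank, 6 gene-body sextiles, 3 downstream flank; see
#' [gene_bins()]), separately for the transcribed strand (TS) and the
#' non-transcribed strand (NTS), and forms the fraction remaining
#' `counts_t / counts_0` per bin. Genes with body length below
#' `n_body_bins` bp or missing coordinates are excluded (the count of
#' exclusions is recorded). The default pools counts before taking the
#' ratio; `mode = "per_gene_mean"` averages per-gene fractions instead.
#'
#' @inheritParams fraction_remaining
#' @inheritParams gene_bins
#' @param mode `"pooled"` (default) or `"per_gene_mean"`.
#' @return an object of class `bin_profile`: `$table` (data.table of bin,
#'   region, strand_role, counts_0, counts_t, fraction, scaled_fraction),
#'   `$n_genes`, `$scale_factor` (1 until a scaling is applied),
#'   `$scaling`.
#' @export
bin_profile <- function(track_t, track_0, genes, flank_bin_bp = 167L,
                        n_body_bins = 6L, mode = c("pooled", "per_gene_mean")) {
  mode <- match.arg(mode)
  keep <- !is.na(genes$tss) & !is.na(genes$tes) &
    abs(genes$tes - genes$tss) >= n_body_bins
  n_excluded <- sum(!keep)
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0L) stop("all genes were filtered out")
  per_gene <- bin_count_table(track_t, track_0, genes, flank_bin_bp, n_body_bins)
  if (mode == "pooled") {
    tab <- per_gene[, list(counts_0 = sum(counts_0), counts_t = sum(counts_t)),
                    by = list(bin, region, strand_role)]
    tab[, fraction := ifelse(counts_0 > 0, counts_t / counts_0, NA_real_)]
  } else {
    tab <- per_gene[, list(
      counts_0 = sum(counts_0), counts_t = sum(counts_t),
      fraction = mean(ifelse(counts_0 > 0, counts_t / counts_0, NA_real_),
                      na.rm = TRUE)),
      by = list(bin, region, strand_role)]
    tab[, fraction := ifelse(is.nan(fraction), NA_real_, fraction)]
  }
  data.table::setorderv(tab, c("strand_role", "bin"))
  tab[, scaled_fraction := fraction]
  structure(
    list(table = tab[], n_genes = nrow(genes), n_excluded = n_excluded,
         scale_factor = 1, scaling = "none",
         flank_bin_bp = flank_bin_bp, n_body_bins = n_body_bins,
         mode = mode),
    class = "bin_profile")
}

#' @export
print.bin_profile <- function(x, ...) {
  cat(sprintf("bin_profile: %d genes (%d excluded), scaling = %s (factor %.4g)\n",
              x$n_genes, x$n_excluded, x$scaling, x$scale_factor))
  print(x$table)
  invisible(x)
}

#' Rescale repair fractions to a bulk (alkaline gel) measurement
#'
#' Sequencing-depth differences between the 0 hr and repair libraries make
#' raw count ratios relative, not absolute. This step multiplies every
#' regional fraction by `s = gel_fraction_remaining / (total_t / total_0)`
#' so that the genome-wide scaled fraction equals the gel-measured bulk
#' fraction exactly.
#'
#' @param x a [bin_profile()] or a numeric vector of raw fractions.
#' @param track_t,track_0 the tracks the fractions came from (used for the
#'   genome-wide totals).
#' @param gel_fraction_remaining bulk fraction of CPDs remaining measured
#'   by the alkaline gel assay, in (0, 1].
#' @return the same type as `x`, rescaled; for a `bin_profile` the
#'   `scaled_fraction` column, `scale_factor` and `scaling` are updated.
#'   For a numeric `x` the factor is attached as attribute
#'   `scale_factor`.
#' @export
gel_scale <- function(x, track_t, track_0, gel_fraction_remaining) {
  if (!(gel_fraction_remaining > 0 && gel_fraction_remaining <= 1)) {
    stop("gel_fraction_remaining must be in (0, 1]")
  }
  tot0 <- total_count(track_0)
  tott <- total_count(track_t)
  if (tot0 == 0L) stop("0 hr track has zero total count")
  s <- gel_fraction_remaining / (tott / tot0)
  if (inherits(x, "bin_profile")) {
    x$table <- data.table::copy(x$table)
    x$table[, scaled_fraction := fraction * s]
    x$scale_factor <- s
    x$scaling <- "gel"
    return(x)
  }
  out <- x * s
  attr(out, "scale_factor") <- s
  out
}

#' Rescale a bin profile so intergenic flank bins match a reference
#'
#' Computes the median, over the six flanking bins and both strand roles
#' (12 ratios), of `test / reference` raw fractions, and divides the test
#' profile by that median, so that the recomputed median flank-bin ratio
#' is exactly 1. Used when comparing libraries without a gel anchor (the
#' flanking intergenic DNA acts as an internal control).
#'
#' @param test,ref [bin_profile()]s built with the same bin layout.
#' @return the rescaled `test` profile (`scale_factor` = 1/m, `scaling` =
#'   `"intergenic_median"`), with the median ratio `m` attached as
#'   attribute `median_ratio`.
#' @export
intergenic_median_scale <- function(test, ref) {
  stopifnot(inherits(test, "bin_profile"), inherits(ref, "bin_profile"))
  key <- c("bin", "strand_role")
  ft <- test$table[region != "body", c(key, "fraction"), with = FALSE]
  fr <- ref$table[region != "body", c(key, "fraction"), with = FALSE]
  data.table::setnames(fr, "fraction", "fraction_ref")
  m_tab <- merge(ft, fr, by = key)
  bad <- m_tab[is.na(fraction_ref) | fraction_ref == 0]
  if (nrow(bad)) {
    stop("reference flank bin(s) undefined or zero: ",
         paste(sprintf("bin %d %s", bad$bin, bad$strand_role), collapse = ", "))
  }
  m <- stats::median(m_tab$fraction / m_tab$fraction_ref, na.rm = TRUE)
  test$table <- data.table::copy(test$table)
  test$table[, scaled_fraction := fraction / m]
  test$scale_factor <- 1 / m
  test$scaling <- "intergenic_median"
  attr(test, "median_ratio") <- m
  test
}

#' Repair asymmetry: log2 TS/NTS fraction remaining per bin
#'
#' Negative values indicate faster repair of the transcribed strand
#' (active TC-NER); values nearer zero indicate reduced asymmetry. The
#' statistic is invariant under any common scale factor, so gel scaling
#' cancels. Bins where either strand's fraction is undefined or zero
#' yield `NA`.
#'
#' @param profile a [bin_profile()].
#' @return data.frame with columns `bin`, `region`, `log2_ts_nts`.
#' @export
asymmetry <- function(profile) {
  stopifnot(inherits(profile, "bin_profile"))
  wide <- data.table::dcast(profile$table, bin + region ~ strand_role,
                            value.var = "scaled_fraction")
  wide[, log2_ts_nts := ifelse(!is.na(TS) & !is.na(NTS) & TS > 0 & NTS > 0,
                               log2(TS / NTS), NA_real_)]
  as.data.frame(wide[, list(bin, region, log2_ts_nts)])
}

#' Single-nucleotide repair profile around the TSS
#'
#' Pools lesion counts across genes at each offset relative to the TSS
#' (gene-strand orientation; minus-strand genes are mirrored), separately
#' for the TS and NTS, and forms the per-offset fraction remaining.
#' Counts (numerator and denominator) are optionally smoothed with a
#' centered moving average of odd width before the ratio is taken. Mean
#' nucleosome dyad coverage per offset is attached when dyads are given.
#'
#' @inheritParams fraction_remaining
#' @param genes gene annotation data.frame with `tss` and `strand`.
#' @param window integer pair: offsets relative to the TSS (must contain 0).
#' @param smooth odd moving-average width in nt (1 = off).
#' @param dyads optional data.table of dyad positions (`chrom`, `pos`,
#'   `count`).
#' @param scale_factor multiplier applied to the fractions (e.g. from
#'   [gel_scale()]).
#' @return an object of class `tss_profile`: `$profile` (data.table of
#'   offset, strand_role, counts_0, counts_t, fraction), `$dyad_coverage`
#'   (data.table of offset, coverage, or NULL), `$n_genes`, `$smooth`.
#' @export
tss_profile <- function(track_t, track_0, genes, window = c(-200L, 1000L),
                        smooth = 11L, dyads = NULL, scale_factor = 1) {
  stopifnot(length(window) == 2L, window[1] <= 0, window[2] >= 0)
  keep <- !is.na(genes$tss) & genes$strand %in% c("+", "-")
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0L) stop("no genes with TSS and strand")
  offsets <- seq.int(window[1], window[2])
  n_off <- length(offsets)
  acc <- list(
    TS  = list(c0 = numeric(n_off), ct = numeric(n_off)),
    NTS = list(c0 = numeric(n_off), ct = numeric(n_off)))
  dy_acc <- numeric(n_off)
  dense_t <- dense_0 <- dense_dy <- list()
  for (ch in unique(genes$chrom)) {
    dense_0[[ch]] <- list(`+` = track_dense(track_0, ch, "+"),
                          `-` = track_dense(track_0, ch, "-"))
    dense_t[[ch]] <- list(`+` = track_dense(track_t, ch, "+"),
                          `-` = track_dense(track_t, ch, "-"))
    if (!is.null(dyads)) {
      v <- numeric(track_0$seqlengths[[ch]])
      dsub <- dyads[dyads$chrom == ch]
      if (nrow(dsub) > 0L) v[dsub$pos + 1L] <- dsub$count
      dense_dy[[ch]] <- v
    }
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    L <- track_0$seqlengths[[g$chrom]]
    pos <- if (g$strand == "+") g$tss + offsets else g$tss - offsets
    ok <- pos >= 0L & pos < L
    idx <- pos[ok] + 1L
    ts_strand <- if (g$strand == "+") "-" else "+"
    acc$TS$c0[ok] <- acc$TS$c0[ok] + dense_0[[g$chrom]][[ts_strand]][idx]
    acc$TS$ct[ok] <- acc$TS$ct[ok] + dense_t[[g$chrom]][[ts_strand]][idx]
    acc$NTS$c0[ok] <- acc$NTS$c0[ok] + dense_0[[g$chrom]][[g$strand]][idx]
    acc$NTS$ct[ok] <- acc$NTS$ct[ok] + dense_t[[g$chrom]][[g$strand]][idx]
    if (!is.null(dyads)) {
      dy_acc[ok] <- dy_acc[ok] + dense_dy[[g$chrom]][idx]
    }
  }
  prof <- data.table::rbindlist(lapply(c("TS", "NTS"), function(role) {
    c0 <- acc[[role]]$c0
    ct <- acc[[role]]$ct
    c0s <- moving_average(c0, smooth)
    cts <- moving_average(ct, smooth)
    data.table::data.table(
      offset = offsets, strand_role = role, counts_0 = c0, counts_t = ct,
      fraction = ifelse(c0s > 0, cts / c0s * scale_factor, NA_real_))
  }))
  dyc <- if (!is.null(dyads)) {
    data.table::data.table(offset = offsets, coverage = dy_acc / nrow(genes))
  } else NULL
  structure(list(profile = prof[], dyad_coverage = dyc,
                 n_genes = nrow(genes), smooth = smooth,
                 scale_factor = scale_factor),
            class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf("tss_profile: %d genes, offsets %d..%d, smoothing %d nt\n",
              x$n_genes, min(x$profile$offset), max(x$profile$offset), x$smooth))
  invisible(x)
}

#' Gene-by-bin repair matrix
#'
#' Per-gene, per-bin fractions of CPDs remaining (per-gene denominators),
#' for both strand roles, ordered for heatmap display. With a
#' `reference` pair of tracks, each cell is the difference
#' `fraction_test - fraction_ref` (both sides multiplied by their scale
#' factors first; difference matrices require identically scaled inputs).
#'
#' @inheritParams bin_profile
#' @param order_by ordering key: `"transcription_rate"` (descending),
#'   `"expr_log2fc"` (ascending) or `"srat_first"` (SRAT genes first, then
#'   descending transcription rate). Genes missing the key are placed
#'   last.
#' @param reference optional list `list(track_t =, track_0 =)` for a
#'   difference matrix.
#' @param scale_factor,ref_scale_factor multipliers applied to the test
#'   and reference fractions.
#' @return an object of class `gene_repair_matrix`: `$matrix` (genes x
#'   24 columns `TS_1..TS_12, NTS_1..NTS_12`), `$genes` (annotation in row
#'   order), `$order_by`, `$is_difference`.
#' @export
gene_matrix <- function(track_t, track_0, genes,
                        order_by = c("transcription_rate", "expr_log2fc",
                                     "srat_first"),
                        reference = NULL, scale_factor = 1,
                        ref_scale_factor = 1,
                        flank_bin_bp = 167L, n_body_bins = 6L) {
  order_by <- match.arg(order_by)
  keep <- !is.na(genes$tss) & !is.na(genes$tes) &
    abs(genes$tes - genes$tss) >= n_body_bins
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0L) stop("all genes were filtered out")
  cell_fractions <- function(tt, t0, s) {
    pg <- bin_count_table(tt, t0, genes, flank_bin_bp, n_body_bins)
    pg[, fraction := ifelse(counts_0 > 0, counts_t / counts_0 * s, NA_real_)]
    wide <- data.table::dcast(pg, gene_id ~ strand_role + bin,
                              value.var = "fraction")
    wide
  }
  w <- cell_fractions(track_t, track_0, scale_factor)
  if (!is.null(reference)) {
    wr <- cell_fractions(reference$track_t, reference$track_0, ref_scale_factor)
    stopifnot(identical(w$gene_id, wr$gene_id))
    for (cn in setdiff(names(w), "gene_id")) {
      w[[cn]] <- w[[cn]] - wr[[cn]]
    }
  }
  n_bins <- n_body_bins + 6L
  col_order <- c(paste0("TS_", seq_len(n_bins)), paste0("NTS_", seq_len(n_bins)))
  m <- as.matrix(w[, col_order, with = FALSE])
  rownames(m) <- w$gene_id
  m <- m[genes$gene_id, , drop = FALSE]
  key <- switch(order_by,
                transcription_rate = order(-xtfrm(genes$transcription_rate),
                                           genes$gene_id, na.last = TRUE),
                expr_log2fc = order(xtfrm(genes$expr_log2fc),
                                    genes$gene_id, na.last = TRUE),
                srat_first = order(genes$srat_class == "none",
                                   -xtfrm(genes$transcription_rate),
                                   genes$gene_id, na.last = TRUE))
  n_missing <- switch(order_by,
                      transcription_rate = sum(is.na(genes$transcription_rate)),
                      expr_log2fc = sum(is.na(genes$expr_log2fc)),
                      srat_first = 0L)
  if (n_missing > 0L) {
    message(n_missing, " gene(s) missing the ordering covariate; placed last")
  }
  structure(list(matrix = m[key, , drop = FALSE],
                 genes = genes[key, , drop = FALSE],
                 order_by = order_by,
                 is_difference = !is.null(reference),
                 n_body_bins = n_body_bins),
            class = "gene_repair_matrix")
}

#' @export
print.gene_repair_matrix <- function(x, ...) {
  cat(sprintf("gene_repair_matrix: %d genes x %d bins (%s), ordered by %s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$is_difference) "differences" else "fractions", x$order_by))
  invisible(x)
}

#' Write a gene repair matrix as CDT text
#'
#' Clustered-data-table text compatible with tree-view heatmap viewers
#' (GID/UID/NAME/GWEIGHT header columns, EWEIGHT row).
#'
#' @param x a [gene_matrix()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cdt <- function(x, path) {
  stopifnot(inherits(x, "gene_repair_matrix"))
  m <- x$matrix
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("GID", "UID", "NAME", "GWEIGHT", colnames(m)),
                   collapse = "\t"), con)
  writeLines(paste(c("EWEIGHT", "", "", "",
                     rep("1", ncol(m))), collapse = "\t"), con)
  ids <- rownames(m)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(paste0("GENE", i, "X"), ids[i], ids[i], "1",
            formatC(m[i, ], format = "g", digits = 6)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Per-bin SRAT versus rest-of-genome contrast
#'
#' For a gene repair (difference) matrix, compares the mean cell value of
#' SRAT-flagged genes with that of the remaining genes in each gene-body
#' bin on the chosen strand role, with a nonparametric bootstrap
#' confidence interval for the contrast (genes resampled within groups).
#'
#' @param x a [gene_matrix()] result (typically a difference matrix).
#' @param srat a logical vector (one per row of `x$matrix`) or NULL to use
#'   `x$genes$srat_class != "none"`.
#' @param role `"NTS"` (default) or `"TS"`.
#' @param n_boot bootstrap draws.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return data.frame with columns `bin`, `mean_srat`, `mean_rest`,
#'   `contrast`, `ci_lo`, `ci_hi`, `n_srat`, `n_rest`.
#' @export
srat_contrast <- function(x, srat = NULL, role = c("NTS", "TS"),
                          n_boot = 1000L, conf = 0.95, seed = 1L) {
  stopifnot(inherits(x, "gene_repair_matrix"))
  role <- match.arg(role)
  if (is.null(srat)) srat <- x$genes$srat_class != "none"
  stopifnot(length(srat) == nrow(x$matrix))
  if (sum(srat) == 0L || sum(!srat) == 0L) {
    stop("both the SRAT group and the rest must contain at least one gene")
  }
  body_bins <- 3L + seq_len(x$n_body_bins)
  cols <- paste0(role, "_", body_bins)
  a <- (1 - conf) / 2
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_along(cols), function(j) {
      v <- x$matrix[, cols[j]]
      vs <- v[srat]
      vr <- v[!srat]
      obs <- mean(vs, na.rm = TRUE) - mean(vr, na.rm = TRUE)
      boot <- vapply(seq_len(n_boot), function(b) {
        mean(sample(vs, replace = TRUE), na.rm = TRUE) -
          mean(sample(vr, replace = TRUE), na.rm = TRUE)
      }, numeric(1))
      ci <- stats::quantile(boot, c(a, 1 - a), na.rm = TRUE, names = FALSE)
      data.frame(bin = body_bins[j],
                 mean_srat = mean(vs, na.rm = TRUE),
                 mean_rest = mean(vr, na.rm = TRUE),
                 contrast = obs, ci_lo = ci[1], ci_hi = ci[2],
                 n_srat = sum(!is.na(vs)), n_rest = sum(!is.na(vr)))
    }))
    out
  })
}

#' Dominant periodicity of a single-nucleotide repair profile
#'
#' Detects nucleosome-periodic repair modulation in a per-offset fraction
#' series: the series is detrended by subtracting a centered moving
#' average of `detrend_width` (one nucleosome repeat, so a periodic
#' component of that repeat survives detrending while slower trends are
#' removed) and its autocorrelation is computed and lightly smoothed. The
#' period is scored as the autocorrelation at the candidate lag plus at
#' its second harmonic (twice the lag), which sharpens the peak against
#' broadband noise; the best lag within `lag_range` is returned together
#' with the autocorrelation value at that lag. A constant series (no
#' modulation at all) returns `NA` for both.
#'
#' @param fraction numeric per-offset fraction series (NAs dropped).
#' @param lag_range integer pair: lags searched for the peak (bp).
#' @param detrend_width moving-average width used for detrending (bp;
#'   set to the expected repeat).
#' @param acf_smooth odd width of the moving average applied to the
#'   autocorrelation before peak picking.
#' @return named numeric vector `c(lag, value)`.
#' @export
profile_periodicity <- function(fraction, lag_range = c(100L, 250L),
                                detrend_width = 165L, acf_smooth = 11L) {
  x <- fraction[!is.na(fraction)]
  if (length(x) < 2L * lag_range[2] || stats::sd(x) == 0) {
    return(c(lag = NA_real_, value = NA_real_))
  }
  if (detrend_width %% 2L == 0L) detrend_width <- detrend_width + 1L
  det <- x - moving_average(x, detrend_width)
  lag_max <- min(2L * lag_range[2], length(det) - 1L)
  ac <- stats::acf(det, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1L]
  acs <- moving_average(ac, acf_smooth)
  lags <- seq.int(lag_range[1], lag_range[2])
  score <- vapply(lags, function(p) {
    acs[p] + if (2L * p <= lag_max) acs[2L * p] else 0
  }, numeric(1))
  best <- lags[which.max(score)]
  c(lag = best, value = acs[best])
}

#' Write a bin profile or asymmetry table as TSV
#' @param x a [bin_profile()], [tss_profile()] or data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table_tsv <- function(x, path) {
  tab <- if (inherits(x, "bin_profile")) x$table
  else if (inherits(x, "tss_profile")) x$profile
  else x
  data.table::fwrite(as.data.frame(tab), path, sep = "\t")
  invisible(path)
}
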