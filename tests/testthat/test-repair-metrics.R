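test_that("regional fraction remaining is a simple counts ratio with NA guards", {
  sl <- c(chr1 = 1000L)
  t0 <- toy_track(list(list("chr1", 10, "+", 60L), list("chr1", 500, "+", 5L)), sl)
  tt <- toy_track(list(list("chr1", 10, "+", 30L), list("chr1", 500, "+", 5L)), sl)
  regions <- data.frame(chrom = "chr1", start = c(0L, 400L, 600L),
                        end = c(100L, 600L, 700L), strand = "+")
  fr <- fraction_remaining(tt, t0, regions)
  expect_equal(fr$fraction, c(0.5, 1.0, NA))

  t_other <- toy_track(list(list("chr2", 10, "+", 1L)), c(chr2 = 100L))
  expect_error(fraction_remaining(t_other, t0, regions),
               "different chromosome sets")
})

test_that("metagene bin geometry: sextiles and 167-bp flanks flush to TSS/TES", {
  sl <- c(chr1 = 10000L)
  gplus <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 2000L, tes = 2600L)
  b <- gene_bins(gplus, sl)
  expect_equal(nrow(b), 12L)
  # upstream flanks, furthest first, flush to the TSS
  expect_equal(b$start[1:3], c(2000L - 501L, 2000L - 334L, 2000L - 167L))
  expect_equal(b$end[1:3], c(2000L - 334L, 2000L - 167L, 2000L))
  # six 100-bp body sextiles
  expect_equal(b$start[4:9], seq(2000L, 2500L, by = 100L))
  expect_equal(b$end[4:9], seq(2100L, 2600L, by = 100L))
  # downstream flanks flush to the TES
  expect_equal(b$start[10:12], c(2600L, 2767L, 2934L))
  expect_equal(b$end[10:12], c(2767L, 2934L, 3101L))

  # remainder rule: 601 bp body -> first sextile gets the extra bp
  g601 <- data.frame(gene_id = "g2", chrom = "chr1", strand = "+",
                     tss = 2000L, tes = 2601L)
  b601 <- gene_bins(g601, sl)
  expect_equal(b601$end[4:9] - b601$start[4:9], c(101L, rep(100L, 5)))

  # minus-strand gene occupying [2000, 2600): mirrored, flush on both sides
  gminus <- data.frame(gene_id = "g3", chrom = "chr1", strand = "-",
                       tss = 2599L, tes = 1999L)
  bm <- gene_bins(gminus, sl)
  # upstream bin 3 is immediately 3' of the TSS in genomic coordinates
  expect_equal(bm$start[3], 2600L)
  expect_equal(bm$end[3], 2767L)
  expect_equal(bm$start[1], 2934L)
  # body covers [2000, 2600) in 100-bp steps, bin 4 nearest the TSS
  expect_equal(bm$start[4], 2500L)
  expect_equal(bm$end[4], 2600L)
  expect_equal(bm$start[9], 2000L)
  # downstream bin 10 flush below the gene start
  expect_equal(bm$end[10], 2000L)
  expect_equal(bm$start[10], 1833L)
})

test_that("pooled bin counts partition gene-body lesions exactly", {
  sim <- generate_genome_and_genes(small_config(seed = 23L))
  ex <- simulate_experiment(sim, "WT", timepoints = 2, seed = 23L)
  prof <- bin_profile(ex$observed_t[["2"]], ex$observed_0, sim$genes)
  body <- prof$table[prof$table$region == "body", ]

  # oracle: direct summation over each gene body from the raw counts table
  counts0 <- ex$observed_0$counts
  in_body <- 0L
  for (i in seq_len(nrow(sim$genes))) {
    g <- sim$genes[i, ]
    sel <- counts0$chrom == g$chrom & counts0$pos >= g$start &
      counts0$pos < g$end
    in_body <- in_body + sum(counts0$count[sel])
  }
  expect_equal(sum(body$counts_0), in_body)
})

test_that("gel scaling anchors the genome-wide fraction to the gel value", {
  sl <- c(chr1 = 1000L)
  t0 <- toy_track(list(list("chr1", 10, "+", 100L)), sl)
  tt <- toy_track(list(list("chr1", 10, "+", 50L)), sl)
  raw <- 0.5
  scaled <- gel_scale(raw, tt, t0, gel_fraction_remaining = 0.4)
  expect_equal(attr(scaled, "scale_factor"), 0.8)
  expect_equal(as.numeric(scaled), 0.4)

  noop <- gel_scale(raw, tt, t0, gel_fraction_remaining = 0.5)
  expect_equal(attr(noop, "scale_factor"), 1)

  expect_error(gel_scale(raw, tt, t0, gel_fraction_remaining = 0),
               "in \\(0, 1\\]")
  empty0 <- lesion_track(NULL, sl)
  expect_error(gel_scale(raw, tt, empty0, 0.5), "zero total")

  # on simulated data with depth-mismatched libraries the scaled
  # genome-wide fraction recovers the true survival
  sim <- generate_genome_and_genes(small_config(seed = 29L))
  ex <- simulate_experiment(sim, "WT", timepoints = 2, seed = 29L)
  truth <- ex$bulk_fraction_remaining[["2"]]
  obs0 <- sample_reads(ex$lesions_0, depth = total_count(ex$lesions_0) / 2,
                       seed = 1L)   # 0 hr at half depth: raw ratio inflated
  obst <- ex$lesions_t[["2"]]
  raw_gw <- total_count(obst) / total_count(obs0)
  expect_gt(raw_gw, truth)  # depth mismatch distorts the raw ratio
  scaled_gw <- gel_scale(raw_gw, obst, obs0, truth)
  expect_equal(as.numeric(scaled_gw), truth)
})

test_that("intergenic-median scaling sets the median flank ratio to one", {
  sim <- generate_genome_and_genes(small_config(seed = 31L))
  ex <- simulate_experiment(sim, "WT", timepoints = 2, seed = 31L)
  ref <- bin_profile(ex$observed_t[["2"]], ex$observed_0, sim$genes)

  self <- intergenic_median_scale(ref, ref)
  expect_equal(attr(self, "median_ratio"), 1)
  expect_equal(self$table$scaled_fraction, ref$table$fraction)

  # doubled test profile scales back to the reference
  doubled <- ref
  doubled$table <- data.table::copy(ref$table)
  doubled$table$fraction <- ref$table$fraction * 2
  halved <- intergenic_median_scale(doubled, ref)
  expect_equal(attr(halved, "median_ratio"), 2)
  expect_equal(halved$table$scaled_fraction, ref$table$fraction)

  # uneven flank ratios: the recomputed median is exactly 1
  uneven <- ref
  uneven$table <- data.table::copy(ref$table)
  fac <- rep(c(0.8, 1.0, 1.25, 1.0, 0.9, 1.1), 4)
  flank <- uneven$table$region != "body"
  uneven$table$fraction[flank] <- ref$table$fraction[flank] * fac[seq_len(sum(flank))]
  sc <- intergenic_median_scale(uneven, ref)
  ratios <- sc$table$scaled_fraction[flank] / ref$table$fraction[flank]
  expect_equal(median(ratios), 1)

  # undefined reference flank bins are an error that names the bins
  broken <- ref
  broken$table <- data.table::copy(ref$table)
  broken$table$fraction[broken$table$bin == 1 &
                          broken$table$strand_role == "TS"] <- 0
  expect_error(intergenic_median_scale(uneven, broken), "bin 1 TS")
})

test_that("asymmetry is the log2 TS/NTS ratio and is scale invariant", {
  sim <- generate_genome_and_genes(small_config(seed = 37L))
  ex <- simulate_experiment(sim, "WT", timepoints = 2, seed = 37L)
  prof <- bin_profile(ex$observed_t[["2"]], ex$observed_0, sim$genes)

  hand <- prof
  hand$table <- data.table::copy(prof$table)
  hand$table$scaled_fraction[hand$table$strand_role == "TS"] <- 0.3
  hand$table$scaled_fraction[hand$table$strand_role == "NTS"] <- 0.6
  a <- asymmetry(hand)
  expect_equal(a$log2_ts_nts, rep(-1, 12))
  hand$table$scaled_fraction[] <- 0.4
  expect_equal(asymmetry(hand)$log2_ts_nts, rep(0, 12))

  before <- asymmetry(prof)
  after <- asymmetry(gel_scale(prof, ex$observed_t[["2"]], ex$observed_0, 0.37))
  expect_equal(after, before)
})

test_that("bin fractions match hand-computed ratios on a two-gene toy genome", {
  sl <- c(chr1 = 2000L)
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "-"),
                      tss = c(300L, 1699L), tes = c(900L, 1099L))
  set.seed(51)
  mk <- function(n) {
    toy_track(lapply(seq_len(n), function(i)
      list("chr1", sample(0:1999, 1), sample(c("+", "-"), 1),
           sample(1:3, 1))), sl)
  }
  t0 <- mk(300)
  tt <- mk(150)
  prof <- bin_profile(tt, t0, genes)
  bins <- gene_bins(genes, sl)

  # independent oracle: loop over bins and sum rows of the raw tables
  sum_in <- function(track, ch, s, a, b) {
    rows <- track$counts
    sum(rows$count[rows$chrom == ch & rows$strand == s &
                     rows$pos >= a & rows$pos < b])
  }
  for (bin_i in 1:12) {
    for (role in c("TS", "NTS")) {
      n0 <- nt <- 0
      for (j in which(bins$bin == bin_i)) {
        s <- if (role == "NTS") bins$gene_strand[j] else
          ifelse(bins$gene_strand[j] == "+", "-", "+")
        n0 <- n0 + sum_in(t0, bins$chrom[j], s, bins$start[j], bins$end[j])
        nt <- nt + sum_in(tt, bins$chrom[j], s, bins$start[j], bins$end[j])
      }
      got <- prof$table$fraction[prof$table$bin == bin_i &
                                   prof$table$strand_role == role]
      expect_equal(got, if (n0 > 0) nt / n0 else NA_real_,
                   label = sprintf("bin %d %s", bin_i, role))
    }
  }
})

test_that("TSS profiles pool counts in gene orientation with mirroring", {
  sl <- c(chr1 = 5000L)
  gene <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                     tss = 1000L, tes = 2000L)
  # lesion at TSS offset +10 on the TS (minus strand for a plus gene)
  t0 <- toy_track(list(list("chr1", 1010L, "-", 4L)), sl)
  tt <- lesion_track(NULL, sl)
  pr <- tss_profile(tt, t0, gene, smooth = 1L)
  ts <- pr$profile[pr$profile$strand_role == "TS", ]
  expect_equal(ts$fraction[ts$offset == 10], 0)
  expect_true(all(is.na(ts$fraction[ts$offset != 10])))

  # mirrored minus-strand twin gives the identical profile
  gene_m <- data.frame(gene_id = "g", chrom = "chr1", strand = "-",
                       tss = 3999L, tes = 2999L)
  t0_m <- toy_track(list(list("chr1", 3989L, "+", 4L)), sl)
  pr_m <- tss_profile(tt, t0_m, gene_m, smooth = 1L)
  expect_equal(as.data.frame(pr_m$profile), as.data.frame(pr$profile))

  expect_error(tss_profile(tt, t0, gene, window = c(100L, 1000L)),
               "window")
})

test_that("gene matrices honour covariate ordering and reference differencing", {
  sim <- generate_genome_and_genes(small_config(seed = 41L))
  genes <- sim$genes[1:3, ]
  genes$transcription_rate <- c(5, 1, 10)
  ex <- simulate_experiment(sim, "WT", timepoints = 2, seed = 41L)
  gm <- gene_matrix(ex$observed_t[["2"]], ex$observed_0, genes)
  expect_equal(gm$genes$gene_id,
               genes$gene_id[c(3, 1, 2)])
  expect_equal(sort(rownames(gm$matrix)), sort(genes$gene_id))

  self_diff <- gene_matrix(
    ex$observed_t[["2"]], ex$observed_0, genes,
    reference = list(track_t = ex$observed_t[["2"]], track_0 = ex$observed_0))
  vals <- self_diff$matrix[!is.na(self_diff$matrix)]
  expect_true(all(vals == 0))
})

test_that("SRAT contrast recovers constructed group shifts with bootstrap CIs", {
  make_gm <- function(m, srat) {
    genes <- data.frame(gene_id = rownames(m),
                        srat_class = ifelse(srat, "polyA", "none"))
    structure(list(matrix = m, genes = genes, order_by = "srat_first",
                   is_difference = TRUE, n_body_bins = 6L),
              class = "gene_repair_matrix")
  }
  cols <- c(paste0("TS_", 1:12), paste0("NTS_", 1:12))
  m <- matrix(0.5, nrow = 40, ncol = 24,
              dimnames = list(sprintf("g%02d", 1:40), cols))
  srat <- rep(c(TRUE, FALSE), each = 20)

  same <- srat_contrast(make_gm(m, srat), n_boot = 50L, seed = 1L)
  expect_equal(same$contrast, rep(0, 6))

  m2 <- m
  m2[srat, paste0("NTS_", 4:9)] <- m2[srat, paste0("NTS_", 4:9)] - 0.1
  shifted <- srat_contrast(make_gm(m2, srat), n_boot = 50L, seed = 1L)
  expect_equal(shifted$contrast, rep(-0.1, 6))

  expect_error(srat_contrast(make_gm(m, rep(TRUE, 40))), "both")
})

test_that("bootstrap CI coverage tracks the normal-theory interval", {
  # Gaussian cells, one body bin: compare empirical coverage of the
  # bootstrap percentile interval with the normal-theory oracle
  n_s <- 25L
  n_r <- 35L
  true_contrast <- -0.08
  cols <- "NTS_4"
  make_gm1 <- function(vals, srat) {
    m <- matrix(vals, ncol = 1, dimnames = list(NULL, cols))
    structure(list(matrix = m,
                   genes = data.frame(gene_id = seq_along(vals),
                                      srat_class = ifelse(srat, "polyA", "none")),
                   order_by = "srat_first", is_difference = TRUE,
                   n_body_bins = 1L),
              class = "gene_repair_matrix")
  }
  srat <- c(rep(TRUE, n_s), rep(FALSE, n_r))
  set.seed(61)
  cover_boot <- cover_norm <- logical(200)
  for (r in 1:200) {
    vals <- c(rnorm(n_s, true_contrast, 0.05), rnorm(n_r, 0, 0.05))
    sc <- srat_contrast(make_gm1(vals, srat), n_boot = 400L, seed = r)
    cover_boot[r] <- sc$ci_lo <= true_contrast & true_contrast <= sc$ci_hi
    se <- sqrt(var(vals[srat]) / n_s + var(vals[!srat]) / n_r)
    d <- mean(vals[srat]) - mean(vals[!srat])
    cover_norm[r] <- abs(d - true_contrast) <= qnorm(0.975) * se
  }
  expect_gt(mean(cover_boot), 0.88)
  expect_lte(mean(cover_boot), 1)
  expect_lt(abs(mean(cover_boot) - mean(cover_norm)), 0.07)
})

test_that("CDT export is a readable matrix with the expected layout", {
  sim <- generate_genome_and_genes(small_config(seed = 43L))
  ex <- simulate_experiment(sim, "WT", timepoints = 2, seed = 43L)
  gm <- gene_matrix(ex$observed_t[["2"]], ex$observed_0, sim$genes)
  path <- withr::local_tempfile(fileext = ".cdt")
  write_cdt(gm, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2L + nrow(gm$matrix))
  header <- strsplit(lines[1], "\t")[[1]]
  expect_equal(header[1:4], c("GID", "UID", "NAME", "GWEIGHT"))
  expect_equal(header[-(1:4)], colnames(gm$matrix))
  row1 <- strsplit(lines[3], "\t")[[1]]
  expect_equal(row1[2], rownames(gm$matrix)[1])
})
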