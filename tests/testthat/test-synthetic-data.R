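test_that("genome and gene generation honours counts, flags and determinism", {
  cfg <- small_config(seed = 7L)

  empty <- generate_genome_and_genes(sim_config(seed = 1L, n_genes = 0L,
                                                chrom_length = 5000L))
  expect_equal(nrow(empty$genes), 0L)
  expect_equal(unname(Biostrings::width(empty$genome)), 5000L)

  a <- generate_genome_and_genes(cfg)
  b <- generate_genome_and_genes(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)
  expect_identical(a$dyads, b$dyads)

  cfg50 <- sim_config(seed = 2L, chrom_length = 100000L, n_genes = 50L,
                      gene_length_range = c(600L, 1200L),
                      intergenic_min = 200L, srat_fraction = 0.2)
  g50 <- generate_genome_and_genes(cfg50)
  expect_equal(sum(g50$genes$srat_class != "none"), 10L)

  # non-overlapping placement and in-bounds dyads
  ord <- order(a$genes$start)
  expect_true(all(diff(a$genes$start[ord]) > 0))
  expect_true(all(a$genes$end[ord][-nrow(a$genes)] <= a$genes$start[ord][-1]))
  expect_true(all(a$dyads$pos >= 0 & a$dyads$pos < cfg$chrom_length))

  expect_error(generate_genome_and_genes(
    sim_config(seed = 1L, chrom_length = 5000L, n_genes = 50L,
               gene_length_range = c(600L, 1200L))),
    "infeasible packing")
})

test_that("dyads start at the configured offset and repeat within gene bodies", {
  sim <- generate_genome_and_genes(small_config(seed = 11L))
  cfg <- sim$config
  g <- sim$genes[1, ]
  dy <- sim$dyads[sim$dyads$chrom == g$chrom &
                    sim$dyads$pos >= g$start & sim$dyads$pos < g$end, ]
  offs <- if (g$strand == "+") sort(dy$pos - g$tss) else sort(g$tss - dy$pos)
  expected <- seq(cfg$first_dyad_offset, g$end - g$start - 1L,
                  by = cfg$nuc_repeat)
  expect_equal(offs, expected)
})

test_that("lesion induction is dipyrimidine-restricted with the right frequency", {
  cfg <- small_config()

  zero <- cfg
  zero$induction_prob[] <- 0
  tr <- induce_lesions(toy_genome(chr1 = "ACGTACGTTT"), zero, seed = 1L)
  expect_equal(total_count(tr), 0L)

  one <- cfg
  one$induction_prob[] <- 0
  one$induction_prob["TT"] <- 1
  tr <- induce_lesions(toy_genome(chr1 = "TT"), one, seed = 1L)
  expect_equal(track_counts(tr),
               data.frame(chrom = "chr1", pos = 0L, strand = "+", count = 1L))

  # with p = 1 for all dipyrimidines every site carries a lesion: the track
  # positions must be exactly the census sites
  all_on <- cfg
  all_on$induction_prob[] <- 1
  gseq <- toy_genome(chr1 = "TTAGGCCATTCGA")
  tr <- induce_lesions(gseq, all_on, seed = 5L)
  census <- dipyrimidine_site_census(gseq)
  expect_equal(total_count(tr), sum(census$count))

  # frequency: mean lesion count over seeds within 3 binomial SDs of
  # n_sites * p, with TT-only induction and the site count enumerated by
  # an independent naive scan
  set.seed(42)
  g10k <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")
  nc <- naive_census(list(g10k))
  n_sites <- nc$plus[["TT"]] + nc$minus[["TT"]]
  p <- 0.01
  tt_only <- cfg
  tt_only$induction_prob[] <- 0
  tt_only$induction_prob["TT"] <- p
  counts <- vapply(1:200, function(s) {
    total_count(induce_lesions(toy_genome(chr1 = g10k), tt_only, seed = s))
  }, numeric(1))
  expected <- n_sites * p
  sd3 <- 3 * sqrt(n_sites * p * (1 - p) / 200)
  expect_lt(abs(mean(counts) - expected), sd3)
})

test_that("repair survival follows the configured exponential kinetics", {
  cfg <- sim_config(seed = 1L, chrom_length = 20000L, n_genes = 0L,
                    k_gg = 0.8, nuc_amplitude = 0)
  sim <- generate_genome_and_genes(cfg)
  # 10,000 independent lesions, all intergenic so k = k_gg = 0.8/hr
  tr0 <- toy_track(lapply(0:9999, function(p) list("chr1", p, "+", 1L)),
                   c(chr1 = 20000L), timepoint = 0)

  same <- simulate_repair(tr0, sim$genes, sim$dyads, cfg, "WT", t = 0, seed = 1L)
  expect_equal(track_counts(same), track_counts(tr0))

  rep2 <- simulate_repair(tr0, sim$genes, sim$dyads, cfg, "WT", t = 2, seed = 9L)
  surv <- total_count(rep2) / total_count(tr0)
  p_true <- exp(-1.6)
  expect_lt(abs(surv - p_true), 3 * sqrt(p_true * (1 - p_true) / 10000))

  # GG-NER-deficient preset: intergenic lesions are never repaired
  r16 <- simulate_repair(tr0, sim$genes, sim$dyads, cfg, "rad16", t = 5, seed = 2L)
  expect_equal(track_counts(r16), track_counts(tr0))

  expect_error(
    simulate_repair(tr0, sim$genes, sim$dyads, cfg, "nonsense", t = 1),
    "available presets.*WT")
})

test_that("depth thinning is binomial with the expected totals", {
  tr <- toy_track(lapply(seq(0, 990, by = 10), function(p)
    list("chr1", p, "+", 10L)), c(chr1 = 1000L))
  tot <- total_count(tr)  # 1000

  # depth >= total: identity
  same <- sample_reads(tr, depth = tot * 2, seed = 1L)
  expect_equal(track_counts(same), track_counts(tr))

  # mean observed total near depth
  depth <- tot / 2
  obs <- vapply(1:200, function(s) {
    total_count(sample_reads(tr, depth, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(obs) - depth), 3 * sqrt(tot * 0.5 * 0.5 / 200))

  # per-position expectation: count * p, against direct binomial simulation
  pos0 <- vapply(1:500, function(s) {
    out <- sample_reads(tr, depth, seed = s)
    sub <- out$counts[out$counts$pos == 0L]
    if (nrow(sub)) as.numeric(sub$count) else 0
  }, numeric(1))
  set.seed(99)
  oracle <- rbinom(500, 10L, 0.5)
  expect_lt(abs(mean(pos0) - mean(oracle)),
            4 * sqrt(10 * 0.5 * 0.5 / 500) * sqrt(2))
})

test_that("gel-curve simulation reports true totals ratios and percent repair", {
  sim <- generate_genome_and_genes(small_config(seed = 3L))
  ex <- simulate_experiment(sim, "WT", timepoints = 2, seed = 3L)

  noiseless <- simulate_gel_curve(ex, noise_sd = 0, seed = 1L)
  at0 <- noiseless[noiseless$timepoint == 0, ]
  expect_true(all(at0$fraction_remaining == 1))
  expect_true(all(at0$percent_repair == 0))
  at2 <- noiseless[noiseless$timepoint == 2, ]
  truth <- total_count(ex$lesions_t[["2"]]) / total_count(ex$lesions_0)
  expect_equal(unique(at2$fraction_remaining), truth)
  expect_equal(unique(at2$percent_repair), 100 * (1 - truth))

  # complete repair: enormous rate drives every lesion out
  fast <- sim
  fast$config$k_gg <- 100
  exf <- simulate_experiment(fast, "WT", timepoints = 2, seed = 3L)
  gf <- simulate_gel_curve(exf, noise_sd = 0, seed = 1L)
  expect_equal(gf$percent_repair[gf$timepoint == 2], rep(100, 3))
})

test_that("lesion totals decay monotonically through nested timepoints", {
  sim <- generate_genome_and_genes(small_config(seed = 5L))
  ex <- simulate_experiment(sim, "WT", timepoints = c(1, 2, 3), seed = 5L)
  totals <- c(total_count(ex$lesions_0),
              vapply(ex$lesions_t, total_count, numeric(1)))
  expect_true(all(diff(totals) <= 0))
  expect_true(all(ex$bulk_fraction_remaining >= 0 &
                    ex$bulk_fraction_remaining <= 1))
  # per-position nesting: counts at 3 hr never exceed counts at 0 hr
  m <- merge(ex$lesions_t[["3"]]$counts, ex$lesions_0$counts,
             by = c("chrom", "pos", "strand"), suffixes = c("_t", "_0"))
  expect_equal(nrow(m), nrow(ex$lesions_t[["3"]]$counts))
  expect_true(all(m$count_t <= m$count_0))
})

test_that("strand asymmetry and the SRAT effect emerge from the presets", {
  sim <- generate_genome_and_genes(sim_config(seed = 8L))
  ex <- simulate_experiment(sim, "WT", timepoints = 2, seed = 8L)
  body <- gene_bins(sim$genes, sim$seqlengths)[region == "body"]
  sum_role <- function(track, role) {
    cache <- strandrepair:::track_cumsum(track)
    s <- if (role == "TS") ifelse(body$gene_strand == "+", "-", "+")
    else body$gene_strand
    total <- 0
    for (i in seq_len(nrow(body))) {
      total <- total + strandrepair:::interval_sum(
        cache, body$chrom[i], s[i], body$start[i], body$end[i])
    }
    total
  }
  f_ts <- sum_role(ex$lesions_t[["2"]], "TS") / sum_role(ex$lesions_0, "TS")
  f_nts <- sum_role(ex$lesions_t[["2"]], "NTS") / sum_role(ex$lesions_0, "NTS")
  expect_lt(f_ts, f_nts)

  # antisense TC-NER under the GG-NER-deficient set2-like preset repairs
  # the NTS of SRAT genes but not of the rest
  exd <- simulate_experiment(sim, "rad16set2", timepoints = 2, seed = 8L)
  nts_fraction <- function(genes_subset) {
    b <- gene_bins(genes_subset, sim$seqlengths)[region == "body"]
    ct <- strandrepair:::track_cumsum(exd$lesions_t[["2"]])
    c0 <- strandrepair:::track_cumsum(exd$lesions_0)
    num <- den <- 0
    for (i in seq_len(nrow(b))) {
      num <- num + strandrepair:::interval_sum(ct, b$chrom[i], b$gene_strand[i],
                                               b$start[i], b$end[i])
      den <- den + strandrepair:::interval_sum(c0, b$chrom[i], b$gene_strand[i],
                                               b$start[i], b$end[i])
    }
    num / den
  }
  srat <- sim$genes$srat_class != "none"
  expect_lt(nts_fraction(sim$genes[srat, ]), nts_fraction(sim$genes[!srat, ]))
})
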