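# Shared fixtures: tiny genomes, hand-built tracks and compact simulator
# configurations used across the test files.

toy_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# A lesion track from explicit (chrom, pos, strand, count) rows.
toy_track <- function(rows, seqlengths, timepoint = NA_real_) {
  lesion_track(do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], pos = as.integer(r[[2]]),
               strand = r[[3]], count = as.integer(r[[4]]))
  })), seqlengths = seqlengths, timepoint = timepoint)
}

# Compact simulator config for fast tests (40 kb genome, 12 genes).
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, chrom_length = 40000L, n_genes = 12L,
             gene_length_range = c(600L, 1500L), intergenic_min = 300L,
             srat_fraction = 0.25, ...)
}

# Naive per-strand dipyrimidine scan, independent of the package's
# Biostrings-based census: slides a 2-bp window over the sequence and its
# reverse complement.
naive_census <- function(seq_chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  scan_one <- function(s) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    out <- stats::setNames(rep(0L, 4L), c("TT", "TC", "CT", "CC"))
    if (n < 2L) return(out)
    for (i in seq_len(n - 1L)) {
      d <- paste0(chars[i], chars[i + 1L])
      if (d %in% names(out)) out[d] <- out[d] + 1L
    }
    out
  }
  rc <- function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  plus <- Reduce(`+`, lapply(seq_chars, scan_one))
  minus <- Reduce(`+`, lapply(seq_chars, function(s) scan_one(rc(s))))
  list(plus = plus, minus = minus)
}

# Normalized counts table for track equality assertions.
track_counts <- function(track) {
  dt <- data.table::copy(track$counts)
  data.table::setkeyv(dt, c("chrom", "strand", "pos"))
  as.data.frame(dt)
}
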