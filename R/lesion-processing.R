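#' Read aligned CPD-seq read 5'-end records
#'
#' Accepts either a BAM file or a 6-column BED-like table
#' (`chrom, start, end, name, count, strand`). The 5' terminus of a
#' plus-strand alignment spanning `[start, end)` is `start`; for a
#' minus-strand alignment it is `end - 1` (the rightmost aligned base).
#' Coordinates returned are 0-based.
#'
#' @param path path to a BAM or BED file (format inferred from the
#'   extension; override with `format`).
#' @param min_mapq drop alignments with mapping quality below this value
#'   (BAM only; records with missing MAPQ are kept when `min_mapq = 0`).
#' @param dedup collapse identical `(chrom, five_prime_pos, strand)`
#'   records into one record with summed counts. Off by default: repeated
#'   lesions at hotspots are signal.
#' @param format `"bam"` or `"bed"`; default inferred from `path`.
#' @return data.frame of read records with columns `chrom`,
#'   `five_prime_pos`, `strand`, `count`.
#' @export
read_alignments <- function(path, min_mapq = 0, dedup = FALSE,
                            format = c("auto", "bam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  records <- if (format == "bam") {
    read_alignments_bam(path, min_mapq)
  } else {
    read_alignments_bed(path)
  }
  if (dedup && nrow(records) > 0L) {
    dt <- data.table::as.data.table(records)
    dt <- dt[, list(count = as.integer(sum(count))),
             by = list(chrom, five_prime_pos, strand)]
    records <- as.data.frame(dt)
  }
  records
}

read_alignments_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4, 6)))
  if (ncol(dt) < 6L) stop("BED input must have 6 columns: chrom, start, end, name, count, strand")
  data.table::setnames(dt, 1:6,
                       c("chrom", "start", "end", "name", "count", "strand"))
  bad <- which(!dt$strand %in% c("+", "-") |
                 is.na(suppressWarnings(as.integer(dt$count))) |
                 dt$count < 1 | is.na(dt$start) | is.na(dt$end) |
                 dt$end <= dt$start)
  if (length(bad)) {
    stop("malformed BED row(s) at line(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  data.frame(chrom = dt$chrom,
             five_prime_pos = as.integer(ifelse(dt$strand == "+",
                                                dt$start, dt$end - 1L)),
             strand = dt$strand,
             count = as.integer(dt$count),
             stringsAsFactors = FALSE)
}

# Reference-consuming CIGAR width (ops M, D, N, =, X).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    kind <- sub("^\\d+", "", ops)
    as.integer(sum(lens[kind %in% c("M", "D", "N", "=", "X")]))
  }, integer(1), USE.NAMES = FALSE)
}

read_alignments_bam <- function(path, min_mapq = 0) {
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  if (length(res$pos) == 0L) {
    return(data.frame(chrom = character(), five_prime_pos = integer(),
                      strand = character(), count = integer()))
  }
  mapq <- res$mapq
  keep <- is.na(mapq) & min_mapq <= 0 | (!is.na(mapq) & mapq >= min_mapq)
  width <- cigar_ref_width(res$cigar)
  start0 <- res$pos - 1L                       # BAM pos is 1-based leftmost
  strand <- as.character(res$strand)
  five <- ifelse(strand == "+", start0, start0 + width - 1L)
  out <- data.frame(chrom = as.character(res$rname),
                    five_prime_pos = as.integer(five),
                    strand = strand, count = 1L, stringsAsFactors = FALSE)
  out[keep & strand %in% c("+", "-"), , drop = FALSE]
}

#' Infer CPD lesion positions from read 5'-end records
#'
#' A CPD-seq read begins at the nucleotide immediately 3' of the cleaved
#' lesion on the strand opposite the damage, so the putative lesion
#' dinucleotide lies on the opposite strand, in the two bases immediately
#' upstream of the read's 5' end in read orientation:
#'
#' * plus-strand read with 5' end `p`: damaged strand is minus, genomic
#'   positions `(p - 2, p - 1)`, dinucleotide read 5' to 3' on the minus
#'   strand is `complement(base(p - 1)), complement(base(p - 2))`; the
#'   lesion is stored at `p - 1` (the 5'-most base on the minus strand).
#' * minus-strand read with 5' end `p`: damaged strand is plus, positions
#'   `(p + 1, p + 2)`, dinucleotide `base(p + 1), base(p + 2)`, stored at
#'   `p + 1`.
#'
#' Records whose inferred dinucleotide is not one of TT, TC, CT, CC, whose
#' dinucleotide contains N, or whose putative positions fall off the
#' chromosome are discarded and tallied; the tally is attached as
#' attribute `qc` (a data.frame of reasons and counts).
#'
#' @param records data.frame of read records (`chrom`, `five_prime_pos`,
#'   `strand`, `count`) from [read_alignments()] or [lesions_to_reads()].
#' @param genome a [Biostrings::DNAStringSet] or named character vector
#'   covering all chromosomes in `records`.
#' @param sample_id,timepoint passed to [lesion_track()].
#' @return a [lesion_track()] of dipyrimidine-filtered lesion counts.
#' @export
infer_lesions <- function(records, genome, sample_id = "sample",
                          timepoint = NA_real_) {
  g <- as_genome_chars(genome)
  sl <- genome_seqlengths(genome)
  missing_chrom <- setdiff(unique(records$chrom), names(g))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  }
  n <- nrow(records)
  if (n == 0L) {
    tr <- lesion_track(NULL, sl, sample_id = sample_id, timepoint = timepoint,
                       provenance = "inferred from 0 records")
    attr(tr, "qc") <- data.frame(
      reason = c("retained", "non_dipyrimidine", "off_chromosome", "contains_N"),
      n = 0L)
    return(tr)
  }
  p <- as.integer(records$five_prime_pos)
  plus_read <- records$strand == "+"
  L <- sl[records$chrom]
  lesion_pos <- ifelse(plus_read, p - 1L, p + 1L)
  lo <- ifelse(plus_read, p - 2L, p + 1L)   # lower genomic pos of the dinuc
  off <- lo < 0L | (lo + 1L) > (L - 1L) | p < 0L | p >= L

  dinuc <- rep(NA_character_, n)
  for (ch in unique(records$chrom)) {
    sel <- which(records$chrom == ch & !off)
    if (!length(sel)) next
    s <- g[[ch]]
    b1 <- substring(s, lo[sel] + 1L, lo[sel] + 1L)      # base at lower pos
    b2 <- substring(s, lo[sel] + 2L, lo[sel] + 2L)      # base at upper pos
    dinuc[sel] <- ifelse(plus_read[sel],
                         # minus-strand dinuc, 5' to 3': comp(upper), comp(lower)
                         paste0(COMPLEMENT[b2], COMPLEMENT[b1]),
                         paste0(b1, b2))
  }
  has_n <- !off & grepl("N", dinuc, fixed = TRUE)
  retained <- !off & !has_n & dinuc %in% PYRIMIDINE_DINUCS
  non_dipyr <- !off & !has_n & !retained
  cnt <- as.integer(records$count)
  qc <- data.frame(
    reason = c("retained", "non_dipyrimidine", "off_chromosome", "contains_N"),
    n = c(sum(cnt[retained]), sum(cnt[non_dipyr]), sum(cnt[off]),
          sum(cnt[has_n])))
  counts <- data.table::data.table(
    chrom = records$chrom[retained],
    pos = lesion_pos[retained],
    strand = ifelse(plus_read[retained], "-", "+"),
    count = cnt[retained])
  tr <- lesion_track(counts, sl, sample_id = sample_id, timepoint = timepoint,
                     provenance = sprintf("inferred from %d records (%d retained)",
                                          sum(cnt), qc$n[1]))
  attr(tr, "qc") <- qc
  tr
}

#' Exhaustive dipyrimidine site census of a genome
#'
#' Counts, per strand, the start positions of each dipyrimidine (TT, TC,
#' CT, CC). The minus-strand census is obtained from the plus-strand
#' counts of the reverse-complement dinucleotides (e.g. minus-strand TT
#' sites equal plus-strand AA sites), summed over chromosomes.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector.
#' @return data.frame with columns `strand`, `dinuc`, `count`.
#' @export
dipyrimidine_site_census <- function(genome) {
  g <- as_genome_chars(genome)
  if (any(nchar(g) == 0L)) stop("genome must be non-empty")
  tally <- function(targets) {
    sapply(targets, function(d) {
      sum(vapply(g, function(s) {
        if (nchar(s) < 2L) return(0L)
        length(Biostrings::matchPattern(d, Biostrings::DNAString(s)))
      }, numeric(1)))
    })
  }
  plus <- tally(PYRIMIDINE_DINUCS)
  minus <- tally(unname(PURINE_DINUCS))
  data.frame(
    strand = rep(c("+", "-"), each = length(PYRIMIDINE_DINUCS)),
    dinuc = rep(PYRIMIDINE_DINUCS, 2L),
    count = as.integer(c(plus, minus)),
    stringsAsFactors = FALSE)
}

#' Write the lesion-calling QC tally as TSV
#' @param track a [lesion_track()] from [infer_lesions()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_lesion_qc <- function(track, path) {
  qc <- attr(track, "qc")
  if (is.null(qc)) stop("track carries no QC tally (not built by infer_lesions)")
  data.table::fwrite(qc, path, sep = "\t")
  invisible(path)
}
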