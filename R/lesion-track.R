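#' Strand-specific lesion count track
#'
#' A `lesion_track` holds sparse per-position CPD counts for one sample and
#' timepoint, split by strand. Positions are 0-based and index the 5'-most
#' base of the lesion dinucleotide on the damaged strand, so a lesion on the
#' minus strand spanning genomic positions `(x, x + 1)` is stored at
#' `x + 1` (the higher coordinate is 5'-most on the minus strand).
#'
#' @param counts a data.frame with columns `chrom` (character), `pos`
#'   (0-based integer), `strand` (`"+"`/`"-"`) and `count` (positive
#'   integer). Duplicate `(chrom, pos, strand)` rows are summed.
#' @param seqlengths named integer vector of chromosome lengths.
#' @param sample_id sample label.
#' @param timepoint repair time in hours (`NA` if not applicable).
#' @param provenance free-text processing history (e.g. `"raw"`,
#'   `"thinned depth=1e5"`).
#'
#' @return An object of class `lesion_track`.
#' @export
lesion_track <- function(counts, seqlengths, sample_id = "sample",
                         timepoint = NA_real_, provenance = "raw") {
  dt <- data.table::as.data.table(counts)
  if (nrow(dt) == 0L) {
    dt <- data.table::data.table(chrom = character(), pos = integer(),
                                 strand = character(), count = integer())
  }
  required <- c("chrom", "pos", "strand", "count")
  if (!all(required %in% names(dt))) {
    stop("counts must have columns chrom, pos, strand, count")
  }
  dt <- dt[, list(count = as.integer(sum(count))),
           by = list(chrom = as.character(chrom), pos = as.integer(pos),
                     strand = as.character(strand))]
  dt <- dt[count > 0L]
  if (nrow(dt) > 0L) {
    if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    bad <- !dt$chrom %in% names(seqlengths)
    if (any(bad)) {
      stop("chromosomes missing from seqlengths: ",
           paste(unique(dt$chrom[bad]), collapse = ", "))
    }
    if (any(dt$pos < 0L) || any(dt$pos >= seqlengths[dt$chrom])) {
      stop("positions out of chromosome bounds")
    }
  }
  data.table::setkeyv(dt, c("chrom", "strand", "pos"))
  structure(
    list(counts = dt,
         seqlengths = stats::setNames(as.integer(seqlengths), names(seqlengths)),
         sample_id = sample_id,
         timepoint = timepoint,
         provenance = provenance),
    class = "lesion_track")
}

#' @export
print.lesion_track <- function(x, ...) {
  cat(sprintf("lesion_track '%s' (t = %s hr): %d positions, %d lesions on %d chromosome(s)\n",
              x$sample_id, format(x$timepoint), nrow(x$counts),
              total_count(x), length(x$seqlengths)))
  cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

#' Total lesion count in a track
#' @param track a [lesion_track()].
#' @return integer total of all per-position counts.
#' @export
total_count <- function(track) {
  stopifnot(inherits(track, "lesion_track"))
  if (nrow(track$counts) == 0L) return(0L)
  as.integer(sum(track$counts$count))
}

# Dense cumulative-sum cache for fast interval sums. For each
# (chrom, strand) stores cs of length L + 1 with cs[1] = 0, so the count in
# 0-based half-open [a, b) is cs[b + 1] - cs[a + 1].
track_cumsum <- function(track) {
  stopifnot(inherits(track, "lesion_track"))
  out <- list()
  for (ch in names(track$seqlengths)) {
    L <- track$seqlengths[[ch]]
    for (s in c("+", "-")) {
      v <- numeric(L)
      sub <- track$counts[list(ch, s)]
      if (nrow(sub) > 0L && !is.na(sub$pos[1L])) {
        v[sub$pos + 1L] <- sub$count
      }
      out[[ch]][[s]] <- c(0, cumsum(v))
    }
  }
  out
}

interval_sum <- function(cache, chrom, strand, start, end) {
  cs <- cache[[chrom]][[strand]]
  if (is.null(cs)) stop("chromosome ", chrom, " not in track")
  L <- length(cs) - 1L
  start <- pmax(start, 0L)
  end <- pmin(end, L)
  out <- cs[pmax(end, start) + 1L] - cs[start + 1L]
  out[end <= start] <- 0
  out
}

# Dense per-position count vector for one (chrom, strand); index pos + 1.
track_dense <- function(track, ch, s) {
  v <- numeric(track$seqlengths[[ch]])
  sub <- track$counts[list(ch, s)]
  if (nrow(sub) > 0L && !is.na(sub$pos[1L])) v[sub$pos + 1L] <- sub$count
  v
}

#' Write a lesion track as a strand-split bedGraph pair
#'
#' Writes `<prefix>.plus.bedgraph` and `<prefix>.minus.bedgraph`
#' (0-based half-open intervals of width one, value = lesion count).
#'
#' @param track a [lesion_track()].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths written.
#' @export
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
write_lesion_track <- function(track, prefix) {
  stopifnot(inherits(track, "lesion_track"))
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (s in c("+", "-")) {
    sub <- track$counts[strand == s]
    gr <- GenomicRanges::GRanges(
      seqnames = if (nrow(sub)) sub$chrom else character(),
      ranges = IRanges::IRanges(start = if (nrow(sub)) sub$pos + 1L else integer(),
                                width = 1L),
      score = if (nrow(sub)) as.numeric(sub$count) else numeric(),
      seqlengths = track$seqlengths)
    rtracklayer::export(gr, paths[[if (s == "+") "plus" else "minus"]],
                        format = "bedGraph")
  }
  invisible(paths)
}

#' Read a strand-split bedGraph pair into a lesion track
#'
#' @param prefix path prefix; `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` must exist.
#' @param seqlengths named integer vector of chromosome lengths.
#' @inheritParams lesion_track
#' @return a [lesion_track()].
#' @export
read_lesion_track <- function(prefix, seqlengths, sample_id = basename(prefix),
                              timepoint = NA_real_, provenance = "bedgraph") {
  parts <- list()
  for (s in c("+", "-")) {
    path <- paste0(prefix, if (s == "+") ".plus.bedgraph" else ".minus.bedgraph")
    if (!file.exists(path)) stop("missing bedGraph file: ", path)
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L) next
    # expand intervals wider than 1 bp to per-position rows
    pos <- unlist(lapply(seq_along(gr), function(i) {
      seq.int(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i] - 1L)
    }))
    chrom <- rep(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::width(gr))
    count <- rep(as.integer(gr$score), GenomicRanges::width(gr))
    parts[[s]] <- data.table::data.table(chrom = chrom, pos = pos,
                                         strand = s, count = count)
  }
  counts <- if (length(parts)) data.table::rbindlist(parts) else
    data.table::data.table(chrom = character(), pos = integer(),
                           strand = character(), count = integer())
  lesion_track(counts, seqlengths, sample_id = sample_id,
               timepoint = timepoint, provenance = provenance)
}
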