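# Internal helpers shared across modules.

PYRIMIDINE_DINUCS <- c("TT", "TC", "CT", "CC")
# reverse complements of the pyrimidine dinucleotides: a minus-strand
# dipyrimidine appears on the plus-strand reference as one of these
PURINE_DINUCS <- c(TT = "AA", TC = "GA", CT = "AG", CC = "GG")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' @importFrom Biostrings DNAStringSet reverseComplement
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalize a genome (DNAStringSet or named character vector) to a named
# uppercase character vector, one element per chromosome.
as_genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("genome sequences must be named by chromosome")
  }
  out
}

genome_seqlengths <- function(genome) {
  g <- as_genome_chars(genome)
  stats::setNames(nchar(g), names(g))
}

# Derive a stream-specific seed from one master seed; stays below 2^31.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) %% 65521) * 31627 + (salt %% 4001) * 97 + 1L)
}

# Centered moving average of odd width; ends are averaged over the
# available window (shrinking window, no NA padding).
moving_average <- function(x, width) {
  stopifnot(width >= 1, width %% 2 == 1)
  if (width == 1L || length(x) < 2L) return(x)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  ifelse(den > 0, num / den, NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
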