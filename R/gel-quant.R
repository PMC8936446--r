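#' Calibrate a gel lane profile to fragment lengths
#'
#' Converts a densitometry profile of (migration distance, intensity) to
#' (fragment length, intensity) using log-linear interpolation of the
#' ladder: migration distance is proportional to -log10(length), the
#' standard behaviour of electrophoretic mobility. Points outside the
#' ladder range are linearly extrapolated on the log scale with a warning.
#'
#' @param lane a list or data.frame-bearing object with elements `profile`
#'   (data.frame: `distance`, `intensity`) and `ladder` (data.frame:
#'   `distance`, `length` in the same length units used downstream, e.g.
#'   kb). Ladder must have at least two points and be strictly monotone in
#'   migration distance.
#' @return data.frame with columns `length` and `intensity`, one row per
#'   profile point.
#' @export
calibrate_lengths <- function(lane) {
  profile <- as.data.frame(lane$profile)
  ladder <- as.data.frame(lane$ladder)
  if (nrow(ladder) < 2L) stop("ladder needs at least 2 points")
  if (any(ladder$length <= 0)) stop("ladder lengths must be positive")
  ord <- order(ladder$distance)
  ladder <- ladder[ord, ]
  if (any(diff(ladder$distance) <= 0)) {
    stop("ladder migration distances must be strictly monotone")
  }
  if (any(diff(log10(ladder$length)) >= 0)) {
    stop("ladder lengths must decrease with migration distance")
  }
  if (any(profile$intensity < 0)) stop("intensities must be non-negative")
  if (any(diff(profile$distance) <= 0)) {
    stop("profile migration distances must be strictly ordered")
  }
  x <- ladder$distance
  y <- log10(ladder$length)
  out_of_range <- profile$distance < min(x) | profile$distance > max(x)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " profile point(s) outside the ladder range; extrapolated")
  }
  # linear interpolation in (distance, log10 length); linear extrapolation
  # using the terminal ladder segments
  interp <- function(d) {
    j <- findInterval(d, x, all.inside = TRUE)
    y[j] + (d - x[j]) * (y[j + 1L] - y[j]) / (x[j + 1L] - x[j])
  }
  data.frame(length = 10^interp(profile$distance),
             intensity = profile$intensity)
}

#' Number-average fragment length
#'
#' For a stained-gel intensity profile, intensity is proportional to DNA
#' mass, so molecule number in a length bin is `I / L` and the
#' number-average length is `Ln = sum(I) / sum(I / L)`.
#'
#' @param length_profile data.frame with columns `length` (> 0) and
#'   `intensity` (>= 0); any consistent length unit (result has the same
#'   unit).
#' @return the number-average length `Ln`.
#' @export
number_average_length <- function(length_profile) {
  L <- length_profile$length
  I <- length_profile$intensity
  if (any(L <= 0)) stop("all length bins must be positive")
  if (sum(I) <= 0) stop("total intensity must be positive")
  sum(I) / sum(I / L)
}

#' Lesion frequency from digested and undigested number-average lengths
#'
#' The lesion-specific endonuclease converts each lesion into a strand
#' break, so `1/Ln` counts breaks per unit length and the no-enzyme lane
#' corrects for background breakage:
#' `CPDs/kb = 1/Ln(+enzyme) - 1/Ln(-enzyme)` with lengths in kb. Negative
#' estimates are floored at 0 with a warning.
#'
#' @param ln_plus number-average length of the enzyme-digested lane (kb).
#' @param ln_minus number-average length of the no-enzyme lane (kb).
#' @return lesions per kb.
#' @export
lesions_per_kb <- function(ln_plus, ln_minus) {
  if (ln_plus <= 0 || ln_minus <= 0) stop("number-average lengths must be positive")
  out <- 1 / ln_plus - 1 / ln_minus
  if (out < 0) {
    warning("negative lesion estimate floored to 0")
    out <- 0
  }
  out
}

#' Percent repair curve from per-timepoint lesion frequencies
#'
#' Normalizes the CPDs/kb at each timepoint to the 0 hr value within each
#' replicate: `percent repair(t) = 100 * (1 - D(t) / D(0))`, then averages
#' across replicates (mean and SEM = sd/sqrt(n)). The per-replicate
#' fraction remaining `D(t)/D(0)` is also returned for use as the bulk
#' anchor in [gel_scale()].
#'
#' @param cpds_per_kb data.frame with columns `timepoint` (hours,
#'   including 0), `replicate`, `cpds_per_kb`.
#' @return an object of class `bulk_repair_curve`: `$replicates`
#'   (per-replicate fraction remaining and percent repair) and `$summary`
#'   (per-timepoint mean, SEM and n for both quantities).
#' @export
percent_repair <- function(cpds_per_kb) {
  dt <- data.table::as.data.table(cpds_per_kb)
  stopifnot(all(c("timepoint", "replicate", "cpds_per_kb") %in% names(dt)))
  if (!any(dt$timepoint == 0)) stop("0 hr timepoint is required")
  d0 <- dt[timepoint == 0, list(d0 = cpds_per_kb), by = replicate]
  if (any(d0$d0 <= 0)) stop("CPDs/kb at 0 hr must be positive in every replicate")
  reps <- merge(dt, d0, by = "replicate")
  reps[, fraction_remaining := cpds_per_kb / d0]
  reps[, percent_repair := 100 * (1 - fraction_remaining)]
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  summ <- reps[, list(
    n = .N,
    mean_percent_repair = mean(percent_repair),
    sem_percent_repair = sem(percent_repair),
    mean_fraction_remaining = mean(fraction_remaining),
    sem_fraction_remaining = sem(fraction_remaining)),
    by = timepoint]
  data.table::setorderv(summ, "timepoint")
  structure(list(replicates = as.data.frame(reps[, list(
    timepoint, replicate, cpds_per_kb, fraction_remaining, percent_repair)]),
    summary = as.data.frame(summ)),
    class = "bulk_repair_curve")
}

#' @export
print.bulk_repair_curve <- function(x, ...) {
  cat("bulk_repair_curve:\n")
  print(x$summary)
  invisible(x)
}

#' Two-sample t-test for replicate percent-repair (or survival) values
#'
#' Two-sided two-sample t-test, Welch variant by default. When both groups
#' have zero variance and equal means the test is degenerate and `p = 1`,
#' `t = 0` is returned by convention (`p = 0`, `t = Inf` for unequal
#' constant groups).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param var_equal use the Student (pooled-variance) variant.
#' @return list with elements `t`, `df`, `p`.
#' @export
repair_ttest <- function(group_a, group_b, var_equal = FALSE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2L, p = 1))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2L, p = 0))
  }
  res <- stats::t.test(group_a, group_b, var.equal = var_equal,
                       alternative = "two.sided")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
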