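#' Sliding windows over a genome
#'
#' Tiles each chromosome with windows of width `W` every `step` bp; the
#' final window(s) are truncated at the chromosome end. A chromosome
#' shorter than `W` yields a single window covering it entirely. No window
#' crosses a chromosome boundary.
#'
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param W Window width in bp (default 1000).
#' @param step Step between window starts in bp (default 100); must divide
#'   `W`.
#' @return `GRanges` of windows, ordered by (chrom, start).
#' @export
make_windows <- function(chrom_sizes, W = 1000L, step = 100L) {
  if (step <= 0L || W < step) stop("require step > 0 and W >= step")
  if (W %% step != 0L) stop("W must be a multiple of step")
  per_chrom <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    if (len <= W) {
      starts <- 0L
    } else {
      starts <- seq.int(0L, len - 1L, by = step)
    }
    data.frame(chrom = chr, start = starts, end = pmin(starts + W, len))
  })
  d <- do.call(rbind, per_chrom)
  out <- GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start + 1L, d$end),
    seqinfo = GenomeInfoDb::Seqinfo(names(chrom_sizes),
                                    unname(chrom_sizes)))
  out
}

#' Genome-wide background window rate
#'
#' Background rate for the Poisson window test: the genome-wide mean count
#' per `W`-bp window, `lambda = total_count * W / genome_length`.
#' Chromosomes with zero counts are excluded from both total and length,
#' so absent scaffolds do not dilute the background.
#'
#' @param track A `binned_track` of raw counts.
#' @param W Window width in bp.
#' @return Positive scalar rate.
#' @export
estimate_lambda <- function(track, W = 1000L) {
  totals <- vapply(track$counts, sum, numeric(1))
  keep <- totals > 0
  if (!any(keep)) stop("empty track: cannot estimate background rate")
  glen <- sum(vapply(names(track$counts)[keep],
                     function(chr) as.numeric(track$chrom_sizes[[chr]]),
                     numeric(1)))
  sum(totals[keep]) * W / glen
}

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`; equals 1 at `k = 0` and is
#' strictly decreasing in `k`.
#'
#' @param k Observed count(s), non-negative integers.
#' @param lambda Poisson rate (> 0).
#' @return Upper-tail probabilities.
#' @export
poisson_upper_p <- function(k, lambda) {
  if (any(k < 0)) stop("count must be non-negative")
  if (any(lambda <= 0)) stop("lambda must be positive")
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} (p_j * m / j)` capped at 1, returned in the input
#' order.
#'
#' @param p Vector of p-values in (0, 1].
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH", n = m)
}

#' Count raw reads in windows from a binned track
#'
#' @param track A `binned_track` whose step divides the window step.
#' @param windows `GRanges` from [make_windows()].
#' @return Integer-valued vector of per-window counts.
#' @export
window_counts <- function(track, windows) {
  ts <- track$step
  counts <- numeric(length(windows))
  chr_all <- as.character(GenomicRanges::seqnames(windows))
  for (chr in unique(chr_all)) {
    v <- track$counts[[chr]]
    if (is.null(v)) stop("track has no counts for chromosome ", chr)
    cs <- c(0, cumsum(v))
    idx <- which(chr_all == chr)
    s0 <- BiocGenerics::start(windows)[idx] - 1L   # 0-based starts
    e0 <- BiocGenerics::end(windows)[idx]          # half-open ends
    if (any(s0 %% ts != 0)) stop("window start not aligned to track bins")
    lo <- s0 %/% ts
    hi <- pmin(ceiling(e0 / ts), length(v))
    counts[idx] <- cs[hi + 1L] - cs[lo + 1L]
  }
  counts
}

#' Call EdU-labeled replicated regions
#'
#' Tiles the genome with `W`-bp windows every `step` bp, tests each
#' window's raw EdU count against a global Poisson background, adjusts
#' p-values by Benjamini-Hochberg, keeps windows with adjusted p strictly
#' below `alpha`, and merges overlapping or bookended significant windows
#' into replicated regions.
#'
#' @param track Raw EdU `binned_track`.
#' @param chrom_sizes Named chromosome lengths.
#' @param W,step Window geometry in bp (defaults 1000 / 100).
#' @param alpha Adjusted-p threshold (default 1e-4, strict inequality).
#' @return List: `regions` (merged `GRanges`), `windows` (data.frame with
#'   chrom, start, end, count, p, p_adj), `lambda`, `alpha`.
#' @export
call_replicated_regions <- function(track, chrom_sizes,
                                    W = 1000L, step = 100L, alpha = 1e-4) {
  windows <- make_windows(chrom_sizes, W, step)
  # exclude chromosomes with no signal from calling (and from lambda)
  totals <- vapply(track$counts, sum, numeric(1))
  live <- names(totals)[totals > 0]
  windows <- windows[as.character(GenomicRanges::seqnames(windows)) %in% live]
  lambda <- estimate_lambda(track, W)
  counts <- window_counts(track, windows)
  # truncated terminal windows are tested at a proportionally reduced rate
  frac <- BiocGenerics::width(windows) / W
  p <- poisson_upper_p(counts, lambda * frac)
  p_adj <- bh_adjust(p)
  sig <- p_adj < alpha
  regions <- GenomicRanges::reduce(windows[sig])
  wtab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(windows)),
    start = BiocGenerics::start(windows) - 1L,
    end = BiocGenerics::end(windows),
    count = counts, p = p, p_adj = p_adj,
    stringsAsFactors = FALSE
  )
  list(regions = regions, windows = wtab, lambda = lambda, alpha = alpha)
}

#' EdU coverage of a peak set
#'
#' A peak is EdU-labeled iff it overlaps at least 1 bp of a replicated
#' region; coverage is the labeled fraction. Downstream kinetic analyses
#' use only the labeled peaks.
#'
#' @param peaks Sorted `GRanges` of peaks.
#' @param regions Merged replicated regions (`GRanges`), e.g.
#'   `call_replicated_regions(...)$regions`.
#' @return List: `peaks` (input with logical `edu_labeled` column),
#'   `labeled` (the labeled subset), `fraction` in \[0, 1\].
#' @export
edu_coverage <- function(peaks, regions) {
  if (length(peaks) == 0L) stop("empty peak set")
  hit <- IRanges::overlapsAny(peaks, regions)
  peaks$edu_labeled <- hit
  list(peaks = peaks, labeled = peaks[hit], fraction = mean(hit))
}
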