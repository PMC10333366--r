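#' Flag genes with EdU-labeled peaks at their promoters
#'
#' The promoter is a strand-aware window around the TSS (default
#' +/-2000 bp; the window always includes the TSS base itself, so a width
#' of 0 keeps exactly the TSS base). A gene is flagged when any labeled
#' peak overlaps its promoter window by at least 1 bp. Genes without
#' strand information are treated as plus-strand and logged.
#'
#' @param genes `GRanges` with `gene_id` (and optionally `group`) metadata;
#'   strand `+`/`-` (or `*`, treated as `+`).
#' @param labeled_peaks `GRanges` of EdU-labeled peaks.
#' @param upstream,downstream Window extent in bp around the TSS, in
#'   transcription direction (defaults 2000/2000).
#' @return data.frame: gene_id, group (if present), promoter_target
#'   (logical).
#' @export
assign_promoter_targets <- function(genes, labeled_peaks,
                                    upstream = 2000L, downstream = 2000L) {
  strand <- as.character(BiocGenerics::strand(genes))
  if (any(strand == "*")) {
    message(sum(strand == "*"),
            " gene(s) without strand treated as plus-strand")
    strand[strand == "*"] <- "+"
  }
  tss0 <- ifelse(strand == "+", BiocGenerics::start(genes) - 1L,
                 BiocGenerics::end(genes) - 1L)
  lo <- ifelse(strand == "+", tss0 - upstream, tss0 - downstream)
  hi <- ifelse(strand == "+", tss0 + downstream, tss0 + upstream)
  promoters <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(start = pmax(lo, 0L) + 1L, end = hi + 1L)
  )
  hit <- IRanges::overlapsAny(promoters, labeled_peaks)
  out <- data.frame(gene_id = genes$gene_id, promoter_target = hit,
                    stringsAsFactors = FALSE)
  if (!is.null(genes$group)) out$group <- genes$group
  out
}

#' Wilcoxon signed-rank test for paired values
#'
#' Tests whether paired differences `x - y` are symmetric about zero.
#' Zero differences are dropped (classic Wilcoxon policy) and ties are
#' mid-ranked. The exact two-sided p-value is the standard doubled tail
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`, computed by convolving the
#' (doubled, hence integer) ranks over all sign assignments — identical
#' to full `2^n` enumeration but feasible up to `n = 25`. The normal
#' approximation applies a tie-corrected variance and a continuity
#' correction.
#'
#' @param x,y Paired numeric vectors (or `y = NULL` to test `x` against
#'   zero).
#' @param mode `"auto"` (exact for n <= 25 after dropping zeros),
#'   `"exact"` or `"normal"`.
#' @return List: `statistic` (W, sum of positive-difference ranks), `p`
#'   (two-sided), `n_used`, `n_zero`, `mode`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  d <- if (is.null(y)) x else x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero: p undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (mode == "auto") mode <- if (n <= 25L) "exact" else "normal"
  if (mode == "exact") {
    if (n > 25L) stop("exact mode supported for n <= 25")
    r2 <- as.integer(round(2 * r))   # midranks doubled -> integers
    total <- sum(r2)
    f <- numeric(total + 1L)          # f[w+1] = #sign patterns with W2 = w
    f[1L] <- 1
    for (ri in r2) {
      f <- f + c(rep(0, ri), f[seq_len(total + 1L - ri)])
    }
    w2 <- as.integer(round(2 * W))
    lower <- sum(f[seq_len(w2 + 1L)]) / 2^n
    upper <- sum(f[seq.int(w2 + 1L, total + 1L)]) / 2^n
    p <- min(1, 2 * min(lower, upper))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = W, p = p, n_used = n, n_zero = n_zero, mode = mode)
}

#' Quartiles of between-condition signal change
#'
#' `delta = signal2 - signal1` per region; regions are split into four
#' groups Q1 (largest decrease) to Q4 (largest increase) of sizes
#' differing by at most one (any remainder goes to the later quartiles).
#' Ties keep the stable input order.
#'
#' @param signal1,signal2 Named numeric vectors of per-region signal in
#'   the two conditions; names are region ids and must match as sets.
#' @return data.frame: region_id, delta, quartile (factor Q1..Q4), in the
#'   input order of `signal1`.
#' @export
delta_quartiles <- function(signal1, signal2) {
  ids <- names(signal1)
  missing <- setdiff(ids, names(signal2))
  extra <- setdiff(names(signal2), ids)
  if (length(missing) || length(extra)) {
    stop("unmatched region ids: ",
         paste(c(missing, extra), collapse = ", "))
  }
  delta <- signal2[ids] - signal1[ids]
  nv <- length(delta)
  if (nv < 4L) stop("need at least 4 regions")
  if (length(unique(delta)) == 1L) {
    warning("all deltas equal; quartiles split by input order")
  }
  sizes <- rep(nv %/% 4L, 4L)
  rem <- nv %% 4L
  if (rem > 0L) sizes[5L - seq_len(rem)] <- sizes[5L - seq_len(rem)] + 1L
  ord <- order(delta)   # ascending: most decreased first
  lab <- character(nv)
  lab[ord] <- rep(paste0("Q", 1:4), times = sizes)
  data.frame(region_id = ids, delta = unname(delta),
             quartile = factor(lab, levels = paste0("Q", 1:4)),
             stringsAsFactors = FALSE)
}

#' Summary of misregulated histone-mark target genes
#'
#' Among genes that are both significantly differentially expressed and
#' flagged as mark targets, counts the up- and downregulated fractions.
#'
#' @param de data.frame with columns `gene_id`, `direction` ("up" or
#'   "down") and `significant` (logical); produced by an external
#'   differential-expression analysis.
#' @param target_ids Character vector of target gene ids (e.g. genes with
#'   EdU-labeled mark peaks at their promoter).
#' @return List: n_total, n_up, n_down, pct_up, pct_down (percentages
#'   rounded to 2 decimals).
#' @export
misregulation_summary <- function(de, target_ids) {
  stopifnot(all(c("gene_id", "direction", "significant") %in% names(de)))
  hit <- de[de$significant & de$gene_id %in% target_ids, , drop = FALSE]
  n_total <- nrow(hit)
  if (n_total == 0L) stop("no significant target genes: percentages undefined")
  n_up <- sum(hit$direction == "up")
  n_down <- sum(hit$direction == "down")
  list(n_total = n_total, n_up = n_up, n_down = n_down,
       pct_up = round(100 * n_up / n_total, 2),
       pct_down = round(100 * n_down / n_total, 2))
}
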