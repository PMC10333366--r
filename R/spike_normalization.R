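#' Spike-in scale factor
#'
#' ChIP-Rx-style scaling: each sample is scaled by the reads-per-million of
#' its exogenous (spike-in) genome, so that signal is comparable across
#' samples regardless of sequencing depth or global changes in the
#' experiment genome.
#'
#' @param spike_reads Unique reads mapped to the spike-in genome (> 0).
#' @return Scale factor `1e6 / spike_reads`.
#' @export
compute_scale_factor <- function(spike_reads) {
  if (any(is.na(spike_reads)) || any(spike_reads <= 0)) {
    stop("spike-in read count must be positive; normalization impossible")
  }
  1e6 / spike_reads
}

#' Reference-adjusted RPKM for a region
#'
#' `value = raw * factor * 1000 / region_length_bp`: reads per kilobase,
#' per million spike-in reads.
#'
#' @param raw Raw read count(s) in the region (>= 0).
#' @param region_length_bp Region length(s) in bp (> 0).
#' @param factor Spike-in scale factor from [compute_scale_factor()].
#' @return Normalized signal, same length as `raw`.
#' @export
normalize_counts <- function(raw, region_length_bp, factor) {
  if (any(raw < 0)) stop("raw counts must be non-negative")
  if (any(region_length_bp <= 0)) stop("region length must be positive")
  raw * factor * 1000 / region_length_bp
}

#' Spike-in stats table constructor
#'
#' @param sample_id Character vector of sample (timepoint) labels.
#' @param experiment_reads Unique reads on the experiment genome.
#' @param spike_reads Unique reads on the spike-in genome (> 0).
#' @return data.frame with a `factor` column (`1e6 / spike_reads`).
#' @export
spikein_stats <- function(sample_id, experiment_reads, spike_reads) {
  data.frame(sample_id = as.character(sample_id),
             experiment_reads = experiment_reads,
             spike_reads = spike_reads,
             factor = compute_scale_factor(spike_reads),
             stringsAsFactors = FALSE)
}

#' Normalize a peaks x timepoints raw count matrix
#'
#' Each column (timepoint) is scaled by its own spike-in factor and each
#' row by its peak length, producing reference-adjusted RPKM. Column order
#' is preserved.
#'
#' @param raw Numeric matrix, peaks in rows, timepoints in columns; column
#'   names are sample ids matching `spike_stats$sample_id`.
#' @param spike_stats data.frame from [spikein_stats()], one row per column
#'   of `raw`.
#' @param peak_lengths Peak lengths in bp, one per row of `raw`.
#' @return Matrix of normalized signal, same dimnames as `raw`.
#' @export
normalize_timecourse <- function(raw, spike_stats, peak_lengths) {
  stopifnot(is.matrix(raw), length(peak_lengths) == nrow(raw))
  missing <- setdiff(colnames(raw), spike_stats$sample_id)
  if (length(missing) > 0L) {
    stop("no spike-in stats for timepoint(s): ",
         paste(missing, collapse = ", "))
  }
  factors <- spike_stats$factor[match(colnames(raw), spike_stats$sample_id)]
  out <- sweep(raw, 2L, factors, `*`)
  sweep(out, 1L, 1000 / peak_lengths, `*`)
}
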