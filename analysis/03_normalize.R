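#!/usr/bin/env Rscript
# Stage 3 — spike-in normalization.
#
# Converts raw per-peak counts at each timepoint to reference-adjusted
# RPKM: counts are scaled by 1e6 / spike-in reads of their timepoint and
# by 1000 / peak length, making signal comparable across timepoints and
# conditions regardless of sequencing depth.

suppressMessages(library(chorkinetics))

indir <- "results/synthetic"
outdir <- "results/normalized"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

raw <- read_matrix_tsv(file.path(indir, "raw_counts.tsv"))
raw2 <- read_matrix_tsv(file.path(indir, "raw_counts_perturbed.tsv"))
st <- utils::read.table(file.path(indir, "spike_stats.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
cs <- read_chrom_sizes(file.path(indir, "chrom.sizes"))
peaks <- read_peaks(file.path(indir, "peaks.narrowPeak"), "narrowPeak", cs)
lens <- stats::setNames(BiocGenerics::width(peaks), peaks$name)

norm <- normalize_timecourse(raw, st, lens[rownames(raw)])
norm2 <- normalize_timecourse(raw2, st, lens[rownames(raw2)])
write_matrix_tsv(norm, file.path(outdir, "normalized.tsv"))
write_matrix_tsv(norm2, file.path(outdir, "normalized_perturbed.tsv"))

cat(sprintf("normalized %d peaks x %d timepoints; spike factors: %s\n",
            nrow(norm), ncol(norm),
            paste(sprintf("%.3f", st$factor), collapse = ", ")))
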