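#!/usr/bin/env Rscript
# Stage 6 — condition and gene-group comparisons.
#
# Compares restoration rates between the reference and the perturbed
# (slow-restoration) condition with a paired two-sided Wilcoxon
# signed-rank test, classifies regions into quartiles Q1-Q4 of signal
# change between conditions, flags genes with EdU-labeled peaks at their
# promoters (TSS +/- 2 kb, strand-aware), and summarizes mis-expressed
# target genes from the differential-expression fixture.

suppressMessages(library(chorkinetics))

seed <- as.integer(Sys.getenv("CHOR_SEED", "1"))
outdir <- "results/groups"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

rr <- utils::read.table("results/restoration/restoration_rate.tsv",
                        header = TRUE, sep = "\t")
rr2 <- utils::read.table("results/restoration/restoration_rate_perturbed.tsv",
                         header = TRUE, sep = "\t")
norm <- read_matrix_tsv("results/normalized/normalized.tsv")
norm2 <- read_matrix_tsv("results/normalized/normalized_perturbed.tsv")
labeled <- read_peaks("results/regions/labeled_peaks.bed", "BED")

wt <- stats::setNames(rr$RR, rr$peak_id)
ko <- stats::setNames(rr2$RR, rr2$peak_id)[names(wt)]
wil <- wilcoxon_signed_rank(ko, wt, mode = "normal")
cat(sprintf("paired signed-rank (perturbed vs reference): W = %.0f, p = %.3g\n",
            wil$statistic, wil$p))
cat(sprintf("median RR: reference %.2f, perturbed %.2f (%.0f%% remaining)\n",
            median(wt), median(ko), 100 * median(ko) / median(wt)))

quart <- delta_quartiles(stats::setNames(rowMeans(norm), rownames(norm)),
                         stats::setNames(rowMeans(norm2), rownames(norm2)))
utils::write.table(quart, file.path(outdir, "delta_quartiles.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
# RR change per delta quartile: stronger losses where signal dropped most
dd <- merge(quart, data.frame(region_id = names(wt), d_rr = ko - wt))
agg <- stats::aggregate(d_rr ~ quartile, dd, median)
cat("median RR change by delta quartile:",
    sprintf("%s=%.2f", agg$quartile, agg$d_rr), "\n")

# gene groups and misregulation summary from the generated annotations
cfg <- chor_config(seed = seed)
g <- simulate_genome(cfg)
tr <- simulate_truth(g$peaks, cfg)
gt <- simulate_gene_tables(g, tr, cfg)
targets <- assign_promoter_targets(gt$genes, labeled)
utils::write.table(targets, file.path(outdir, "promoter_targets.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
mis <- misregulation_summary(gt$de, targets$gene_id[targets$promoter_target])
cat(sprintf("misregulated targets: %d total, %.2f%% up, %.2f%% down\n",
            mis$n_total, mis$pct_up, mis$pct_down))
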