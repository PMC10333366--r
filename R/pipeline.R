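#' Run the full ChOR-seq analysis pipeline on a synthetic dataset
#'
#' Orchestrates every stage on one generated dataset: simulate, call
#' replicated regions, compute EdU coverage, normalize time courses,
#' restoration-rate table and quartile clusters, pattern clustering with
#' semantic names, summit-window spatial profile, and the group
#' comparisons (paired signed-rank test of reference vs perturbed rates,
#' delta quartiles, promoter targets and the misregulation summary). All
#' tables are written under `outdir` together with a manifest of file
#' checksums and the full configuration, so an unchanged rerun is
#' byte-identical.
#'
#' @param config From [chor_config()].
#' @param outdir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisible list with all stage results (`dataset`, `regions`,
#'   `coverage`, `norm`, `rr`, `rr_perturbed`, `clustering`,
#'   `cluster_names`, `cluster_props`, `profile`, `wilcoxon`, `quartiles`,
#'   `targets`, `misregulation`).
#' @export
run_chor_pipeline <- function(config = chor_config(), outdir = NULL) {
  ds <- simulate_chor_dataset(config)
  tp <- config$timepoints

  called <- call_replicated_regions(ds$edu_track, ds$chrom_sizes)
  cov <- edu_coverage(ds$peaks, called$regions)

  norm <- normalize_timecourse(ds$tc$raw, ds$tc$spike_stats,
                               ds$tc$peak_lengths)
  norm2 <- normalize_timecourse(ds$tc_perturbed$raw,
                                ds$tc_perturbed$spike_stats,
                                ds$tc_perturbed$peak_lengths)
  # downstream kinetics use only EdU-labeled peaks
  lab_ids <- cov$labeled$name
  rr <- rr_table(norm[rownames(norm) %in% lab_ids, , drop = FALSE], tp)
  rr2 <- rr_table(norm2[rownames(norm2) %in% lab_ids, , drop = FALSE], tp)
  rr$rr_cluster <- rr_quartile_clusters(rr$RR)

  z <- standardize_trajectories(
    norm[rownames(norm) %in% lab_ids, , drop = FALSE])
  cl <- fuzzy_cmeans(z, k = 3L, seed = config$seed)
  cl_names <- name_clusters(cl, tp)
  props <- cluster_proportions(cl_names[cl$labels])

  sw_norm <- lapply(ds$summit_counts, function(raw) {
    normalize_timecourse(raw, attr(ds$summit_counts, "spike_stats"),
                         rep(attr(ds$summit_counts, "window_bp"),
                             nrow(raw)))
  })
  profile <- rr_spatial_profile(sw_norm, tp)

  wt <- stats::setNames(rr$RR, rr$peak_id)
  ko <- stats::setNames(rr2$RR, rr2$peak_id)
  wil <- wilcoxon_signed_rank(ko[names(wt)], wt, mode = "normal")
  level1 <- stats::setNames(rowMeans(norm), rownames(norm))
  level2 <- stats::setNames(rowMeans(norm2), rownames(norm2))
  quart <- delta_quartiles(level1, level2[names(level1)])

  targets <- assign_promoter_targets(ds$genes, cov$labeled)
  mis <- misregulation_summary(ds$de,
                               targets$gene_id[targets$promoter_target])

  res <- list(dataset = ds, regions = called, coverage = cov,
              norm = norm, rr = rr, rr_perturbed = rr2,
              clustering = cl, cluster_names = cl_names,
              cluster_props = props, profile = profile, wilcoxon = wil,
              quartiles = quart, targets = targets, misregulation = mis)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  invisible(res)
}

#' Write pipeline outputs and a manifest
#'
#' @param res Result list from [run_chor_pipeline()].
#' @param outdir Output directory.
#' @return Invisible vector of written paths.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  ds <- res$dataset
  utils::write.table(
    data.frame(chrom = names(ds$chrom_sizes), length = ds$chrom_sizes),
    p("chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_narrowpeak(ds$peaks, p("peaks.narrowPeak"))
  write_track(ds$edu_track, p("edu_raw.bedGraph"))
  utils::write.table(ds$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(res$regions$regions, p("replicated_regions.bed"))
  utils::write.table(res$regions$windows, p("window_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("edu_coverage\t%.6f", res$coverage$fraction),
             p("coverage.txt"))
  write_matrix_tsv(res$norm, p("normalized_timecourse.tsv"))
  utils::write.table(res$rr, p("restoration_rate.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  memb <- data.frame(peak_id = rownames(res$clustering$membership),
                     res$clustering$membership,
                     hard_label = res$clustering$labels,
                     semantic_name =
                       res$cluster_names[res$clustering$labels])
  names(memb)[2:(1 + res$clustering$k)] <-
    paste0("membership_", seq_len(res$clustering$k))
  utils::write.table(memb, p("pattern_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$profile, p("rr_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$quartiles, p("delta_quartiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$targets, p("promoter_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mis <- res$misregulation
  writeLines(c(sprintf("n_total\t%d", mis$n_total),
               sprintf("n_up\t%d", mis$n_up),
               sprintf("n_down\t%d", mis$n_down),
               sprintf("pct_up\t%.2f", mis$pct_up),
               sprintf("pct_down\t%.2f", mis$pct_down)),
             p("misregulation.tsv"))
  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  cfg <- res$dataset$config
  cfg_str <- paste(names(cfg),
                   vapply(cfg, function(x) paste(x, collapse = ","),
                          character(1)),
                   sep = "=", collapse = "; ")
  writeLines(c(paste0("# config: ", cfg_str),
               paste(manifest$file, manifest$md5, sep = "\t")),
             p("manifest.tsv"))
  invisible(files)
}
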