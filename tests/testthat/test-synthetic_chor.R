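tp <- c(0, 2, 4, 6)

test_that("the dataset is bit-exactly regenerable from (config, seed)", {
  cfg <- chor_config(seed = 60L, n_peaks = 150L, chrom_length = 1.5e6)
  d1 <- suppressMessages(simulate_chor_dataset(cfg))
  d2 <- suppressMessages(simulate_chor_dataset(cfg))
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$tc$raw, d2$tc$raw)
  expect_identical(d1$edu_track$counts, d2$edu_track$counts)
  expect_identical(d1$de, d2$de)
  d3 <- suppressMessages(simulate_chor_dataset(chor_config(seed = 61L,
                                                           n_peaks = 150L,
                                                           chrom_length = 1.5e6)))
  expect_false(identical(d1$tc$raw, d3$tc$raw))
})

test_that("simulated peaks are disjoint, sorted and within the genome", {
  cfg <- chor_config(seed = 62L, n_peaks = 200L, chrom_length = 2e6)
  g <- simulate_genome(cfg)
  expect_length(g$peaks, 200L)
  expect_true(all(BiocGenerics::end(g$peaks) <=
                    g$chrom_sizes[as.character(
                      GenomicRanges::seqnames(g$peaks))]))
  ov <- GenomicRanges::findOverlaps(g$peaks, drop.self = TRUE)
  expect_length(ov, 0L)
  expect_false(is.unsorted(BiocGenerics::start(g$peaks)[
    as.character(GenomicRanges::seqnames(g$peaks)) == "chr1"]))
  expect_error(simulate_genome(chor_config(seed = 1L, n_peaks = 5000L,
                                           chrom_length = 1e6)),
               "too small")
  g0 <- simulate_genome(chor_config(seed = 1L, n_peaks = 0L))
  expect_length(g0$peaks, 0L)
})

test_that("truth honors configured class proportions and labeling", {
  cfg <- chor_config(seed = 63L)
  g <- simulate_genome(cfg)
  truth <- simulate_truth(g$peaks, cfg)
  expect_equal(unname(table(truth$class)[c("early", "intermediate",
                                           "late")]),
               unname(allocate_counts(1000L, cfg$class_props)),
               ignore_attr = TRUE)
  expect_equal(mean(truth$edu_labeled), 0.70)
  # class encodes Tmax location
  rng <- list(early = c(0, 2), intermediate = c(2, 4), late = c(4, 6))
  for (cl in names(rng)) {
    tm <- truth$Tmax[truth$class == cl]
    expect_true(all(tm > rng[[cl]][1] & tm <= rng[[cl]][2]))
  }
  # true RR is the closed-form mean slope of the true quadratic
  i <- 17L
  expect_equal(truth$true_RR[i],
               mean_slope_oracle(truth$a[i], truth$b[i], truth$c[i],
                                 0, truth$Tmax[i]))
})

test_that("zero-noise counts recover the true rates within rounding", {
  cfg <- chor_config(seed = 64L, n_peaks = 200L, chrom_length = 2e6,
                     noise = "none")
  g <- simulate_genome(cfg)
  truth <- simulate_truth(g$peaks, cfg)
  tc <- suppressMessages(simulate_timecourses(g$peaks, truth, cfg))
  norm <- normalize_timecourse(tc$raw, tc$spike_stats, tc$peak_lengths)
  tab <- rr_table(norm, tp)
  m <- match(tab$peak_id, truth$peak_id)
  # exclude peaks whose quadratic dips below zero (clipped means)
  lo <- pmin(truth$c[m],
             truth$a[m] * 36 + truth$b[m] * 6 + truth$c[m])
  ok <- lo >= 0
  expect_gt(sum(ok), 50)
  expect_lt(max(abs(tab$RR[ok] - truth$true_RR[m][ok])), 0.1)
})

test_that("doubling a spike depth leaves normalized expectations unchanged", {
  base <- chor_config(seed = 65L, n_peaks = 150L, chrom_length = 1.5e6,
                      noise = "none")
  alt <- base
  alt$spike_reads <- base$spike_reads * c(1, 2, 1, 1)
  g <- simulate_genome(base)
  truth <- simulate_truth(g$peaks, base)
  n1 <- with(suppressMessages(simulate_timecourses(g$peaks, truth, base)),
             normalize_timecourse(raw, spike_stats, peak_lengths))
  n2 <- with(suppressMessages(simulate_timecourses(g$peaks, truth, alt)),
             normalize_timecourse(raw, spike_stats, peak_lengths))
  # rounding of the doubled raw counts differs by at most half a count
  expect_lt(max(abs(n1 - n2)), 0.5)
})

test_that("EdU track drives the caller as configured", {
  cfg <- chor_config(seed = 66L, n_peaks = 150L, chrom_length = 3e6)
  g <- simulate_genome(cfg)
  truth <- simulate_truth(g$peaks, cfg)
  track <- simulate_edu_track(g, truth, cfg)
  called <- call_replicated_regions(track, g$chrom_sizes)
  cov <- edu_coverage(g$peaks, called$regions)
  hit <- cov$peaks$edu_labeled
  lab <- truth$edu_labeled[match(g$peaks$name, truth$peak_id)]
  expect_gte(mean(hit[lab]), 0.95)          # recall on labeled peaks

  # labeled fraction 0 -> essentially nothing called over peaks
  cfg0 <- cfg; cfg0$labeled_fraction <- 0
  truth0 <- simulate_truth(g$peaks, cfg0)
  track0 <- simulate_edu_track(g, truth0, cfg0)
  called0 <- call_replicated_regions(track0, g$chrom_sizes)
  cov0 <- if (length(called0$regions) == 0) 0 else
    edu_coverage(g$peaks, called0$regions)$fraction
  expect_lte(cov0, 0.01)

  # fold -> 1 is the null limit
  cfg1 <- cfg; cfg1$edu_fold <- 1
  expect_warning(track1 <- simulate_edu_track(g, truth, cfg1), "fold")
  called1 <- call_replicated_regions(track1, g$chrom_sizes)
  expect_lte(length(called1$regions), 5L)

  expect_error(simulate_edu_track(g, truth,
                                  within(cfg, edu_lambda <- 0)),
               "positive")
})

test_that("gene tables feed the misregulation summary as configured", {
  cfg <- chor_config(seed = 67L, n_peaks = 300L, chrom_length = 4e6)
  g <- simulate_genome(cfg)
  truth <- simulate_truth(g$peaks, cfg)
  gt <- simulate_gene_tables(g, truth, cfg)
  s <- misregulation_summary(gt$de, gt$target_ids)
  expect_equal(s$n_total, 299)
  expect_equal(s$pct_up, 43.81)
  expect_equal(s$pct_down, 56.19)

  one <- simulate_gene_tables(g, truth, cfg,
                              group_props = c(housekeeping = 1, ES = 0,
                                              bivalent = 0,
                                              tissue_specific = 0))
  expect_true(all(one$genes$group == "housekeeping"))

  none <- gt$de
  none$significant <- FALSE
  expect_error(misregulation_summary(none, gt$target_ids), "undefined")
})
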