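#' Default configuration for the synthetic ChOR-seq generator
#'
#' The defaults emulate the synchronized four-timepoint design: samples at
#' 0, 2, 4 and 6 h post-labeling; restoration-pattern classes "early",
#' "intermediate" and "late" in proportions 0.2873 / 0.3087 / 0.4030 with
#' per-class argmax times (Tmax) drawn from truncated normals centered at
#' 1, 3 and 5 h (sd 0.5) within the class ranges \[0,2\], (2,4\] and
#' (4,6\]; 70 percent of peaks EdU-labeled; and an EdU enrichment of
#' 10-fold over a background of 10 reads per 1-kb window.
#'
#' @param seed Integer master seed.
#' @param n_peaks Number of peaks (default 1000).
#' @param n_chroms,chrom_length Genome geometry (default 2 x 5 Mb).
#' @param timepoints Hours post-labeling (default `c(0, 2, 4, 6)`).
#' @param class_props Pattern-class proportions (early, intermediate,
#'   late).
#' @param tmax_centers,tmax_sd Truncated-normal Tmax parameters per class.
#' @param labeled_fraction EdU-labeled peak fraction (default 0.70).
#' @param edu_lambda Background EdU reads per 1-kb window (default 10).
#' @param edu_fold EdU enrichment fold in labeled peaks (default 10).
#' @param baseline_range Nascent (T0) signal range, reference-adjusted
#'   RPKM.
#' @param curvature_range Quadratic curvature range (RPKM per h^2).
#' @param spike_reads Spike-in read depth per timepoint.
#' @param peak_width_range Peak widths in bp.
#' @param min_gap Minimum distance between adjacent peaks in bp (default
#'   2000; peak callers merge regions closer than the window scale, so
#'   independent peaks are at least this far apart).
#' @param amplitude_profile Relative signal amplitude of the five
#'   summit-centered windows (center-maximal by default).
#' @param rr_effect Multiplier on curvature in the perturbed condition
#'   (default 0.5, i.e. restoration at half speed).
#' @param noise `"poisson"` for Poisson counts, `"none"` for rounded
#'   means.
#' @return Named list of generator settings.
#' @export
chor_config <- function(seed = 1L,
                        n_peaks = 1000L,
                        n_chroms = 2L,
                        chrom_length = 5e6,
                        timepoints = c(0, 2, 4, 6),
                        class_props = c(early = 0.2873,
                                        intermediate = 0.3087,
                                        late = 0.4030),
                        tmax_centers = c(1, 3, 5),
                        tmax_sd = 0.25,
                        labeled_fraction = 0.70,
                        edu_lambda = 10,
                        edu_fold = 10,
                        baseline_range = c(60, 150),
                        curvature_range = c(3, 6),
                        spike_reads = c(3.0e6, 3.5e6, 2.5e6, 4.0e6),
                        peak_width_range = c(1500, 2500),
                        min_gap = 2000L,
                        amplitude_profile = c(0.6, 0.8, 1, 0.8, 0.6),
                        rr_effect = 0.5,
                        noise = "poisson") {
  as.list(environment())
}

# deterministic integer allocation: counts per class, largest remainder
allocate_counts <- function(n, props) {
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * props - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Simulate a genome with non-overlapping peaks
#'
#' Places `n_peaks` non-overlapping peaks across `n_chroms` chromosomes
#' (round-robin), with uniform random inter-peak gaps and a summit drawn
#' in the central half of each peak.
#'
#' @param config From [chor_config()].
#' @return List: `chrom_sizes` (named integer vector), `peaks` (sorted
#'   `GRanges` with `name` and `summit`).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  chrom_sizes <- stats::setNames(rep(as.integer(config$chrom_length),
                                     config$n_chroms),
                                 paste0("chr", seq_len(config$n_chroms)))
  per_chrom <- allocate_counts(config$n_peaks,
                               rep(1 / config$n_chroms, config$n_chroms))
  all_peaks <- list()
  pk <- 0L
  for (ci in seq_len(config$n_chroms)) {
    ni <- per_chrom[ci]
    if (ni == 0L) next
    w <- as.integer(round(stats::runif(ni, config$peak_width_range[1],
                                       config$peak_width_range[2])))
    margin <- 2000L   # keep summit windows clear of chromosome edges
    gap <- config$min_gap
    avail <- config$chrom_length - 2 * margin - sum(w) - (ni - 1L) * gap
    if (avail < ni) stop("genome too small for requested peaks")
    cuts <- sort(stats::runif(ni, 0, avail))
    starts <- as.integer(margin + cuts +
                           c(0, cumsum(w))[seq_len(ni)] +
                           (seq_len(ni) - 1L) * gap)
    summit <- as.integer(round(w * stats::runif(ni, 0.25, 0.75)))
    all_peaks[[ci]] <- data.frame(
      chrom = names(chrom_sizes)[ci], start = starts, end = starts + w,
      name = sprintf("peak_%04d", pk + seq_len(ni)), summit = summit,
      stringsAsFactors = FALSE)
    pk <- pk + ni
  }
  d <- do.call(rbind, all_peaks)
  peaks <- if (is.null(d)) {
    GenomicRanges::GRanges(name = character(0), summit = integer(0))
  } else {
    make_peakset(d$chrom, d$start, d$end, d$name, d$summit, chrom_sizes)
  }
  list(chrom_sizes = chrom_sizes, peaks = peaks)
}

#' Draw per-peak kinetic ground truth
#'
#' Each peak gets a pattern class (deterministic largest-remainder counts
#' at the configured proportions, shuffled), an argmax time Tmax from the
#' class's truncated normal, a nascent baseline `L0` and curvature `a2`,
#' defining the quadratic `f(t) = A - a2 * (t - Tmax)^2` with
#' `A = L0 + a2 * Tmax^2` (so `f(0) = L0`). The true restoration rate is
#' the mean slope `(f(Tmax) - f(0)) / Tmax = a2 * Tmax`. An EdU-labeled
#' flag is assigned to a deterministic 70 percent (shuffled).
#'
#' @param peaks `GRanges` from [simulate_genome()].
#' @param config From [chor_config()].
#' @return data.frame: peak_id, class, Tmax, a, b, c, true_RR,
#'   edu_labeled.
#' @export
simulate_truth <- function(peaks, config) {
  set.seed(config$seed + 1L)
  n <- length(peaks)
  counts <- allocate_counts(n, config$class_props)
  cls <- sample(rep(names(config$class_props), times = counts))
  ranges <- list(early = c(0, 2), intermediate = c(2, 4), late = c(4, 6))
  tmax <- numeric(n)
  for (i in seq_along(config$class_props)) {
    idx <- cls == names(config$class_props)[i]
    r <- ranges[[names(config$class_props)[i]]]
    tmax[idx] <- rtrunc_norm(sum(idx), config$tmax_centers[i],
                             config$tmax_sd, r[1], r[2])
  }
  L0 <- stats::runif(n, config$baseline_range[1], config$baseline_range[2])
  a2 <- stats::runif(n, config$curvature_range[1], config$curvature_range[2])
  # labeling is independent of class; allocate the labeled fraction
  # within each class so the labeled subset keeps the class proportions
  labeled <- logical(n)
  for (cl in names(config$class_props)) {
    idx <- which(cls == cl)
    n_lab <- as.integer(round(config$labeled_fraction * length(idx)))
    labeled[sample(idx, n_lab)] <- TRUE
  }
  data.frame(
    peak_id = peaks$name,
    class = cls,
    Tmax = tmax,
    a = -a2,
    b = 2 * a2 * tmax,
    c = L0,
    true_RR = a2 * tmax,
    edu_labeled = labeled,
    stringsAsFactors = FALSE
  )
}

#' Simulate the raw EdU coverage track
#'
#' Background bins draw Poisson counts at `edu_lambda * step / 1000`;
#' bins inside EdU-labeled peaks (the replicated domains) at `edu_fold`
#' times that rate.
#'
#' @param genome From [simulate_genome()].
#' @param truth From [simulate_truth()].
#' @param config From [chor_config()].
#' @param step Bin width in bp (default 100).
#' @return A `binned_track` of raw EdU counts.
#' @export
simulate_edu_track <- function(genome, truth, config, step = 100L) {
  if (config$edu_lambda <= 0) stop("edu_lambda must be positive")
  if (config$edu_fold <= 1) warning("edu_fold <= 1: no enrichment signal")
  set.seed(config$seed + 2L)
  per_bin <- config$edu_lambda * step / 1000
  counts <- lapply(genome$chrom_sizes, function(len) {
    stats::rpois(ceiling(len / step), per_bin)
  })
  labeled <- genome$peaks[truth$edu_labeled[match(genome$peaks$name,
                                                  truth$peak_id)]]
  chr_all <- as.character(GenomicRanges::seqnames(labeled))
  for (i in seq_along(labeled)) {
    chr <- chr_all[i]
    bins <- ((BiocGenerics::start(labeled)[i] - 1L) %/% step + 1L):
      ceiling(BiocGenerics::end(labeled)[i] / step)
    counts[[chr]][bins] <- stats::rpois(length(bins),
                                        config$edu_fold * per_bin)
  }
  binned_track(counts, step, genome$chrom_sizes, genome = "experiment")
}

# expected signal at time t for one peak's quadratic, clipped at zero
quad_mean <- function(truth, t) {
  mu <- truth$a * t * t + truth$b * t + truth$c
  pmax(mu, 0)
}

#' Simulate per-peak ChOR-seq time-course counts
#'
#' Raw counts at each timepoint are Poisson around
#' `f(t) * length_kb * depth`, where `depth = spike_reads / 1e6`, so that
#' spike-in normalization ([normalize_timecourse()]) recovers `f(t)` in
#' expectation regardless of per-timepoint depth. Negative quadratic
#' means are clipped at zero (with a message) before drawing counts.
#'
#' @param peaks `GRanges` of peaks (widths set region length).
#' @param truth From [simulate_truth()].
#' @param config From [chor_config()].
#' @param curvature_scale Multiplier on curvature (and hence on the true
#'   rate); 1 for the reference condition, `config$rr_effect` for the
#'   perturbed one.
#' @param seed_offset Offset added to the master seed so conditions get
#'   independent noise.
#' @return List: `raw` (peaks x timepoints integer matrix),
#'   `spike_stats`, `timepoints`, `peak_lengths`.
#' @export
simulate_timecourses <- function(peaks, truth, config,
                                 curvature_scale = 1, seed_offset = 3L) {
  set.seed(config$seed + seed_offset)
  tp <- config$timepoints
  stopifnot(length(config$spike_reads) == length(tp))
  tr <- truth
  tr$a <- tr$a * curvature_scale
  tr$b <- tr$b * curvature_scale
  lens <- BiocGenerics::width(peaks)[match(tr$peak_id, peaks$name)]
  depth <- config$spike_reads / 1e6
  mu <- vapply(seq_along(tp), function(j) {
    quad_mean(tr, tp[j]) * (lens / 1000) * depth[j]
  }, numeric(nrow(tr)))
  if (!is.matrix(mu)) mu <- matrix(mu, nrow = nrow(tr))
  raw_neg <- sum(tr$a * outer(rep(1, nrow(tr)), tp)^2 +
                   outer(tr$b, tp) + tr$c < 0)
  if (raw_neg > 0) {
    message(raw_neg, " negative quadratic mean(s) clipped at zero")
  }
  raw <- if (identical(config$noise, "none")) {
    round(mu)
  } else {
    matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
  }
  dimnames(raw) <- list(tr$peak_id, paste0("T", tp))
  list(raw = raw,
       spike_stats = spikein_stats(paste0("T", tp),
                                   experiment_reads = colSums(raw),
                                   spike_reads = config$spike_reads),
       timepoints = tp,
       peak_lengths = stats::setNames(lens, tr$peak_id))
}

#' Simulate summit-window time courses
#'
#' Produces the five per-window time-course count matrices used by
#' [rr_spatial_profile()]. Each 300-bp window shares its peak's kinetics
#' scaled by the configured center-maximal amplitude profile, so the true
#' restoration rate decreases from the summit outward.
#'
#' @param truth From [simulate_truth()].
#' @param config From [chor_config()].
#' @param window_bp Window width (default 300).
#' @return Named list of five raw count matrices (names are window
#'   centers), plus attribute `spike_stats`.
#' @export
simulate_summit_window_counts <- function(truth, config, window_bp = 300L) {
  set.seed(config$seed + 7L)
  tp <- config$timepoints
  depth <- config$spike_reads / 1e6
  centers <- c("-600", "-300", "0", "300", "600")
  out <- stats::setNames(vector("list", 5L), centers)
  for (w in seq_len(5L)) {
    amp <- config$amplitude_profile[w]
    mu <- vapply(seq_along(tp), function(j) {
      amp * quad_mean(truth, tp[j]) * (window_bp / 1000) * depth[j]
    }, numeric(nrow(truth)))
    if (!is.matrix(mu)) mu <- matrix(mu, nrow = nrow(truth))
    raw <- if (identical(config$noise, "none")) {
      round(mu)
    } else {
      matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
    }
    dimnames(raw) <- list(truth$peak_id, paste0("T", tp))
    out[[w]] <- raw
  }
  attr(out, "spike_stats") <- spikein_stats(
    paste0("T", tp), experiment_reads = rep(0, length(tp)),
    spike_reads = config$spike_reads)
  attr(out, "window_bp") <- window_bp
  out
}

#' Simulate gene annotations, groups and a differential-expression table
#'
#' Target genes get their TSS at the summit of an EdU-labeled peak (so
#' their promoter windows overlap labeled peaks); decoy genes are placed
#' midway between peaks, clear of any promoter overlap. Functional groups
#' are assigned at the configured proportions. The differential-expression
#' table marks configured numbers of significant up- and downregulated
#' genes among the targets (defaults 131 up / 168 down of 299, the
#' headline misregulation counts) plus background significant genes among
#' the decoys.
#'
#' @param genome From [simulate_genome()].
#' @param truth From [simulate_truth()].
#' @param config From [chor_config()].
#' @param n_up,n_down Significant up-/downregulated target genes.
#' @param group_props Group proportions (defaults from the real gene-set
#'   sizes 202/39/1378/811).
#' @return List: `genes` (`GRanges` with gene_id, group, strand), `de`
#'   (data.frame gene_id, log2fc, padj, direction, significant),
#'   `target_ids`.
#' @export
simulate_gene_tables <- function(genome, truth, config,
                                 n_up = 131L, n_down = 168L,
                                 group_props = c(housekeeping = 202,
                                                 ES = 39,
                                                 bivalent = 1378,
                                                 tissue_specific = 811) /
                                   2430) {
  set.seed(config$seed + 4L)
  peaks <- genome$peaks
  labeled <- peaks[truth$edu_labeled[match(peaks$name, truth$peak_id)]]
  n_target_needed <- n_up + n_down
  if (length(labeled) < 1L) stop("no labeled peaks to anchor target genes")
  # recycle labeled peaks if more targets than peaks are requested
  anchor <- labeled[((seq_len(n_target_needed) - 1L) %% length(labeled)) + 1L]
  tss_t <- BiocGenerics::start(anchor) - 1L + anchor$summit
  chr_t <- as.character(GenomicRanges::seqnames(anchor))
  # decoys: far from every peak (>= 6 kb from any peak edge)
  n_decoy <- max(200L, n_target_needed %/% 2L)
  gaps <- suppressWarnings(
    GenomicRanges::gaps(GenomicRanges::reduce(peaks + 6000L)))
  gaps <- gaps[BiocGenerics::width(gaps) > 2000L &
                 as.character(BiocGenerics::strand(gaps)) == "*"]
  gi <- sample(length(gaps), n_decoy, replace = TRUE)
  tss_d <- BiocGenerics::start(gaps)[gi] - 1L +
    as.integer(round(BiocGenerics::width(gaps)[gi] / 2))
  chr_d <- as.character(GenomicRanges::seqnames(gaps))[gi]
  chr <- c(chr_t, chr_d)
  tss <- c(tss_t, tss_d)
  n_genes <- length(tss)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  glen <- 5000L
  start0 <- ifelse(strand == "+", tss, pmax(tss - glen, 0L))
  end0 <- ifelse(strand == "+", tss + glen, tss + 1L)
  genes <- GenomicRanges::GRanges(
    chr, IRanges::IRanges(start0 + 1L, end0), strand = strand,
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    group = sample(rep(names(group_props),
                       times = allocate_counts(n_genes, group_props)))
  )
  target_ids <- genes$gene_id[seq_len(n_target_needed)]
  direction <- c(rep("up", n_up), rep("down", n_down),
                 sample(c("up", "down"), n_decoy, replace = TRUE))
  significant <- c(rep(TRUE, n_target_needed),
                   stats::runif(n_decoy) < 0.1)
  lfc <- ifelse(direction == "up", 1, -1) *
    stats::runif(n_genes, 0.5, 3) * ifelse(significant, 1, 0.1)
  de <- data.frame(gene_id = genes$gene_id, log2fc = lfc,
                   padj = ifelse(significant,
                                 stats::runif(n_genes, 1e-10, 0.049),
                                 stats::runif(n_genes, 0.1, 1)),
                   direction = direction, significant = significant,
                   stringsAsFactors = FALSE)
  list(genes = genes, de = de, target_ids = target_ids)
}

#' Generate a complete synthetic ChOR-seq dataset
#'
#' Runs every generator stage under one configuration: genome and peaks,
#' kinetic ground truth, EdU track, reference- and perturbed-condition
#' time courses, summit-window counts, and gene/DE tables. Bit-exactly
#' regenerable from `(config, seed)`.
#'
#' @param config From [chor_config()].
#' @return List with components `config`, `chrom_sizes`, `peaks`,
#'   `truth`, `edu_track`, `tc` (reference condition), `tc_perturbed`,
#'   `summit_counts`, `genes`, `de`, `target_ids`.
#' @export
simulate_chor_dataset <- function(config = chor_config()) {
  genome <- simulate_genome(config)
  truth <- simulate_truth(genome$peaks, config)
  edu <- simulate_edu_track(genome, truth, config)
  tc <- simulate_timecourses(genome$peaks, truth, config,
                             curvature_scale = 1, seed_offset = 3L)
  tc2 <- simulate_timecourses(genome$peaks, truth, config,
                              curvature_scale = config$rr_effect,
                              seed_offset = 5L)
  sw <- simulate_summit_window_counts(truth, config)
  gt <- simulate_gene_tables(genome, truth, config)
  list(config = config, chrom_sizes = genome$chrom_sizes,
       peaks = genome$peaks, truth = truth, edu_track = edu,
       tc = tc, tc_perturbed = tc2, summit_counts = sw,
       genes = gt$genes, de = gt$de, target_ids = gt$target_ids)
}
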