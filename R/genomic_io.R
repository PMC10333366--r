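#' Read a chrom.sizes file
#'
#' Parses a two-column whitespace-delimited file of chromosome names and
#' lengths into a named integer vector. All interval containers produced by
#' this package are validated against such a map.
#'
#' @param path Path to a chrom.sizes file (name, length per line).
#' @return Named integer vector of chromosome lengths (bp).
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty chrom.sizes file: ", path)
    return(stats::setNames(integer(0), character(0)))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(fields, function(f) length(f) < 2L, logical(1))
  if (any(bad)) {
    stop("malformed chrom.sizes line: '", lines[which(bad)[1L]], "'")
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  bad <- is.na(len) | len != floor(len) | len <= 0
  if (any(bad)) {
    stop("invalid chromosome length on line: '", lines[which(bad)[1L]], "'")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name: '",
         nm[anyDuplicated(nm)], "'")
  }
  stats::setNames(as.integer(len), nm)
}

#' Build a GRanges peak set from parsed fields
#'
#' @param chrom,start,end,name Vectors of equal length; coordinates are
#'   0-based half-open (BED convention).
#' @param summit Integer offset of the summit from `start`, or `NA` to fall
#'   back to the interval midpoint.
#' @param chrom_sizes Optional named lengths for coordinate validation.
#' @return Sorted `GRanges` with metadata columns `name` and `summit`
#'   (offset from interval start, 0-based).
#' @keywords internal
make_peakset <- function(chrom, start, end, name,
                         summit = NA_integer_, chrom_sizes = NULL) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(summit) == 1L) summit <- rep(as.integer(summit), length(start))
  width <- end - start
  summit <- ifelse(is.na(summit) | summit < 0L, width %/% 2L, summit)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    name = as.character(name),
    summit = as.integer(summit)
  )
  if (!is.null(chrom_sizes)) {
    sl <- chrom_sizes[as.character(GenomeInfoDb::seqnames(gr))]
    if (anyNA(sl)) {
      stop("peak on unknown chromosome: ",
           as.character(GenomicRanges::seqnames(gr))[which(is.na(sl))[1L]])
    }
    if (any(BiocGenerics::end(gr) > sl)) {
      stop("peak extends beyond chromosome end")
    }
  }
  GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
}

#' Read peak calls in BED6 or narrowPeak format
#'
#' Coordinates are kept 0-based half-open internally (stored in a `GRanges`,
#' which is 1-based; converters in this package handle the shift). For
#' narrowPeak input the 10th column is the summit offset from the interval
#' start; a value of -1 (summit not determined) falls back to the interval
#' midpoint, as does BED input which carries no summit at all. Lines that
#' violate the coordinate invariants (start >= end, summit outside the
#' interval) are rejected and counted in a message.
#'
#' @param path Path to a BED6 or narrowPeak file.
#' @param format `"narrowPeak"` or `"BED"`.
#' @param chrom_sizes Optional named chromosome lengths for validation.
#' @return Sorted `GRanges` with `name` and `summit` metadata columns.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "BED"),
                       chrom_sizes = NULL) {
  format <- match.arg(format)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character", comment.char = "#")
  start <- as.numeric(d[[2L]]); end <- as.numeric(d[[3L]])
  name <- if (ncol(d) >= 4L) d[[4L]] else paste0("peak_", seq_len(nrow(d)))
  summit <- if (format == "narrowPeak" && ncol(d) >= 10L) {
    as.integer(d[[10L]])
  } else {
    rep(NA_integer_, nrow(d))
  }
  ok <- !is.na(start) & !is.na(end) & start >= 0 & start < end &
    (is.na(summit) | summit < 0L | summit < (end - start))
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    message(n_bad, " invalid peak line(s) rejected from ", path)
  }
  if (!any(ok)) {
    return(GenomicRanges::GRanges(name = character(0), summit = integer(0)))
  }
  make_peakset(d[[1L]][ok], as.integer(start[ok]), as.integer(end[ok]),
               name[ok], summit[ok], chrom_sizes)
}

#' Construct a binned track
#'
#' A binned track holds fixed-step per-chromosome read counts. Bin `i`
#' (1-based) covers genomic interval `[(i-1)*step, i*step)`, truncated at
#' the chromosome end.
#'
#' @param counts Named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param step Bin width in bp.
#' @param chrom_sizes Named chromosome lengths; each vector must have
#'   `ceiling(length/step)` bins.
#' @param genome `"experiment"` or `"spikein"` provenance tag.
#' @return A `binned_track` list: `step`, `counts`, `chrom_sizes`, `genome`.
#' @export
binned_track <- function(counts, step, chrom_sizes,
                         genome = c("experiment", "spikein")) {
  genome <- match.arg(genome)
  stopifnot(step > 0, is.list(counts), !is.null(names(counts)))
  for (chr in names(counts)) {
    if (!chr %in% names(chrom_sizes)) {
      stop("track chromosome not in chrom sizes: ", chr)
    }
    expected <- ceiling(chrom_sizes[[chr]] / step)
    if (length(counts[[chr]]) != expected) {
      stop("chromosome ", chr, ": expected ", expected, " bins, got ",
           length(counts[[chr]]))
    }
    if (any(counts[[chr]] < 0)) stop("negative counts on ", chr)
  }
  structure(list(step = as.integer(step), counts = counts,
                 chrom_sizes = chrom_sizes, genome = genome),
            class = "binned_track")
}

#' Read a step-aligned bedGraph or bin-count table into a binned track
#'
#' bedGraph records must be aligned to the bin grid (start and end both
#' multiples of `step`, or end at the chromosome end); a single record may
#' span several bins, all of which receive its value. Missing bins are
#' zero-filled. The `counts_tsv` format is a three-column
#' (chrom, bin_index, count) table with 0-based bin indices.
#'
#' @param path Input file.
#' @param chrom_sizes Named chromosome lengths.
#' @param step Bin width in bp.
#' @param format `"bedGraph"` or `"counts_tsv"`.
#' @param genome Provenance tag passed to [binned_track()].
#' @return A `binned_track`.
#' @export
read_track <- function(path, chrom_sizes, step,
                       format = c("bedGraph", "counts_tsv"),
                       genome = "experiment") {
  format <- match.arg(format)
  counts <- lapply(chrom_sizes, function(len) numeric(ceiling(len / step)))
  names(counts) <- names(chrom_sizes)
  d <- tryCatch(
    utils::read.table(path, sep = "", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) NULL)
  if (!is.null(d) && nrow(d) > 0L) {
    if (format == "bedGraph") {
      chr <- as.character(d[[1L]])
      s <- as.numeric(d[[2L]]); e <- as.numeric(d[[3L]])
      v <- as.numeric(d[[4L]])
      unknown <- !chr %in% names(chrom_sizes)
      if (any(unknown)) stop("bedGraph chromosome not in chrom sizes: ",
                             chr[which(unknown)[1L]])
      at_end <- e == chrom_sizes[chr]
      mis <- (s %% step != 0) | (e %% step != 0 & !at_end)
      if (any(mis)) {
        i <- which(mis)[1L]
        stop("bedGraph interval not aligned to ", step, "-bp bins: ",
             chr[i], ":", s[i], "-", e[i])
      }
      for (i in seq_along(chr)) {
        bins <- (s[i] %/% step + 1L):ceiling(e[i] / step)
        counts[[chr[i]]][bins] <- counts[[chr[i]]][bins] + v[i]
      }
    } else {
      chr <- as.character(d[[1L]])
      idx <- as.integer(d[[2L]]) + 1L
      v <- as.numeric(d[[3L]])
      for (i in seq_along(chr)) {
        if (!chr[i] %in% names(counts)) {
          stop("unknown chromosome in counts table: ", chr[i])
        }
        if (idx[i] < 1L || idx[i] > length(counts[[chr[i]]])) {
          stop("bin index out of range on ", chr[i], ": ", idx[i] - 1L)
        }
        counts[[chr[i]]][idx[i]] <- counts[[chr[i]]][idx[i]] + v[i]
      }
    }
  }
  binned_track(counts, step, chrom_sizes, genome)
}

#' Write intervals as BED6 (+ summit) text
#'
#' Writes 0-based half-open coordinates. If the `GRanges` carries a `summit`
#' metadata column a 7th column with the summit offset is added, so that
#' [read_peaks()] round-trips (`format = "narrowPeak"` readers should use
#' [write_narrowpeak()] instead).
#'
#' @param gr A `GRanges`, typically from [read_peaks()].
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) gr$name else rep(".", n),
    score = rep(0L, n),
    strand = rep(".", n),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$summit)) d$summit <- gr$summit
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intervals as ENCODE narrowPeak
#'
#' @inheritParams write_bed
#' @export
write_narrowpeak <- function(gr, path) {
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = 0L, strand = ".", signal = 0, p = -1, q = -1,
    summit = if (!is.null(gr$summit)) gr$summit
             else (BiocGenerics::width(gr)) %/% 2L,
    stringsAsFactors = FALSE
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a binned track as bedGraph
#'
#' Zero bins are omitted; runs of equal values are not merged, one record
#' per bin.
#'
#' @param track A `binned_track`.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  rows <- lapply(names(track$counts), function(chr) {
    v <- track$counts[[chr]]
    nz <- which(v != 0)
    if (length(nz) == 0L) return(NULL)
    data.frame(chrom = chr,
               start = (nz - 1L) * track$step,
               end = pmin(nz * track$step, track$chrom_sizes[[chr]]),
               value = v[nz], stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) d <- data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0), value = numeric(0))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a named numeric matrix as TSV
#'
#' Row names go in a leading `id` column; the header row carries column
#' labels. `read_matrix_tsv(write_matrix_tsv(x)) == x`.
#'
#' @param m Numeric matrix with row and column names.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}
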