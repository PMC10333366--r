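#' Least-squares quadratic fit to a time course
#'
#' Ordinary least squares of `y` on the monomial basis `(1, t, t^2)`, so
#' that `f(t) = a*t^2 + b*t + c`. With exactly three points the fit
#' interpolates (RSS = 0). Time is in hours, `y` in normalized signal
#' units (reference-adjusted RPKM).
#'
#' @param t Strictly increasing numeric vector of timepoints (length >= 3).
#' @param y Signal values, same length as `t`.
#' @return A `quad_fit` list: `a`, `b`, `c`, `rss`.
#' @export
fit_quadratic <- function(t, y) {
  if (length(t) < 3L) stop("need at least 3 timepoints for a quadratic fit")
  if (length(t) != length(y)) stop("t and y lengths differ")
  if (any(diff(t) <= 0)) stop("timepoints must be strictly increasing")
  X <- cbind(1, t, t * t)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  structure(list(a = unname(cf[3L]), b = unname(cf[2L]), c = unname(cf[1L]),
                 rss = sum(fit$residuals^2)),
            class = "quad_fit")
}

#' Evaluate a quadratic fit
#' @param fit A `quad_fit`.
#' @param t Timepoints.
#' @return `a*t^2 + b*t + c`.
#' @export
predict_quadratic <- function(fit, t) {
  fit$a * t * t + fit$b * t + fit$c
}

#' Bounded argmax of a quadratic on \[T0, Tx\]
#'
#' The time in `[T0, Tx]` at which `f` attains its maximum: the vertex
#' `-b/(2a)` when the parabola opens downward and the vertex falls inside
#' the interval, otherwise the boundary with the larger value. Exact ties
#' resolve to `Tx`.
#'
#' @param fit A `quad_fit`.
#' @param T0,Tx Interval bounds (hours), `T0 < Tx`.
#' @return `Tmax` in `[T0, Tx]`.
#' @export
bounded_argmax <- function(fit, T0, Tx) {
  if (T0 >= Tx) stop("require T0 < Tx")
  cand <- c(T0, Tx)
  if (fit$a < 0) {
    vertex <- -fit$b / (2 * fit$a)
    if (vertex >= T0 && vertex <= Tx) cand <- c(cand, vertex)
  }
  vals <- predict_quadratic(fit, cand)
  # ties resolve to the latest candidate time
  best <- max(vals)
  max(cand[vals >= best - 0])
}

#' Restoration rate of a fitted time course
#'
#' The average derivative of the fitted quadratic over `n` equally spaced
#' points spanning `[T0, Tmax]` (both endpoints included), where `Tmax` is
#' the bounded argmax of `f` on `[T0, Tx]`:
#' `RR = (1/n) * sum f'(t_i)` with `f'(t) = 2*a*t + b`. Because `f'` is
#' linear this equals `f'` at the grid mean, and converges to the mean
#' slope `(f(Tmax) - f(T0)) / (Tmax - T0)` as `n` grows. In the degenerate
#' case `Tmax = T0` the continuity limit `f'(T0)` is returned.
#'
#' @param fit A `quad_fit`.
#' @param T0,Tx Time-course bounds in hours.
#' @param n Number of grid points (default 10000, >= 2).
#' @return List: `RR` (signal units per hour), `Tmax`.
#' @export
restoration_rate <- function(fit, T0, Tx, n = 10000L) {
  if (n < 2L) stop("n must be at least 2")
  Tmax <- bounded_argmax(fit, T0, Tx)
  if (Tmax == T0) {
    return(list(RR = 2 * fit$a * T0 + fit$b, Tmax = Tmax))
  }
  grid <- seq(T0, Tmax, length.out = n)
  list(RR = mean(2 * fit$a * grid + fit$b), Tmax = Tmax)
}

#' Per-peak restoration-rate table
#'
#' Fits each row of a peaks x timepoints matrix with a quadratic and
#' computes its restoration rate.
#'
#' @param tc Numeric matrix of normalized signal, peaks in rows; rownames
#'   are peak ids.
#' @param timepoints Hours for each column (strictly increasing, >= 3).
#' @param Tx Upper bound for the argmax search; defaults to the last
#'   timepoint.
#' @param n Derivative grid size (default 10000).
#' @return data.frame: peak_id, a, b, c, rss, Tmax, RR.
#' @export
rr_table <- function(tc, timepoints, Tx = max(timepoints), n = 10000L) {
  stopifnot(is.matrix(tc), ncol(tc) == length(timepoints))
  T0 <- timepoints[1L]
  rows <- lapply(seq_len(nrow(tc)), function(i) {
    fit <- fit_quadratic(timepoints, tc[i, ])
    rr <- restoration_rate(fit, T0, Tx, n)
    data.frame(peak_id = rownames(tc)[i], a = fit$a, b = fit$b, c = fit$c,
               rss = fit$rss, Tmax = rr$Tmax, RR = rr$RR,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quartile clusters of restoration rates
#'
#' Splits peaks into four clusters by descending restoration rate:
#' "super-fast" (A, top quartile), "fast" (B), "slow" (C) and
#' "bottom-slow" (D). Cluster sizes differ by at most one, with any
#' remainder going to the faster clusters; ties keep the stable input
#' order.
#'
#' @param rr Numeric vector of restoration rates (length >= 4).
#' @return Factor of labels in input order, levels
#'   `c("super-fast", "fast", "slow", "bottom-slow")`.
#' @export
rr_quartile_clusters <- function(rr) {
  nv <- length(rr)
  if (nv < 4L) stop("need at least 4 values for quartile clusters")
  if (length(unique(rr)) == 1L) {
    warning("all restoration rates equal; quartiles split by input order")
  }
  sizes <- rep(nv %/% 4L, 4L)
  rem <- nv %% 4L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  labels <- c("super-fast", "fast", "slow", "bottom-slow")
  ord <- order(rr, decreasing = TRUE)   # stable for ties
  lab <- character(nv)
  lab[ord] <- rep(labels, times = sizes)
  factor(lab, levels = labels)
}

#' Five summit-centered analysis windows per peak
#'
#' The analysis region is +/-750 bp centered at each peak's summit. In
#' `"tiles"` mode (default) it is cut into five non-overlapping 300-bp
#' windows; in `"sliding"` mode five 1.5-kb windows are placed every
#' 300 bp, each centered on one of the same five window centers. Window
#' centers are labeled -600, -300, 0, +300, +600 bp relative to the
#' summit. Peaks whose windows would run off a chromosome end are skipped
#' with a message.
#'
#' @param peaks `GRanges` with `name` and `summit` columns.
#' @param chrom_sizes Named chromosome lengths.
#' @param mode `"tiles"` or `"sliding"`.
#' @return `GRanges` of windows with `name` (peak) and `window_center`
#'   metadata columns.
#' @export
summit_windows <- function(peaks, chrom_sizes, mode = c("tiles", "sliding")) {
  mode <- match.arg(mode)
  centers <- c(-600L, -300L, 0L, 300L, 600L)
  half <- if (mode == "tiles") 150L else 750L
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  summit_pos <- BiocGenerics::start(peaks) - 1L + peaks$summit  # 0-based
  reach <- max(abs(centers)) + half
  len <- chrom_sizes[chrom]
  ok <- summit_pos - reach >= 0 & summit_pos + reach <= len
  if (any(!ok)) {
    message(sum(!ok), " peak(s) too close to a chromosome edge skipped")
  }
  idx <- which(ok)
  n <- length(idx)
  GenomicRanges::GRanges(
    rep(chrom[idx], each = 5L),
    IRanges::IRanges(
      start = rep(summit_pos[idx], each = 5L) + rep(centers, n) - half + 1L,
      end = rep(summit_pos[idx], each = 5L) + rep(centers, n) + half
    ),
    name = rep(peaks$name[idx], each = 5L),
    window_center = rep(centers, n)
  )
}

#' Spatial restoration-rate profile around peak summits
#'
#' Computes the restoration rate for each of the five summit-centered
#' windows of every peak, then averages across peaks per window position.
#'
#' @param tc_by_window Named list of five peaks x timepoints matrices, one
#'   per window center; names are the centers (e.g. "-600").
#' @param timepoints Hours per column.
#' @param Tx,n Passed to [rr_table()].
#' @return data.frame: window_center, mean_RR, n_peaks.
#' @export
rr_spatial_profile <- function(tc_by_window, timepoints,
                               Tx = max(timepoints), n = 10000L) {
  stopifnot(is.list(tc_by_window), length(tc_by_window) == 5L)
  rows <- lapply(names(tc_by_window), function(ctr) {
    tab <- rr_table(tc_by_window[[ctr]], timepoints, Tx, n)
    data.frame(window_center = as.integer(ctr),
               mean_RR = mean(tab$RR), n_peaks = nrow(tab))
  })
  out <- do.call(rbind, rows)
  out[order(out$window_center), , drop = FALSE]
}
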