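#' Standardize time-course trajectories
#'
#' Row-wise z-score (mean 0, sd 1, sd with denominator n-1) so that
#' clustering sees the shape and timing of each trajectory, not its
#' amplitude. Constant rows cannot be standardized; they are dropped and
#' reported.
#'
#' @param tc Peaks x timepoints numeric matrix.
#' @return Standardized matrix (constant rows removed), with attribute
#'   `excluded` holding the dropped row names.
#' @export
standardize_trajectories <- function(tc) {
  stopifnot(is.matrix(tc), ncol(tc) >= 2L)
  mu <- rowMeans(tc)
  sdv <- apply(tc, 1L, stats::sd)
  keep <- sdv > 0
  if (any(!keep)) {
    message(sum(!keep), " constant trajectorie(s) excluded from clustering")
  }
  z <- (tc[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  attr(z, "excluded") <- rownames(tc)[!keep]
  z
}

#' Seeded fuzzy c-means clustering of trajectories
#'
#' Standard Bezdek fuzzy c-means with Euclidean distance: memberships
#' `u_ij` proportional to `(1/d_ij^2)^(1/(m-1))`, centroids the
#' `u^m`-weighted means, iterated until the objective
#' `sum_ij u_ij^m d_ij^2` changes by less than `tol`. Initial centroids
#' are `k` distinct trajectories sampled under the seed, so runs are
#' deterministic.
#'
#' @param x Trajectories (rows) x timepoints matrix, typically
#'   standardized by [standardize_trajectories()].
#' @param k Number of clusters (1 <= k <= nrow(x)).
#' @param fuzzifier Fuzzifier m > 1 (default 2).
#' @param seed Integer seed for centroid initialization.
#' @param max_iter Iteration cap (default 200).
#' @param tol Objective-change convergence tolerance (default 1e-9).
#' @param centers Optional k x timepoints matrix of initial centroids;
#'   overrides the seeded sampling.
#' @return List of class `fuzzy_clustering`: `centroids` (k x timepoints),
#'   `membership` (rows x k, rows sum to 1), `labels` (hard assignment,
#'   ties to the lower cluster index), `objective` (per-iteration values),
#'   `converged`, `k`, `fuzzifier`, `seed`.
#' @export
fuzzy_cmeans <- function(x, k, fuzzifier = 2, seed = 1L,
                         max_iter = 200L, tol = 1e-9, centers = NULL) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (k < 1L || k > n) stop("require 1 <= k <= number of trajectories")
  if (fuzzifier <= 1) stop("fuzzifier must exceed 1")
  if (k == 1L) {
    centroids <- matrix(colMeans(x), nrow = 1L,
                        dimnames = list(NULL, colnames(x)))
    u <- matrix(1, n, 1L, dimnames = list(rownames(x), NULL))
    return(structure(list(centroids = centroids, membership = u,
                          labels = rep(1L, n), objective = numeric(0),
                          converged = TRUE, k = 1L, fuzzifier = fuzzifier,
                          seed = seed),
                     class = "fuzzy_clustering"))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  if (is.null(centers)) {
    set.seed(seed)
    centroids <- x[sample.int(n, k), , drop = FALSE]
  } else {
    stopifnot(is.matrix(centers), nrow(centers) == k,
              ncol(centers) == ncol(x))
    centroids <- centers
  }
  expo <- 1 / (fuzzifier - 1)
  obj <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # squared distances n x k
    d2 <- outer(rowSums(x^2), rep(1, k)) +
      outer(rep(1, n), rowSums(centroids^2)) -
      2 * x %*% t(centroids)
    d2[d2 < 1e-300] <- 1e-300
    w <- d2^(-expo)
    u <- w / rowSums(w)
    um <- u^fuzzifier
    obj <- c(obj, sum(um * d2))
    centroids <- (t(um) %*% x) / colSums(um)
    if (iter > 1L && abs(obj[iter - 1L] - obj[iter]) < tol) {
      converged <- TRUE
      break
    }
  }
  dimnames(centroids) <- list(NULL, colnames(x))
  rownames(u) <- rownames(x)
  structure(list(centroids = centroids, membership = u,
                 labels = max.col(u, ties.method = "first"),
                 objective = obj, converged = converged, k = k,
                 fuzzifier = fuzzifier, seed = seed),
            class = "fuzzy_clustering")
}

#' Semantic names for restoration-pattern clusters
#'
#' With k = 3, clusters are named by the timing of their centroid maxima:
#' the centroid peaking earliest is "early", then "intermediate", then
#' "late" restoration. Argmax ties between centroids are broken in favor
#' of the centroid with the larger value at the first timepoint (it is
#' restoring earlier) and logged. For k != 3 generic names are returned
#' with a warning.
#'
#' @param clustering A `fuzzy_clustering`.
#' @param timepoints Hours per centroid column.
#' @return Character vector mapping cluster index to semantic name.
#' @export
name_clusters <- function(clustering, timepoints) {
  cen <- clustering$centroids
  if (clustering$k != 3L) {
    warning("semantic names are defined for k = 3; using generic names")
    return(paste0("cluster_", seq_len(clustering$k)))
  }
  argmax_t <- timepoints[max.col(cen, ties.method = "first")]
  if (anyDuplicated(argmax_t)) {
    message("centroid argmax tie broken by value at the first timepoint")
  }
  ord <- order(argmax_t, -cen[, 1L])
  nm <- character(3L)
  nm[ord] <- c("early", "intermediate", "late")
  nm
}

#' Cluster label proportions
#'
#' @param labels Vector (or factor) of cluster labels.
#' @return Named numeric vector of fractions summing to 1.
#' @export
cluster_proportions <- function(labels) {
  if (length(labels) == 0L) stop("no labels")
  tab <- table(labels)
  stats::setNames(as.numeric(tab) / length(labels), names(tab))
}
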