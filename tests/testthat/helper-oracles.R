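# Independent oracles used across tests. Each reimplements the target
# quantity by a different route (brute force, enumeration, closed form)
# than the package code.

# quadratic-time Benjamini-Hochberg step-up:
# q_i = min_{j >= i} p_(j) * m / j, capped at 1, in the input order
bh_oracle <- function(p, m = length(p)) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- (m / seq_len(n)) * p[ord]
  q <- vapply(seq_len(n), function(i) min(q_sorted[i:n]), numeric(1))
  out <- numeric(n)
  out[ord] <- pmin(q, 1)
  out
}

# Poisson upper tail by direct finite summation of the pmf
poisson_tail_oracle <- function(k, lambda) {
  if (k == 0) return(1)
  i <- 0:(k - 1)
  terms <- exp(-lambda + i * log(lambda) - lfactorial(i))
  1 - sum(terms)
}

# closed-form 3x3 normal-equations solve for the quadratic fit
quadfit_oracle <- function(t, y) {
  X <- cbind(1, t, t * t)
  cf <- solve(crossprod(X), crossprod(X, y))
  list(c = cf[1], b = cf[2], a = cf[3],
       rss = sum((y - X %*% cf)^2))
}

# closed-form mean slope of a quadratic between T0 and Tmax
mean_slope_oracle <- function(a, b, cc, T0, Tmax) {
  f <- function(t) a * t * t + b * t + cc
  (f(Tmax) - f(T0)) / (Tmax - T0)
}

# exact two-sided signed-rank p by literal enumeration of all 2^n sign
# assignments (zeros dropped, midranks)
signrank_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(grid %*% r)
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

# reference quadratic truth for small kinetic fixtures:
# f(t) = A - a2 * (t - Tmax)^2 with f(0) = L0
make_true_quadratic <- function(L0, a2, Tmax) {
  list(a = -a2, b = 2 * a2 * Tmax, c = L0,
       true_RR = if (Tmax > 0) a2 * Tmax else 0)
}
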