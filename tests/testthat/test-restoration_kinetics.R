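tp <- c(0, 2, 4, 6)

test_that("quadratic fits recover exact and least-squares solutions", {
  f1 <- fit_quadratic(tp, rep(5, 4))
  expect_equal(c(f1$a, f1$b, f1$c, f1$rss), c(0, 0, 5, 0))

  f2 <- fit_quadratic(tp, tp^2)
  expect_equal(c(f2$a, f2$b, f2$c, f2$rss), c(1, 0, 0, 0))

  y <- c(1, 5, 7, 7)
  f3 <- fit_quadratic(tp, y)
  o <- quadfit_oracle(tp, y)
  expect_equal(f3$a, o$a, tolerance = 1e-9)
  expect_equal(f3$b, o$b, tolerance = 1e-9)
  expect_equal(f3$c, o$c, tolerance = 1e-9)
  expect_equal(f3$rss, o$rss, tolerance = 1e-9)

  # three points interpolate
  f4 <- fit_quadratic(c(0, 2, 4), c(1, 3, 2))
  expect_equal(f4$rss, 0, tolerance = 1e-12)

  expect_error(fit_quadratic(c(0, 2), c(1, 2)), "at least 3")
  expect_error(fit_quadratic(c(0, 2, 2, 6), c(1, 2, 3, 4)),
               "strictly increasing")
})

test_that("bounded argmax picks the vertex or the better boundary", {
  vertex_in <- structure(list(a = -1, b = 6, c = 0), class = "quad_fit")
  expect_equal(bounded_argmax(vertex_in, 0, 6), 3)
  increasing <- structure(list(a = 0, b = 1, c = 0), class = "quad_fit")
  expect_equal(bounded_argmax(increasing, 0, 6), 6)
  decreasing <- structure(list(a = 0, b = -1, c = 0), class = "quad_fit")
  expect_equal(bounded_argmax(decreasing, 0, 6), 0)
  # constant: tie resolves to Tx
  flat <- structure(list(a = 0, b = 0, c = 2), class = "quad_fit")
  expect_equal(bounded_argmax(flat, 0, 6), 6)
})

test_that("restoration rate equals the closed-form mean slope", {
  fit <- structure(list(a = -1, b = 6, c = 0), class = "quad_fit")
  rr <- restoration_rate(fit, 0, 6)
  expect_equal(rr$Tmax, 3)
  expect_equal(rr$RR, 3.0)

  flat <- structure(list(a = 0, b = 0, c = 7), class = "quad_fit")
  expect_equal(restoration_rate(flat, 0, 6)$RR, 0)

  set.seed(20)
  for (rep in 1:100) {
    a <- -runif(1, 0.5, 5)
    vtx <- runif(1, 0.5, 5.5)        # interior vertex
    b <- -2 * a * vtx
    cc <- runif(1, -5, 5)
    fit <- structure(list(a = a, b = b, c = cc), class = "quad_fit")
    rr <- restoration_rate(fit, 0, 6, n = 10000L)
    expect_equal(rr$Tmax, vtx, tolerance = 1e-12)
    expect_lt(abs(rr$RR - mean_slope_oracle(a, b, cc, 0, rr$Tmax)), 1e-9)
  }
  expect_error(restoration_rate(fit, 0, 6, n = 1), "at least 2")
})

test_that("RR is shift-invariant in y and scales linearly", {
  set.seed(21)
  y <- c(2, 9, 11, 8)
  rr0 <- restoration_rate(fit_quadratic(tp, y), 0, 6)$RR
  rr_shift <- restoration_rate(fit_quadratic(tp, y + 100), 0, 6)$RR
  expect_equal(rr_shift, rr0)
  rr_scale <- restoration_rate(fit_quadratic(tp, 3.5 * y), 0, 6)$RR
  expect_equal(rr_scale, 3.5 * rr0)
})

test_that("rr_table recovers known quadratics and is order-independent", {
  truth <- list(make_true_quadratic(10, 2, 3),
                make_true_quadratic(50, 4, 5),
                make_true_quadratic(80, 3, 1))
  tc <- t(vapply(truth, function(q) q$a * tp^2 + q$b * tp + q$c,
                 numeric(4)))
  rownames(tc) <- paste0("pk", 1:3)
  tab <- rr_table(tc, tp)
  for (i in 1:3) expect_equal(tab$RR[i], truth[[i]]$true_RR,
                              tolerance = 1e-9)
  perm <- c(3, 1, 2)
  tab2 <- rr_table(tc[perm, ], tp)
  expect_equal(tab2$RR, tab$RR[perm])

  zero <- matrix(0, 3, 4, dimnames = list(paste0("z", 1:3), NULL))
  expect_true(all(rr_table(zero, tp)$RR == 0))
})

test_that("RR is stable between n = 1000 and n = 10000", {
  set.seed(22)
  worst <- 0
  for (rep in 1:200) {
    y <- runif(4, 0, 100)
    fit <- fit_quadratic(tp, y)
    r1 <- restoration_rate(fit, 0, 6, n = 1000L)$RR
    r2 <- restoration_rate(fit, 0, 6, n = 10000L)$RR
    worst <- max(worst, abs(r2 - r1) / (abs(r2) + 1e-12))
  }
  expect_lt(worst, 1e-3)
})

test_that("quartile clusters split by descending RR with stable ties", {
  lab <- rr_quartile_clusters(c(5, 7, 1, 3, 8, 2, 6, 4))
  expect_equal(as.character(lab[c(5, 2)]), rep("super-fast", 2))
  expect_equal(as.character(lab[c(3, 6)]), rep("bottom-slow", 2))

  sizes <- table(rr_quartile_clusters(rnorm(4187)))
  expect_equal(unname(as.integer(sizes)), c(1047, 1047, 1047, 1046))

  expect_warning(tied <- rr_quartile_clusters(rep(1, 8)), "equal")
  expect_equal(as.character(tied[1:2]), rep("super-fast", 2))
  expect_error(rr_quartile_clusters(1:3), "at least 4")
})

test_that("summit windows tile +/-750 bp and skip edge peaks", {
  cs <- c(chr1 = 100000L)
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(5001, 201), width = 2000),
    name = c("mid", "edge"), summit = c(1000L, 100L))
  expect_message(w <- summit_windows(peaks, cs), "1 peak")
  expect_length(w, 5L)
  expect_equal(w$window_center, c(-600L, -300L, 0L, 300L, 600L))
  # summit of "mid" is at 0-based 6000; central window covers it
  central <- w[w$window_center == 0L]
  expect_equal(BiocGenerics::start(central) - 1L, 6000L - 150L)
  expect_equal(BiocGenerics::width(w), rep(300L, 5))
  # five windows tile [summit - 750, summit + 750) without overlap
  expect_equal(sum(BiocGenerics::width(GenomicRanges::reduce(w))), 1500L)

  wide <- summit_windows(peaks[1], cs, mode = "sliding")
  expect_equal(BiocGenerics::width(wide), rep(1500L, 5))
})

test_that("spatial profile averages per-window rates", {
  truth <- list(make_true_quadratic(20, 2, 3), make_true_quadratic(40, 5, 4))
  base <- t(vapply(truth, function(q) q$a * tp^2 + q$b * tp + q$c,
                   numeric(4)))
  rownames(base) <- c("p1", "p2")
  centers <- c("-600", "-300", "0", "300", "600")
  # identical kinetics in all windows -> flat profile
  flat <- rr_spatial_profile(setNames(rep(list(base), 5), centers), tp)
  expect_equal(var(flat$mean_RR), 0, tolerance = 1e-18)
  # single peak -> profile equals that peak's window rates
  single <- rr_spatial_profile(
    setNames(rep(list(base["p1", , drop = FALSE]), 5), centers), tp)
  expect_equal(single$mean_RR, rep(truth[[1]]$true_RR, 5), tolerance = 1e-9)
  # center-enriched amplitude -> center-maximal, non-increasing outward
  amp <- c(0.5, 0.8, 1, 0.8, 0.5)
  scaled <- setNames(lapply(amp, function(a) base * a), centers)
  prof <- rr_spatial_profile(scaled, tp)
  expect_equal(which.max(prof$mean_RR), 3L)
  expect_true(all(diff(prof$mean_RR[1:3]) > 0))
  expect_true(all(diff(prof$mean_RR[3:5]) < 0))
})
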