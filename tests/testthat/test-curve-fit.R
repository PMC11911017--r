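test_that("marking keeps peak and endpoints when the scan finds nothing", {
  # interior peak; the only significant pair (2,5) never involves the
  # scan reference, so rules ii adds nothing and rule iii adds the ends
  b <- make_binned(c(5, 3, 30, 6, 4), 0:5)
  sig <- matrix(FALSE, 5, 5)
  sig[2, 5] <- sig[5, 2] <- TRUE
  m <- mark_points(b, sig)
  expect_equal(m$indices, c(1L, 3L, 5L))
  expect_equal(m$highest_index, 3L)
  expect_equal(m$degree, 2L)
})

test_that("a fully significant staircase marks every bin", {
  # large N makes adjacent CIs disjoint
  counts <- c(5000, 3000, 1500, 400, 100)
  b <- make_binned(counts, 0:5)
  sig <- pairwise_significance(b)
  expect_true(all(sig[upper.tri(sig)]))
  m <- mark_points(b, sig)
  expect_equal(m$indices, 1:5)
  expect_equal(m$degree, 4L)
})

test_that("the marking scan agrees with a brute-force oracle", {
  set.seed(21)
  for (rep in 1:40) {
    k <- sample(4:12, 1)
    counts <- as.vector(stats::rmultinom(1, size = sample(c(80, 2000), 1),
                                         prob = rgamma(k, 1.2)))
    if (sum(counts) == 0) next
    b <- make_binned(counts, 0:k)
    sig <- pairwise_significance(b)
    if (!any(sig)) next
    m <- mark_points(b, sig)
    expect_equal(m$indices, mark_oracle(b$proportions, sig))
    expect_equal(m$degree, m$n_marked - 1L)
  }
})

test_that("reversing the gradient mirrors the marked set", {
  set.seed(33)
  for (rep in 1:20) {
    k <- sample(5:10, 1)
    counts <- as.vector(stats::rmultinom(1, 3000, prob = rgamma(k, 1.5)))
    b <- make_binned(counts, 0:k)
    sig <- pairwise_significance(b)
    if (!any(sig) || sum(counts == max(counts)) > 1L) next
    b_rev <- make_binned(rev(counts), 0:k)
    sig_rev <- pairwise_significance(b_rev)
    m <- mark_points(b, sig)
    m_rev <- mark_points(b_rev, sig_rev)
    expect_equal(sort(k + 1L - m_rev$indices), m$indices)
  }
})

test_that("ties at the maximum resolve to the leftmost bin", {
  b <- make_binned(c(10, 40, 40, 10), 0:4)
  sig <- matrix(FALSE, 4, 4); sig[1, 4] <- sig[4, 1] <- TRUE
  expect_equal(mark_points(b, sig)$highest_index, 2L)
})

test_that("no significant pair raises the exclusion condition", {
  b <- make_binned(c(10, 10, 10), 0:3)
  sig <- pairwise_significance(b)
  expect_error(mark_points(b, sig), class = "nichegradient_exclusion")
})

test_that("degree overrides shift the polynomial degree by one term", {
  b <- make_binned(c(5000, 3000, 1500, 400, 100), 0:5)
  sig <- pairwise_significance(b)
  expect_equal(mark_points(b, sig, degree_delta = -1L)$degree, 3L)
  expect_equal(mark_points(b, sig, degree_delta = 1L)$degree, 5L)
})

test_that("intercept-only fit recovers the common proportion", {
  b <- make_binned(c(10, 10, 10, 10), 0:4)
  d <- fit_logistic_polynomial(b, degree = 0L)
  expect_equal(d$p(c(0.7, 2.2, 3.9)), rep(0.25, 3), tolerance = 1e-6)
})

test_that("a two-bin decreasing sample yields a decreasing logit line", {
  b <- make_binned(c(20, 0), 0:2)
  d <- fit_logistic_polynomial(b, degree = 1L)
  expect_gt(d$p(b$midpoints[1L]), d$p(b$midpoints[2L]))
  xs <- seq(0, 2, length.out = 50)
  # separation saturates the logistic at the ends: non-increasing overall
  expect_true(all(diff(d$p(xs)) <= 0))
})

test_that("a known quadratic-logit curve is recovered from bin counts", {
  k <- 15L
  n_total <- 1e5L
  edges <- seq(0, 1, length.out = k + 1L)
  mids <- (edges[-1L] + edges[-(k + 1L)]) / 2
  z <- 2 * (mids - min(mids)) / (max(mids) - min(mids)) - 1
  truth <- stats::plogis(-2.2 + 0.8 * z - 3.0 * z^2)
  counts <- round(n_total * truth)
  b <- make_binned(counts, edges, N = n_total)
  d <- fit_logistic_polynomial(b, degree = 2L)
  expect_true(all(abs(d$p(mids) - truth) < 0.02))
})

test_that("fitted curves stay inside (0,1) and refit deterministically", {
  set.seed(55)
  x <- c(rnorm(150, 12, 2), rnorm(80, 17, 1.5))
  b <- bin_counts(x, compute_bins(x))
  m <- mark_points(b, pairwise_significance(b))
  d <- fit_logistic_polynomial(b, degree = min(m$degree, b$k - 1L))
  grid <- seq(d$domain[1L], d$domain[2L], length.out = 1000L)
  p <- d$p(grid)
  expect_true(all(p > 0 & p < 1))
  d2 <- fit_logistic_polynomial(b, degree = min(m$degree, b$k - 1L))
  expect_identical(d$coefficients, d2$coefficients)
})

test_that("both coefficient scales evaluate to the same curve", {
  set.seed(77)
  x <- rgamma(250, shape = 4, scale = 50)
  b <- bin_counts(x, compute_bins(x))
  d <- fit_logistic_polynomial(b, degree = 3L)
  grid <- seq(d$domain[1L], d$domain[2L], length.out = 200L)
  eta_x <- drop(outer(grid, 0:d$degree, `^`) %*% d$coefficients_x)
  expect_equal(stats::plogis(eta_x), d$p(grid), tolerance = 1e-6)
})
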