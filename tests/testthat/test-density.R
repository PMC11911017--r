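gauss_curve <- function(center, height = 0.6, width = 1) {
  force(center); force(height); force(width)
  function(x) height * exp(-((x - center) / width)^2 / 2)
}

test_that("total area integrates the curve over the sample range", {
  d <- fake_density(function(x) rep(0.5, length(x)), c(0, 10))
  expect_equal(total_area(d), 5)

  d1 <- fake_density(function(x) 0.1 * exp(-x), c(0, 4))
  d2 <- fake_density(function(x) 0.2 * exp(-x), c(0, 4))
  expect_equal(total_area(d2), 2 * total_area(d1), tolerance = 1e-12)
})

test_that("Simpson integration matches adaptive quadrature on a fit", {
  set.seed(9)
  x <- c(rnorm(200, 30, 4), rnorm(100, 45, 5))
  b <- bin_counts(x, compute_bins(x))
  d <- fit_logistic_polynomial(b, degree = min(5L, b$k - 1L))
  ref <- stats::integrate(d$p, d$domain[1L], d$domain[2L],
                          rel.tol = 1e-10)$value
  expect_equal(total_area(d, grid_points = 2001L), ref,
               tolerance = 1e-6)
})

test_that("the mode of a symmetric peak is its center", {
  d <- fake_density(gauss_curve(3.7), c(0, 10))
  m <- find_mode(d)
  expect_equal(m$mode, 3.7, tolerance = 1e-4 * 10)
  expect_false(m$mode_at_endpoint)
})

test_that("a monotone curve has its mode on the endpoint, flagged", {
  d <- fake_density(function(x) stats::plogis(-3 + 0.8 * x), c(0, 10))
  m <- find_mode(d)
  expect_equal(m$mode, 10)
  expect_true(m$mode_at_endpoint)
  d2 <- fake_density(function(x) stats::plogis(3 - 0.8 * x), c(0, 10))
  m2 <- find_mode(d2)
  expect_equal(m2$mode, 0)
  expect_true(m2$mode_at_endpoint)
})

test_that("the quarter-area interval is symmetric for a symmetric peak", {
  d <- fake_density(gauss_curve(5), c(0, 10))
  h <- highest_probability_interval(d, mass = 0.25)
  expect_equal(h$mass, 0.25, tolerance = 1e-4)
  expect_equal(h$xU - 5, 5 - h$xL, tolerance = 1e-3)
  expect_false(h$flagged)
  expect_true(h$xL <= h$mode && h$mode <= h$xU)
})

test_that("an endpoint mode gives a one-sided interval", {
  d <- fake_density(function(x) stats::plogis(-4 + 0.9 * x), c(0, 10))
  h <- highest_probability_interval(d, mass = 0.25)
  expect_equal(h$xU, 10)
  expect_true(h$mode_at_endpoint)
  # xL solves the one-sided quarter-area equation
  total <- total_area(d)
  tail_area <- stats::integrate(d$p, h$xL, 10)$value
  expect_equal(tail_area / total, 0.25, tolerance = 1e-4)
})

test_that("the interval is the shortest one holding the target mass", {
  curves <- list(
    fake_density(gauss_curve(4, width = 1.5), c(0, 10)),
    fake_density(function(x) 0.5 * stats::dgamma(x, 3, scale = 1.2),
                 c(0.05, 12)))
  for (d in curves) {
    h <- highest_probability_interval(d, mass = 0.25)
    # brute force: shortest grid interval reaching a quarter of the area
    m <- 2001L
    xs <- seq(d$domain[1L], d$domain[2L], length.out = m)
    ys <- d$p(xs)
    hstep <- xs[2L] - xs[1L]
    cum <- c(0, cumsum((ys[-1L] + ys[-m]) / 2 * hstep))
    target <- 0.25 * cum[m]
    best_len <- Inf
    j <- 1L
    for (i in seq_len(m)) {
      while (j <= m && cum[j] - cum[i] < target) j <- j + 1L
      if (j > m) break
      len <- xs[j] - xs[i]
      if (len < best_len) best_len <- len
    }
    expect_equal(h$xU - h$xL, best_len, tolerance = 3 * hstep)
  }
})

test_that("the interval ignores positive rescaling of the curve", {
  d1 <- fake_density(function(x) 0.15 * exp(-(x - 6)^2 / 3), c(0, 12))
  d2 <- fake_density(function(x) 0.60 * exp(-(x - 6)^2 / 3), c(0, 12))
  h1 <- highest_probability_interval(d1)
  h2 <- highest_probability_interval(d2)
  expect_equal(h1$xL, h2$xL, tolerance = 1e-6)
  expect_equal(h1$xU, h2$xU, tolerance = 1e-6)
})

test_that("relative distance follows the three-case formula", {
  r0 <- relative_distance(40, 60, 0, 100)
  expect_equal(r0$relDis, 0)
  expect_equal(r0$side, "inside")
  r_above <- relative_distance(60, 70, 0, 100)
  expect_equal(r_above$relDis, 10)
  expect_equal(r_above$side, "above")
  r_below <- relative_distance(10, 20, 0, 100)
  expect_equal(r_below$relDis, -30)
  expect_equal(r_below$side, "below")
  expect_error(relative_distance(1, 2, 5, 5), "degenerate")
})

test_that("relative distance never leaves [-50, 50] and mirrors", {
  set.seed(101)
  for (rep in 1:200) {
    lims <- sort(stats::runif(2, -100, 100))
    while (diff(lims) < 1e-6) lims <- sort(stats::runif(2, -100, 100))
    ab <- sort(stats::runif(2, lims[1L], lims[2L]))
    if (ab[1L] == ab[2L]) next
    r <- relative_distance(ab[1L], ab[2L], lims[1L], lims[2L])
    expect_gte(r$relDis, -50)
    expect_lte(r$relDis, 50)
    # mirror: negating the axis negates relDis and swaps the side
    rm <- relative_distance(-ab[2L], -ab[1L], -lims[2L], -lims[1L])
    expect_equal(rm$relDis, -r$relDis, tolerance = 1e-10)
    expect_equal(rm$side,
                 switch(r$side, inside = "inside", below = "above",
                        above = "below"))
  }
  # extremes only as the interval collapses onto a range endpoint
  eps <- 1e-9
  hi <- relative_distance(100 - eps, 100, 0, 100)
  expect_equal(hi$relDis, 50, tolerance = 1e-6)
  lo <- relative_distance(0, eps, 0, 100)
  expect_equal(lo$relDis, -50, tolerance = 1e-6)
})

test_that("centroid displacement reduces to unidimensional distance", {
  expect_equal(centroid_displacement_distance(c(3, 4)), 5)
  expect_equal(centroid_displacement_distance(c(0, 0, -7, 0)), 7)
  expect_equal(centroid_displacement_distance(rep(0, 5)), 0)
})
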