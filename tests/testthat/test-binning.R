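test_that("bin width follows 2*IQR/n^(1/3) with edges anchored at min", {
  values <- 1:8  # IQR (type 7) = 3.5, n^(1/3) = 2
  edges <- compute_bins(values, rule = "fd_as_written")
  expect_equal(edges[2L] - edges[1L], 3.5)
  expect_equal(edges[1L], 1)
  expect_gte(edges[length(edges)], 8)

  # zero IQR degenerates the width; Sturges fallback with a warning
  expect_warning(e2 <- compute_bins(c(rep(5, 10), 1, 9),
                                    rule = "fd_as_written"),
                 "falling back")
  expect_true(min(e2) <= 1 && max(e2) >= 9)

  expect_error(compute_bins(rep(2, 5)), "degenerate")
})

test_that("sturges_r rule gives ceil(log2 n)+1 nice-width bins", {
  edges <- compute_bins(1:8, rule = "sturges_r")
  expect_equal(length(edges) - 1L, 4L)  # ceil(log2 8) + 1
  expect_equal(diff(edges), rep(2, 4))  # snapped to a nice width
  # edges cover arbitrary data
  set.seed(3)
  x <- rnorm(100, 50, 7)
  e <- compute_bins(x, rule = "sturges_r")
  expect_true(min(e) <= min(x) && max(e) >= max(x))
})

test_that("counting respects half-open bins with a closed last bin", {
  b <- bin_counts(c(0, 1, 2), edges = c(0, 1.5, 3))
  expect_equal(b$counts, c(2L, 1L))
  expect_equal(b$midpoints, c(0.75, 2.25))
  # the maximum lands exactly on the last edge and is counted once
  b2 <- bin_counts(c(0, 1.5, 3), edges = c(0, 1.5, 3))
  expect_equal(sum(b2$counts), 3L)
  expect_equal(b2$counts[2L], 2L)
})

test_that("counts conserve n and proportions sum to one", {
  set.seed(11)
  for (rep in 1:20) {
    x <- rgamma(sample(30:300, 1), shape = 2, scale = 10)
    b <- bin_counts(x, compute_bins(x))
    expect_equal(sum(b$counts), length(x))
    expect_equal(sum(b$proportions), 1)
    expect_true(all(b$ci_lower <= b$proportions + 1e-12))
    expect_true(all(b$proportions <= b$ci_upper + 1e-12))
    expect_true(all(b$ci_lower >= 0) && all(b$ci_upper <= 1))
  }
})

test_that("Bonferroni adjustment divides alpha by k", {
  expect_equal(bonferroni_alpha(0.05, 6), 0.05 / 6)
  expect_equal(round(bonferroni_alpha(0.05, 6), 4), 0.0083)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
})

test_that("Clopper-Pearson bounds match the binomial tail inversion", {
  expect_equal(clopper_pearson_ci(0, 50, 0.05)[1L, "lower"],
               c(lower = 0))
  expect_equal(clopper_pearson_ci(239, 239, 0.05)[1L, "upper"],
               c(upper = 1))
  expect_error(clopper_pearson_ci(10, 5, 0.05), "count")

  # independent oracle: bisection on the binomial tail sums
  cases <- rbind(c(94, 239), c(3, 50), c(47, 50), c(120, 250))
  for (i in seq_len(nrow(cases))) {
    got <- clopper_pearson_ci(cases[i, 1L], cases[i, 2L], 0.0083)
    want <- cp_oracle(cases[i, 1L], cases[i, 2L], 0.0083)
    expect_equal(unname(got[1L, ]), want, tolerance = 1e-8)
  }
})

test_that("smaller adjusted alpha never narrows a confidence interval", {
  n <- 200
  counts <- c(0, 1, 17, 94, 199, 200)
  ci_k1 <- clopper_pearson_ci(counts, n, 0.05)
  ci_k10 <- clopper_pearson_ci(counts, n, 0.005)
  expect_true(all(ci_k10[, "lower"] <= ci_k1[, "lower"] + 1e-15))
  expect_true(all(ci_k10[, "upper"] >= ci_k1[, "upper"] - 1e-15))
})

test_that("pairwise significance is strict non-overlap, symmetric", {
  b <- make_binned(c(5, 5), c(0, 1, 2))
  b$ci_lower <- c(0.1, 0.4); b$ci_upper <- c(0.3, 0.6)
  expect_true(pairwise_significance(b)[1L, 2L])
  b$ci_upper[1L] <- 0.4  # touching intervals overlap: not significant
  expect_false(pairwise_significance(b)[1L, 2L])

  b2 <- make_binned(c(10, 10, 10), c(0, 1, 2, 3))
  sig <- pairwise_significance(b2)
  expect_false(any(sig))  # equal counts: identical CIs
  expect_true(isSymmetric(sig))
  expect_false(any(diag(sig)))
})

test_that("omnibus chi-squared test matches hand computation", {
  b0 <- make_binned(c(10, 10, 10, 10), 0:4)
  r0 <- omnibus_chi_square(b0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  b1 <- make_binned(c(20, 0), 0:2)
  r1 <- omnibus_chi_square(b1)
  expect_equal(r1$statistic, 20)
  expect_equal(r1$df, 1L)

  # agrees with the stock goodness-of-fit implementation
  b2 <- make_binned(c(12, 30, 7, 1), 0:4)
  r2 <- omnibus_chi_square(b2)
  ref <- suppressWarnings(stats::chisq.test(b2$counts))
  expect_equal(r2$statistic, unname(ref$statistic))
  expect_equal(r2$p_value, unname(ref$p.value))

  # invariant under bin reordering
  b3 <- make_binned(c(1, 7, 30, 12), 0:4)
  expect_equal(omnibus_chi_square(b3)$statistic, r2$statistic)
})
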