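#' Histogram bin edges for a species-variable sample
#'
#' Two rules are available. `fd_as_written` uses a bin width of twice
#' the interquartile range divided by the cube root of the sample size
#' (quartiles by linear interpolation, R's default type 7), anchoring the
#' first edge at the sample minimum and taking K = ceiling(range / width)
#' bins so the last edge reaches at least the maximum. `sturges_r`
#' targets K = ceiling(log2 n) + 1 equal-width bins spanning the data,
#' with the width snapped up to a "nice" number (1, 2, 2.5 or 5 times a
#' power of ten) and edges anchored on multiples of that width. If the
#' IQR is zero the FD width degenerates, and the Sturges rule is used
#' with a warning.
#'
#' @param sample a `species_variable_sample` (or plain numeric vector).
#' @param rule `"fd_as_written"` or `"sturges_r"`.
#' @return Numeric vector of strictly increasing edges covering the data.
#' @export
compute_bins <- function(sample, rule = c("fd_as_written", "sturges_r")) {
  rule <- match.arg(rule)
  values <- if (inherits(sample, "species_variable_sample")) {
    sample$values
  } else {
    as.numeric(sample)
  }
  n <- length(values)
  if (n < 2L) stop("need at least 2 values to bin")
  lo <- min(values)
  hi <- max(values)
  if (lo == hi) stop("degenerate sample: all values identical")
  if (rule == "fd_as_written") {
    width <- 2 * stats::IQR(values, type = 7) / n^(1 / 3)
    if (width <= 0) {
      warning("interquartile range is zero; falling back to sturges_r")
      return(compute_bins(values, rule = "sturges_r"))
    }
    k <- ceiling((hi - lo) / width)
    edges <- lo + width * (0:k)
    # guard against the last edge falling a rounding error short of max
    if (edges[length(edges)] < hi) edges[length(edges)] <- hi
    return(edges)
  }
  k <- ceiling(log2(n)) + 1
  width <- nice_width((hi - lo) / k)
  first <- floor(lo / width) * width
  edges <- seq(first, by = width,
               length.out = ceiling((hi - first) / width) + 1L)
  if (edges[length(edges)] < hi) {
    edges <- c(edges, edges[length(edges)] + width)
  }
  edges
}

# smallest of {1, 2, 2.5, 5, 10} * 10^m at or above w
nice_width <- function(w) {
  stopifnot(w > 0)
  m <- floor(log10(w))
  base <- w / 10^m
  mult <- c(1, 2, 2.5, 5, 10)
  mult[which(base <= mult + 1e-12)[1L]] * 10^m
}

#' Bin a sample into given edges
#'
#' Bins are half-open `[e_i, e_{i+1})`, except the last bin which is
#' closed at the top so the sample maximum is counted exactly once.
#' Counts are converted to proportions of the total sample size, with
#' exact Clopper-Pearson confidence intervals at the Bonferroni-adjusted
#' level.
#'
#' @param sample a `species_variable_sample` or numeric vector.
#' @param edges strictly increasing numeric edges covering all values.
#' @param alpha family-wide significance level. The Bonferroni divisor
#'   is the number of bins; use [with_adjusted_alpha()] to rebuild the
#'   CIs under an alternative divisor (e.g., the number of marked
#'   points).
#' @return A list of class `binned_sample` with elements `edges`,
#'   `counts`, `midpoints`, `N`, `proportions`, `ci_lower`, `ci_upper`,
#'   `alpha`, `alpha_adj`, `k`.
#' @export
bin_counts <- function(sample, edges, alpha = 0.05) {
  values <- if (inherits(sample, "species_variable_sample")) {
    sample$values
  } else {
    as.numeric(sample)
  }
  stopifnot(length(edges) >= 2L, !is.unsorted(edges, strictly = TRUE))
  if (min(values) < edges[1L] || max(values) > edges[length(edges)]) {
    stop("internal error: edges do not cover the data")
  }
  k <- length(edges) - 1L
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = k)
  n_total <- length(values)
  alpha_adj <- bonferroni_alpha(alpha, k)
  ci <- clopper_pearson_ci(counts, n_total, alpha_adj)
  structure(list(edges = edges,
                 counts = counts,
                 midpoints = (edges[-length(edges)] + edges[-1L]) / 2,
                 N = n_total,
                 proportions = counts / n_total,
                 ci_lower = ci[, 1L],
                 ci_upper = ci[, 2L],
                 alpha = alpha,
                 alpha_adj = alpha_adj,
                 k = k,
                 xmin = min(values),
                 xmax = max(values)),
            class = "binned_sample")
}

#' Recompute a binned sample's confidence intervals at a new divisor
#'
#' @param binned a `binned_sample`.
#' @param k Bonferroni divisor to use.
#' @return The `binned_sample` with CIs and `alpha_adj` rebuilt.
#' @export
with_adjusted_alpha <- function(binned, k) {
  stopifnot(inherits(binned, "binned_sample"))
  binned$alpha_adj <- bonferroni_alpha(binned$alpha, k)
  ci <- clopper_pearson_ci(binned$counts, binned$N, binned$alpha_adj)
  binned$ci_lower <- ci[, 1L]
  binned$ci_upper <- ci[, 2L]
  binned
}

#' @export
print.binned_sample <- function(x, ...) {
  cat("Binned sample: K =", x$k, "bins, N =", x$N, "\n")
  cat("  alpha_adj =", format(x$alpha_adj, digits = 4), "\n")
  print(data.frame(midpoint = x$midpoints, count = x$counts,
                   proportion = round(x$proportions, 4),
                   ci_lower = round(x$ci_lower, 4),
                   ci_upper = round(x$ci_upper, 4)))
  invisible(x)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wide level, in (0, 1).
#' @param k number of comparisons, at least 1.
#' @return `alpha / k`.
#' @examples
#' bonferroni_alpha(0.05, 6) # 0.00833...
#' @export
bonferroni_alpha <- function(alpha, k) {
  stopifnot(alpha > 0, alpha < 1)
  if (any(k < 1)) stop("k must be at least 1")
  alpha / k
}

#' Exact Clopper-Pearson confidence interval for a binomial proportion
#'
#' The interval inverts the binomial tail probabilities; its bounds are
#' quantiles of Beta distributions. The lower bound is 0 when no
#' successes were observed, the upper bound 1 when all trials succeeded.
#'
#' @param count number of successes (vectorized).
#' @param n number of trials.
#' @param alpha_adj significance level (already adjusted for multiple
#'   comparisons when applicable).
#' @return A two-column matrix `cbind(lower, upper)`.
#' @export
clopper_pearson_ci <- function(count, n, alpha_adj) {
  stopifnot(n >= 1, alpha_adj > 0, alpha_adj < 1)
  if (any(count < 0) || any(count > n)) {
    stop("count must lie in [0, n]")
  }
  lower <- ifelse(count == 0, 0,
                  stats::qbeta(alpha_adj / 2, count, n - count + 1))
  upper <- ifelse(count == n, 1,
                  stats::qbeta(1 - alpha_adj / 2, count + 1, n - count))
  cbind(lower = lower, upper = upper)
}

#' Pairwise significance by strict CI non-overlap
#'
#' Bins i and j are declared significantly different when their
#' simultaneous confidence intervals do not overlap at all; intervals
#' that merely touch count as overlapping (not significant).
#'
#' @param binned a `binned_sample` with CIs computed.
#' @return A symmetric logical K x K matrix with `FALSE` diagonal.
#' @export
pairwise_significance <- function(binned) {
  stopifnot(inherits(binned, "binned_sample"))
  lo <- binned$ci_lower
  up <- binned$ci_upper
  sig <- outer(up, lo, `<`) | t(outer(up, lo, `<`))
  diag(sig) <- FALSE
  sig
}

#' Omnibus chi-squared test for equal bin proportions
#'
#' Pearson goodness-of-fit of the observed bin counts against equal
#' expected counts N/K in every bin (the uniformity null: no bin is
#' preferred along the gradient).
#'
#' @param binned a `binned_sample`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
omnibus_chi_square <- function(binned) {
  stopifnot(inherits(binned, "binned_sample"))
  k <- binned$k
  if (k < 2L) stop("need at least 2 bins")
  if (binned$N < k) stop("need N >= K for the omnibus test")
  expected <- binned$N / k
  statistic <- sum((binned$counts - expected)^2 / expected)
  df <- k - 1L
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}
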