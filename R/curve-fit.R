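#' Mark significantly different bins and choose the polynomial degree
#'
#' Implements the four marking rules that turn the binned proportions
#' and their simultaneous confidence intervals into a polynomial degree:
#' (i) mark the highest proportion (leftmost on ties, a fixed
#' deterministic choice); (ii) scanning outward from it on each side,
#' repeatedly mark the nearest bin whose confidence interval does not
#' overlap that of the most recently marked bin on that side; (iii) mark
#' both endpoint bins, which anchors the regression at the range limits;
#' (iv) the number of polynomial terms equals the number of marked
#' points, so the degree is one less (plus any configured per-combination
#' adjustment).
#'
#' A combination in which no two bins differ significantly carries no
#' usable shape information; such combinations are excluded from the
#' analysis, signalled by a condition of class
#' `nichegradient_exclusion`.
#'
#' @param binned a `binned_sample`.
#' @param significance K x K logical matrix from
#'   [pairwise_significance()].
#' @param degree_delta optional +/-1 adjustment of the polynomial terms.
#' @return A list of class `marked_points` with elements `indices`,
#'   `highest_index`, `n_marked`, `degree`.
#' @export
mark_points <- function(binned, significance, degree_delta = 0L) {
  stopifnot(inherits(binned, "binned_sample"),
            is.matrix(significance),
            nrow(significance) == binned$k)
  if (!any(significance)) {
    cond <- structure(
      class = c("nichegradient_exclusion", "error", "condition"),
      list(message = paste0(
             "no pair of bins differs significantly; ",
             "combination excluded from analysis"),
           call = sys.call()))
    stop(cond)
  }
  k <- binned$k
  highest <- which.max(binned$proportions)  # leftmost on ties
  marked <- highest
  for (step in c(-1L, 1L)) {
    ref <- highest
    j <- highest + step
    while (j >= 1L && j <= k) {
      if (significance[ref, j]) {
        marked <- c(marked, j)
        ref <- j
      }
      j <- j + step
    }
  }
  marked <- sort(unique(c(marked, 1L, k)))
  degree <- length(marked) - 1L + as.integer(degree_delta)
  if (degree < 1L) degree <- 1L
  structure(list(indices = marked,
                 highest_index = highest,
                 n_marked = length(marked),
                 degree = degree),
            class = "marked_points")
}

#' @export
print.marked_points <- function(x, ...) {
  cat("Marked points:", paste(x$indices, collapse = ", "),
      "(highest:", x$highest_index, ")\n")
  cat("  polynomial degree:", x$degree, "\n")
  invisible(x)
}

# coefficients of sum_j c_j (a + b x)^j as a polynomial in x
poly_compose_affine <- function(coef_z, a, b) {
  d <- length(coef_z) - 1L
  out <- numeric(d + 1L)
  pow <- 1  # (a + b x)^j, coefficients in x, starting with j = 0
  for (j in 0:d) {
    out[seq_along(pow)] <- out[seq_along(pow)] + coef_z[j + 1L] * pow
    # multiply by (a + b x)
    pow <- c(pow * a, 0) + c(0, pow * b)
  }
  out
}

#' Fit the polynomial logistic occurrence-probability curve
#'
#' Treats bin i as a binomial observation of `counts[i]` successes in N
#' trials located at the bin midpoint, and fits p(x) =
#' 1 / (1 + exp(-f(x))) with f a polynomial of the given degree, by
#' maximum likelihood (iteratively reweighted least squares, at most 100
#' iterations, deviance tolerance 1e-8). The predictor is standardized
#' to [-1, 1] before the polynomial expansion to keep the design matrix
#' well conditioned at high degree; coefficients are reported on both
#' scales and the returned curve evaluates on the original scale.
#'
#' If the optimizer fails to converge or yields non-finite coefficients
#' the degree is reduced by one and the fit repeated, recording each
#' reduction; failure below degree 1 is an error (degree 0 is only
#' accepted when explicitly requested).
#'
#' @param binned a `binned_sample`.
#' @param degree polynomial degree, at most K - 1.
#' @param grid_points grid size for the stored total-area value.
#' @return A list of class `fitted_density`: `coefficients` (standardized
#'   scale), `coefficients_x` (original scale), `degree`, `p` (function),
#'   `domain`, `total_area`, `converged`, `degree_reductions`.
#' @export
fit_logistic_polynomial <- function(binned, degree, grid_points = 2001L) {
  stopifnot(inherits(binned, "binned_sample"), degree >= 0L,
            degree <= binned$k - 1L)
  requested <- as.integer(degree)
  x <- binned$midpoints
  lo <- min(x)
  hi <- max(x)
  b <- 2 / (hi - lo)
  a <- -(hi + lo) / (hi - lo)
  z <- a + b * x
  y <- binned$proportions
  w <- rep(binned$N, binned$k)

  d <- requested
  reductions <- 0L
  repeat {
    design <- outer(z, 0:d, `^`)
    colnames(design) <- paste0("z", 0:d)
    fit <- tryCatch(
      suppressWarnings(
        stats::glm.fit(design, y, weights = w,
                       family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-8,
                                                    maxit = 100))),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged &&
      all(is.finite(stats::coef(fit)))
    if (ok) break
    if (d <= 1L) {
      if (!is.null(fit) && all(is.finite(stats::coef(fit)))) {
        ok <- TRUE  # keep a finite degree-1 fit even if IRLS hit maxit
        break
      }
      stop("polynomial logistic fit failed even at degree 1")
    }
    d <- d - 1L
    reductions <- reductions + 1L
  }
  coef_z <- unname(stats::coef(fit))
  coef_x <- poly_compose_affine(coef_z, a, b)
  p_fun <- local({
    cz <- coef_z; aa <- a; bb <- b; dd <- d
    function(xx) {
      zz <- aa + bb * xx
      eta <- drop(outer(zz, 0:dd, `^`) %*% cz)
      stats::plogis(eta)
    }
  })
  domain <- c(binned$xmin, binned$xmax)
  dens <- structure(list(coefficients = coef_z,
                         coefficients_x = coef_x,
                         degree = d,
                         requested_degree = requested,
                         standardization = c(a = a, b = b),
                         p = p_fun,
                         domain = domain,
                         total_area = NA_real_,
                         converged = fit$converged,
                         degree_reductions = reductions),
                    class = "fitted_density")
  dens$total_area <- total_area(dens, grid_points)
  dens
}

#' @export
print.fitted_density <- function(x, ...) {
  cat("Polynomial logistic density, degree", x$degree)
  if (x$degree_reductions > 0L) {
    cat(" (reduced from", x$requested_degree, ")")
  }
  cat("\n  domain: [", format(x$domain[1L]), ", ", format(x$domain[2L]),
      "], total area ", format(x$total_area, digits = 6), "\n", sep = "")
  invisible(x)
}
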