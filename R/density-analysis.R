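# Composite Simpson on a uniform grid; y has odd length.
simpson_uniform <- function(y, h) {
  m <- length(y)
  stopifnot(m >= 3L, m %% 2L == 1L)
  h / 3 * (y[1L] + y[m] +
             4 * sum(y[seq(2L, m - 1L, by = 2L)]) +
             2 * sum(y[seq(3L, m - 2L, by = 2L)]))
}

density_grid <- function(density, grid_points = 2001L) {
  grid_points <- as.integer(grid_points)
  if (grid_points %% 2L == 0L) grid_points <- grid_points + 1L
  x <- seq(density$domain[1L], density$domain[2L],
           length.out = grid_points)
  list(x = x, y = density$p(x), h = x[2L] - x[1L])
}

#' Total area under a fitted occurrence-probability curve
#'
#' Composite Simpson integration of p(x) over the sample's range. The
#' area is used as the normalization constant of the probability density
#' — and since the highest-probability interval is defined by a relative
#' quarter of the area, the normalization itself can be skipped
#' downstream.
#'
#' @param density a `fitted_density`.
#' @param grid_points number of grid points (odd; even values are
#'   incremented).
#' @return The integral, a positive scalar.
#' @export
total_area <- function(density, grid_points = 2001L) {
  stopifnot(inherits(density, "fitted_density"))
  g <- density_grid(density, grid_points)
  if (any(!is.finite(g$y))) {
    stop("fitted curve evaluates to a non-finite value on the grid")
  }
  simpson_uniform(g$y, g$h)
}

#' Mode of a fitted occurrence-probability curve
#'
#' Global argmax of p on a grid, refined by golden-section/parabolic
#' search within the bracketing cell. The mode is flagged as lying on an
#' endpoint when the argmax falls within one grid cell of the domain
#' limit and the curve is monotone into that limit.
#'
#' @param density a `fitted_density`.
#' @param grid_points grid size.
#' @return List with `mode` and `mode_at_endpoint`.
#' @export
find_mode <- function(density, grid_points = 2001L) {
  stopifnot(inherits(density, "fitted_density"))
  g <- density_grid(density, grid_points)
  m <- length(g$x)
  i <- which.max(g$y)
  lo <- g$x[max(1L, i - 1L)]
  hi <- g$x[min(m, i + 1L)]
  if (lo < hi) {
    opt <- stats::optimize(density$p, c(lo, hi), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    mode <- opt$maximum
    # keep the grid argmax if refinement did not actually improve
    if (density$p(mode) < g$y[i]) mode <- g$x[i]
  } else {
    mode <- g$x[i]
  }
  window <- min(10L, m)
  at_lower <- (mode - g$x[1L]) <= g$h &&
    all(diff(g$y[seq_len(window)]) <= 0)
  at_upper <- (g$x[m] - mode) <= g$h &&
    all(diff(g$y[seq(m - window + 1L, m)]) >= 0)
  if (at_lower) mode <- g$x[1L]
  if (at_upper) mode <- g$x[m]
  list(mode = mode, mode_at_endpoint = at_lower || at_upper)
}

# Connected component of {x : p(x) >= c} containing the mode, with
# crossing points refined by root finding; returns c(xL, xU).
component_at_threshold <- function(density, grid, threshold, mode) {
  x <- grid$x
  y <- grid$y
  m <- length(x)
  i <- which.min(abs(x - mode))
  # walk left
  j <- i
  while (j > 1L && y[j - 1L] >= threshold) j <- j - 1L
  x_l <- if (j == 1L) {
    x[1L]
  } else {
    tryCatch(stats::uniroot(function(t) density$p(t) - threshold,
                            c(x[j - 1L], x[j]),
                            tol = .Machine$double.eps^0.5)$root,
             error = function(e) x[j])
  }
  # walk right
  j <- i
  while (j < m && y[j + 1L] >= threshold) j <- j + 1L
  x_u <- if (j == m) {
    x[m]
  } else {
    tryCatch(stats::uniroot(function(t) density$p(t) - threshold,
                            c(x[j], x[j + 1L]),
                            tol = .Machine$double.eps^0.5)$root,
             error = function(e) x[j])
  }
  c(x_l, x_u)
}

interval_area <- function(density, x_l, x_u, points = 801L) {
  if (x_u <= x_l) return(0)
  xx <- seq(x_l, x_u, length.out = points)
  simpson_uniform(density$p(xx), xx[2L] - xx[1L])
}

#' Highest-probability interval of a fitted curve
#'
#' The contiguous interval around the global mode that contains a fixed
#' fraction (default one quarter) of the total area under the curve at
#' the highest probability densities. It is found by bisecting on a
#' density threshold c: the connected component of `{x : p(x) >= c}`
#' containing the mode, with c tuned until the component's area equals
#' `mass` times the total area. When the mode sits on an endpoint of the
#' range the component is one-sided from that endpoint. For a unimodal
#' curve this interval is the shortest interval holding the requested
#' mass.
#'
#' @param density a `fitted_density`.
#' @param mass fraction of the total area, in (0, 1); default 0.25.
#' @param grid_points grid size.
#' @param tol tolerance on the achieved mass fraction; default 1e-4.
#' @param max_iter bisection iteration cap.
#' @return A list of class `highest_probability_interval`: `xL`, `xU`,
#'   `mass` (achieved fraction), `mode`, `mode_at_endpoint`, `flagged`
#'   (TRUE when the mass could not be reached within tolerance, e.g.
#'   strong multimodality).
#' @export
highest_probability_interval <- function(density, mass = 0.25,
                                         grid_points = 2001L,
                                         tol = 1e-4, max_iter = 50L) {
  stopifnot(inherits(density, "fitted_density"), mass > 0, mass < 1)
  g <- density_grid(density, grid_points)
  total <- simpson_uniform(g$y, g$h)
  md <- find_mode(density, grid_points)
  target <- mass * total

  c_lo <- 0
  c_hi <- max(g$y)
  best <- NULL
  for (iter in seq_len(max_iter)) {
    c_mid <- (c_lo + c_hi) / 2
    comp <- component_at_threshold(density, g, c_mid, md$mode)
    area <- interval_area(density, comp[1L], comp[2L])
    if (is.null(best) || abs(area - target) < abs(best$area - target)) {
      best <- list(comp = comp, area = area, c = c_mid)
    }
    if (abs(area / total - mass) <= tol / 10) break
    if (area > target) c_lo <- c_mid else c_hi <- c_mid
  }
  achieved <- best$area / total
  flagged <- abs(achieved - mass) > tol
  x_l <- best$comp[1L]
  x_u <- best$comp[2L]
  # numerical safety: the mode must lie inside the interval
  x_l <- min(x_l, md$mode)
  x_u <- max(x_u, md$mode)
  structure(list(xL = x_l, xU = x_u, mass = achieved,
                 mode = md$mode, mode_at_endpoint = md$mode_at_endpoint,
                 threshold = best$c, flagged = flagged),
            class = "highest_probability_interval")
}

#' @export
print.highest_probability_interval <- function(x, ...) {
  cat("Highest-probability interval: [", format(x$xL, digits = 6), ", ",
      format(x$xU, digits = 6), "]\n", sep = "")
  cat("  mode ", format(x$mode, digits = 6),
      if (x$mode_at_endpoint) " (at endpoint)" else "",
      ", achieved mass ", format(x$mass, digits = 5),
      if (x$flagged) " [flagged: mass off target]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Relative distance of the highest-probability interval from the
#' gradient midpoint
#'
#' The midpoint `(xmin + xmax)/2` of a species' observed range is the
#' unidimensional niche center. The relative distance is 0 when the
#' midpoint lies inside the interval `[xL, xU]`; otherwise it is the
#' distance from the midpoint to the nearest interval limit, as a
#' percentage of the full range — positive when the interval lies above
#' the midpoint, negative when below. Its mathematical domain is
#' [-50%, 50%], the extremes being approached as the interval collapses
#' onto a range endpoint.
#'
#' @param xL,xU interval limits.
#' @param xmin,xmax observed range of the variable for the species.
#' @return List with `relDis` (percent), `side` (`"inside"`, `"below"`,
#'   `"above"`), `xmid`.
#' @export
relative_distance <- function(xL, xU, xmin, xmax) {
  if (xmin >= xmax) stop("degenerate range: xmin must be below xmax")
  stopifnot(xmin <= xL, xL < xU, xU <= xmax)
  xmid <- (xmin + xmax) / 2
  if (xmid < xL) {
    list(relDis = (xL - xmid) / (xmax - xmin) * 100, side = "above",
         xmid = xmid)
  } else if (xmid > xU) {
    list(relDis = (xU - xmid) / (xmax - xmin) * 100, side = "below",
         xmid = xmid)
  } else {
    list(relDis = 0, side = "inside", xmid = xmid)
  }
}

#' Euclidean distance of a displaced niche position from the centroid
#'
#' Displacing the preferred position away from the niche centroid by
#' `d_i` on each of several environmental gradients moves it
#' `sqrt(sum(d_i^2))` away from the centroid in the multidimensional
#' niche space; a single nonzero displacement moves it by exactly
#' `|d_i|`. This is why gradients can be analyzed one at a time.
#'
#' @param displacements numeric vector of per-gradient displacements.
#' @return The Euclidean distance.
#' @export
centroid_displacement_distance <- function(displacements) {
  stopifnot(length(displacements) >= 1L,
            all(is.finite(displacements)))
  sqrt(sum(displacements^2))
}
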