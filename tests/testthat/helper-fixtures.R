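# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

toy_table_df <- function() {
  data.frame(
    species = c("sp_a", "sp_a", "sp_b"),
    site_id = c("s1", "s2", "s3"),
    longitude = c(-99.1, -98.7, -100.2),
    latitude = c(19.4, 19.9, 21.1),
    var_one = c(1.5, 2.5, 3.5),
    var_two = c(10, 20, 30),
    stringsAsFactors = FALSE)
}

# Build a binned_sample directly from counts (bypassing compute_bins),
# with Clopper-Pearson CIs at alpha / k.
make_binned <- function(counts, edges, alpha = 0.05, N = sum(counts)) {
  k <- length(counts)
  stopifnot(length(edges) == k + 1L)
  alpha_adj <- alpha / k
  ci <- clopper_pearson_ci(counts, N, alpha_adj)
  structure(list(edges = edges,
                 counts = counts,
                 midpoints = (edges[-(k + 1L)] + edges[-1L]) / 2,
                 N = N,
                 proportions = counts / N,
                 ci_lower = ci[, 1L],
                 ci_upper = ci[, 2L],
                 alpha = alpha,
                 alpha_adj = alpha_adj,
                 k = k,
                 xmin = edges[1L],
                 xmax = edges[k + 1L]),
            class = "binned_sample")
}

# A fitted_density stand-in wrapping an arbitrary curve 0 < p < 1.
fake_density <- function(p, domain) {
  structure(list(coefficients = NULL, coefficients_x = NULL,
                 degree = NA_integer_, requested_degree = NA_integer_,
                 standardization = NULL, p = p, domain = domain,
                 total_area = NA_real_, converged = TRUE,
                 degree_reductions = 0L),
            class = "fitted_density")
}

# Independent Clopper-Pearson oracle: invert the binomial tail sums by
# bisection on p (never touching qbeta).
cp_oracle <- function(count, n, alpha_adj) {
  lower <- if (count == 0) 0 else {
    stats::uniroot(function(p) {
      stats::pbinom(count - 1, n, p, lower.tail = FALSE) - alpha_adj / 2
    }, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (count == n) 1 else {
    stats::uniroot(function(p) {
      stats::pbinom(count, n, p) - alpha_adj / 2
    }, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower, upper)
}

# Brute-force reimplementation of the outward marking scan (rules i-iii)
# used as an oracle against mark_points.
mark_oracle <- function(proportions, sig) {
  k <- length(proportions)
  highest <- which.max(proportions)
  marked <- highest
  for (step in c(-1L, 1L)) {
    ref <- highest
    for (j in seq(highest + step, by = step,
                  length.out = max(0L, if (step < 0) highest - 1L else
                    k - highest))) {
      if (sig[ref, j]) {
        marked <- c(marked, j)
        ref <- j
      }
    }
  }
  sort(unique(c(marked, 1L, k)))
}

# Sample sizes shaped like a real multi-species herbarium study
study_like_sizes <- c(95L, 140L, 106L, 239L, 95L, 213L, 176L, 287L,
                      109L, 321L, 85L, 70L)

# Full 12-species x 16-variable synthetic study grid: distribution
# family chosen by each variable's natural domain (normal on unbounded
# gradients, gamma on nonnegative ones, scaled beta on the unit-bounded
# ratio, and a half-normal boundary-mode shape for terrain slope),
# with per-species parameter shifts so the combinations differ.
grid_specs_12x16 <- function(seed = 1L) {
  domains <- load_variable_domains()
  vars <- names(domains)
  species <- sprintf("species_%02d", seq_len(12L))
  normal_loc <- c(mean_annual_temperature = 20,
                  mean_temp_coldest_month = 12,
                  mean_temp_warmest_month = 28,
                  soil_ph = 6.5)
  specs <- list()
  for (i in seq_along(species)) {
    f <- 0.8 + 0.05 * i
    for (j in seq_along(vars)) {
      v <- vars[j]
      dom <- domains[[v]]
      sp_seed <- (seed * 1000L + i * 16L + j) %% 2147483587L
      spec <- if (v %in% names(normal_loc)) {
        synthetic_spec(species[i], v, "normal",
                       list(mean = normal_loc[[v]] * f,
                            sd = 1.5 + 0.2 * (j %% 3)),
                       dom, n = study_like_sizes[i], seed = sp_seed)
      } else if (v == "summer_to_total_precipitation_ratio") {
        synthetic_spec(species[i], v, "beta_scaled",
                       list(shape1 = 2 + f, shape2 = 2.5,
                            min = 0, max = 1),
                       dom, n = study_like_sizes[i], seed = sp_seed)
      } else if (v == "terrain_slope") {
        synthetic_spec(species[i], v, "normal",
                       list(mean = 0, sd = 6 * f),
                       dom, n = study_like_sizes[i], seed = sp_seed)
      } else {
        synthetic_spec(species[i], v, "gamma",
                       list(shape = 1.5 + (j %% 4) * 0.8,
                            scale = (10 + 5 * j) * f),
                       dom, n = study_like_sizes[i], seed = sp_seed)
      }
      specs[[length(specs) + 1L]] <- spec
    }
  }
  specs
}
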