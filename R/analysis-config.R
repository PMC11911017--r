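#' Analysis configuration
#'
#' Collects every tunable of the per-combination pipeline in one object.
#'
#' @param hpi_mass fraction of the area under the fitted curve that the
#'   highest-probability interval must contain. Default 0.25.
#' @param family_alpha family-wide significance level before Bonferroni
#'   adjustment. Default 0.05.
#' @param bin_rule `"fd_as_written"` (bin width = 2 IQR / n^(1/3)) or
#'   `"sturges_r"` (ceil(log2 n) + 1 equal-width bins on nice edges).
#' @param bonferroni_k_rule what the Bonferroni divisor k counts:
#'   `"n_bins"` (number of histogram bins, the default) or `"n_marked"`
#'   (number of marked points).
#' @param grid_points number of grid points for density evaluation,
#'   integration and interval search; at least 101 (odd values are used
#'   as given, even values are incremented for Simpson integration).
#' @param degree_overrides optional data.frame with columns `species`,
#'   `variable`, `delta` (+1 or -1 polynomial terms) reproducing manual
#'   degree adjustments.
#' @param seed integer seed for any stochastic routine.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(hpi_mass = 0.25,
                            family_alpha = 0.05,
                            bin_rule = c("fd_as_written", "sturges_r"),
                            bonferroni_k_rule = c("n_bins", "n_marked"),
                            grid_points = 2001L,
                            degree_overrides = NULL,
                            seed = 1L) {
  bin_rule <- match.arg(bin_rule)
  bonferroni_k_rule <- match.arg(bonferroni_k_rule)
  stopifnot(hpi_mass > 0, hpi_mass < 1,
            family_alpha > 0, family_alpha < 1,
            grid_points >= 101)
  grid_points <- as.integer(grid_points)
  if (grid_points %% 2L == 0L) grid_points <- grid_points + 1L
  if (!is.null(degree_overrides)) {
    stopifnot(is.data.frame(degree_overrides),
              all(c("species", "variable", "delta") %in%
                    names(degree_overrides)),
              all(degree_overrides$delta %in% c(-1L, 1L)))
  }
  structure(list(hpi_mass = hpi_mass,
                 family_alpha = family_alpha,
                 bin_rule = bin_rule,
                 bonferroni_k_rule = bonferroni_k_rule,
                 grid_points = grid_points,
                 degree_overrides = degree_overrides,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

degree_override_for <- function(config, species, variable) {
  ov <- config$degree_overrides
  if (is.null(ov)) return(0L)
  hit <- ov$species == species & ov$variable == variable
  if (!any(hit)) return(0L)
  as.integer(ov$delta[which(hit)[1L]])
}
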