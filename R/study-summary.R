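#' Pairwise Pearson correlations among environmental variables
#'
#' One correlation matrix over all specimen rows pooled across species
#' — a screen for variables that "move together" and would therefore
#' contribute redundant gradients. V variables give (V^2 - V)/2
#' unordered pairs. No significance testing is performed on r.
#'
#' @param table an `occurrence_table`.
#' @param variables variable names; defaults to all declared variables.
#' @return List with `matrix` (V x V Pearson matrix) and `summary`:
#'   `n_pairs`, `min_abs`, `max_abs`, `mean_abs`, `median_abs`,
#'   `n_below_half`, `n_at_least_half` (of |r|), and `n_undefined` for
#'   pairs involving a zero-variance variable.
#' @export
correlation_matrix <- function(table, variables = NULL) {
  stopifnot(inherits(table, "occurrence_table"))
  if (is.null(variables)) variables <- table_variables(table)
  stopifnot(length(variables) >= 2L, nrow(table) >= 3L)
  mat <- suppressWarnings(
    stats::cor(as.data.frame(table)[, variables, drop = FALSE],
               method = "pearson"))
  diag(mat) <- 1
  r <- mat[upper.tri(mat)]
  abs_r <- abs(r[!is.na(r)])
  list(matrix = mat,
       summary = list(n_pairs = length(r),
                      min_abs = min(abs_r),
                      max_abs = max(abs_r),
                      mean_abs = mean(abs_r),
                      median_abs = stats::median(abs_r),
                      n_below_half = sum(abs_r < 0.5),
                      n_at_least_half = sum(abs_r >= 0.5),
                      n_undefined = sum(is.na(r))))
}

#' Tally relative-distance verdicts
#'
#' Counts how many species-variable combinations have their
#' highest-probability interval containing the midpoint (`inside`),
#' below it, or above it, and per species the percentage of its
#' variables that are centered.
#'
#' @param verdicts list of verdict records, each with `species` and
#'   `side`.
#' @return List with `n_centered`, `n_below`, `n_above`, and
#'   `per_species_centered_pct` (named numeric vector, percent).
#' @export
tally_distances <- function(verdicts) {
  stopifnot(length(verdicts) > 0L)
  sides <- vapply(verdicts, function(v) v$side, character(1L))
  species <- vapply(verdicts, function(v) v$species, character(1L))
  pct <- vapply(split(sides, species),
                function(s) 100 * mean(s == "inside"), numeric(1L))
  list(n_centered = sum(sides == "inside"),
       n_below = sum(sides == "below"),
       n_above = sum(sides == "above"),
       per_species_centered_pct = pct[unique(species)])
}

#' Exact two-sided sign test for below- vs above-midpoint counts
#'
#' Under the center-periphery expectation, intervals off the midpoint
#' should fall on either side with probability one half. The p-value is
#' the exact binomial two-sided probability, defined as twice the
#' smaller tail, capped at 1.
#'
#' @param n_below,n_above counts on each side.
#' @return Two-sided p-value.
#' @export
sign_test <- function(n_below, n_above) {
  stopifnot(n_below >= 0, n_above >= 0, n_below + n_above >= 1)
  n <- n_below + n_above
  k <- min(n_below, n_above)
  min(1, 2 * stats::pbinom(k, n, 0.5))
}

#' Assemble the study-level summary
#'
#' @param results list of `combination_result` records from
#'   [run_study()] or [run_combination()].
#' @param correlation optional output of [correlation_matrix()].
#' @return A list of class `study_summary`.
#' @export
study_summary <- function(results, correlation = NULL) {
  excluded <- vapply(results, function(r) isTRUE(r$excluded), logical(1L))
  analyzed <- results[!excluded]
  tal <- if (length(analyzed) > 0L) {
    tally_distances(lapply(analyzed, function(r) r$verdict))
  } else {
    list(n_centered = 0L, n_below = 0L, n_above = 0L,
         per_species_centered_pct = numeric(0))
  }
  categories <- vapply(analyzed,
                       function(r) r$symmetry$category, character(1L))
  p <- if (tal$n_below + tal$n_above >= 1L) {
    sign_test(tal$n_below, tal$n_above)
  } else {
    NA_real_
  }
  structure(list(n_combinations_input = length(results),
                 n_excluded = sum(excluded),
                 n_analyzed = length(analyzed),
                 n_centered = tal$n_centered,
                 n_below = tal$n_below,
                 n_above = tal$n_above,
                 per_species_centered_pct = tal$per_species_centered_pct,
                 category_counts = table(factor(categories,
                   levels = c("centered", "expansion_possible",
                              "expansion_impossible",
                              "undefined_d1_zero"))),
                 sign_test_p = p,
                 correlation_summary = correlation$summary),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Study summary\n")
  cat("  combinations: ", x$n_combinations_input, " attempted, ",
      x$n_excluded, " excluded, ", x$n_analyzed, " analyzed\n", sep = "")
  cat("  midpoint inside HPI: ", x$n_centered, " (",
      if (x$n_analyzed > 0)
        format(100 * x$n_centered / x$n_analyzed, digits = 3)
      else "NA",
      "%); below: ", x$n_below, "; above: ", x$n_above, "\n", sep = "")
  cat("  expansion categories:\n")
  print(x$category_counts)
  if (!is.na(x$sign_test_p)) {
    cat("  two-sided sign test (below vs above): p =",
        format(x$sign_test_p, digits = 3), "\n")
  }
  if (!is.null(x$correlation_summary)) {
    cs <- x$correlation_summary
    cat("  |r| over ", cs$n_pairs, " variable pairs: mean ",
        format(cs$mean_abs, digits = 3), ", median ",
        format(cs$median_abs, digits = 3), "\n", sep = "")
  }
  invisible(x)
}
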