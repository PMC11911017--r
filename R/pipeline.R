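#' Run the full analysis for one species-variable combination
#'
#' Executes, in order: histogram binning, conversion to proportions with
#' Bonferroni-adjusted Clopper-Pearson confidence intervals, the
#' exclusion check (no significantly different bin pair anywhere means
#' the combination carries no usable shape information), the marking
#' rules, the polynomial logistic fit, mode and highest-probability
#' interval extraction, the relative distance from the gradient
#' midpoint, and the symmetry/truncation assessment. Every fallback
#' (bin-rule degeneracy, degree reduction, interval-mass shortfall) is
#' recorded in `flags`.
#'
#' @param sample a `species_variable_sample`.
#' @param domain the variable's `variable_domain`.
#' @param config an `analysis_config`.
#' @return A list of class `combination_result`. Excluded combinations
#'   carry `excluded = TRUE`, the binned sample, the omnibus test, and
#'   no downstream fields.
#' @export
run_combination <- function(sample, domain,
                            config = analysis_config()) {
  stopifnot(inherits(sample, "species_variable_sample"),
            inherits(domain, "variable_domain"),
            inherits(config, "analysis_config"))
  check_domain(domain, sample$values)
  flags <- character(0)

  edges <- withCallingHandlers(
    compute_bins(sample, rule = config$bin_rule),
    warning = function(w) {
      flags <<- c(flags, "bin_rule_fallback")
      invokeRestart("muffleWarning")
    })
  binned <- bin_counts(sample, edges, alpha = config$family_alpha)
  omnibus <- omnibus_chi_square(binned)
  sig <- pairwise_significance(binned)

  base <- list(species = sample$species, variable = sample$variable,
               n = sample$n, binned = binned, omnibus = omnibus)

  delta <- degree_override_for(config, sample$species, sample$variable)
  marked <- tryCatch(mark_points(binned, sig, degree_delta = delta),
                     nichegradient_exclusion = function(e) NULL)
  if (is.null(marked)) {
    return(structure(c(base, list(excluded = TRUE,
                                  flags = "no_significant_pair")),
                     class = "combination_result"))
  }
  if (config$bonferroni_k_rule == "n_marked") {
    # alternative divisor: rebuild CIs with k = marked points, re-mark
    binned <- with_adjusted_alpha(binned, marked$n_marked)
    sig <- pairwise_significance(binned)
    marked2 <- tryCatch(mark_points(binned, sig, degree_delta = delta),
                        nichegradient_exclusion = function(e) NULL)
    if (is.null(marked2)) {
      return(structure(c(base, list(excluded = TRUE,
                                    flags = "no_significant_pair")),
                       class = "combination_result"))
    }
    marked <- marked2
    base$binned <- binned
    flags <- c(flags, "bonferroni_k_n_marked")
  }
  if (delta != 0L) flags <- c(flags, "degree_override")

  density <- fit_logistic_polynomial(binned,
                                     degree = min(marked$degree,
                                                  binned$k - 1L),
                                     grid_points = config$grid_points)
  if (density$degree_reductions > 0L) {
    flags <- c(flags, paste0("degree_reduced_",
                             density$degree_reductions))
  }
  hpi <- highest_probability_interval(density, mass = config$hpi_mass,
                                      grid_points = config$grid_points)
  if (hpi$flagged) flags <- c(flags, "hpi_mass_shortfall")
  rel <- relative_distance(hpi$xL, hpi$xU, binned$xmin, binned$xmax)
  verdict <- list(species = sample$species, variable = sample$variable,
                  xmin = binned$xmin, xmax = binned$xmax,
                  xmid = rel$xmid, xL = hpi$xL, xU = hpi$xU,
                  relDis = rel$relDis, side = rel$side)
  symmetry <- assess_symmetry(sample$species, sample$variable,
                              binned$xmin, binned$xmax, hpi$mode,
                              domain, rel$relDis)
  structure(c(base,
              list(excluded = FALSE, marked = marked,
                   density = density, hpi = hpi, verdict = verdict,
                   symmetry = symmetry, flags = flags)),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat("Combination: ", x$species, " / ", x$variable, " (n = ", x$n,
      ")\n", sep = "")
  if (isTRUE(x$excluded)) {
    cat("  excluded: no pair of bins differs significantly\n")
    return(invisible(x))
  }
  cat("  degree ", x$density$degree, "; mode ",
      format(x$hpi$mode, digits = 5), "; HPI [",
      format(x$hpi$xL, digits = 5), ", ",
      format(x$hpi$xU, digits = 5), "]\n", sep = "")
  cat("  relDis ", format(x$verdict$relDis, digits = 4), "% (",
      x$verdict$side, "); category ", x$symmetry$category, "\n",
      sep = "")
  if (length(x$flags) > 0L) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the study over the full species-by-variable grid
#'
#' Iterates [run_combination()] over every (species, variable) pair in
#' the table; any per-combination failure is captured as a flagged
#' record rather than aborting the run. Adds the pooled correlation
#' screen and the study-level summary.
#'
#' @param table an `occurrence_table`.
#' @param domains a registry from [load_variable_domains()] (or named
#'   list of `variable_domain`s) covering every table variable.
#' @param config an `analysis_config`.
#' @return A list of class `study_result` with `results` (one
#'   `combination_result` per grid cell), `summary` (a
#'   `study_summary`), `correlation`, and `config`.
#' @export
run_study <- function(table, domains, config = analysis_config()) {
  stopifnot(inherits(table, "occurrence_table"))
  species <- table_species(table)
  variables <- table_variables(table)
  if (length(species) == 0L || length(variables) == 0L) {
    stop("empty species-by-variable grid")
  }
  for (v in variables) domain_for(domains, v)  # fail fast on config gaps
  results <- list()
  for (sp in species) {
    for (v in variables) {
      sample <- extract_sample(table, sp, v)
      res <- tryCatch(
        run_combination(sample, domain_for(domains, v), config),
        error = function(e) {
          structure(list(species = sp, variable = v, n = sample$n,
                         excluded = TRUE,
                         flags = paste0("stage_error: ",
                                        conditionMessage(e))),
                    class = "combination_result")
        })
      results[[paste(sp, v, sep = "|")]] <- res
    }
  }
  correlation <- correlation_matrix(table, variables)
  structure(list(results = results,
                 summary = study_summary(results, correlation),
                 correlation = correlation,
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' One-row-per-combination results table
#'
#' @param study a `study_result` (or plain list of
#'   `combination_result`s).
#' @return data.frame with one row per combination: range, midpoint,
#'   mode, interval limits, relative distance, side, symmetry fields,
#'   category, flags.
#' @export
results_table <- function(study) {
  results <- if (inherits(study, "study_result")) study$results else
    study
  rows <- lapply(results, function(r) {
    if (isTRUE(r$excluded)) {
      data.frame(species = r$species, variable = r$variable, n = r$n,
                 excluded = TRUE, k_bins = if (!is.null(r$binned))
                   r$binned$k else NA_integer_,
                 degree = NA_integer_, chi_sq_p = if (!is.null(r$omnibus))
                   r$omnibus$p_value else NA_real_,
                 xmin = NA_real_, xmax = NA_real_, xmid = NA_real_,
                 mode = NA_real_, xL = NA_real_, xU = NA_real_,
                 relDis = NA_real_, side = NA_character_,
                 d1 = NA_real_, d2 = NA_real_,
                 required_limit = NA_real_,
                 expansion_side = NA_character_,
                 category = NA_character_,
                 expansion_factor = NA_real_,
                 flags = paste(r$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(species = r$species, variable = r$variable, n = r$n,
                 excluded = FALSE, k_bins = r$binned$k,
                 degree = r$density$degree,
                 chi_sq_p = r$omnibus$p_value,
                 xmin = r$verdict$xmin, xmax = r$verdict$xmax,
                 xmid = r$verdict$xmid, mode = r$hpi$mode,
                 xL = r$verdict$xL, xU = r$verdict$xU,
                 relDis = r$verdict$relDis, side = r$verdict$side,
                 d1 = r$symmetry$d1, d2 = r$symmetry$d2,
                 required_limit = r$symmetry$required_limit,
                 expansion_side = r$symmetry$expansion_side,
                 category = r$symmetry$category,
                 expansion_factor = r$symmetry$expansion_factor,
                 flags = paste(r$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}

#' Write study outputs to a directory
#'
#' Writes `results.csv` (one row per combination), `symmetry.csv` (the
#' required-limits table for analyzed combinations), `summary.json`,
#' and `metadata.json` (configuration and package version). Reruns with
#' identical inputs and configuration produce byte-identical files.
#'
#' @param study a `study_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(study, dir) {
  stopifnot(inherits(study, "study_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- results_table(study)
  utils::write.csv(format(tab, digits = 12, trim = TRUE),
                   file.path(dir, "results.csv"), row.names = FALSE)
  sym <- tab[!tab$excluded,
             c("species", "variable", "mode", "d1", "d2",
               "required_limit", "expansion_side", "category",
               "expansion_factor")]
  utils::write.csv(format(sym, digits = 12, trim = TRUE),
                   file.path(dir, "symmetry.csv"), row.names = FALSE)
  s <- study$summary
  jsonlite::write_json(
    list(n_combinations_input = s$n_combinations_input,
         n_excluded = s$n_excluded,
         n_analyzed = s$n_analyzed,
         n_centered = s$n_centered,
         n_below = s$n_below,
         n_above = s$n_above,
         per_species_centered_pct =
           as.list(s$per_species_centered_pct),
         category_counts = as.list(s$category_counts),
         sign_test_p = s$sign_test_p,
         correlation_summary = s$correlation_summary),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  cfg <- study$config
  jsonlite::write_json(
    list(package_version =
           as.character(utils::packageVersion("nichegradient")),
         hpi_mass = cfg$hpi_mass,
         family_alpha = cfg$family_alpha,
         bin_rule = cfg$bin_rule,
         bonferroni_k_rule = cfg$bonferroni_k_rule,
         grid_points = cfg$grid_points,
         seed = cfg$seed),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
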