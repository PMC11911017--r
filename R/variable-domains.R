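#' Natural mathematical domain of an environmental variable
#'
#' Many environmental variables are naturally truncated: precipitation
#' and slope cannot be negative, a precipitation ratio cannot exceed 1.
#' A `variable_domain` records the hard bounds (or their absence), which
#' drives the expansion-feasibility classification: a species' gradient
#' cannot be expanded past a natural bound by collecting more data.
#'
#' @param variable variable name.
#' @param lower,upper numeric bound or `-Inf`/`Inf` for an unbounded
#'   side.
#' @return A list of class `variable_domain`.
#' @export
variable_domain <- function(variable, lower = -Inf, upper = Inf) {
  stopifnot(is.character(variable), nzchar(variable))
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (is.na(lower) || is.na(upper)) stop("bounds must be numbers or +/-Inf")
  if (is.finite(lower) && is.finite(upper) && lower >= upper) {
    stop("lower bound must be below upper bound")
  }
  structure(list(variable = variable, lower = lower, upper = upper),
            class = "variable_domain")
}

#' @export
print.variable_domain <- function(x, ...) {
  fmt <- function(b) if (is.finite(b)) format(b) else "unbounded"
  cat("Domain of ", x$variable, ": [", fmt(x$lower), ", ", fmt(x$upper),
      "]\n", sep = "")
  invisible(x)
}

parse_bound <- function(value, side) {
  if (is.null(value) || identical(value, "unbounded") || is.na(value)) {
    return(if (side == "lower") -Inf else Inf)
  }
  as.numeric(value)
}

#' Load a variable-domain registry from a YAML config
#'
#' The config maps each variable to its natural lower/upper bound
#' (`unbounded` for none) and an optional alias list for spreadsheet
#' headers. The package ships a default registry covering the 16
#' environmental variables of the reference study: 11 nonnegative
#' variables, one unit-bounded precipitation ratio, and four fully
#' unbounded variables (the temperature variables and soil pH).
#'
#' @param path YAML file; defaults to the packaged registry.
#' @return A named list of `variable_domain` objects, with attribute
#'   `aliases` (named character vector: header -> canonical name).
#' @export
load_variable_domains <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "variable_domains.yml",
                        package = "nichegradient")
  }
  if (!file.exists(path)) stop("domain config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variables)) stop("domain config lacks a 'variables' map")
  domains <- list()
  aliases <- character(0)
  for (v in names(cfg$variables)) {
    entry <- cfg$variables[[v]]
    domains[[v]] <- variable_domain(v,
                                    lower = parse_bound(entry$lower, "lower"),
                                    upper = parse_bound(entry$upper, "upper"))
    if (!is.null(entry$aliases)) {
      aliases <- c(aliases,
                   stats::setNames(rep(v, length(entry$aliases)),
                                   unlist(entry$aliases)))
    }
  }
  structure(domains, aliases = aliases, class = "variable_domain_registry")
}

#' Look up the domain of a variable, erroring when unregistered
#'
#' @param registry a registry from [load_variable_domains()], or a plain
#'   named list of `variable_domain` objects.
#' @param variable variable name.
#' @return The `variable_domain`.
#' @export
domain_for <- function(registry, variable) {
  d <- registry[[variable]]
  if (is.null(d)) {
    stop("variable '", variable,
         "' is present in the data but absent from the domain registry")
  }
  d
}

#' Check that sample values respect the variable's domain
#' @param domain a `variable_domain`.
#' @param values numeric vector.
#' @return `TRUE` invisibly; errors when a value lies outside the domain.
#' @export
check_domain <- function(domain, values) {
  stopifnot(inherits(domain, "variable_domain"))
  bad <- values < domain$lower | values > domain$upper
  if (any(bad)) {
    stop("value ", format(values[which(bad)[1L]]), " of '",
         domain$variable, "' lies outside its natural domain")
  }
  invisible(TRUE)
}
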