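#' Construct and validate an occurrence table
#'
#' An occurrence table holds one row per collection site of a species:
#' a species label, a site identifier, geographic coordinates (carried
#' through but never computed on), and one numeric column per
#' environmental variable. All variable values must be present in every
#' row, and no (species, site) pair may be repeated — repeated
#' collections of the same species at the same site would spuriously
#' inflate the occurrence frequency under that site's conditions.
#'
#' @param df data.frame with columns `species`, `site_id`, `longitude`,
#'   `latitude`, and one numeric column per environmental variable.
#' @param variables character vector of variable column names. Defaults
#'   to every column not among the four reserved ones.
#' @return A data.frame of class `occurrence_table` with attribute
#'   `variables`.
#' @export
occurrence_table <- function(df, variables = NULL) {
  stopifnot(is.data.frame(df))
  reserved <- c("species", "site_id", "longitude", "latitude")
  missing_cols <- setdiff(reserved, names(df))
  if (length(missing_cols) > 0L) {
    stop("occurrence table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(variables)) {
    variables <- setdiff(names(df), reserved)
  }
  if (length(variables) == 0L) {
    stop("occurrence table declares no environmental variables")
  }
  if (any(!nzchar(variables))) stop("variable names must be non-empty")
  unknown <- setdiff(variables, names(df))
  if (length(unknown) > 0L) {
    stop("variable column(s) not in table: ", paste(unknown, collapse = ", "))
  }
  df$species <- as.character(df$species)
  df$site_id <- as.character(df$site_id)
  if (any(!nzchar(df$species)) || anyNA(df$species)) {
    stop("species labels must be non-empty")
  }
  if (any(!nzchar(df$site_id)) || anyNA(df$site_id)) {
    stop("site identifiers must be non-empty")
  }
  dup <- duplicated(df[, c("species", "site_id")])
  if (any(dup)) {
    stop("duplicated (species, site_id) pair(s), e.g. row ",
         which(dup)[1L], ": ", df$species[which(dup)[1L]], " / ",
         df$site_id[which(dup)[1L]])
  }
  for (v in variables) {
    if (is.integer(df[[v]])) df[[v]] <- as.double(df[[v]])
    col <- df[[v]]
    if (!is.numeric(col)) {
      stop("variable column '", v, "' is not numeric")
    }
    bad <- which(!is.finite(col))
    if (length(bad) > 0L) {
      stop("missing or non-finite value for variable '", v,
           "' in row ", bad[1L], " (species ", df$species[bad[1L]],
           ", site ", df$site_id[bad[1L]], ")")
    }
  }
  df <- df[, c(reserved, variables)]
  structure(df, variables = variables,
            class = c("occurrence_table", "data.frame"))
}

#' Variables declared by an occurrence table
#' @param table an `occurrence_table`.
#' @return Character vector of variable names.
#' @export
table_variables <- function(table) {
  stopifnot(inherits(table, "occurrence_table"))
  attr(table, "variables")
}

#' Species present in an occurrence table
#' @param table an `occurrence_table`.
#' @return Character vector of unique species labels, in first-appearance
#'   order.
#' @export
table_species <- function(table) {
  stopifnot(inherits(table, "occurrence_table"))
  unique(table$species)
}

#' Read an occurrence table from disk
#'
#' Reads a delimited text file or spreadsheet laid out like the package's
#' expected raw-data format: columns for species, site identifier,
#' longitude, latitude, then one numeric column per environmental
#' variable. Column headers are mapped onto canonical variable labels by
#' the optional `aliases` map (header -> canonical name); unmapped
#' headers are kept as-is.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"tsv"`, `"xlsx"`. Guessed from the
#'   file extension by default.
#' @param aliases optional named character vector or list mapping file
#'   headers to canonical variable names.
#' @param species_col,site_col,longitude_col,latitude_col header names of
#'   the four reserved columns in the file.
#' @return A validated `occurrence_table`.
#' @export
load_occurrence_table <- function(path,
                                  format = c("guess", "csv", "tsv", "xlsx"),
                                  aliases = NULL,
                                  species_col = "species",
                                  site_col = "site_id",
                                  longitude_col = "longitude",
                                  latitude_col = "latitude") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  raw <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE),
    tsv = utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the 'readxl' package")
      }
      as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
    })
  ren <- c(stats::setNames("species", species_col),
           stats::setNames("site_id", site_col),
           stats::setNames("longitude", longitude_col),
           stats::setNames("latitude", latitude_col))
  if (!is.null(aliases)) ren <- c(ren, unlist(aliases))
  hit <- names(raw) %in% names(ren)
  names(raw)[hit] <- unname(ren[names(raw)[hit]])
  reserved <- c("species", "site_id", "longitude", "latitude")
  miss <- setdiff(reserved, names(raw))
  if (length(miss) > 0L) {
    stop("input file lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  vars <- setdiff(names(raw), reserved)
  for (v in vars) {
    col <- raw[[v]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)))
      if (length(bad) > 0L) {
        stop("non-numeric value '", col[bad[1L]], "' for variable '", v,
             "' in data row ", bad[1L])
      }
      raw[[v]] <- num
    }
    empty <- which(is.na(raw[[v]]))
    if (length(empty) > 0L) {
      stop("missing value for variable '", v, "' in data row ", empty[1L])
    }
  }
  occurrence_table(raw, variables = vars)
}

#' Write an occurrence table to CSV at full precision
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces the numeric values bit-for-bit.
#'
#' @param table an `occurrence_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(table, path) {
  stopifnot(inherits(table, "occurrence_table"))
  out <- as.data.frame(table)
  for (v in table_variables(table)) {
    out[[v]] <- formatC(out[[v]], digits = 17, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Extract one species-variable sample
#'
#' The species-variable sample is the unit of analysis: the raw values of
#' one environmental variable at every collection site of one species,
#' in original row order.
#'
#' @param table an `occurrence_table`.
#' @param species species label.
#' @param variable variable name.
#' @return A list of class `species_variable_sample` with elements
#'   `species`, `variable`, `values`, `n`.
#' @export
extract_sample <- function(table, species, variable) {
  stopifnot(inherits(table, "occurrence_table"))
  if (!species %in% table$species) {
    stop("unknown species: ", species)
  }
  if (!variable %in% table_variables(table)) {
    stop("unknown variable: ", variable)
  }
  values <- table[[variable]][table$species == species]
  species_variable_sample(species, variable, values)
}

#' Construct a species-variable sample directly from values
#'
#' @param species species label.
#' @param variable variable name.
#' @param values numeric vector of raw gradient values, one per site.
#' @return A list of class `species_variable_sample`.
#' @export
species_variable_sample <- function(species, variable, values) {
  stopifnot(is.character(species), nzchar(species),
            is.character(variable), nzchar(variable))
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a sample needs at least 2 values")
  if (any(!is.finite(values))) stop("sample values must be finite")
  structure(list(species = species, variable = variable,
                 values = values, n = length(values)),
            class = "species_variable_sample")
}

#' @export
print.species_variable_sample <- function(x, ...) {
  cat("Species-variable sample: ", x$species, " / ", x$variable,
      " (n = ", x$n, ")\n", sep = "")
  cat("  range: [", format(min(x$values)), ", ",
      format(max(x$values)), "]\n", sep = "")
  invisible(x)
}
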