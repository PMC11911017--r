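#' Range limit required for symmetry around the mode
#'
#' For the mode to sit at the midpoint of the species' (possibly
#' expanded) range limits, the shorter tail — the distance from the mode
#' to the nearest observed extreme, d1 — would have to grow to match the
#' longer tail d2. The required limit is the mode plus/minus d2 on the
#' short side's direction.
#'
#' @param xmin,xmax observed range limits.
#' @param mode mode of the fitted curve, inside `[xmin, xmax]`.
#' @return List with `expansion_side` (`"left"`, `"right"`, `"none"`),
#'   `required_limit`, `d1`, `d2`.
#' @examples
#' # limits 17.5 and 27.5, mode 26.02: the upper limit must reach 34.54
#' required_symmetric_limit(17.5, 27.5, 26.02)
#' @export
required_symmetric_limit <- function(xmin, xmax, mode) {
  stopifnot(xmin < xmax, mode >= xmin, mode <= xmax)
  left <- mode - xmin
  right <- xmax - mode
  d1 <- min(left, right)
  d2 <- max(left, right)
  if (left == right) {
    side <- "none"
    required <- xmax  # already symmetric; no limit needs to move
  } else if (right < left) {
    side <- "right"
    required <- mode + d2
  } else {
    side <- "left"
    required <- mode - d2
  }
  list(expansion_side = side, required_limit = required, d1 = d1, d2 = d2)
}

#' Signed expansion factor d2/d1
#'
#' The ratio of the tail length required for symmetry (d2) to the
#' observed shorter tail (d1), signed positive when the expansion is
#' needed to the right and negative to the left. When the mode sits
#' exactly on a range extreme (d1 = 0) the factor is undefined: the true
#' mode is unknown beyond the truncation.
#'
#' @param d1 shorter tail length (>= 0).
#' @param d2 longer tail length (>= d1).
#' @param expansion_side `"left"`, `"right"`, or `"none"`.
#' @return Signed ratio, or `NA` when d1 = 0.
#' @export
expansion_factor <- function(d1, d2, expansion_side) {
  stopifnot(d1 >= 0, d2 >= d1,
            expansion_side %in% c("left", "right", "none"))
  if (d1 == 0) return(NA_real_)
  sign <- switch(expansion_side, right = 1, left = -1, none = 1)
  sign * d2 / d1
}

#' Classify expansion feasibility of a species-variable combination
#'
#' A combination is `centered` when its relative distance is zero (the
#' midpoint lies inside the highest-probability interval). Otherwise,
#' with the mode on a range extreme (d1 = 0) the assessment is
#' `undefined_d1_zero`. Otherwise the required symmetric limit is
#' checked against the variable's natural domain: falling outside a
#' finite bound makes expansion `expansion_impossible` (e.g.,
#' precipitation cannot be negative); otherwise it is
#' `expansion_possible` — note a naturally truncated variable can still
#' be expandable when the required limit does not reach the bound.
#' Boundary equality counts as possible: the bound itself is attainable.
#'
#' @param required_limit limit needed for symmetry.
#' @param expansion_side `"left"`, `"right"`, or `"none"`.
#' @param domain a `variable_domain`.
#' @param relDis relative distance in percent.
#' @param d1 shorter tail length.
#' @return One of `"centered"`, `"expansion_possible"`,
#'   `"expansion_impossible"`, `"undefined_d1_zero"`.
#' @export
classify_expansion <- function(required_limit, expansion_side, domain,
                               relDis, d1) {
  stopifnot(inherits(domain, "variable_domain"))
  if (relDis == 0) return("centered")
  if (d1 == 0) return("undefined_d1_zero")
  if (required_limit < domain$lower || required_limit > domain$upper) {
    return("expansion_impossible")
  }
  "expansion_possible"
}

#' Is a required limit inside the study-wide observed range?
#'
#' Compares the limit required for symmetry with the overall range of
#' the variable observed across all species (closed interval): if the
#' required parameter already exists somewhere in the study region, the
#' expansion is not merely theoretical.
#'
#' @param required_limit the limit needed for symmetry.
#' @param expansion_side unused in the comparison, kept for record
#'   completeness.
#' @param study_range numeric length-2 vector `c(min, max)` across all
#'   species.
#' @return Logical.
#' @export
compare_required_to_observed <- function(required_limit, expansion_side,
                                         study_range) {
  stopifnot(length(study_range) == 2L, study_range[1L] <= study_range[2L])
  required_limit >= study_range[1L] && required_limit <= study_range[2L]
}

#' Full symmetry assessment for one combination
#'
#' Bundles [required_symmetric_limit()], [expansion_factor()] and
#' [classify_expansion()] into one record.
#'
#' @param species,variable labels.
#' @param xmin,xmax observed range.
#' @param mode fitted mode.
#' @param domain a `variable_domain`.
#' @param relDis relative distance in percent.
#' @return A list of class `symmetry_assessment`.
#' @export
assess_symmetry <- function(species, variable, xmin, xmax, mode, domain,
                            relDis) {
  lim <- required_symmetric_limit(xmin, xmax, mode)
  structure(list(species = species,
                 variable = variable,
                 mode = mode,
                 d1 = lim$d1,
                 d2 = lim$d2,
                 required_limit = lim$required_limit,
                 expansion_side = lim$expansion_side,
                 category = classify_expansion(lim$required_limit,
                                               lim$expansion_side,
                                               domain, relDis, lim$d1),
                 expansion_factor = expansion_factor(lim$d1, lim$d2,
                                                     lim$expansion_side)),
            class = "symmetry_assessment")
}
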