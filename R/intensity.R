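#' MET cut points for activity intensity classes
#'
#' The four intensity classes partition the non-negative MET axis into
#' half-open intervals: sedentary `[0, 1.8)`, light `[1.8, 3.0)`,
#' moderate `[3.0, 6.0)` and vigorous `[6.0, Inf)`.
#'
#' @return Named numeric vector of lower bounds for the four classes.
#' @export
met_cutpoints <- function() {
  c(sedentary = 0, light = 1.8, moderate = 3.0, vigorous = 6.0)
}

#' Intensity class labels in increasing order of intensity
#' @return Character vector of the four class labels.
#' @export
intensity_levels <- function() {
  c("sedentary", "light", "moderate", "vigorous")
}

#' Classify MET values into activity intensity classes
#'
#' Assigns each minute-level MET value to the unique intensity class whose
#' half-open interval contains it: sedentary below 1.8 METs, light from 1.8
#' up to (but excluding) 3.0, moderate from 3.0 up to 6.0, and vigorous at
#' 6.0 METs or above. Boundary values belong to the upper class (3.0 METs is
#' moderate, 6.0 is vigorous).
#'
#' @param mets Numeric vector of MET values, all non-negative.
#' @return Factor with levels `sedentary`, `light`, `moderate`, `vigorous`,
#'   the same length as `mets`.
#' @examples
#' classify_intensity(c(1.5, 1.8, 3, 6))
#' @export
classify_intensity <- function(mets) {
  if (!is.numeric(mets)) stop("`mets` must be numeric")
  if (anyNA(mets)) stop("`mets` contains missing values")
  if (any(mets < 0)) stop("MET values must be non-negative")
  cut(mets,
    breaks = c(met_cutpoints(), Inf), labels = intensity_levels(),
    right = FALSE, include.lowest = TRUE
  )
}

# Fast internal variant: integer codes 1..4 without factor overhead.
intensity_code <- function(mets) {
  findInterval(mets, c(1.8, 3.0, 6.0)) + 1L
}
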