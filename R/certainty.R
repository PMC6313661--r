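#' GRADE certainty levels
#'
#' The four GRADE certainty-of-evidence levels recognised by the package,
#' ordered from least to most certain.
#'
#' @return Character vector `c("very_low", "low", "moderate", "high")`.
#' @export
certainty_levels <- function() {
  c("very_low", "low", "moderate", "high")
}

#' Certainty level to numeric multiplier mapping
#'
#' Builds the mapping from GRADE certainty levels to the 0-1 multipliers
#' used in certainty-adjusted scoring. The defaults are very low = 0.1,
#' low = 0.4, moderate = 0.7, high = 1.0; they are configurable because
#' the particular values are a convention, not a law, but any mapping must
#' be strictly increasing with level and lie in [0, 1].
#'
#' @param very_low,low,moderate,high Multipliers for each level.
#' @return Named numeric vector of length 4, class `certainty_mapping`.
#' @examples
#' certainty_mapping()
#' certainty_mapping(moderate = 0.8)
#' @export
certainty_mapping <- function(very_low = 0.1, low = 0.4, moderate = 0.7,
                              high = 1.0) {
  m <- c(very_low = very_low, low = low, moderate = moderate, high = high)
  if (!is.numeric(m) || anyNA(m)) {
    stop("certainty multipliers must be non-missing numbers", call. = FALSE)
  }
  if (any(m < 0) || any(m > 1)) {
    stop("certainty multipliers must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(m) <= 0)) {
    stop("certainty multipliers must be strictly increasing with level",
         call. = FALSE)
  }
  structure(m, class = "certainty_mapping")
}

#' Numeric multiplier for a GRADE certainty level
#'
#' @param level One of `"very_low"`, `"low"`, `"moderate"`, `"high"`.
#' @param mapping A [certainty_mapping()]; defaults to the standard
#'   0.1/0.4/0.7/1.0 mapping.
#' @return The multiplier, a number in [0, 1].
#' @examples
#' certainty_multiplier("high")      # 1.0
#' certainty_multiplier("very_low")  # 0.1
#' @export
certainty_multiplier <- function(level, mapping = certainty_mapping()) {
  if (length(level) != 1L || !is.character(level) ||
      !level %in% certainty_levels()) {
    stop("unknown certainty level: ",
         paste(as.character(level), collapse = ", "),
         " (expected one of ", paste(certainty_levels(), collapse = ", "),
         ")", call. = FALSE)
  }
  unname(mapping[[level]])
}
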