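#' Value-function specification
#'
#' Describes how a raw performance measurement becomes a 0-1 rating.
#' Four kinds are supported:
#' \describe{
#'   \item{identity}{the raw value already is a rating; clipped to [0,1].}
#'   \item{one_minus_risk}{an event probability p becomes 1 - p (a harm
#'     turned into a value).}
#'   \item{linear_anchor}{linear rescaling with `worst_raw` mapping to 0
#'     and `best_raw` mapping to 1, clipped.}
#'   \item{reference_anchored}{one option is pinned at `reference_rating`
#'     and the raw value, read as a signed benefit relative to that
#'     reference, moves the rating by `scale` per raw unit, clipped. Used
#'     when only effect *differences* are published.}
#' }
#'
#' @param kind One of `"identity"`, `"one_minus_risk"`, `"linear_anchor"`,
#'   `"reference_anchored"`.
#' @param worst_raw,best_raw Anchors for `linear_anchor` (must differ).
#' @param reference_rating Rating of the reference option,
#'   for `reference_anchored`; in [0, 1].
#' @param scale Raw-to-rating slope for `reference_anchored`; > 0.
#' @param units Optional unit string; checked against the units supplied
#'   to [apply_value_function()].
#' @return An object of class `value_function`.
#' @export
value_function <- function(kind = c("identity", "one_minus_risk",
                                    "linear_anchor", "reference_anchored"),
                           worst_raw = NULL, best_raw = NULL,
                           reference_rating = 0.5, scale = 0.5,
                           units = NULL) {
  kind <- match.arg(kind)
  if (kind == "linear_anchor") {
    if (is.null(worst_raw) || is.null(best_raw)) {
      stop("linear_anchor needs worst_raw and best_raw", call. = FALSE)
    }
    if (worst_raw == best_raw) {
      stop("worst_raw and best_raw must differ", call. = FALSE)
    }
  }
  if (kind == "reference_anchored") {
    if (reference_rating < 0 || reference_rating > 1) {
      stop("reference_rating must lie in [0, 1]", call. = FALSE)
    }
    if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, worst_raw = worst_raw, best_raw = best_raw,
                 reference_rating = reference_rating, scale = scale,
                 units = units),
            class = "value_function")
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Convert a raw performance value to a 0-1 rating
#'
#' @param raw Numeric raw value. For `reference_anchored` this is the
#'   signed benefit relative to the reference option, in raw units.
#' @param spec A [value_function()].
#' @param polarity `"benefit"` or `"harm"`; `one_minus_risk` requires
#'   harm polarity (it inverts an event probability).
#' @param units Optional unit string for `raw`; if both this and
#'   `spec$units` are given they must agree.
#' @return A rating in [0, 1].
#' @examples
#' apply_value_function(0, value_function("one_minus_risk"), "harm")  # 1
#' vf <- value_function("linear_anchor", worst_raw = 30, best_raw = 0)
#' apply_value_function(15, vf, "harm")  # 0.5
#' @export
apply_value_function <- function(raw, spec, polarity = c("harm", "benefit"),
                                 units = NULL) {
  polarity <- match.arg(polarity)
  if (!inherits(spec, "value_function")) {
    stop("spec must be built with value_function()", call. = FALSE)
  }
  if (!is.null(units) && !is.null(spec$units) && units != spec$units) {
    stop("units mismatch: raw value in '", units,
         "' but value function expects '", spec$units, "'", call. = FALSE)
  }
  if (!is.numeric(raw) || anyNA(raw)) {
    stop("raw value must be numeric and non-missing", call. = FALSE)
  }
  switch(spec$kind,
    identity = clip01(raw),
    one_minus_risk = {
      if (polarity != "harm") {
        stop("one_minus_risk applies to harm-polarity criteria", call. = FALSE)
      }
      if (any(raw < 0) || any(raw > 1)) {
        stop("event probability outside [0, 1]: ", format(raw), call. = FALSE)
      }
      1 - raw
    },
    linear_anchor = clip01((raw - spec$worst_raw) /
                             (spec$best_raw - spec$worst_raw)),
    reference_anchored = clip01(spec$reference_rating + spec$scale * raw)
  )
}
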