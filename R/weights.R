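#' Normalize raw importance weights
#'
#' Importance weightings are elicited as raw nonnegative numbers on any
#' convenient scale (e.g. 0-100 sliders) and normalized to sum to 1, so
#' the normalized view is invariant to positive rescaling of the raw
#' responses.
#'
#' @param raw Nonnegative numeric vector, at least one entry strictly
#'   positive. Names, if present, are kept as criterion ids.
#' @param criteria Optional character vector of criterion ids; must match
#'   `length(raw)`. Overrides names of `raw`.
#' @return An object of class `weight_set` with elements `raw`,
#'   `normalized` (sums to 1) and `criteria`.
#' @examples
#' normalize_weights(c(2, 3, 5))$normalized  # 0.2 0.3 0.5
#' @export
normalize_weights <- function(raw, criteria = NULL) {
  if (!is.numeric(raw) || length(raw) == 0L || anyNA(raw)) {
    stop("weights must be a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  if (is.null(criteria)) criteria <- names(raw)
  if (!is.null(criteria) && length(criteria) != length(raw)) {
    stop("criteria ids and weights differ in length", call. = FALSE)
  }
  lab <- if (is.null(criteria)) as.character(seq_along(raw)) else criteria
  neg <- which(raw < 0)
  if (length(neg) > 0L) {
    stop("negative weight for criterion ",
         paste(lab[neg], collapse = ", "), call. = FALSE)
  }
  s <- sum(raw)
  if (s <= 0) stop("degenerate weights: all entries are zero", call. = FALSE)
  raw <- unname(as.numeric(raw))
  normalized <- raw / s
  if (!is.null(criteria)) {
    names(raw) <- criteria
    names(normalized) <- criteria
  }
  structure(list(raw = raw, normalized = normalized, criteria = criteria),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("Weight set over", length(x$normalized), "criteria (normalized):\n")
  print(round(x$normalized, 4))
  invisible(x)
}

# Align a weight_set (or raw numeric vector) with a model's criteria,
# returning the normalized vector in model order. Errors on dimension or
# id mismatch.
weights_for_model <- function(weights, model) {
  if (is.numeric(weights)) weights <- normalize_weights(weights)
  if (!inherits(weights, "weight_set")) {
    stop("weights must be a weight_set or a numeric vector", call. = FALSE)
  }
  ids <- criterion_ids(model)
  w <- weights$normalized
  if (length(w) != length(ids)) {
    stop("weight vector has ", length(w), " entries but the model has ",
         length(ids), " criteria", call. = FALSE)
  }
  if (!is.null(names(w))) {
    if (!setequal(names(w), ids)) {
      stop("weight names do not match the model's criteria", call. = FALSE)
    }
    w <- w[ids]
  } else {
    names(w) <- ids
  }
  w
}
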