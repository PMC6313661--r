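#' Define a decision criterion
#'
#' A criterion is one consideration on which the options are compared:
#' an evidence outcome (mortality, stroke, ...) or a practical
#' consideration the person rates themselves. Ratings live on a 0-1
#' "larger is better" value scale regardless of polarity; `polarity`
#' records whether larger *raw* values (risks, days) are good or bad,
#' which matters when a value function converts raw evidence to ratings.
#'
#' @param id Short unique token, e.g. `"bleeding"`.
#' @param label Display text; defaults to `id`.
#' @param polarity `"benefit"` (larger raw values better) or `"harm"`.
#' @param locked Logical; locked criteria carry evidence-derived ratings
#'   that users may not edit (prevents misrepresentation).
#' @param certainty GRADE certainty level of the supporting evidence.
#' @param source `"evidence"` or `"user"`.
#' @param value_function Optional [value_function()] spec describing how
#'   raw performance was converted to the 0-1 rating.
#' @return An object of class `criterion`.
#' @export
criterion <- function(id, label = id, polarity = c("harm", "benefit"),
                      locked = FALSE,
                      certainty = c("high", "moderate", "low", "very_low"),
                      source = c("user", "evidence"),
                      value_function = NULL) {
  polarity <- match.arg(polarity)
  certainty <- match.arg(certainty)
  source <- match.arg(source)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(label), length(label) == 1L,
            is.logical(locked), length(locked) == 1L, !is.na(locked))
  if (!is.null(value_function) && !inherits(value_function, "value_function")) {
    stop("value_function must be built with value_function()", call. = FALSE)
  }
  structure(
    list(id = id, label = label, polarity = polarity, locked = locked,
         certainty = certainty, source = source,
         value_function = value_function),
    class = "criterion"
  )
}

#' Construct a decision model
#'
#' The central container: two or more options, an ordered list of
#' criteria, and a complete ratings matrix on [0, 1] indexed
#' (option, criterion). Criterion order is preserved everywhere; no
#' output ever sorts criteria, so reports are stable.
#'
#' @param options Character vector of option ids (length >= 2).
#' @param criteria List of [criterion()] objects.
#' @param ratings Numeric matrix, `length(options)` rows by
#'   `length(criteria)` columns, entries in [0, 1].
#' @param raw_values Optional matrix of raw performances (same shape),
#'   retained for audit alongside the derived ratings.
#' @param metadata Named list; `title`, free-form `notes`, and the
#'   mandatory not-a-validated-decision-aid `disclaimer` (added if
#'   absent).
#' @return An object of class `decision_model`.
#' @seealso [validate_model()], [set_user_rating()], [mcda_score()]
#' @export
decision_model <- function(options, criteria, ratings, raw_values = NULL,
                           metadata = list()) {
  criteria <- lapply(criteria, function(cr) {
    if (!inherits(cr, "criterion")) stop("criteria must be criterion() objects",
                                         call. = FALSE)
    cr
  })
  ratings <- as.matrix(ratings)
  ids <- vapply(criteria, `[[`, character(1), "id")
  dimnames(ratings) <- list(options, ids)
  if (!is.null(raw_values)) {
    raw_values <- as.matrix(raw_values)
    dimnames(raw_values) <- list(options, ids)
  }
  if (is.null(metadata$disclaimer)) metadata$disclaimer <- mcda_disclaimer()
  model <- structure(
    list(options = options, criteria = criteria, ratings = ratings,
         raw_values = raw_values, metadata = metadata),
    class = "decision_model"
  )
  model
}

criterion_ids <- function(model) {
  vapply(model$criteria, `[[`, character(1), "id")
}

criterion_certainties <- function(model) {
  vapply(model$criteria, `[[`, character(1), "certainty")
}

#' Validate a decision model
#'
#' Checks every structural invariant and returns the violations as data,
#' not exceptions: an empty character vector means the model is valid.
#' Each violation names the offending field or cell.
#'
#' @param model A [decision_model()].
#' @return Character vector of violation messages (possibly empty).
#' @examples
#' m <- tavi_savr_model()
#' validate_model(m)  # character(0)
#' @export
validate_model <- function(model) {
  v <- character(0)
  if (!inherits(model, "decision_model")) {
    return("not a decision_model object")
  }
  if (length(model$options) < 2L) {
    v <- c(v, "model must have at least 2 options")
  }
  if (anyDuplicated(model$options)) {
    v <- c(v, paste0("duplicate option id: ",
                     paste(unique(model$options[duplicated(model$options)]),
                           collapse = ", ")))
  }
  ids <- criterion_ids(model)
  if (anyDuplicated(ids)) {
    v <- c(v, paste0("duplicate criterion id: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (cr in model$criteria) {
    if (!cr$certainty %in% certainty_levels()) {
      v <- c(v, paste0("criterion ", cr$id, ": unknown certainty level '",
                       cr$certainty, "'"))
    }
    if (!cr$polarity %in% c("benefit", "harm")) {
      v <- c(v, paste0("criterion ", cr$id, ": unknown polarity '",
                       cr$polarity, "'"))
    }
  }
  R <- model$ratings
  if (!is.matrix(R) || nrow(R) != length(model$options) ||
      ncol(R) != length(model$criteria)) {
    v <- c(v, "ratings matrix dimensions do not match options x criteria")
    return(v)
  }
  for (i in seq_len(nrow(R))) {
    for (j in seq_len(ncol(R))) {
      x <- R[i, j]
      if (is.na(x)) {
        v <- c(v, paste0("missing rating at (", model$options[i], ", ",
                         ids[j], ")"))
      } else if (x < 0 || x > 1) {
        v <- c(v, paste0("rating out of [0,1] at (", model$options[i], ", ",
                         ids[j], "): ", format(x)))
      }
    }
  }
  v
}

#' Set a user-supplied rating
#'
#' Writes one cell of the ratings matrix, but only for unlocked criteria:
#' evidence-derived ratings are locked to prevent editing and possible
#' misrepresentation. The update is immutable — a new model is returned
#' and the original is untouched — so an elicitation session can be
#' replayed or logged.
#'
#' @param model A [decision_model()].
#' @param criterion_id Id of an *unlocked* criterion.
#' @param option_id Id of an option.
#' @param rating Number in [0, 1].
#' @return A new `decision_model` with the cell updated.
#' @export
set_user_rating <- function(model, criterion_id, option_id, rating) {
  ids <- criterion_ids(model)
  j <- match(criterion_id, ids)
  if (is.na(j)) stop("unknown criterion: ", criterion_id, call. = FALSE)
  i <- match(option_id, model$options)
  if (is.na(i)) stop("unknown option: ", option_id, call. = FALSE)
  if (!is.numeric(rating) || length(rating) != 1L || is.na(rating) ||
      rating < 0 || rating > 1) {
    stop("rating must be a number in [0, 1], got ",
         paste(format(rating), collapse = ", "), call. = FALSE)
  }
  if (isTRUE(model$criteria[[j]]$locked)) {
    stop("locked rating: criterion '", criterion_id,
         "' carries evidence-derived ratings and cannot be edited",
         call. = FALSE)
  }
  model$ratings[i, j] <- rating
  model
}

#' @export
print.decision_model <- function(x, ...) {
  ids <- criterion_ids(x)
  locked <- vapply(x$criteria, `[[`, logical(1), "locked")
  cat("Decision model: ",
      if (!is.null(x$metadata$title)) x$metadata$title else "<untitled>",
      "\n", sep = "")
  cat("  options : ", paste(x$options, collapse = ", "), "\n", sep = "")
  cat("  criteria: ", length(ids), " (", sum(locked), " locked)\n", sep = "")
  tab <- t(x$ratings)
  rownames(tab) <- paste0(ifelse(locked, "[L] ", "    "), ids)
  print(round(tab, 3))
  invisible(x)
}

#' Fingerprint of a decision model
#'
#' MD5 hash of the model's options, criterion definitions and full-precision
#' ratings. Score objects store the hash of the model they were computed
#' from, so a report cannot silently be rendered against an edited model.
#'
#' @param model A [decision_model()].
#' @return A 32-character hex string.
#' @export
model_hash <- function(model) {
  lines <- c(
    paste(model$options, collapse = "|"),
    vapply(model$criteria, function(cr) {
      paste(cr$id, cr$polarity, cr$locked, cr$certainty, cr$source,
            sep = "|")
    }, character(1)),
    sprintf("%.17g", as.vector(model$ratings))
  )
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(lines, f)
  unname(tools::md5sum(f))
}

#' Standard disclaimer carried by every document and report
#'
#' @return A single string.
#' @export
mcda_disclaimer <- function() {
  paste("DISCLAIMER: This is not a validated clinical decision aid.",
        "Scores are preference-sensitive opinions intended to support",
        "discussion, provided without any warranty that the underlying",
        "evidence is accurate or up to date; any reliance on them is",
        "strictly at the user's own risk.")
}
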