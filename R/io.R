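# Versioned JSON model-document format. Unknown fields are rejected, not
# ignored: silent misconfiguration is unacceptable in a clinical-facing
# tool. Ratings are written at full precision so write-then-read is
# bit-identical.

MODEL_SCHEMA_VERSION <- "1.0"

vf_to_list <- function(vf) {
  if (is.null(vf)) return(NULL)
  list(kind = vf$kind, worst_raw = vf$worst_raw, best_raw = vf$best_raw,
       reference_rating = vf$reference_rating, scale = vf$scale,
       units = vf$units)
}

vf_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  value_function(kind = x$kind,
                 worst_raw = x$worst_raw, best_raw = x$best_raw,
                 reference_rating = if (is.null(x$reference_rating)) 0.5 else x$reference_rating,
                 scale = if (is.null(x$scale)) 0.5 else x$scale,
                 units = x$units)
}

#' Write a decision model document
#'
#' Serialises a [decision_model()] to the package's versioned JSON schema
#' (schema_version, metadata incl. the mandatory disclaimer, options,
#' criteria, ratings, optional raw_values). Numbers are written at full
#' precision so a write/read round trip reproduces the ratings
#' bit-identically.
#'
#' @param model A [decision_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (is.null(model$metadata$disclaimer)) {
    model$metadata$disclaimer <- mcda_disclaimer()
  }
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    metadata = model$metadata,
    options = as.list(model$options),
    criteria = lapply(model$criteria, function(cr) {
      list(id = cr$id, label = cr$label, polarity = cr$polarity,
           locked = cr$locked, certainty = cr$certainty, source = cr$source,
           value_function = vf_to_list(cr$value_function))
    }),
    ratings = lapply(seq_len(nrow(model$ratings)),
                     function(i) as.list(unname(model$ratings[i, ]))),
    raw_values = if (is.null(model$raw_values)) NULL else
      lapply(seq_len(nrow(model$raw_values)),
             function(i) as.list(unname(model$raw_values[i, ])))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

doc_field <- function(x, name, where) {
  if (is.null(x[[name]])) {
    stop("malformed model document: missing '", name, "' in ", where,
         call. = FALSE)
  }
  x[[name]]
}

#' Read a decision model document
#'
#' Parses a JSON model document written by [write_model()], rejecting
#' unknown schema versions and unknown fields, and validates the result:
#' a document that does not yield a valid model fails with the list of
#' violations, each locating the offending field or cell.
#'
#' @param path Path to a model document.
#' @return A validated [decision_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed model document: ", conditionMessage(e),
                         call. = FALSE)
                  })
  allowed <- c("schema_version", "metadata", "options", "criteria",
               "ratings", "raw_values")
  extra <- setdiff(names(doc), allowed)
  if (length(extra) > 0L) {
    stop("unknown field(s) in model document: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  ver <- doc_field(doc, "schema_version", "document root")
  if (!identical(ver, MODEL_SCHEMA_VERSION)) {
    stop("unsupported schema version '", ver, "' (supported: ",
         MODEL_SCHEMA_VERSION, ")", call. = FALSE)
  }
  options <- unlist(doc_field(doc, "options", "document root"))
  crit_list <- doc_field(doc, "criteria", "document root")
  criteria <- lapply(crit_list, function(cr) {
    extra <- setdiff(names(cr), c("id", "label", "polarity", "locked",
                                  "certainty", "source", "value_function"))
    if (length(extra) > 0L) {
      stop("unknown criterion field(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    criterion(id = doc_field(cr, "id", "criterion"),
              label = doc_field(cr, "label", "criterion"),
              polarity = doc_field(cr, "polarity", "criterion"),
              locked = doc_field(cr, "locked", "criterion"),
              certainty = doc_field(cr, "certainty", "criterion"),
              source = doc_field(cr, "source", "criterion"),
              value_function = vf_from_list(cr$value_function))
  })
  rat_rows <- doc_field(doc, "ratings", "document root")
  if (length(rat_rows) != length(options)) {
    stop("ratings have ", length(rat_rows), " rows for ", length(options),
         " options", call. = FALSE)
  }
  ids <- vapply(criteria, `[[`, character(1), "id")
  ratings <- matrix(NA_real_, nrow = length(options), ncol = length(criteria))
  for (i in seq_along(rat_rows)) {
    row <- rat_rows[[i]]
    if (length(row) != length(criteria)) {
      stop("ratings row for option '", options[i], "' has ", length(row),
           " cells for ", length(criteria), " criteria", call. = FALSE)
    }
    for (j in seq_along(row)) {
      cell <- row[[j]]
      if (is.null(cell) || !is.numeric(cell)) {
        stop("missing rating at (", options[i], ", ", ids[j], ")",
             call. = FALSE)
      }
      ratings[i, j] <- cell
    }
  }
  raw_values <- NULL
  if (!is.null(doc$raw_values)) {
    raw_values <- matrix(NA_real_, nrow = length(options),
                         ncol = length(criteria))
    for (i in seq_along(doc$raw_values)) {
      row <- doc$raw_values[[i]]
      for (j in seq_along(row)) {
        raw_values[i, j] <- if (is.null(row[[j]])) NA_real_ else row[[j]]
      }
    }
  }
  metadata <- doc$metadata
  if (!is.null(metadata$notes)) metadata$notes <- unlist(metadata$notes)
  model <- decision_model(options = options, criteria = criteria,
                          ratings = ratings, raw_values = raw_values,
                          metadata = metadata)
  v <- validate_model(model)
  if (length(v) > 0L) {
    stop("model document fails validation:\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  }
  model
}

#' Turn elicited importance responses into weights
#'
#' Takes one raw importance response per criterion on the 0-100 slider
#' scale, in model order (or named by criterion id), and delegates to
#' [normalize_weights()]. The responses are kept on the result as a
#' transcript attribute so a session can be revised and replayed.
#'
#' @param model A [decision_model()].
#' @param responses Numeric vector, one response in [0, 100] per
#'   criterion; if named, names must cover the model's criteria.
#' @return A `weight_set`; `attr(, "transcript")` holds the
#'   criterion/response table.
#' @export
elicit_weights <- function(model, responses) {
  ids <- criterion_ids(model)
  if (length(responses) != length(ids)) {
    stop("expected one response per criterion (", length(ids), "), got ",
         length(responses), call. = FALSE)
  }
  if (anyNA(responses)) stop("missing importance response", call. = FALSE)
  if (!is.null(names(responses))) {
    if (!setequal(names(responses), ids)) {
      stop("response names do not match the model's criteria", call. = FALSE)
    }
    responses <- responses[ids]
  }
  if (any(responses < 0) || any(responses > 100)) {
    stop("importance responses must lie on the 0-100 scale", call. = FALSE)
  }
  ws <- normalize_weights(as.numeric(responses), criteria = ids)
  attr(ws, "transcript") <- data.frame(criterion = ids,
                                       response = as.numeric(responses),
                                       stringsAsFactors = FALSE)
  ws
}
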