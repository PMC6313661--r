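# The "decisiographic": one plain-text screen integrating the evidence
# (ratings, locked cells marked), the person's weightings, and the score
# pairs that result — plus, when supplied, the sensitivity analyses. The
# body is deterministic (no timestamps), so regenerating a report from the
# same inputs is byte-identical and golden-file testable. It deliberately
# contains no directive language: the tool renders opinions, not advice.

#' Render the one-screen decision report
#'
#' @param model A [decision_model()].
#' @param weights The `weight_set` the scores were computed with.
#' @param scores An [mcda_score()] result computed from exactly this
#'   model and these weights; a hash mismatch (model edited after
#'   scoring) is an error.
#' @param flips Optional [flip_thresholds()] data.frame.
#' @param shares Optional [preference_share()] result.
#' @param classification Optional [classify_recommendation()] result.
#' @return A single string of class `decisiographic` (printed with
#'   `cat`).
#' @examples
#' m <- tavi_savr_model()
#' w <- normalize_weights(rep(1, 10), criteria = sapply(m$criteria, `[[`, "id"))
#' render_decisiographic(m, w, mcda_score(m, w))
#' @export
render_decisiographic <- function(model, weights, scores, flips = NULL,
                                  shares = NULL, classification = NULL) {
  if (!inherits(scores, "mcda_scores")) {
    stop("scores must come from mcda_score()", call. = FALSE)
  }
  if (!identical(scores$model_hash, model_hash(model))) {
    stop("stale scores: the model has changed since these scores were computed",
         call. = FALSE)
  }
  w <- weights_for_model(weights, model)
  if (!isTRUE(all.equal(unname(w), unname(scores$weights),
                        tolerance = 1e-12))) {
    stop("stale scores: weights differ from those used for scoring",
         call. = FALSE)
  }
  ids <- criterion_ids(model)
  labels <- vapply(model$criteria, `[[`, character(1), "label")
  locked <- vapply(model$criteria, `[[`, logical(1), "locked")
  cert <- criterion_certainties(model)

  hr <- strrep("-", 78)
  lines <- c(
    hr,
    if (!is.null(model$metadata$title)) model$metadata$title else "Decision model",
    hr,
    sprintf("Options: %s", paste(model$options, collapse = " vs ")),
    "",
    "Criteria ([L] = locked evidence rating), weights and ratings:",
    sprintf("  %-42s %-9s %6s  %s", "criterion", "certainty", "weight",
            paste(sprintf("%6s", model$options), collapse = " "))
  )
  for (j in seq_along(ids)) {
    lines <- c(lines, sprintf(
      "  %s %-38s %-9s %6.4f  %s",
      if (locked[j]) "[L]" else "   ",
      substr(labels[j], 1, 38), cert[j], w[[j]],
      paste(sprintf("%6.3f", model$ratings[, j]), collapse = " ")))
  }
  lines <- c(lines, "",
             "Expected-value scores (0-1; higher = performs better on what matters to you):",
             sprintf("  %-8s %12s %20s", "option", "unadjusted",
                     "certainty-adjusted"))
  for (i in seq_along(model$options)) {
    lines <- c(lines, sprintf("  %-8s %12.4f %20.4f", model$options[i],
                              scores$unadjusted[i], scores$adjusted[i]))
  }
  pu <- preferred_option(scores$unadjusted)
  pa <- preferred_option(scores$adjusted)
  lines <- c(lines,
             sprintf("  highest unadjusted: %s; highest adjusted: %s",
                     if (is.na(pu)) "tie" else pu,
                     if (is.na(pa)) "tie" else pa),
             sprintf("  adjustment: %s mode; certainty mapping %s", scores$mode,
                     paste(sprintf("%s=%.2g", names(scores$mapping),
                                   scores$mapping), collapse = ", ")))
  if (!is.null(flips)) {
    lines <- c(lines, "",
               "One-way weight sensitivity (weight at which the preferred option flips):")
    for (i in seq_len(nrow(flips))) {
      lines <- c(lines, if (is.na(flips$threshold[i])) {
        sprintf("  %-24s no flip", flips$criterion[i])
      } else {
        sprintf("  %-24s flips to %s above weight %.4f", flips$criterion[i],
                flips$direction[i], flips$threshold[i])
      })
    }
  }
  if (!is.null(shares)) {
    sh <- if (inherits(shares, "preference_shares")) shares$shares else shares
    n <- if (inherits(shares, "preference_shares")) shares$n else NA_integer_
    lines <- c(lines, "",
               sprintf("Simulated preference heterogeneity (%s weight vectors):",
                       format(n, big.mark = ",")),
               vapply(names(sh), function(o) {
                 sprintf("  share preferring %-6s %.4f", o, sh[[o]])
               }, character(1)))
    if (!is.null(classification)) {
      lines <- c(lines, sprintf(
        "  preference pattern: %s (strong >= %.2f, weak >= %.2f of shares)",
        classification$class, classification$thresholds[["strong"]],
        classification$thresholds[["weak"]]))
    }
  }
  if (!is.null(model$metadata$notes)) {
    lines <- c(lines, "", "Notes:",
               paste0("  - ", model$metadata$notes))
  }
  lines <- c(lines, "", model$metadata$disclaimer, hr)
  structure(paste(lines, collapse = "\n"), class = "decisiographic")
}

#' @export
print.decisiographic <- function(x, ...) {
  cat(x, "\n", sep = "")
  invisible(x)
}
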