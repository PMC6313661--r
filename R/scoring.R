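# Effective ratings after certainty adjustment. Certainty attaches to the
# criterion (GRADE grades evidence per outcome), so every option shares the
# multiplier c_k on criterion k.
#   multiplicative: r' = c * r          (down-weights everything certain-ly)
#   shrink        : r' = c*r + (1-c)/2  (pulls uncertain ratings to 0.5)
effective_ratings <- function(model, mode = c("multiplicative", "shrink"),
                              mapping = certainty_mapping()) {
  mode <- match.arg(mode)
  ck <- vapply(criterion_certainties(model),
               certainty_multiplier, numeric(1), mapping = mapping)
  R <- model$ratings
  A <- sweep(R, 2, ck, `*`)
  if (mode == "shrink") {
    A <- A + matrix(rep((1 - ck) * 0.5, each = nrow(R)), nrow = nrow(R),
                    dimnames = dimnames(R))
  }
  A
}

#' Score options by weighted expected value
#'
#' The core of value-based compensatory MCDA: each option's score is the
#' weighted sum of its ratings, `S_o = sum_k w_k r_ok`, with normalized
#' weights `w` and ratings `r` in [0, 1]. Alongside the unadjusted scores
#' the certainty-adjusted pair `S'_o` is always computed, so the effect
#' of evidence certainty is visible: in `"multiplicative"` mode
#' `S'_o = sum_k w_k c_k r_ok`; in `"shrink"` mode uncertain ratings are
#' pulled towards the neutral 0.5,
#' `S'_o = sum_k w_k (c_k r_ok + (1 - c_k) 0.5)`.
#'
#' @param model A valid [decision_model()].
#' @param weights A `weight_set` from [normalize_weights()] (or a raw
#'   nonnegative vector, normalized on the fly), over exactly the model's
#'   criteria.
#' @param mode Certainty-adjustment mode, `"multiplicative"` (default) or
#'   `"shrink"`.
#' @param mapping Certainty [certainty_mapping()].
#' @return An object of class `mcda_scores`: named vectors `unadjusted`
#'   and `adjusted`, per-(option, criterion) `contributions` matrices for
#'   both, the `mode`, `mapping`, aligned `weights`, and the hash of the
#'   scored model.
#' @examples
#' m <- tavi_savr_model()
#' s <- mcda_score(m, rep(1, 10))
#' s
#' coef(s)
#' @export
mcda_score <- function(model, weights, mode = c("multiplicative", "shrink"),
                       mapping = certainty_mapping()) {
  mode <- match.arg(mode)
  v <- validate_model(model)
  if (length(v) > 0L) {
    stop("invalid model:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  w <- weights_for_model(weights, model)
  R <- model$ratings
  A <- effective_ratings(model, mode, mapping)
  contrib_u <- sweep(R, 2, w, `*`)
  contrib_a <- sweep(A, 2, w, `*`)
  structure(
    list(unadjusted = rowSums(contrib_u),
         adjusted = rowSums(contrib_a),
         contributions = list(unadjusted = contrib_u, adjusted = contrib_a),
         mode = mode,
         mapping = mapping,
         weights = w,
         options = model$options,
         model_hash = model_hash(model)),
    class = "mcda_scores"
  )
}

#' Unadjusted expected-value scores
#'
#' Convenience wrapper returning only the unadjusted `S_o = sum_k w_k r_ok`
#' as a named vector. See [mcda_score()] for the full object.
#'
#' @inheritParams mcda_score
#' @return Named numeric vector of per-option scores in [0, 1].
#' @export
expected_value_scores <- function(model, weights) {
  mcda_score(model, weights)$unadjusted
}

# Scores are declared tied when within this tolerance; ties are reported,
# never silently ordered.
SCORE_TIE_TOL <- 1e-9

preferred_option <- function(scores, tol = SCORE_TIE_TOL) {
  mx <- max(scores)
  top <- names(scores)[scores >= mx - tol]
  if (length(top) > 1L) NA_character_ else top
}

#' @export
print.mcda_scores <- function(x, digits = 4, ...) {
  cat("MCDA expected-value scores (", length(x$options), " options, ",
      length(x$weights), " criteria)\n", sep = "")
  tab <- cbind(unadjusted = x$unadjusted, adjusted = x$adjusted)
  print(round(tab, digits))
  cat("certainty adjustment: ", x$mode, " mode, mapping ",
      paste(sprintf("%s=%.2g", names(x$mapping), x$mapping), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.mcda_scores <- function(object, ...) {
  pu <- preferred_option(object$unadjusted)
  pa <- preferred_option(object$adjusted)
  structure(list(scores = object,
                 preferred_unadjusted = pu,
                 preferred_adjusted = pa),
            class = "summary.mcda_scores")
}

#' @export
print.summary.mcda_scores <- function(x, ...) {
  print(x$scores)
  fmt <- function(p) if (is.na(p)) "tie (within 1e-9)" else p
  cat("highest unadjusted score: ", fmt(x$preferred_unadjusted), "\n",
      "highest adjusted score  : ", fmt(x$preferred_adjusted), "\n", sep = "")
  cat("per-criterion contributions (adjusted):\n")
  print(round(x$scores$contributions$adjusted, 4))
  invisible(x)
}

#' @export
coef.mcda_scores <- function(object, ...) {
  cbind(unadjusted = object$unadjusted, adjusted = object$adjusted)
}

#' @export
plot.mcda_scores <- function(x, ...) {
  tab <- rbind(unadjusted = x$unadjusted, adjusted = x$adjusted)
  graphics::barplot(tab, beside = TRUE, ylim = c(0, 1),
                    legend.text = rownames(tab),
                    ylab = "expected-value score",
                    main = "Option scores (unadjusted vs certainty-adjusted)",
                    ...)
  invisible(x)
}

#' Simulate preference heterogeneity for a scored model
#'
#' `simulate()` on an `mcda_scores` object re-scores the same model under
#' `nsim` Dirichlet-sampled weight vectors and returns the share of
#' simulated weightings preferring each option. A thin wrapper around
#' [sample_weight_vectors()] and [preference_share()].
#'
#' @param object An `mcda_scores` object (must carry its model via the
#'   `model` argument since scores store only a hash).
#' @param nsim Number of weight vectors.
#' @param seed Integer RNG seed (required, for reproducibility).
#' @param model The [decision_model()] the scores came from.
#' @param concentration Dirichlet concentration (scalar or per-criterion).
#' @param adjusted Use certainty-adjusted ratings?
#' @param ... Unused.
#' @return A `preference_shares` object.
#' @export
simulate.mcda_scores <- function(object, nsim = 10000, seed = 1, model,
                                 concentration = 1, adjusted = TRUE, ...) {
  if (missing(model)) stop("supply the model the scores were computed from",
                           call. = FALSE)
  if (!identical(object$model_hash, model_hash(model))) {
    stop("stale scores: model has changed since scoring", call. = FALSE)
  }
  smp <- sample_weight_vectors(nsim, length(object$weights),
                               concentration = concentration, seed = seed)
  preference_share(model, smp, adjusted = adjusted, mode = object$mode,
                   mapping = object$mapping)
}

#' Check for a dominant option
#'
#' An option dominates when it is rated at least as well on every
#' criterion and strictly better on at least one; no weighting can then
#' prefer the other option. Exact comparisons are used — ratings are
#' data, not estimates.
#'
#' @param model A two-option [decision_model()].
#' @return An object of class `dominance_result`: `dominant` (option id,
#'   or `NA` if none) and `comparison`, a per-criterion factor with
#'   levels first_better/second_better/tie.
#' @examples
#' dominance_check(tavi_savr_model())  # no dominant option
#' @export
dominance_check <- function(model) {
  if (length(model$options) != 2L) {
    stop("dominance_check expects exactly 2 options", call. = FALSE)
  }
  d <- model$ratings[1, ] - model$ratings[2, ]
  comparison <- factor(ifelse(d > 0, "first_better",
                              ifelse(d < 0, "second_better", "tie")),
                       levels = c("first_better", "second_better", "tie"))
  names(comparison) <- criterion_ids(model)
  dominant <- NA_character_
  if (all(d >= 0) && any(d > 0)) dominant <- model$options[1]
  if (all(d <= 0) && any(d < 0)) dominant <- model$options[2]
  structure(list(dominant = dominant, comparison = comparison,
                 options = model$options),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  if (is.na(x$dominant)) {
    cat("No dominant option: each option is superior on some criteria",
        "and inferior on others.\n")
  } else {
    cat("Dominant option:", x$dominant, "\n")
  }
  tab <- table(x$comparison)
  cat(sprintf("  %s better on %d criteria, %s better on %d, ties on %d\n",
              x$options[1], tab[["first_better"]],
              x$options[2], tab[["second_better"]], tab[["tie"]]))
  invisible(x)
}
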