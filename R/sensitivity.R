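# Score difference between the two options as a function of the target
# criterion's normalized weight t, with the remaining weights rescaled
# proportionally to sum to 1 - t (standard normalized one-way analysis):
#   D(t) = t * d_j + (1 - t) * B,  B = sum_{k != j} (w_k / (1 - w_j)) d_k
# Linear in t, so the flip point is the closed-form root.

#' One-way weight flip threshold
#'
#' Varies one criterion's normalized weight t over [0, 1], rescaling the
#' remaining weights proportionally, and returns the smallest t at which
#' the preferred option differs from the preference at t = 0. Because the
#' score difference is linear in t the threshold is found in closed form.
#'
#' @param model A two-option [decision_model()].
#' @param weights Baseline `weight_set` (or raw vector).
#' @param criterion_id Criterion whose weight is varied.
#' @param adjusted Use certainty-adjusted ratings?
#' @param mode,mapping Certainty adjustment settings (see [mcda_score()]).
#' @return An object of class `flip_threshold`: `criterion`, `threshold`
#'   (in [0, 1], or `NA` if the preference never flips), `direction` (the
#'   option preferred above the threshold, `NA` if none), and
#'   `preferred_at_zero`.
#' @examples
#' m <- tavi_savr_model()
#' one_way_flip_threshold(m, rep(1, 10), "pacemaker")
#' @export
one_way_flip_threshold <- function(model, weights, criterion_id,
                                   adjusted = FALSE,
                                   mode = c("multiplicative", "shrink"),
                                   mapping = certainty_mapping()) {
  mode <- match.arg(mode)
  if (length(model$options) != 2L) {
    stop("flip-threshold analysis expects exactly 2 options", call. = FALSE)
  }
  ids <- criterion_ids(model)
  j <- match(criterion_id, ids)
  if (is.na(j)) stop("unknown criterion: ", criterion_id, call. = FALSE)
  w <- weights_for_model(weights, model)
  R <- if (adjusted) effective_ratings(model, mode, mapping) else model$ratings
  d <- R[1, ] - R[2, ]
  dj <- d[j]
  s0 <- 1 - w[j]
  B <- if (s0 > 0) sum(w[-j] * d[-j]) / s0 else mean(d[-j])

  pref_of <- function(diff) {
    if (diff > 0) model$options[1] else if (diff < 0) model$options[2]
    else NA_character_
  }
  p0 <- pref_of(B)
  threshold <- NA_real_
  direction <- NA_character_
  if (B == 0 && dj != 0) {
    # tied at t = 0; any positive weight on the criterion breaks the tie
    threshold <- 0
    direction <- pref_of(dj)
  } else if (B * dj < 0) {
    # opposite signs: D crosses zero at an interior t
    threshold <- unname(B / (B - dj))
    direction <- pref_of(dj)
  }
  structure(list(criterion = criterion_id, threshold = threshold,
                 direction = direction, preferred_at_zero = p0,
                 adjusted = adjusted, mode = mode),
            class = "flip_threshold")
}

#' @export
print.flip_threshold <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat(sprintf("criterion %s: no flip (preference is %s for any weight)\n",
                x$criterion,
                if (is.na(x$preferred_at_zero)) "tied" else x$preferred_at_zero))
  } else {
    cat(sprintf("criterion %s: preference flips to %s once its weight exceeds %.4f\n",
                x$criterion, x$direction, x$threshold))
  }
  invisible(x)
}

#' Flip thresholds for every criterion
#'
#' @inheritParams one_way_flip_threshold
#' @return A data.frame with columns `criterion`, `threshold`,
#'   `direction`, `preferred_at_zero`, one row per criterion in model
#'   order.
#' @export
flip_thresholds <- function(model, weights, adjusted = FALSE,
                            mode = c("multiplicative", "shrink"),
                            mapping = certainty_mapping()) {
  mode <- match.arg(mode)
  ids <- criterion_ids(model)
  rows <- lapply(ids, function(id) {
    ft <- one_way_flip_threshold(model, weights, id, adjusted = adjusted,
                                 mode = mode, mapping = mapping)
    data.frame(criterion = id, threshold = ft$threshold,
               direction = ft$direction,
               preferred_at_zero = ft$preferred_at_zero,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample weight vectors from a Dirichlet preference population
#'
#' Models heterogeneity in how people value the criteria as a Dirichlet
#' distribution on the weight simplex. The default symmetric
#' concentration 1 is uniform on the simplex — maximally agnostic; larger
#' concentrations encode tighter consensus around equal weights. Sampling
#' uses the gamma representation (independent Gamma(alpha_k) draws,
#' normalized).
#'
#' @param n Number of vectors (>= 1).
#' @param k Number of criteria.
#' @param concentration Positive scalar (symmetric) or length-k vector of
#'   Dirichlet concentration parameters.
#' @param seed Integer seed; the same (n, k, concentration, seed) always
#'   reproduces the sample bit-identically.
#' @return An object of class `preference_sample`: `weights` (n x k
#'   matrix, rows sum to 1), `n`, `k`, `concentration`, `seed`.
#' @export
sample_weight_vectors <- function(n, k, concentration = 1, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (length(concentration) == 1L) concentration <- rep(concentration, k)
  if (length(concentration) != k) {
    stop("concentration must be scalar or length k", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentration parameters must be positive", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("an integer seed is required", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  G <- vapply(seq_len(k),
              function(jj) stats::rgamma(n, shape = concentration[jj]),
              numeric(n))
  G <- matrix(G, nrow = n, ncol = k)
  W <- G / rowSums(G)
  structure(list(weights = W, n = n, k = k, concentration = concentration,
                 seed = as.integer(seed)),
            class = "preference_sample")
}

#' @export
print.preference_sample <- function(x, ...) {
  cat(sprintf("Preference sample: %d Dirichlet draws over %d criteria (seed %d)\n",
              x$n, x$k, x$seed))
  cat("concentration:", paste(format(x$concentration), collapse = " "), "\n")
  invisible(x)
}

#' Share of simulated preferences favouring each option
#'
#' Scores the model under every sampled weight vector and counts which
#' option comes out on top; exact score ties contribute equally to each
#' tied option, so shares are unbiased under perfect symmetry.
#'
#' @param model A [decision_model()].
#' @param sample A [sample_weight_vectors()] result whose `k` matches the
#'   model's criteria count.
#' @param adjusted Use certainty-adjusted ratings?
#' @param mode,mapping Certainty adjustment settings.
#' @return An object of class `preference_shares`: named `shares` summing
#'   to 1, plus `n`, `adjusted`, `mode`.
#' @export
preference_share <- function(model, sample, adjusted = FALSE,
                             mode = c("multiplicative", "shrink"),
                             mapping = certainty_mapping()) {
  mode <- match.arg(mode)
  if (!inherits(sample, "preference_sample")) {
    stop("sample must come from sample_weight_vectors()", call. = FALSE)
  }
  if (sample$k != length(model$criteria)) {
    stop("sample has ", sample$k, " criteria but the model has ",
         length(model$criteria), call. = FALSE)
  }
  R <- if (adjusted) effective_ratings(model, mode, mapping) else model$ratings
  S <- sample$weights %*% t(R)       # n x options score matrix
  mx <- do.call(pmax, as.data.frame(S))
  counts <- numeric(length(model$options))
  is_top <- S >= mx                  # exact ties share the win
  ntop <- rowSums(is_top)
  for (o in seq_along(counts)) counts[o] <- sum(is_top[, o] / ntop)
  shares <- counts / sample$n
  names(shares) <- model$options
  structure(list(shares = shares, n = sample$n, adjusted = adjusted,
                 mode = mode, seed = sample$seed),
            class = "preference_shares")
}

#' @export
print.preference_shares <- function(x, ...) {
  cat(sprintf("Simulated preference shares (n = %d, %s ratings):\n", x$n,
              if (x$adjusted) "certainty-adjusted" else "unadjusted"))
  print(round(x$shares, 4))
  invisible(x)
}

#' Classify preference shares into strength categories
#'
#' Operationalises GRADE's verbal strong/weak distinction: a strong
#' pattern means most informed patients would choose the same option; a
#' weak pattern means choices vary with values and preferences. The
#' numeric boundaries are conventions (defaults 0.9 and 0.6), surfaced in
#' every output because GRADE itself gives none.
#'
#' @param shares Named per-option shares (a `preference_shares` object or
#'   its `shares` vector) summing to 1.
#' @param strong_threshold Share at or above which the pattern is
#'   `strong_for_<option>`.
#' @param weak_threshold Share at or above which it is
#'   `weak_for_<option>`; requires `0.5 < weak < strong <= 1`.
#' @return An object of class `recommendation_class`: `class` (e.g.
#'   `"strong_for_TAVI"` or `"equipoise"`), `shares`, `thresholds`.
#' @examples
#' classify_recommendation(c(TAVI = 0.7, SAVR = 0.3))  # weak_for_TAVI
#' @export
classify_recommendation <- function(shares, strong_threshold = 0.9,
                                    weak_threshold = 0.6) {
  if (inherits(shares, "preference_shares")) shares <- shares$shares
  if (!(weak_threshold > 0.5 && strong_threshold > weak_threshold &&
        strong_threshold <= 1)) {
    stop("thresholds must satisfy 0.5 < weak_threshold < strong_threshold <= 1",
         call. = FALSE)
  }
  mx <- max(shares)
  top <- names(shares)[shares == mx]
  cls <- if (length(top) > 1L || mx < weak_threshold) {
    "equipoise"
  } else if (mx >= strong_threshold) {
    paste0("strong_for_", top)
  } else {
    paste0("weak_for_", top)
  }
  structure(list(class = cls, shares = shares,
                 thresholds = c(strong = strong_threshold,
                                weak = weak_threshold)),
            class = "recommendation_class")
}

#' @export
print.recommendation_class <- function(x, ...) {
  cat(sprintf("preference pattern: %s (strong >= %.2f, weak >= %.2f)\n",
              x$class, x$thresholds[["strong"]], x$thresholds[["weak"]]))
  print(round(x$shares, 4))
  invisible(x)
}
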