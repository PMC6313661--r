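# Independent reference implementations used to cross-check the package.
# Deliberately naive: explicit loops, no shared code with R/.

# Explicit double-loop weighted sum; certainty multiplier inserted when a
# mapping is supplied.
naive_scores <- function(model, w_norm, mode = NULL,
                         mapping = c(very_low = 0.1, low = 0.4,
                                     moderate = 0.7, high = 1.0)) {
  out <- numeric(length(model$options))
  names(out) <- model$options
  for (i in seq_along(model$options)) {
    s <- 0
    for (j in seq_along(model$criteria)) {
      r <- model$ratings[i, j]
      if (!is.null(mode)) {
        ck <- mapping[[model$criteria[[j]]$certainty]]
        r <- if (mode == "multiplicative") ck * r else ck * r + (1 - ck) * 0.5
      }
      s <- s + w_norm[j] * r
    }
    out[i] <- s
  }
  out
}

# Grid scan for the one-way flip threshold: walk t over a fixed grid,
# rescale the other weights proportionally, and report the first t whose
# preferred option differs from t = 0.
grid_flip <- function(model, w_norm, j, step = 0.001) {
  d <- model$ratings[1, ] - model$ratings[2, ]
  s0 <- 1 - w_norm[j]
  others <- if (s0 > 0) w_norm[-j] / s0 else
    rep(1 / (length(w_norm) - 1), length(w_norm) - 1)
  pref <- function(t) sign(t * d[j] + (1 - t) * sum(others * d[-j]))
  p0 <- pref(0)
  for (t in seq(0, 1, by = step)) {
    if (pref(t) != p0) return(t)
  }
  NA_real_
}

# A random valid model for property tests (uses the ambient RNG state).
random_model <- function(n_options = 2, n_criteria = 5) {
  crits <- lapply(seq_len(n_criteria), function(j) {
    criterion(id = paste0("c", j),
              certainty = sample(certainty_levels(), 1),
              polarity = sample(c("benefit", "harm"), 1),
              locked = FALSE, source = "user")
  })
  decision_model(options = paste0("opt", seq_len(n_options)),
                 criteria = crits,
                 ratings = matrix(runif(n_options * n_criteria),
                                  nrow = n_options))
}

random_weights <- function(model) {
  normalize_weights(runif(length(model$criteria)),
                    criteria = vapply(model$criteria, `[[`, character(1), "id"))
}

equal_weights <- function(model) {
  normalize_weights(rep(1, length(model$criteria)),
                    criteria = vapply(model$criteria, `[[`, character(1), "id"))
}
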