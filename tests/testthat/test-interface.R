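test_that("model documents round-trip bit-identically", {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  m <- tavi_savr_model("75_under_85")
  write_model(m, f)
  m2 <- read_model(f)
  expect_identical(m2$ratings, m$ratings)
  expect_identical(m2$options, m$options)
  expect_identical(lapply(m2$criteria, unclass), lapply(m$criteria, unclass))
  expect_identical(model_hash(m2), model_hash(m))

  # random models, awkward floating-point ratings included
  set.seed(61)
  for (rep in 1:40) {
    mr <- random_model(sample(2:5, 1), sample(2:12, 1))
    write_model(mr, f)
    back <- read_model(f)
    expect_identical(back$ratings, mr$ratings)
  }
})

test_that("malformed or off-schema documents are rejected with locations", {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  m <- tavi_savr_model()
  write_model(m, f)

  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  tweak <- function(d) {
    writeLines(jsonlite::toJSON(d, auto_unbox = TRUE, digits = I(17),
                                null = "null"), f)
    f
  }

  d <- doc; d$schema_version <- "9.9"
  expect_error(read_model(tweak(d)), "schema version")

  d <- doc; d$surprise <- 1
  expect_error(read_model(tweak(d)), "unknown field")

  d <- doc; d$ratings[[1]][[3]] <- NULL
  expect_error(read_model(tweak(d)), "cells")

  d <- doc; d$ratings[[2]][[1]] <- 1.5
  expect_error(read_model(tweak(d)), "out of \\[0,1\\]")

  d <- doc; d$criteria[[1]]$id <- d$criteria[[2]]$id
  expect_error(read_model(tweak(d)), "duplicate criterion")

  expect_error(read_model(tempfile()), "no such file")
  writeLines("{not json", f)
  expect_error(read_model(f), "malformed")

  # every emitted document carries the disclaimer
  write_model(m, f)
  expect_true(any(grepl("not a validated clinical decision aid",
                        readLines(f))))
})

test_that("weight elicitation delegates to normalization and keeps a transcript", {
  m <- tavi_savr_model()
  w <- elicit_weights(m, rep(100, 10))
  expect_equal(unname(w$normalized), rep(0.1, 10))

  resp <- c(100, rep(0, 9))
  w1 <- elicit_weights(m, resp)
  expect_equal(unname(w1$normalized), c(1, rep(0, 9)))

  resp2 <- c(50, 100, rep(50, 8))
  expect_equal(elicit_weights(m, resp2)$normalized,
               normalize_weights(resp2, criteria = colnames(m$ratings))$normalized)
  expect_identical(attr(elicit_weights(m, resp2), "transcript")$response, resp2)

  expect_error(elicit_weights(m, rep(50, 9)), "one response per criterion")
  expect_error(elicit_weights(m, c(-5, rep(50, 9))), "0-100")
  expect_error(elicit_weights(m, c(NA, rep(50, 9))), "missing")
})

test_that("the one-screen report integrates ratings, weights and score pairs", {
  m <- tavi_savr_model()
  w <- elicit_weights(m, rep(100, 10))
  s <- mcda_score(m, w)
  ft <- flip_thresholds(m, w)
  smp <- sample_weight_vectors(1000, 10, 1, seed = 4)
  sh <- preference_share(m, smp, adjusted = TRUE)
  cls <- classify_recommendation(sh)
  rep1 <- render_decisiographic(m, w, s, flips = ft, shares = sh,
                                classification = cls)

  txt <- unclass(rep1)
  expect_match(txt, "TAVI vs SAVR")
  expect_equal(sum(grepl("^  \\[L\\]", strsplit(txt, "\n")[[1]])), 7)
  expect_match(txt, "not a validated clinical decision aid")
  expect_match(txt, "certainty-adjusted")
  expect_match(txt, "share preferring")
  expect_match(txt, "flips to")
  # the tool renders opinions, never directives
  expect_false(grepl("recommendation", txt, ignore.case = TRUE))

  # byte-identical on regeneration
  rep2 <- render_decisiographic(m, w, s, flips = ft, shares = sh,
                                classification = cls)
  expect_identical(rep1, rep2)

  # all-high certainty shows identical score pairs
  mh <- tavi_savr_model(overrides = list(
    certainty = setNames(rep("high", 7),
                         c("mortality", "stroke", "bleeding",
                           "atrial_fibrillation", "heart_failure",
                           "pacemaker", "reintervention"))))
  sh2 <- mcda_score(mh, elicit_weights(mh, rep(100, 10)))
  expect_equal(sh2$adjusted, sh2$unadjusted, tolerance = 1e-12)

  # editing the model after scoring invalidates the report
  m_edit <- set_user_rating(m, "recovery_burden", "TAVI", 0.9)
  expect_error(render_decisiographic(m_edit, w, s), "stale")
  w_other <- elicit_weights(m, c(90, rep(50, 9)))
  expect_error(render_decisiographic(m, w_other, s), "stale")
})

test_that("the CLI drives the full pipeline with clean exit statuses", {
  td <- tempfile(); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  mfile <- file.path(td, "model.json")
  wfile <- file.path(td, "weights.csv")

  expect_equal(suppressMessages(
    mcda_cli(c("fixture", "--age", "65-75", "--out", mfile))), 0L)
  m <- read_model(mfile)
  expect_identical(m$metadata$age_group, "65_under_75")

  writeLines(c("criterion,weight",
               paste0(colnames(m$ratings), ",", 10)), wfile)
  rfile <- file.path(td, "report.txt")
  expect_equal(suppressMessages(
    mcda_cli(c("score", "--model", mfile, "--weights", wfile,
               "--out", rfile))), 0L)
  expect_match(paste(readLines(rfile), collapse = "\n"), "Expected-value scores")

  sfile <- file.path(td, "flips.csv")
  expect_equal(suppressMessages(
    mcda_cli(c("sensitivity", "--model", mfile, "--weights", wfile,
               "--out", sfile))), 0L)
  ft <- read.csv(sfile)
  expect_identical(names(ft), c("criterion", "threshold", "direction"))
  expect_equal(nrow(ft), 10)

  # simulate twice with the same seed: byte-identical tables
  f1 <- file.path(td, "sim1.csv"); f2 <- file.path(td, "sim2.csv")
  for (f in c(f1, f2)) {
    console <- suppressMessages(capture.output(
      status <- mcda_cli(c("simulate", "--model", mfile, "--n", "2000",
                           "--seed", "7", "--out", f))))
    expect_equal(status, 0L)
    expect_match(console, "preference pattern", all = FALSE)
  }
  expect_identical(readLines(f1), readLines(f2))
  sim <- read.csv(f1)
  expect_identical(names(sim), c("option", "share"))
  expect_equal(sum(sim$share), 1, tolerance = 1e-6)

  vout <- suppressMessages(capture.output(
    vstatus <- mcda_cli(c("validate", "--model", mfile))))
  expect_equal(vstatus, 0L)
  expect_match(vout, "OK: model is valid", all = FALSE)
  expect_equal(suppressMessages(mcda_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(
    mcda_cli(c("score", "--model", file.path(td, "nope.json"),
               "--weights", wfile))), 1L)
  expect_equal(suppressMessages(mcda_cli(c("fixture", "--age", "banana"))), 1L)
})
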