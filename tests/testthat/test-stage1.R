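test_that("degenerate and hand-computed item summaries are exact", {
  # unanimous maximum on a 1-5 scale
  m <- make_rm(matrix(5, 3, 1), scale_max = 5)
  s <- weighted_item_summary(m, "Q1")
  expect_equal(s$weighted_mean, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$weighted_index, 100)
  expect_equal(s$preferred_response, 5)
  expect_equal(s$q25, 5)
  expect_equal(s$q75, 5)

  # weights (1, 3), responses (1, 5): mass 0.25 on 1, 0.75 on 5
  m2 <- make_rm(matrix(c(1, 5), 2, 1), scale_max = 5, weights = c(1, 3))
  s2 <- weighted_item_summary(m2, "Q1")
  expect_equal(s2$weighted_mean, 4)
  expect_equal(s2$weighted_index, 80)
  expect_equal(s2$preferred_response, 5)
  expect_equal(s2$weighted_pct_preferred, 75)

  # modal majority at the top of a 1-6 scale collapses the upper quartile
  m3 <- make_rm(matrix(c(6, 6, 5), 3, 1), scale_max = 6)
  s3 <- weighted_item_summary(m3, "Q1")
  expect_equal(s3$preferred_response, 6)
  expect_equal(s3$q75, 6)
})

test_that("missing responses are excluded and conserved; empty items error", {
  vals <- matrix(c(2, NA, 4, NA, NA, NA), 3, 2)
  items <- data.frame(item_id = c("Qa", "Qb"), scale_min = 1, scale_max = 5)
  m <- response_matrix(vals, items, weights = c(1, 2, 3))
  s <- weighted_item_summary(m, "Qa")
  expect_equal(s$n_responses + s$n_missing, 3)
  expect_equal(s$n_missing, 1)
  expect_equal(s$weighted_mean, (1 * 2 + 3 * 4) / 4) # middle row excluded
  expect_error(weighted_item_summary(m, "Qb"), "all responses missing")
  expect_error(weighted_item_summary(m, "Qz"), "unknown item_id")
})

test_that("construction rejects out-of-bounds cells and bad weights", {
  items <- data.frame(item_id = "Q1", scale_min = 1, scale_max = 5)
  expect_error(response_matrix(matrix(6, 1, 1), items), "out of scale bounds")
  expect_error(response_matrix(matrix(2.5, 1, 1), items),
               "out of scale bounds")
  expect_error(response_matrix(matrix(3, 2, 1), items, weights = c(1, -1)),
               "positive")
  expect_error(response_matrix(matrix(3, 1, 2), items),
               "2 columns but 1 items")
})

test_that("summaries are invariant to respondent/item permutation and weight scale", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    k <- sample(2:5, 1)
    vals <- matrix(sample(c(1:5, NA), n * k, replace = TRUE,
                          prob = c(rep(0.18, 5), 0.1)), n, k)
    if (all(is.na(vals[, 1]))) vals[1, 1] <- 3
    for (j in seq_len(k)) if (all(is.na(vals[, j]))) vals[1, j] <- 2
    w <- runif(n, 0.5, 4)
    m <- make_rm(vals, scale_max = 5, weights = w)
    s <- summarize_items(m)

    # permute respondents and items
    pr <- sample(n)
    pc <- sample(k)
    m2 <- response_matrix(m$values[pr, pc, drop = FALSE],
                          m$items[pc, , drop = FALSE],
                          respondent_id = m$respondent_id[pr],
                          weights = w[pr])
    s2 <- summarize_items(m2)
    s2 <- s2[match(s$item_id, s2$item_id), ]
    rownames(s2) <- NULL
    expect_equal(s2, s, tolerance = 1e-12)

    # rescale all weights by a positive constant
    cst <- runif(1, 0.01, 50)
    m3 <- response_matrix(m$values, m$items, respondent_id = m$respondent_id,
                          weights = w * cst)
    s3 <- summarize_items(m3)
    for (col in c("weighted_mean", "weighted_index", "preferred_response",
                  "q25", "q75", "sd", "weighted_pct_preferred")) {
      expect_equal(s3[[col]], s[[col]], tolerance = 1e-10)
    }
  }
})

test_that("integer-weight summaries equal the replicated-respondent oracle", {
  set.seed(31)
  shapes <- expand.grid(n = 1:6, k = 1:4)
  for (i in seq_len(nrow(shapes))) {
    n <- shapes$n[i]
    k <- shapes$k[i]
    for (rep in 1:3) {
      vals <- matrix(sample(c(1:5, NA), n * k, replace = TRUE,
                            prob = c(rep(0.17, 5), 0.15)), n, k)
      for (j in seq_len(k)) if (all(is.na(vals[, j]))) vals[sample(n, 1), j] <- 4
      w <- sample(1:3, n, replace = TRUE)
      m <- make_rm(vals, scale_max = 5, weights = w)
      s <- summarize_items(m)
      for (j in seq_len(k)) {
        oracle <- expanded_summary(vals[, j], w, scale_max = 5)
        row <- s[s$item_id == m$items$item_id[j], ]
        for (f in names(oracle)) {
          expect_equal(row[[f]], oracle[[f]], tolerance = 1e-12,
                       info = paste("field", f, "shape", n, "x", k))
        }
      }
    }
  }
})

test_that("items rank descending with stable, flagged tie handling", {
  s <- data.frame(
    item_id = c("Q1.2", "Q1.1", "Q1.3"),
    weighted_index = c(15.40, 15.77, 15.77),
    weighted_mean = c(3.1, 3.9, 3.9),
    stringsAsFactors = FALSE
  )
  r <- rank_items(s)
  expect_equal(r$item_id, c("Q1.1", "Q1.3", "Q1.2"))
  expect_equal(r$rank, 1:3)
  expect_equal(r$rank_tie, c(TRUE, TRUE, FALSE))

  single <- rank_items(s[1, , drop = FALSE])
  expect_equal(single$item_id, "Q1.2")
  expect_false(single$rank_tie)

  r2 <- rank_items(s, key = "weighted_mean")
  expect_equal(r2$item_id[3], "Q1.2")
})

test_that("criterion extraction averages source-item indices and validates", {
  s <- data.frame(
    item_id = c("Q1.1", "Q1.4", "Q1.12"),
    weighted_index = c(60, 70, 80),
    stringsAsFactors = FALSE
  )
  cr <- extract_criteria(s, list(A1 = c("Q1.1", "Q1.4", "Q1.12")))
  expect_equal(cr$salience, 70)
  one <- extract_criteria(s, list(A2 = "Q1.4"))
  expect_equal(one$salience, 70)
  expect_equal(one$n_items, 1)
  expect_error(extract_criteria(s, list(A1 = character(0))),
               "no source items")
  expect_error(extract_criteria(s, list(A1 = c("Q1.1", "Q9.9"))),
               "unknown item.*Q9.9")
})

test_that("response matrices round-trip through CSV", {
  sim <- simulate_survey(default_survey_spec(n_respondents = 25), seed = 5)
  tmp <- tempfile(fileext = ".csv")
  write_response_matrix(sim$responses, tmp)
  m2 <- read_response_matrix(tmp, sim$responses$items,
                             weights = sim$responses$weights)
  expect_equal(m2$values, sim$responses$values)
  expect_identical(m2$respondent_id, sim$responses$respondent_id)
  expect_equal(summarize_items(m2), summarize_items(sim$responses))
  unlink(tmp)
})
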