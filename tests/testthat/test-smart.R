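test_that("SMART score normalization matches its definition and bounds", {
  expect_equal(smart_normalize_weights(c(10, 10, 10, 10)), rep(0.25, 4))
  expect_equal(smart_normalize_weights(c(70, 60, 40, 30)),
               c(0.35, 0.30, 0.20, 0.15))
  expect_equal(smart_normalize_weights(55), 1)
  expect_error(smart_normalize_weights(c(5, 50)), "\\[10, 100\\]")
  expect_error(smart_normalize_weights(c(50, 101)), "\\[10, 100\\]")
  expect_error(smart_normalize_weights(numeric(0)), "at least one")

  set.seed(41)
  for (i in 1:200) {
    raw <- runif(sample(1:8, 1), 10, 100)
    w <- smart_normalize_weights(raw)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w > 0))
  }
})

test_that("alternative ranking totals are rank times strategy weight", {
  alts <- data.frame(
    id = c("S1", "S2", "S3"),
    strategy_weight = 0.35,
    importance_rank = 1:3,
    stringsAsFactors = FALSE
  )
  out <- rank_alternatives(alts)
  expect_equal(out$total_ranking, c(0.35, 0.70, 1.05))
  expect_equal(rank_alternatives(
    data.frame(id = "X", strategy_weight = 0.5, importance_rank = 2)
  )$total_ranking, 1)
  alts$importance_rank[1] <- 0
  expect_error(rank_alternatives(alts), "positive")
})

test_that("attribute values and dimension scores follow rank x weight", {
  expect_equal(attribute_value(3, 0.3), 0.9)
  expect_equal(attribute_value(1, 0.2), 0.2)
  expect_equal(attribute_value(2, 0.35), 0.7)
  expect_equal(dimension_score(c(0.6, 0.6, 0.3, 0.9)), 2.4)
  expect_equal(dimension_score(0.35), 0.35)
  # S3's service-planning ranks at w = 0.3 (printed per-cell typo corrected
  # by the formula, which reproduces the printed column total)
  expect_equal(dimension_score(attribute_value(c(1, 3, 2, 1), 0.3)), 2.1)
  expect_error(dimension_score(numeric(0)), "at least one")
})

test_that("the packaged resilience model reproduces the published analysis", {
  m <- resilience_decision_model()
  expect_equal(sum(m$dimensions$weight), 1, tolerance = 1e-9)
  expect_equal(m$dimensions$weight, c(0.35, 0.30, 0.20, 0.15))
  expect_equal(unname(rowSums(m$ranks)), c(14, 14, 14))

  res <- smart_evaluate(m)
  expect_equal(unname(res$performance$totals[c("S1", "S2", "S3")]),
               c(3.70, 3.80, 3.90), tolerance = 0.005)
  expect_equal(unname(res$utilities[c("S1", "S2", "S3")]),
               c(1.04, 1.09, 1.14), tolerance = 0.005)
  expect_equal(res$optimal, "S3")
  expect_false(res$tie_flag)
  expect_equal(res$ranking, c("S3", "S2", "S1"))
  # dimension scores of the published performance matrix
  expect_equal(unname(res$performance$scores["S1", ]),
               c(0.35, 2.70, 0.20, 0.45), tolerance = 1e-9)
  expect_equal(unname(res$performance$scores["S3", ]),
               c(1.05, 2.10, 0.60, 0.15), tolerance = 1e-9)
})

test_that("model validation rejects broken rank budgets and dangling ids", {
  m <- resilience_decision_model()
  bad_ranks <- m$ranks
  bad_ranks["S2", "A1"] <- 5 # S2 total becomes 17
  expect_error(
    decision_model(m$dimensions, m$attributes, m$alternatives, bad_ranks,
                   rank_total = 14),
    "S2 \\(17\\)"
  )
  expect_error(
    decision_model(m$dimensions, m$attributes, m$alternatives,
                   m$ranks[, 1:5], rank_total = 14),
    "incomplete rank assignment"
  )
  dims2 <- m$dimensions
  dims2$weight <- dims2$weight * 2
  expect_error(
    decision_model(dims2, m$attributes, m$alternatives, m$ranks),
    "sum to 1"
  )
  attrs2 <- m$attributes
  attrs2$dimension_id[1] <- "K9"
  expect_error(
    decision_model(m$dimensions, attrs2, m$alternatives, m$ranks),
    "K9"
  )
})

test_that("additive utility matches hand examples and basis weights", {
  scores <- rbind(S3 = c(1.05, 2.10, 0.60, 0.15))
  expect_equal(unname(additive_utility(scores,
                                       c(0.35, 0.30, 0.20, 0.15))),
               1.14, tolerance = 5e-3)
  scores1 <- rbind(S1 = c(0.35, 2.70, 0.20, 0.45))
  expect_equal(unname(additive_utility(scores1,
                                       c(0.35, 0.30, 0.20, 0.15))),
               1.04, tolerance = 5e-3)
  abcd <- rbind(X = c(7, 11, 13, 17))
  expect_equal(unname(additive_utility(abcd, c(1, 0, 0, 0))), 7)
  expect_error(additive_utility(abcd, c(0.5, 0.5)), "2 weights for 4")
})

test_that("optimal selection is argmax with flagged lowest-id tie-break", {
  expect_equal(select_optimal(c(S1 = 1.04, S2 = 1.09, S3 = 1.14))$optimal,
               "S3")
  one <- select_optimal(c(S9 = 0.2))
  expect_equal(one$optimal, "S9")
  expect_false(one$tie_flag)
  tie <- select_optimal(c(S2 = 1.0, S1 = 1.0))
  expect_equal(tie$optimal, "S1")
  expect_true(tie$tie_flag)
  expect_error(select_optimal(numeric(0)), "no utilities")
})

test_that("evaluation agrees with brute-force enumeration of rank assignments", {
  # exhaustive over shapes with <= 8 rank cells, ranks in {1, 2, 3}
  shapes <- list(
    list(n_alt = 2, attrs = c(A1 = "K1", A2 = "K2")),
    list(n_alt = 2, attrs = c(A1 = "K1", A2 = "K1", A3 = "K2")),
    list(n_alt = 2, attrs = c(A1 = "K1", A2 = "K2", A3 = "K2", A4 = "K3")),
    list(n_alt = 3, attrs = c(A1 = "K1", A2 = "K2"))
  )
  for (sh in shapes) {
    dims <- unique(unname(sh$attrs))
    w <- smart_normalize_weights(seq(100, by = -20,
                                     length.out = length(dims)))
    names(w) <- dims
    n_cell <- sh$n_alt * length(sh$attrs)
    grid <- as.matrix(expand.grid(rep(list(1:3), n_cell)))
    for (g in seq_len(nrow(grid))) {
      ranks <- matrix(grid[g, ], nrow = sh$n_alt,
                      dimnames = list(paste0("S", seq_len(sh$n_alt)),
                                      names(sh$attrs)))
      oracle <- brute_force_smart(w, as.list(sh$attrs), ranks)
      res <- smart_evaluate(make_model(w, as.list(sh$attrs), ranks))
      expect_equal(res$utilities, oracle$utilities, tolerance = 1e-12)
      expect_equal(res$optimal, oracle$optimal)
    }
  }
  # fixed-seed sample of the larger 3-alternative x 4-attribute space
  set.seed(61)
  attrs <- c(A1 = "K1", A2 = "K2", A3 = "K3", A4 = "K4")
  w <- c(K1 = 0.35, K2 = 0.30, K3 = 0.20, K4 = 0.15)
  for (g in 1:2000) {
    ranks <- matrix(sample(1:3, 12, replace = TRUE), nrow = 3,
                    dimnames = list(c("S1", "S2", "S3"), names(attrs)))
    oracle <- brute_force_smart(w, as.list(attrs), ranks)
    res <- smart_evaluate(make_model(w, as.list(attrs), ranks))
    expect_equal(res$utilities, oracle$utilities, tolerance = 1e-12)
    expect_equal(res$optimal, oracle$optimal)
  }
})

test_that("utility is monotone in ranks and respects dominance", {
  set.seed(51)
  for (i in 1:1000) {
    rm_ <- random_model()
    res <- smart_evaluate(rm_$model)
    # bump one random rank cell: that alternative's utility must rise
    a <- sample(rownames(rm_$ranks), 1)
    attr <- sample(colnames(rm_$ranks), 1)
    ranks2 <- rm_$ranks
    ranks2[a, attr] <- ranks2[a, attr] + 1
    res2 <- smart_evaluate(make_model(rm_$weights, rm_$dim_of_attr, ranks2))
    expect_gt(res2$utilities[[a]], res$utilities[[a]])
    pos1 <- match(a, res$ranking)
    pos2 <- match(a, res2$ranking)
    expect_lte(pos2, pos1)
  }

  set.seed(52)
  for (i in 1:200) {
    rm_ <- random_model()
    ranks <- rm_$ranks
    # make S1 dominate: >= everywhere, > on one attribute
    ranks["S1", ] <- apply(ranks, 2, max)
    ranks["S1", 1] <- ranks["S1", 1] + 1
    res <- smart_evaluate(make_model(rm_$weights, rm_$dim_of_attr, ranks))
    expect_equal(res$optimal, "S1")
    expect_true(all(res$utilities[["S1"]] >
                      res$utilities[setdiff(names(res$utilities), "S1")]))
  }
})

test_that("adding a constant to all dimension scores shifts utilities by it", {
  set.seed(71)
  for (i in 1:50) {
    rm_ <- random_model()
    perf <- performance_matrix(rm_$model)
    u <- additive_utility(perf)
    cst <- runif(1, -2, 2)
    u2 <- additive_utility(perf$scores + cst, perf$weights)
    expect_equal(u2, u + cst, tolerance = 1e-10)
    expect_equal(names(sort(-u2)), names(sort(-u)))
  }
})

test_that("decision models round-trip through YAML and JSON", {
  m <- resilience_decision_model()
  tmp <- tempfile(fileext = ".json")
  cfg <- list(
    rank_total = 14,
    dimensions = m$dimensions,
    attributes = m$attributes,
    alternatives = m$alternatives,
    ranks = stats::setNames(
      lapply(rownames(m$ranks), function(a) as.list(m$ranks[a, ])),
      rownames(m$ranks)
    )
  )
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  m2 <- read_decision_model(tmp)
  expect_equal(m2$ranks, m$ranks)
  expect_equal(m2$dimensions$weight, m$dimensions$weight)
  expect_equal(smart_evaluate(m2)$utilities, smart_evaluate(m)$utilities)
  unlink(tmp)
})
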