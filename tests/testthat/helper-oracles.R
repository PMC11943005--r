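# Independent oracles and small model builders shared across tests.
# Everything here is deliberately brute-force and loop-based so it shares no
# code path with the package implementation.

# Brute-force SMART evaluation: explicit loops over alternatives,
# dimensions and attributes.
brute_force_smart <- function(weights, dim_of_attr, ranks) {
  alts <- rownames(ranks)
  dims <- names(weights)
  scores <- matrix(0, length(alts), length(dims),
                   dimnames = list(alts, dims))
  for (a in alts) {
    for (k in dims) {
      s <- 0
      for (attr in names(dim_of_attr)) {
        if (dim_of_attr[[attr]] == k) {
          s <- s + ranks[a, attr] * weights[[k]]
        }
      }
      scores[a, k] <- s
    }
  }
  totals <- apply(scores, 1, sum)
  u <- numeric(length(alts))
  names(u) <- alts
  for (a in alts) {
    acc <- 0
    for (k in dims) acc <- acc + weights[[k]] * scores[a, k]
    u[a] <- acc
  }
  # same tie convention as the package contract: utilities within 1e-9 are
  # an exact tie, broken toward the lowest id
  best <- names(u)[u >= max(u) - 1e-9]
  list(scores = scores, totals = totals, utilities = u,
       optimal = sort(best)[1])
}

# Build a decision_model from bare parts (uniform helper for random models).
make_model <- function(weights, dim_of_attr, ranks, rank_total = NULL) {
  dims <- data.frame(id = names(weights), weight = unname(weights),
                     stringsAsFactors = FALSE)
  attrs <- data.frame(id = names(dim_of_attr),
                      dimension_id = unname(unlist(dim_of_attr)),
                      stringsAsFactors = FALSE)
  alts <- data.frame(id = rownames(ranks), stringsAsFactors = FALSE)
  decision_model(dims, attrs, alts, ranks, rank_total = rank_total)
}

# Random valid model: 2-4 dimensions, 1-2 attributes each, 2-3 alternatives,
# ranks in 1..4.
random_model <- function() {
  n_dim <- sample(2:4, 1)
  w <- runif(n_dim, 0.05, 1)
  w <- w / sum(w)
  names(w) <- paste0("K", seq_len(n_dim))
  n_attr_per <- sample(1:2, n_dim, replace = TRUE)
  dim_of_attr <- list()
  for (k in seq_len(n_dim)) {
    for (j in seq_len(n_attr_per[k])) {
      dim_of_attr[[paste0("A", k, ".", j)]] <- paste0("K", k)
    }
  }
  n_alt <- sample(2:3, 1)
  ranks <- matrix(sample(1:4, n_alt * length(dim_of_attr), replace = TRUE),
                  n_alt, length(dim_of_attr),
                  dimnames = list(paste0("S", seq_len(n_alt)),
                                  names(dim_of_attr)))
  list(weights = w, dim_of_attr = dim_of_attr, ranks = ranks,
       model = make_model(w, dim_of_attr, ranks))
}

# Unweighted summary of an expanded response vector: the oracle for
# integer-weight aggregation (respondent i replicated w_i times).
expanded_summary <- function(x, w, scale_max) {
  keep <- !is.na(x)
  xe <- rep(x[keep], times = w[keep])
  tab <- table(xe)
  top <- names(tab)[tab == max(tab)]
  preferred <- min(as.numeric(top))
  # type-1 quantile on the expanded sample
  q1 <- function(p) {
    xs <- sort(xe)
    cdf <- seq_along(xs) / length(xs)
    xs[which(cdf >= p - 1e-12)[1]]
  }
  list(
    weighted_mean = mean(xe),
    sd = sqrt(mean((xe - mean(xe))^2)),
    weighted_index = mean(xe) / scale_max * 100,
    preferred_response = preferred,
    weighted_pct_preferred = max(tab) / length(xe) * 100,
    q25 = q1(0.25),
    q75 = q1(0.75)
  )
}

# Small response matrix builder.
make_rm <- function(values, scale_max = 5, weights = NULL, scale_min = 1) {
  values <- as.matrix(values)
  items <- data.frame(
    item_id = if (is.null(colnames(values)))
      paste0("Q", seq_len(ncol(values))) else colnames(values),
    scale_min = scale_min, scale_max = scale_max,
    stringsAsFactors = FALSE
  )
  colnames(values) <- items$item_id
  response_matrix(values, items, weights = weights)
}
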