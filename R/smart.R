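# SMART (Simple Multi-Attribute Rating Technique) decision core:
# weight normalization, rank-based performance matrix, linear additive
# utility U_j = sum_k w_k * u_jk, and optimal-alternative selection.

#' Normalize SMART importance scores into criterion weights
#'
#' SMART elicits a raw importance score between 10 (least important) and 100
#' (most important) per criterion and normalizes by the total: w_k = raw_k /
#' sum(raw). Scores outside \[10, 100\] are a domain error — the bounded
#' scale is part of the method's definition, not a soft convention.
#'
#' @param raw_scores Numeric vector of per-dimension scores in \[10, 100\]
#'   (names preserved).
#' @return Weights summing to 1 (within 1e-9).
#' @examples
#' smart_normalize_weights(c(70, 60, 40, 30)) # 0.35 0.30 0.20 0.15
#' @export
smart_normalize_weights <- function(raw_scores) {
  if (length(raw_scores) == 0) {
    stop("at least one dimension score is required", call. = FALSE)
  }
  if (any(!is.finite(raw_scores)) ||
      any(raw_scores < 10) || any(raw_scores > 100)) {
    stop("SMART scores must lie in [10, 100]", call. = FALSE)
  }
  raw_scores / sum(raw_scores)
}

#' Construct and validate a SMART decision model
#'
#' Bundles the dimensions (criteria K1..Kk with normalized weights), their
#' attributes, the alternatives (strategies S1..Sj) and the per-alternative
#' attribute importance ranks into one validated object.
#'
#' Validation is all-or-nothing: weights must sum to 1 (within 1e-9) unless
#' raw SMART scores are supplied (then they are normalized here), every
#' attribute must belong to exactly one dimension, the rank assignment must
#' be complete over alternatives x attributes with integer ranks >= 1, and —
#' when `rank_total` is given — each alternative's ranks must sum to that
#' constant (a budget that forces prioritization rather than rating
#' everything highest).
#'
#' @param dimensions Data frame with `id`, `weight` (or `raw_score` to be
#'   normalized) and optionally `label` / `alt_label`.
#' @param attributes Data frame with `id`, `dimension_id`, optional `label`.
#' @param alternatives Data frame with `id`, optional `label`,
#'   `strategy_weight` (> 0) and `importance_rank` (>= 1).
#' @param ranks Numeric matrix of importance ranks, alternatives in rows and
#'   attributes in columns (dimnames required).
#' @param rank_total Optional integer: required rank sum per alternative.
#' @return An object of class `decision_model`.
#' @export
decision_model <- function(dimensions, attributes, alternatives, ranks,
                           rank_total = NULL) {
  stopifnot(is.data.frame(dimensions), is.data.frame(attributes),
            is.data.frame(alternatives))
  dimensions$id <- as.character(dimensions$id)
  attributes$id <- as.character(attributes$id)
  attributes$dimension_id <- as.character(attributes$dimension_id)
  alternatives$id <- as.character(alternatives$id)
  if (anyDuplicated(dimensions$id) || anyDuplicated(attributes$id) ||
      anyDuplicated(alternatives$id)) {
    stop("duplicate dimension, attribute or alternative id", call. = FALSE)
  }
  if (!"weight" %in% names(dimensions)) {
    if (!"raw_score" %in% names(dimensions)) {
      stop("dimensions need a 'weight' or 'raw_score' column", call. = FALSE)
    }
    dimensions$weight <- smart_normalize_weights(dimensions$raw_score)
  }
  if (any(dimensions$weight <= 0) || any(dimensions$weight > 1)) {
    stop("dimension weights must lie in (0, 1]", call. = FALSE)
  }
  if (abs(sum(dimensions$weight) - 1) > 1e-9) {
    stop("dimension weights must sum to 1 (got ",
         format(sum(dimensions$weight)), ")", call. = FALSE)
  }
  orphan <- setdiff(attributes$dimension_id, dimensions$id)
  if (length(orphan) > 0) {
    stop("attribute(s) reference unknown dimension(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(dimensions$id, attributes$dimension_id)
  if (length(empty) > 0) {
    stop("dimension(s) without attributes: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  ranks <- as.matrix(ranks)
  if (is.null(rownames(ranks)) || is.null(colnames(ranks))) {
    stop("rank matrix needs alternative row names and attribute column names",
         call. = FALSE)
  }
  missing_cells <- c(
    if (length(setdiff(alternatives$id, rownames(ranks))) > 0)
      paste("rows:", paste(setdiff(alternatives$id, rownames(ranks)),
                           collapse = ", ")),
    if (length(setdiff(attributes$id, colnames(ranks))) > 0)
      paste("columns:", paste(setdiff(attributes$id, colnames(ranks)),
                              collapse = ", "))
  )
  if (length(missing_cells) > 0) {
    stop("incomplete rank assignment (", paste(missing_cells, collapse = "; "),
         ")", call. = FALSE)
  }
  ranks <- ranks[alternatives$id, attributes$id, drop = FALSE]
  if (anyNA(ranks) || any(ranks < 1) || any(ranks != round(ranks))) {
    stop("importance ranks must be integers >= 1 for every cell",
         call. = FALSE)
  }
  if ("strategy_weight" %in% names(alternatives)) {
    if (any(alternatives$strategy_weight <= 0)) {
      stop("strategy_weight must be positive", call. = FALSE)
    }
  }
  if ("importance_rank" %in% names(alternatives)) {
    if (any(alternatives$importance_rank < 1)) {
      stop("alternative importance_rank must be >= 1", call. = FALSE)
    }
  }
  if (!is.null(rank_total)) {
    totals <- rowSums(ranks)
    bad <- names(totals)[abs(totals - rank_total) > 1e-9]
    if (length(bad) > 0) {
      stop("rank totals must equal ", rank_total,
           " for every alternative; offending: ",
           paste(paste0(bad, " (", totals[bad], ")"), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(dimensions = dimensions, attributes = attributes,
         alternatives = alternatives, ranks = ranks,
         rank_total = rank_total),
    class = "decision_model"
  )
}

#' @export
print.decision_model <- function(x, ...) {
  cat("<decision_model> ", nrow(x$alternatives), " alternatives x ",
      nrow(x$dimensions), " dimensions (",
      nrow(x$attributes), " attributes)\n", sep = "")
  cat("  weights:",
      paste(sprintf("%s=%.2f", x$dimensions$id, x$dimensions$weight),
            collapse = " "), "\n")
  if (!is.null(x$rank_total)) {
    cat("  rank budget per alternative:", x$rank_total, "\n")
  }
  invisible(x)
}

#' Total ranking value of each alternative
#'
#' Each strategy carries a common coefficient (0.35 in the packaged
#' resilience model) and an importance rank; the total ranking value is
#' their product (rank 3 x 0.35 = 1.05).
#'
#' @param alternatives Data frame with `id`, `importance_rank` and
#'   `strategy_weight`, or a `decision_model`.
#' @return Data frame with a `total_ranking` column appended.
#' @export
rank_alternatives <- function(alternatives) {
  if (inherits(alternatives, "decision_model")) {
    alternatives <- alternatives$alternatives
  }
  stopifnot(all(c("importance_rank", "strategy_weight") %in%
                  names(alternatives)))
  if (any(alternatives$importance_rank < 1)) {
    stop("importance ranks must be positive", call. = FALSE)
  }
  if (any(alternatives$strategy_weight <= 0)) {
    stop("strategy_weight must be positive", call. = FALSE)
  }
  alternatives$total_ranking <-
    alternatives$importance_rank * alternatives$strategy_weight
  alternatives
}

#' Weighted value of one attribute
#'
#' The elementary SMART cell: importance rank times the weight of the
#' dimension the attribute belongs to.
#'
#' @param rank Integer importance rank, >= 1.
#' @param w_dim Dimension weight in (0, 1].
#' @return `rank * w_dim`.
#' @export
attribute_value <- function(rank, w_dim) {
  stopifnot(all(rank >= 1), all(w_dim > 0), all(w_dim <= 1))
  rank * w_dim
}

#' Dimension score from attribute values
#'
#' A dimension's score for an alternative is the sum of its attributes'
#' weighted values; single-attribute dimensions return that value.
#'
#' @param attribute_values Nonempty numeric vector.
#' @return The sum.
#' @export
dimension_score <- function(attribute_values) {
  if (length(attribute_values) == 0) {
    stop("a dimension needs at least one attribute value", call. = FALSE)
  }
  sum(attribute_values)
}

#' Build the performance matrix
#'
#' For every alternative and dimension: multiply each attribute's importance
#' rank by the dimension weight ([attribute_value()]), sum within the
#' dimension ([dimension_score()]), giving the dimension score u_jk; the
#' per-alternative performance total is the sum over dimensions.
#'
#' @param model A [decision_model()].
#' @return List of class `performance_matrix` with `scores` (alternatives x
#'   dimensions matrix of u_jk), `totals` (named per-alternative vector) and
#'   `weights` (the dimension weights used).
#' @export
performance_matrix <- function(model) {
  stopifnot(inherits(model, "decision_model"))
  alts <- model$alternatives$id
  dims <- model$dimensions$id
  w <- stats::setNames(model$dimensions$weight, dims)
  scores <- matrix(0, length(alts), length(dims),
                   dimnames = list(alts, dims))
  for (k in dims) {
    attrs <- model$attributes$id[model$attributes$dimension_id == k]
    vals <- attribute_value(model$ranks[alts, attrs, drop = FALSE], w[[k]])
    scores[, k] <- apply(vals, 1, dimension_score)
  }
  structure(
    list(scores = scores, totals = rowSums(scores), weights = w),
    class = "performance_matrix"
  )
}

#' @export
print.performance_matrix <- function(x, ...) {
  cat("<performance_matrix>\n")
  m <- cbind(x$scores, total = x$totals)
  print(round(m, 4))
  invisible(x)
}

#' Linear additive utility of each alternative
#'
#' U_j = sum_k w_k * u_jk: each alternative's dimension scores weighted by
#' the normalized dimension weights and summed. The weights must match the
#' score columns and sum to 1.
#'
#' @param perf A [performance_matrix()], or a bare alternatives x dimensions
#'   score matrix.
#' @param weights Dimension weights; defaults to those stored in `perf`.
#' @return Named numeric vector of utilities U_j.
#' @export
additive_utility <- function(perf, weights = NULL) {
  if (inherits(perf, "performance_matrix")) {
    scores <- perf$scores
    if (is.null(weights)) weights <- perf$weights
  } else {
    scores <- as.matrix(perf)
  }
  if (is.null(weights)) {
    stop("dimension weights are required", call. = FALSE)
  }
  if (length(weights) != ncol(scores)) {
    stop("got ", length(weights), " weights for ", ncol(scores),
         " dimensions", call. = FALSE)
  }
  if (!is.null(names(weights)) && !is.null(colnames(scores))) {
    if (!setequal(names(weights), colnames(scores))) {
      stop("weight names do not match dimension score columns",
           call. = FALSE)
    }
    weights <- weights[colnames(scores)]
  }
  drop(scores %*% weights)
}

#' Select the optimal alternative
#'
#' Argmax of utility; exact ties are broken toward the lexicographically
#' lowest alternative id and flagged.
#'
#' @param utilities Named numeric vector of U_j.
#' @return List with `optimal` (id), `utility` and `tie_flag`.
#' @export
select_optimal <- function(utilities) {
  if (length(utilities) == 0) stop("no utilities given", call. = FALSE)
  if (is.null(names(utilities))) {
    names(utilities) <- paste0("S", seq_along(utilities))
  }
  top <- max(utilities)
  winners <- sort(names(utilities)[utilities >= top - 1e-9])
  list(optimal = winners[1], utility = unname(utilities[winners[1]]),
       tie_flag = length(winners) > 1)
}

#' Evaluate a decision model end to end
#'
#' Performance matrix, additive utilities, ranking and optimal selection in
#' one call.
#'
#' @param model A [decision_model()].
#' @return List of class `smart_result`: `performance`
#'   ([performance_matrix()]), `utilities`, `ranking` (alternative ids by
#'   decreasing utility), `optimal`, `tie_flag`.
#' @examples
#' m <- resilience_decision_model()
#' smart_evaluate(m)
#' @export
smart_evaluate <- function(model) {
  perf <- performance_matrix(model)
  u <- additive_utility(perf)
  sel <- select_optimal(u)
  structure(
    list(performance = perf, utilities = u,
         ranking = names(sort(-u)), optimal = sel$optimal,
         tie_flag = sel$tie_flag),
    class = "smart_result"
  )
}

#' @export
print.smart_result <- function(x, ...) {
  print(x$performance)
  cat("utilities U_j:\n")
  print(round(x$utilities, 4))
  cat("ranking:", paste(x$ranking, collapse = " > "), "\n")
  cat("optimal alternative:", x$optimal,
      if (x$tie_flag) "(tie, broken by id)" else "", "\n")
  invisible(x)
}

#' Load a decision model from a YAML or JSON configuration
#'
#' The file must define `dimensions` (id, weight or raw_score, labels),
#' `attributes` (id, dimension_id, label), `alternatives` (id, label,
#' strategy_weight, importance_rank), `ranks` (per-alternative named rank
#' lists) and optionally `rank_total`. Validation is all-or-nothing via
#' [decision_model()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` model file.
#' @return A `decision_model`.
#' @export
read_decision_model <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  needed <- c("dimensions", "attributes", "alternatives", "ranks")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    stop("decision model config is missing section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  to_df <- function(x) {
    if (is.data.frame(x)) return(x)
    rows <- lapply(x, function(row) row[!vapply(row, is.null, logical(1))])
    cols <- unique(unlist(lapply(rows, names)))
    do.call(rbind, lapply(rows, function(row) {
      row[setdiff(cols, names(row))] <- NA
      as.data.frame(row[cols], stringsAsFactors = FALSE)
    }))
  }
  dims <- to_df(cfg$dimensions)
  attrs <- to_df(cfg$attributes)
  alts <- to_df(cfg$alternatives)
  rk <- cfg$ranks
  if (is.list(rk) && !is.matrix(rk)) {
    attr_ids <- as.character(attrs$id)
    ranks <- t(vapply(rk, function(row) {
      miss <- setdiff(attr_ids, names(row))
      if (length(miss) > 0) {
        stop("rank assignment missing attribute(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      unlist(row)[attr_ids]
    }, numeric(nrow(attrs))))
    rownames(ranks) <- names(rk)
  } else {
    ranks <- as.matrix(rk)
  }
  decision_model(dims, attrs, alts, ranks, rank_total = cfg$rank_total)
}

#' The packaged healthcare-resilience decision model
#'
#' The four-dimension, seven-attribute, three-strategy model for improving
#' national health-system resilience after the COVID-19 pandemic: dimension
#' weights (0.35, 0.30, 0.20, 0.15) over budget allocation, healthcare
#' service planning, human-resource management and the legal framework;
#' strategies S1 (emergency-regime prioritization), S2 (medium-term
#' solutions) and S3 (long-term prioritization), each with an attribute rank
#' budget of 14. Dimension labels carry an `alt_label` where the source
#' tables used conflicting names for the same weights.
#'
#' @return A `decision_model`.
#' @export
resilience_decision_model <- function() {
  path <- system.file("extdata", "resilience_model.yaml",
                      package = "resilmcda", mustWork = TRUE)
  read_decision_model(path)
}
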