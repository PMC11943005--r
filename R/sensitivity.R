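# One-at-a-time weight-sensitivity analysis: the standard SMART companion
# check for rank reversal under perturbed criterion weights.

# Perturb one dimension weight by delta (signed) and renormalize the others
# proportionally so the vector still sums to 1. Returns NULL when the move
# would drive any weight out of (0, 1).
perturb_weights <- function(weights, k, delta) {
  w <- weights
  wk <- w[[k]] + delta
  if (wk <= 0 || wk >= 1) return(NULL)
  others <- setdiff(seq_along(w), k)
  w[others] <- w[others] * (1 - wk) / (1 - w[[k]])
  w[k] <- wk
  if (any(w <= 0)) return(NULL)
  w
}

#' Weight-sensitivity and rank-reversal analysis
#'
#' For each dimension and each perturbation size delta in the grid, moves
#' that dimension's weight by +/- delta, renormalizes the remaining weights
#' proportionally (so they keep their relative proportions and the vector
#' sums to 1), re-scores the model from its rank assignment under the
#' perturbed weights, and records whether the optimal alternative changes.
#' Perturbations that would drive any weight outside (0, 1) are skipped and
#' noted.
#'
#' Because every dimension score is (sum of ranks in that dimension) x w_k,
#' re-scoring under perturbed weights is a full model re-evaluation, not a
#' rescaling of stored utilities.
#'
#' @param model A [decision_model()].
#' @param delta_grid Increasing vector of perturbation sizes in \[0, 1).
#' @return List of class `sensitivity_report`: `baseline_optimal`, `grid`
#'   (one row per dimension x delta x direction with utilities, the optimal
#'   under perturbation, `reversed` and `skipped`), and `min_reversal_delta`
#'   (named per-dimension; NA when no reversal occurs within the grid).
#' @export
sensitivity_analysis <- function(model, delta_grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(inherits(model, "decision_model"))
  if (any(delta_grid < 0) || any(delta_grid >= 1)) {
    stop("delta grid values must lie in [0, 1)", call. = FALSE)
  }
  base <- smart_evaluate(model)
  dims <- model$dimensions$id
  w0 <- stats::setNames(model$dimensions$weight, dims)
  rows <- list()
  for (k in seq_along(dims)) {
    for (delta in delta_grid) {
      for (dir in c(-1, 1)) {
        if (delta == 0 && dir == 1) next # +0 and -0 are the same point
        w <- perturb_weights(w0, k, dir * delta)
        if (is.null(w)) {
          rows[[length(rows) + 1]] <- data.frame(
            dimension = dims[k], delta = delta, direction = dir,
            optimal = NA_character_, reversed = NA, skipped = TRUE,
            note = "perturbation drives a weight outside (0, 1)",
            stringsAsFactors = FALSE
          )
          next
        }
        m2 <- model
        m2$dimensions$weight <- unname(w[dims])
        res <- smart_evaluate(m2)
        u <- as.data.frame(t(res$utilities))
        names(u) <- paste0("U_", names(res$utilities))
        rows[[length(rows) + 1]] <- cbind(
          data.frame(dimension = dims[k], delta = delta, direction = dir,
                     optimal = res$optimal,
                     reversed = !identical(res$optimal, base$optimal),
                     skipped = FALSE, note = "",
                     stringsAsFactors = FALSE),
          u
        )
      }
    }
  }
  grid <- do.call(rbind, lapply(rows, function(r) {
    for (nm in paste0("U_", model$alternatives$id)) {
      if (!nm %in% names(r)) r[[nm]] <- NA_real_
    }
    r[, c("dimension", "delta", "direction", "optimal", "reversed",
          "skipped", "note", paste0("U_", model$alternatives$id))]
  }))
  min_rev <- vapply(dims, function(d) {
    g <- grid[grid$dimension == d & !grid$skipped & grid$reversed, ]
    if (nrow(g) == 0) NA_real_ else min(g$delta)
  }, numeric(1))
  structure(
    list(baseline_optimal = base$optimal, grid = grid,
         min_reversal_delta = min_rev),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> baseline optimal:", x$baseline_optimal, "\n")
  cat("smallest weight perturbation causing a rank reversal:\n")
  for (d in names(x$min_reversal_delta)) {
    v <- x$min_reversal_delta[[d]]
    cat("  ", d, ": ",
        if (is.na(v)) "none within grid" else format(v), "\n", sep = "")
  }
  n_skip <- sum(x$grid$skipped)
  if (n_skip > 0) cat(" (", n_skip, " infeasible perturbations skipped)\n",
                      sep = "")
  invisible(x)
}
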