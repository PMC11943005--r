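# Stage-1 aggregation: weighted Likert item summaries, item ranking and
# criterion extraction.

#' Construct a response matrix
#'
#' The stage-1 container: a respondents x items grid of integer Likert
#' responses (NA = missing), item scale metadata, and one composite weight
#' per respondent. All invariants are checked at construction: grid
#' dimensions match the id/item lists and every non-missing cell lies within
#' its item's scale bounds.
#'
#' @param values Integer matrix (respondents x items) with NA for missing
#'   answers; column names must match `items$item_id`.
#' @param items Data frame with columns `item_id`, `scale_min`, `scale_max`
#'   (scales here are 1-5 or 1-6, but any `scale_min < scale_max` is
#'   accepted).
#' @param respondent_id Character vector of respondent identifiers; defaults
#'   to the row names of `values` or `r1..rn`.
#' @param weights Positive numeric vector of per-respondent composite
#'   weights; defaults to 1 (unweighted).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(values, items, respondent_id = NULL,
                            weights = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.data.frame(items),
            all(c("item_id", "scale_min", "scale_max") %in% names(items)))
  items$item_id <- as.character(items$item_id)
  if (anyDuplicated(items$item_id)) {
    stop("duplicate item_id in item metadata", call. = FALSE)
  }
  if (any(items$scale_min >= items$scale_max)) {
    stop("scale_min must be < scale_max for every item", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) != nrow(items)) {
      stop("response grid has ", ncol(values), " columns but ",
           nrow(items), " items", call. = FALSE)
    }
    colnames(values) <- items$item_id
  }
  if (!setequal(colnames(values), items$item_id) ||
      ncol(values) != nrow(items)) {
    stop("response grid columns do not match the item list", call. = FALSE)
  }
  values <- values[, items$item_id, drop = FALSE]
  if (is.null(respondent_id)) {
    respondent_id <- rownames(values)
    if (is.null(respondent_id)) {
      respondent_id <- paste0("r", seq_len(nrow(values)))
    }
  }
  respondent_id <- as.character(respondent_id)
  if (length(respondent_id) != nrow(values)) {
    stop("respondent_id length does not match the response grid",
         call. = FALSE)
  }
  rownames(values) <- respondent_id
  if (is.null(weights)) weights <- rep(1, nrow(values))
  if (length(weights) != nrow(values)) {
    stop("weights length does not match the response grid", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("composite weights must be positive and finite", call. = FALSE)
  }
  for (j in seq_len(nrow(items))) {
    x <- values[, items$item_id[j]]
    ok <- is.na(x) | (x >= items$scale_min[j] & x <= items$scale_max[j] &
                        x == round(x))
    if (!all(ok)) {
      stop("responses out of scale bounds for item ", items$item_id[j],
           call. = FALSE)
    }
  }
  structure(
    list(values = values, items = items, respondent_id = respondent_id,
         weights = as.numeric(weights)),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$values), " respondents x ",
      ncol(x$values), " items\n", sep = "")
  cat("  scales: ", paste0(x$items$scale_min, "-", x$items$scale_max,
                           collapse = ", "), "\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

#' Read a response matrix from CSV
#'
#' Expects a `respondent_id` column plus one column per item; empty cells
#' and "NA" are missing answers. Item scale metadata comes from `items`
#' (typically the pipeline configuration).
#'
#' @param path CSV path.
#' @param items Item metadata data frame (see [response_matrix()]).
#' @param weights Optional per-respondent weights in row order.
#' @return A `response_matrix`.
#' @export
read_response_matrix <- function(path, items, weights = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  if (!"respondent_id" %in% names(df)) {
    stop("response CSV must have a respondent_id column", call. = FALSE)
  }
  ids <- as.character(df$respondent_id)
  vals <- as.matrix(df[, setdiff(names(df), "respondent_id"), drop = FALSE])
  response_matrix(vals, items, respondent_id = ids, weights = weights)
}

#' Write a response matrix to CSV
#'
#' @param m A `response_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(m, path) {
  df <- data.frame(respondent_id = m$respondent_id, m$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Type-1 (left-continuous inverse CDF) weighted quantile: the smallest value
# whose weighted CDF reaches p. On discrete Likert scales this always
# returns an observed scale point, never an interpolated value.
weighted_quantile1 <- function(x, w, p) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cdf <- cumsum(w) / sum(w)
  vapply(p, function(pp) x[which(cdf >= pp - 1e-12)[1]], numeric(1))
}

#' Weighted summary of one Likert item
#'
#' All statistics are computed on the weighted empirical distribution of the
#' non-missing responses: respondent i contributes mass w_i. Reported fields:
#'
#' * `weighted_mean` = sum(w x) / sum(w);
#' * `sd` = weighted population standard deviation (divides by sum(w), so it
#'   is invariant to rescaling all weights);
#' * `weighted_index` = weighted_mean / scale_max x 100, a percentage-scaled
#'   agreement index comparable across items with different scales;
#' * `preferred_response` = the scale point carrying the greatest total
#'   weight (the weighted mode); exact ties go to the lower scale point with
#'   `mode_tie` set, so agreement is never overstated by default;
#' * `weighted_pct_preferred` = the preferred point's weight share x 100;
#' * `q25`/`q75` = type-1 weighted quantiles (lower bracketing scale point).
#'
#' Missing responses contribute to neither numerator nor denominator;
#' `n_responses + n_missing` always equals the number of respondents.
#'
#' @param m A [response_matrix()].
#' @param item_id Item to summarize.
#' @return A one-row data frame (an item summary record).
#' @export
weighted_item_summary <- function(m, item_id) {
  stopifnot(inherits(m, "response_matrix"))
  j <- match(item_id, m$items$item_id)
  if (is.na(j)) stop("unknown item_id: ", item_id, call. = FALSE)
  x <- m$values[, item_id]
  w <- m$weights
  keep <- !is.na(x)
  if (!any(keep)) {
    stop("all responses missing for item ", item_id, call. = FALSE)
  }
  x <- x[keep]
  w <- w[keep]
  scale_max <- m$items$scale_max[j]
  wm <- sum(w * x) / sum(w)
  wsd <- sqrt(sum(w * (x - wm)^2) / sum(w))
  mass <- tapply(w, factor(x, levels = sort(unique(x))), sum)
  top <- max(mass)
  modes <- as.numeric(names(mass)[mass >= top - 1e-12])
  preferred <- min(modes)
  q <- weighted_quantile1(x, w, c(0.25, 0.75))
  data.frame(
    item_id = item_id,
    weighted_index = wm / scale_max * 100,
    weighted_pct_preferred = sum(mass[as.character(preferred)]) / sum(w) * 100,
    preferred_response = preferred,
    mode_tie = length(modes) > 1,
    weighted_mean = wm,
    sd = wsd,
    q25 = q[1],
    q75 = q[2],
    n_responses = sum(keep),
    n_missing = sum(!keep),
    stringsAsFactors = FALSE
  )
}

#' Summarize every item of a response matrix
#'
#' @param m A [response_matrix()].
#' @return Data frame with one [weighted_item_summary()] row per item, in
#'   item order.
#' @export
summarize_items <- function(m) {
  stopifnot(inherits(m, "response_matrix"))
  do.call(rbind, lapply(m$items$item_id, weighted_item_summary, m = m))
}

#' Rank items by a weighted summary statistic
#'
#' Descending, stable; exact ties are broken toward lexicographically
#' smaller `item_id` and flagged in `rank_tie`.
#'
#' @param summaries Data frame of item summaries ([summarize_items()]).
#' @param key `"weighted_index"` (default) or `"weighted_mean"`.
#' @return `summaries` reordered, with `rank` and `rank_tie` columns.
#' @export
rank_items <- function(summaries, key = c("weighted_index", "weighted_mean")) {
  key <- match.arg(key)
  if (nrow(summaries) == 0) stop("no item summaries to rank", call. = FALSE)
  v <- summaries[[key]]
  o <- order(-v, summaries$item_id)
  out <- summaries[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  vo <- out[[key]]
  tie <- rep(FALSE, nrow(out))
  if (nrow(out) > 1) {
    same_prev <- c(FALSE, abs(diff(vo)) < 1e-12)
    tie <- same_prev | c(same_prev[-1], FALSE)
  }
  out$rank_tie <- tie
  rownames(out) <- NULL
  out
}

#' Extract decision criteria from item summaries
#'
#' Aggregates stage-1 evidence onto the risk/opportunity attributes of the
#' decision model: each attribute is backed by a configured set of source
#' items and scored by the mean of their weighted indices (its salience).
#'
#' @param summaries Data frame of item summaries.
#' @param mapping Named list: attribute id -> character vector of source
#'   item ids. Every attribute needs at least one source item and every
#'   referenced item must exist.
#' @return Data frame with columns `attribute_id`, `salience`, `n_items`,
#'   `source_items` (comma-separated).
#' @export
extract_criteria <- function(summaries, mapping) {
  if (length(mapping) == 0 || is.null(names(mapping))) {
    stop("criteria mapping must be a named list", call. = FALSE)
  }
  out <- lapply(names(mapping), function(a) {
    src <- mapping[[a]]
    if (length(src) == 0) {
      stop("attribute '", a, "' has no source items", call. = FALSE)
    }
    missing <- setdiff(src, summaries$item_id)
    if (length(missing) > 0) {
      stop("attribute '", a, "' references unknown item(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    idx <- summaries$weighted_index[match(src, summaries$item_id)]
    data.frame(
      attribute_id = a,
      salience = mean(idx),
      n_items = length(src),
      source_items = paste(src, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
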