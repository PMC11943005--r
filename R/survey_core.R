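#' @keywords internal
"_PACKAGE"

# Category vocabularies for the three weighted demographic fields plus the
# purely descriptive ones. Order within each vector is the coefficient order
# of the corresponding weight list (lowest to highest).
respondent_categories <- list(
  education_level = c(
    "health_assistant", "medical_assistant", "resident",
    "specialist_or_pharmacist", "primary_doctor_or_pharmacist", "phd_academic"
  ),
  experience_band = c("0-4", "5-9", "10-14", "15-19", "20+"),
  pandemic_role = c(
    "not_involved_or_education", "dsp_ministry_pharmacy_ngo",
    "triage_or_vaccination", "civil_hospital",
    "covid_support_hospital_er_ambulance"
  ),
  profession = c("doctor", "pharmacist", "medical_assistant"),
  sector = c("private", "civil", "public_order_security"),
  sex = c("male", "female")
)

#' Default respondent weight-coefficient map
#'
#' Differentiated weight coefficients for survey respondents: education level
#' (1 to 3.5), years of specialty experience (1 to 3) and role during the
#' pandemic response (1 to 3). Higher qualification, longer experience and
#' more exposed pandemic roles receive larger coefficients, so their answers
#' carry more mass in every weighted item summary.
#'
#' @return A named list with components `education_level`, `experience_band`
#'   and `pandemic_role`, each a named numeric vector mapping every category
#'   token to its coefficient.
#' @examples
#' default_weight_map()$education_level[["phd_academic"]] # 3.5
#' @export
default_weight_map <- function() {
  list(
    education_level = c(
      health_assistant = 1, medical_assistant = 1.5, resident = 2,
      specialist_or_pharmacist = 2.5, primary_doctor_or_pharmacist = 3,
      phd_academic = 3.5
    ),
    experience_band = c(
      "0-4" = 1, "5-9" = 1.5, "10-14" = 2, "15-19" = 2.5, "20+" = 3
    ),
    pandemic_role = c(
      not_involved_or_education = 1, dsp_ministry_pharmacy_ngo = 1.5,
      triage_or_vaccination = 2, civil_hospital = 2.5,
      covid_support_hospital_er_ambulance = 3
    )
  )
}

#' Combine the three respondent coefficients into one composite weight
#'
#' The three per-field coefficients must be collapsed into a single
#' per-respondent weight before item aggregation. Three schemes are
#' supported; the default, the arithmetic mean, keeps the composite on the
#' same 1-3.5 scale as its inputs and avoids the multiplicative blow-up of
#' the product scheme (maximum 31.5).
#'
#' @param w_edu,w_exp,w_role Numeric coefficients; `w_edu` in \[1, 3.5\],
#'   the others in \[1, 3\]. Vectorized.
#' @param scheme One of `"mean"`, `"product"`, `"sum"`.
#' @return Positive numeric vector of composite weights.
#' @examples
#' composite_weight(3.5, 3, 3) # 9.5 / 3
#' composite_weight(2, 1.5, 1, scheme = "product") # 3
#' @export
composite_weight <- function(w_edu, w_exp, w_role,
                             scheme = c("mean", "product", "sum")) {
  scheme <- match.arg(scheme)
  stopifnot(
    all(w_edu >= 1 & w_edu <= 3.5),
    all(w_exp >= 1 & w_exp <= 3),
    all(w_role >= 1 & w_role <= 3)
  )
  switch(scheme,
    mean = (w_edu + w_exp + w_role) / 3,
    product = w_edu * w_exp * w_role,
    sum = w_edu + w_exp + w_role
  )
}

#' Assign weight coefficients to respondents
#'
#' Maps each respondent's education level, experience band and pandemic role
#' to its coefficient and combines them into a composite weight. Every
#' category must be present in the weight map: an unmapped or missing
#' category is an error naming the offending field, never a silent default
#' (defaulting to 1 would quietly flatten the weighting scheme).
#'
#' @param respondents Data frame with columns `education_level`,
#'   `experience_band`, `pandemic_role` (and usually `id`).
#' @param weight_map Named list as returned by [default_weight_map()].
#' @param scheme Composite scheme passed to [composite_weight()].
#' @return The input data frame with numeric columns `w_edu`, `w_exp`,
#'   `w_role` and `composite` appended.
#' @export
assign_respondent_weights <- function(respondents,
                                      weight_map = default_weight_map(),
                                      scheme = c("mean", "product", "sum")) {
  scheme <- match.arg(scheme)
  fields <- c("education_level", "experience_band", "pandemic_role")
  missing_cols <- setdiff(fields, names(respondents))
  if (length(missing_cols) > 0) {
    stop("respondent table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  coef <- lapply(fields, function(f) {
    vals <- as.character(respondents[[f]])
    map <- weight_map[[f]]
    if (is.null(map)) {
      stop("weight map has no entry for field '", f, "'", call. = FALSE)
    }
    bad <- is.na(vals) | !(vals %in% names(map))
    if (any(bad)) {
      stop("unmapped or missing category in field '", f, "': ",
           paste(unique(ifelse(is.na(vals[bad]), "<NA>", vals[bad])),
                 collapse = ", "),
           call. = FALSE)
    }
    unname(map[vals])
  })
  respondents$w_edu <- coef[[1]]
  respondents$w_exp <- coef[[2]]
  respondents$w_role <- coef[[3]]
  respondents$composite <- composite_weight(
    coef[[1]], coef[[2]], coef[[3]], scheme = scheme
  )
  respondents
}

#' Validate a respondent table against the category vocabularies
#'
#' Checks that every demographic/behavioral field holds only known category
#' tokens. Unknown tokens are a load-time error; the optional fields `age`
#' and `sex` may be missing or NA.
#'
#' @param respondents Data frame of respondents.
#' @return The validated data frame, invisibly.
#' @export
validate_respondents <- function(respondents) {
  required <- c("education_level", "experience_band", "pandemic_role",
                "profession", "sector")
  missing_cols <- setdiff(required, names(respondents))
  if (length(missing_cols) > 0) {
    stop("respondent table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (f in required) {
    vals <- as.character(respondents[[f]])
    bad <- !is.na(vals) & !(vals %in% respondent_categories[[f]])
    if (any(bad)) {
      stop("unknown category in field '", f, "': ",
           paste(unique(vals[bad]), collapse = ", "), call. = FALSE)
    }
    if (anyNA(vals)) {
      stop("missing value in required field '", f, "'", call. = FALSE)
    }
  }
  if ("sex" %in% names(respondents)) {
    vals <- as.character(respondents$sex)
    bad <- !is.na(vals) & !(vals %in% respondent_categories$sex)
    if (any(bad)) {
      stop("unknown category in field 'sex': ",
           paste(unique(vals[bad]), collapse = ", "), call. = FALSE)
    }
  }
  invisible(respondents)
}

#' Read a respondent table from CSV
#'
#' One row per respondent; demographic columns use the category tokens of
#' [default_weight_map()] and `respondent_categories`. Empty strings and
#' "NA" are read as missing. The table is validated on load.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated data frame of respondents.
#' @export
read_respondents <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_respondents(df)
  df
}

#' Minimum sample size for a proportion in a large population
#'
#' Cochran's formula n0 = z^2 p (1 - p) / e^2 for populations large enough
#' (N >= 100,000) that the finite-population correction is negligible. The
#' dispersion p(1 - p) is maximal (0.25) at p = 0.5, which gives the
#' conventional worst-case planning value. The result is truncated to an
#' integer (384 at z = 1.96, p = 0.5, e = 0.05, from 384.16).
#'
#' @param z Standard-normal quantile for the confidence level (1.96 for 95%).
#' @param p Anticipated proportion, in (0, 1). Use 0.5 when unknown.
#' @param e Margin of error, > 0 (0.05 for +/- 5 points).
#' @return Integer minimum sample size.
#' @examples
#' cochran_sample_size(1.96, 0.5, 0.05) # 384
#' @export
cochran_sample_size <- function(z, p, e) {
  if (!is.numeric(z) || length(z) != 1 || z <= 0) {
    stop("z must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(e) || length(e) != 1 || e <= 0) {
    stop("e must be positive", call. = FALSE)
  }
  as.integer(floor(z^2 * p * (1 - p) / e^2))
}
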