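#' Canonical variable registry
#'
#' The assessment system works on a fixed panel of one target variable
#' (operative time, minutes) and 16 candidate predictors: four demographic
#' variables, four serum metabolites, and eight variables measured or counted
#' on the donor's abdominal CT scan (renal artery count, perinephric fat
#' geometry and attenuation, subcutaneous fat geometry). This registry pins
#' the canonical snake_case name, unit, and kind of each variable, plus the
#' column alias commonly seen in published tables (e.g. `numberRA`,
#' `maxthickMPF`).
#'
#' @return A data.frame with columns `name`, `unit`, `kind`
#'   (`"continuous"`, `"binary"` or `"count"`), `alias` and `role`
#'   (`"target"` or `"predictor"`), one row per canonical variable
#'   (1 target + 16 predictors).
#' @examples
#' variable_registry()
#' @export
variable_registry <- function() {
  data.frame(
    name = c(
      "operative_time",
      "sex_male", "age", "body_weight", "body_height",
      "total_protein", "albumin", "triglyceride", "total_cholesterol",
      "number_ra", "maxthick_mpf", "medthick_mpf", "medthick_lpf",
      "area_pnf", "ctv_pnf", "thick_scf", "area_scf"
    ),
    unit = c(
      "min",
      "1/0", "years", "kg", "cm",
      "g/dL", "g/dL", "mg/dL", "mg/dL",
      "count", "mm", "mm", "mm",
      "cm^2", "HU", "mm", "cm^2"
    ),
    kind = c(
      "continuous",
      "binary", "continuous", "continuous", "continuous",
      "continuous", "continuous", "continuous", "continuous",
      "count", "continuous", "continuous", "continuous",
      "continuous", "continuous", "continuous", "continuous"
    ),
    alias = c(
      "OperativeTime",
      "Male", "Age", "BodyWeight", "BodyHeight",
      "TotalProtein", "Albumin", "Triglyceride", "TotalCholesterol",
      "numberRA", "maxthickMPF", "medthickMPF", "medthickLPF",
      "areaPNF", "ctvPNF", "thickSCF", "areaSCF"
    ),
    role = c("target", rep("predictor", 16L)),
    stringsAsFactors = FALSE
  )
}

#' Names of the 16 candidate predictors, in canonical registry order.
#' @return Character vector of length 16.
#' @export
predictor_names <- function() {
  reg <- variable_registry()
  reg$name[reg$role == "predictor"]
}

#' Named predictor subsets
#'
#' The five named predictor subsets used throughout the workload analyses:
#' * `A` — demographic frame only (sex, age, weight, height);
#' * `B` — A plus the four serum metabolites;
#' * `C` — B plus the six perinephric CT variables;
#' * `D` — all 16 variables (C plus the two subcutaneous-fat variables);
#' * `E` — the 9-variable model selected by the cross-validation/.632 funnel
#'   (age, total protein, total cholesterol, renal artery count, medial
#'   perinephric fat thicknesses, perinephric fat area and attenuation,
#'   subcutaneous fat area).
#'
#' @return Named list of character vectors of canonical predictor names.
#' @examples
#' workload_sets()$E
#' @export
workload_sets <- function() {
  list(
    A = c("sex_male", "age", "body_weight", "body_height"),
    B = c("sex_male", "age", "body_weight", "body_height",
          "total_protein", "albumin", "triglyceride", "total_cholesterol"),
    C = c("sex_male", "age", "body_weight", "body_height",
          "total_protein", "albumin", "triglyceride", "total_cholesterol",
          "number_ra", "maxthick_mpf", "medthick_mpf", "medthick_lpf",
          "area_pnf", "ctv_pnf"),
    D = c("sex_male", "age", "body_weight", "body_height",
          "total_protein", "albumin", "triglyceride", "total_cholesterol",
          "number_ra", "maxthick_mpf", "medthick_mpf", "medthick_lpf",
          "area_pnf", "ctv_pnf", "thick_scf", "area_scf"),
    E = c("age", "total_protein", "total_cholesterol", "number_ra",
          "maxthick_mpf", "medthick_mpf", "area_pnf", "ctv_pnf", "area_scf")
  )
}

#' Ordinal encoding of modified Clavien complication grades
#'
#' Maps the modified Clavien grade labels to integer ranks for rank
#' correlations: 0 (no complication) < 1 < 2a < 2b < 3a < 3b < 4.
#'
#' @return Named integer vector (names are grade labels).
#' @export
clavien_ranks <- function() {
  c("0" = 0L, "1" = 1L, "2a" = 2L, "2b" = 3L,
    "3a" = 4L, "3b" = 5L, "4" = 6L)
}

# resolve user-supplied predictor spec (names, aliases, set letter, or mask)
# to canonical names; errors name the offending entry
resolve_subset <- function(subset) {
  preds <- predictor_names()
  if (is.numeric(subset) && length(subset) == 1L && subset == trunc(subset)) {
    return(mask_members(as.integer(subset)))
  }
  subset <- as.character(subset)
  if (length(subset) == 1L) {
    up <- toupper(sub("^[Ss]et\\s*", "", subset))
    if (up %in% names(workload_sets()))
      return(workload_sets()[[up]])
    subset <- strsplit(subset, ",")[[1]]
    subset <- trimws(subset)
  }
  reg <- variable_registry()
  out <- character(length(subset))
  for (i in seq_along(subset)) {
    s <- subset[i]
    if (s %in% preds) {
      out[i] <- s
    } else {
      hit <- match(tolower(s), tolower(reg$alias))
      if (is.na(hit) || reg$role[hit] != "predictor")
        stop("unknown predictor: '", s, "'", call. = FALSE)
      out[i] <- reg$name[hit]
    }
  }
  if (anyDuplicated(out))
    stop("duplicated predictor(s) in subset: ",
         paste(unique(out[duplicated(out)]), collapse = ", "), call. = FALSE)
  # canonical registry order, as the feature order of x
  preds[preds %in% out]
}
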