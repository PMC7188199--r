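#' Construct a donor cohort from a data.frame
#'
#' Validates and types a table of donors (one row each) against the
#' canonical variable registry. Column names may be canonical snake_case
#' names or the published aliases (`numberRA`, `areaPNF`, ...); an extra
#' alias map can be supplied for other headers. Values are kept on their
#' native scales (no unit conversion, no standardisation).
#'
#' @param df data.frame with a header-derived set of columns containing the
#'   operative time and the 16 candidate predictors. Optional columns:
#'   `donor_id`, `complication_grade` (modified Clavien labels, see
#'   [clavien_ranks()]).
#' @param aliases optional named character vector mapping canonical names to
#'   source column names, overriding the built-in aliases.
#' @param provenance free-text description of where the table came from.
#' @return An object of class `wl_cohort` (a data.frame with canonical
#'   columns, `donor_id` first).
#' @export
as_cohort <- function(df, aliases = NULL, provenance = "user") {
  if (!is.data.frame(df)) stop("`df` must be a data.frame", call. = FALSE)
  if (nrow(df) == 0L) stop("empty input: cohort has no rows", call. = FALSE)
  reg <- variable_registry()
  need <- reg$name

  resolve_col <- function(canon) {
    if (!is.null(aliases) && canon %in% names(aliases) &&
        aliases[[canon]] %in% names(df))
      return(aliases[[canon]])
    if (canon %in% names(df)) return(canon)
    alias <- reg$alias[match(canon, reg$name)]
    hit <- match(tolower(alias), tolower(names(df)))
    if (!is.na(hit)) return(names(df)[hit])
    NA_character_
  }

  src <- vapply(need, resolve_col, character(1))
  if (anyNA(src)) {
    miss <- reg$alias[match(need[is.na(src)], reg$name)]
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  out <- data.frame(row.names = NULL)
  ids <- if ("donor_id" %in% names(df)) as.character(df$donor_id) else
    sprintf("D%03d", seq_len(nrow(df)))
  if (anyDuplicated(ids))
    stop("donor_id values must be unique", call. = FALSE)
  out <- data.frame(donor_id = ids, stringsAsFactors = FALSE)

  for (canon in need) {
    v <- df[[src[[canon]]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
    if (length(bad))
      stop("non-numeric value in column '", src[[canon]], "' at row ",
           bad[1], ": '", v[bad[1]], "'", call. = FALSE)
    out[[canon]] <- num
  }

  if ("complication_grade" %in% names(df)) {
    g <- as.character(df$complication_grade)
    known <- names(clavien_ranks())
    bad <- which(!is.na(g) & !(g %in% known))
    if (length(bad))
      stop("unknown complication grade '", g[bad[1]], "' at row ", bad[1],
           "; expected one of: ", paste(known, collapse = ", "),
           call. = FALSE)
    out$complication_grade <- g
    out$complication_rank <- unname(clavien_ranks()[g])
  }

  if (any(!is.na(out$operative_time) & out$operative_time <= 0))
    stop("operative_time must be positive", call. = FALSE)
  if (any(!is.na(out$sex_male) & !(out$sex_male %in% c(0, 1))))
    stop("sex_male must be coded 1/0", call. = FALSE)
  if (any(!is.na(out$number_ra) &
          (out$number_ra < 1 | out$number_ra != trunc(out$number_ra))))
    stop("number_ra must be a positive integer count", call. = FALSE)

  structure(out, class = c("wl_cohort", "data.frame"),
            provenance = provenance)
}

#' Read a donor cohort table from CSV or XLSX
#'
#' @param path file path; `.csv` files are read with [utils::read.csv()],
#'   `.xlsx` with `readxl::read_excel()` (package `readxl` must be
#'   installed).
#' @param aliases optional alias map, see [as_cohort()].
#' @param sheet XLSX sheet name or index (default: first sheet).
#' @return A `wl_cohort` object; row order is preserved.
#' @examples
#' coh <- simulate_cohort(n = 20, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_cohort(coh, f)
#' coh2 <- read_cohort(f)
#' stopifnot(identical(coh$area_pnf, coh2$area_pnf))
#' @export
read_cohort <- function(path, aliases = NULL, sheet = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package", call. = FALSE)
    as.data.frame(readxl::read_excel(path, sheet = if (is.null(sheet)) 1 else sheet))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L)
    stop("empty input: ", path, " has no data rows", call. = FALSE)
  as_cohort(df, aliases = aliases, provenance = path)
}

#' Write a cohort to CSV
#'
#' Numeric cells are written with 17 significant digits (`%.17g`) so that a
#' write/read round trip reproduces every double bit-identically.
#'
#' @param cohort a `wl_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "wl_cohort"))
  df <- as.data.frame(cohort)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      s <- sprintf("%.17g", df[[nm]])
      s[is.na(df[[nm]])] <- ""
      # integers render without exponent for readability
      iv <- !is.na(df[[nm]]) & df[[nm]] == trunc(df[[nm]]) &
        abs(df[[nm]]) < 1e15
      s[iv] <- sprintf("%.0f", df[[nm]][iv])
      df[[nm]] <- s
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @export
print.wl_cohort <- function(x, ...) {
  cat(sprintf("<wl_cohort> %d donors (%s)\n", nrow(x),
              attr(x, "provenance") %||% "unknown"))
  if (inherits(x, "wl_labeled")) {
    thr <- attr(x, "threshold_min")
    cat(sprintf("  workload threshold: %g min; difficult %d / easy %d\n",
                thr, sum(x$workload == "difficult"),
                sum(x$workload == "easy")))
  }
  cat(sprintf("  operative time: mean %.1f min, range %g-%g\n",
              mean(x$operative_time), min(x$operative_time),
              max(x$operative_time)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dichotomize operative time into workload groups
#'
#' Labels each donor `difficult` when operative time is greater than or
#' equal to the threshold ("210 min or longer" is the default reading), else
#' `easy`. The default 210-minute boundary corresponds to the 84.1th
#' percentile of the development cohort, i.e. the mean + 1 SD mass of a
#' normal distribution (pnorm(1) = 0.841).
#'
#' @param cohort a `wl_cohort`.
#' @param threshold_min boundary in minutes (default 210).
#' @return A `wl_labeled` cohort: the cohort plus a `workload` factor with
#'   levels `easy`, `difficult` and attribute `threshold_min`. Warns when a
#'   group is empty (such cohorts cannot be fitted).
#' @examples
#' lab <- dichotomize(simulate_cohort(n = 128, seed = 1))
#' table(lab$workload)
#' @export
dichotomize <- function(cohort, threshold_min = 210) {
  stopifnot(inherits(cohort, "wl_cohort"))
  if (!is.numeric(threshold_min) || length(threshold_min) != 1L ||
      threshold_min <= 0)
    stop("threshold_min must be a single positive number", call. = FALSE)
  lab <- factor(ifelse(cohort$operative_time >= threshold_min,
                       "difficult", "easy"),
                levels = c("easy", "difficult"))
  if (any(tabulate(lab, 2L) == 0L))
    warning("degenerate labeling: one workload group is empty at threshold ",
            threshold_min, " min", call. = FALSE)
  out <- cohort
  out$workload <- lab
  class(out) <- c("wl_labeled", class(cohort))
  attr(out, "threshold_min") <- threshold_min
  out
}

#' Operative-time value at a given percentile
#'
#' Percentiles use linear interpolation between closest order statistics
#' ([stats::quantile()] type 7), the convention fixed for the whole package;
#' it only matters for the threshold-sweep analyses, since the primary
#' dichotomization uses the fixed minute threshold.
#'
#' @param cohort a `wl_cohort`.
#' @param percentile number strictly between 0 and 100.
#' @return Threshold in minutes.
#' @export
percentile_threshold <- function(cohort, percentile) {
  stopifnot(inherits(cohort, "wl_cohort"))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  unname(stats::quantile(cohort$operative_time, percentile / 100,
                         type = 7, names = FALSE))
}

#' Body mass index of each donor
#'
#' BMI = weight / height^2 with height in metres (kg/m^2).
#'
#' @param cohort a `wl_cohort`.
#' @return Numeric vector of BMI values.
#' @export
cohort_bmi <- function(cohort) {
  stopifnot(inherits(cohort, "wl_cohort"))
  cohort$body_weight / (cohort$body_height / 100)^2
}
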