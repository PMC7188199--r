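#' Hit rates across alternative workload thresholds
#'
#' Re-runs the discriminant evaluation with the difficult/easy boundary
#' placed at each requested operative-time percentile, to assess how
#' sensitive the rates are to the choice of boundary (the primary analysis
#' fixes it at the 84.1th percentile, the mean + 1 SD mass of a normal
#' distribution). Thresholds are realized via [percentile_threshold()]
#' (type-7 linear interpolation) followed by the inclusive `>=` labeling
#' rule. Percentiles whose dichotomy cannot be fitted (fewer than 2 donors
#' in a group, or a singular covariance) are reported with status
#' `"skipped"`, never interpolated.
#'
#' @inheritParams fit_nldr
#' @param cohort an unlabeled `wl_cohort`.
#' @param percentiles numeric vector in (0,100); default `2:98`, the
#'   1-percentile grid.
#' @param mode `"apparent"` (training-data rates) or `"loocv"`
#'   (leave-one-out estimates) at each threshold.
#' @return Data.frame with one row per percentile: `percentile`,
#'   `threshold_min`, `n_difficult`, `n_easy`, the five rates, `status`.
#' @examples
#' coh <- simulate_cohort(n = 128, seed = 1)
#' sw <- sweep_thresholds(coh, "E", percentiles = c(25, 50, 84.1))
#' sw
#' @export
sweep_thresholds <- function(cohort, subset, percentiles = 2:98,
                             mode = c("apparent", "loocv"),
                             covariance = c("pooled", "total"), ridge = 0) {
  stopifnot(inherits(cohort, "wl_cohort"))
  mode <- match.arg(mode)
  covariance <- match.arg(covariance)
  if (length(percentiles) == 0L)
    stop("percentiles must be a non-empty vector", call. = FALSE)
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie strictly between 0 and 100", call. = FALSE)
  subset <- resolve_subset(subset)

  rows <- lapply(percentiles, function(p) {
    thr <- percentile_threshold(cohort, p)
    lab <- suppressWarnings(dichotomize(cohort, thr))
    nd <- sum(lab$workload == "difficult")
    ne <- sum(lab$workload == "easy")
    base <- data.frame(percentile = p, threshold_min = thr,
                       n_difficult = nd, n_easy = ne)
    rates <- tryCatch(
      if (mode == "apparent")
        apparent_rates(lab, subset, covariance, ridge)
      else
        loocv_rates(lab, subset, covariance, ridge),
      error = function(e) NULL)
    if (is.null(rates)) {
      cbind(base, hrdc = NA_real_, hrec = NA_real_,
            sensitivity = NA_real_, specificity = NA_real_,
            total = NA_real_, status = "skipped")
    } else {
      cbind(base, as.data.frame(as.list(unclass(rates)[1:5])),
            status = "ok")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "subset") <- subset
  attr(out, "mode") <- mode
  out
}
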