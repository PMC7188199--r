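# Supporting association statistics ------------------------------------------
#
# These reproduce the conventional analyses that accompany the discriminant
# rule: which variables drive operative time (OLS regression, correlations),
# what distinguishes the extreme-workload donors (rank tests), and whether
# complications track perinephric fat (exact contingency test). Standard
# fits are delegated to stats:: (lm, cor.test, wilcox.test, fisher.test).

#' Univariate and multivariate linear regression of operative time
#'
#' Ordinary least squares of operative time (minutes) on the 16 candidate
#' predictors: one predictor at a time (univariate) and all 16 jointly with
#' intercept (multivariate). Coefficients are minutes per unit of the
#' predictor; p-values are two-sided t-tests on the coefficients.
#'
#' @param cohort a `wl_cohort` with complete predictors.
#' @return Data.frame with columns `variable`, `mode`
#'   (`univariate`/`multivariate`), `coefficient`, `p_value`, `n`.
#' @examples
#' reg <- regress_operative_time(simulate_cohort(n = 128, seed = 1))
#' subset(reg, variable == "number_ra")
#' @export
regress_operative_time <- function(cohort) {
  stopifnot(inherits(cohort, "wl_cohort"))
  preds <- predictor_names()
  df <- as.data.frame(cohort)[, c("operative_time", preds)]
  if (anyNA(df)) stop("regression requires complete cases", call. = FALSE)
  n <- nrow(df)
  if (n < length(preds) + 2L)
    stop("need at least ", length(preds) + 2L,
         " donors for the multivariate fit", call. = FALSE)

  uni <- do.call(rbind, lapply(preds, function(v) {
    fit <- stats::lm(stats::reformulate(v, "operative_time"), data = df)
    cf <- summary(fit)$coefficients
    data.frame(variable = v, mode = "univariate",
               coefficient = cf[v, "Estimate"],
               p_value = cf[v, "Pr(>|t|)"], n = n,
               stringsAsFactors = FALSE)
  }))

  fit <- stats::lm(stats::reformulate(preds, "operative_time"), data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient multivariate fit; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  multi <- data.frame(variable = preds, mode = "multivariate",
                      coefficient = cf[preds, "Estimate"],
                      p_value = cf[preds, "Pr(>|t|)"], n = n,
                      stringsAsFactors = FALSE)
  out <- rbind(uni, multi)
  rownames(out) <- NULL
  out
}

#' Correlation of each predictor with operative time or complication rank
#'
#' Pearson product-moment or Spearman rank correlation (average ranks for
#' ties) of every candidate predictor with the chosen target. Zero-variance
#' predictors get an undefined (`NA`) coefficient, flagged in the output.
#'
#' @param cohort a `wl_cohort`; for `target = "complication_rank"` the
#'   cohort must carry complication grades (see [simulate_complications()]
#'   or a `complication_grade` column in the source table).
#' @param target `"operative_time"` or `"complication_rank"`.
#' @param method `"pearson"` or `"spearman"`.
#' @return Data.frame with `variable`, `r`, `p_value`, `n`, `defined`.
#' @export
correlate_cohort <- function(cohort,
                             target = c("operative_time",
                                        "complication_rank"),
                             method = c("pearson", "spearman")) {
  stopifnot(inherits(cohort, "wl_cohort"))
  target <- match.arg(target)
  method <- match.arg(method)
  if (!target %in% names(cohort))
    stop("cohort has no '", target, "' column", call. = FALSE)
  y <- cohort[[target]]
  out <- do.call(rbind, lapply(predictor_names(), function(v) {
    x <- cohort[[v]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L)
      stop("fewer than 3 complete pairs for ", v, call. = FALSE)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(variable = v, r = NA_real_, p_value = NA_real_,
                        n = sum(ok), defined = FALSE))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
    data.frame(variable = v, r = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok), defined = TRUE,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare predictors between extreme-workload donors
#'
#' Splits out the heaviest-workload donors (operative time `>= high_min`)
#' and the lightest (`<= low_min`) and compares every predictor between the
#' two groups: Mann-Whitney U (two-sided; exact for small tie-free samples,
#' otherwise normal approximation with tie correction, per
#' [stats::wilcox.test()]) for continuous/count variables and Fisher's
#' exact test for the binary sex variable. Optionally also compares the
#' discrimination index under a supplied fitted rule.
#'
#' @param cohort a `wl_cohort`.
#' @param high_min lower bound (minutes) of the heavy group (default 240).
#' @param low_min upper bound of the light group (default 100).
#' @param model optional `nldr` fit; if given, its discrimination index is
#'   compared as an extra row.
#' @return Data.frame with `variable`, `test`, `statistic`, `p_value`,
#'   `median_high`, `median_low`, plus attributes `n_high`, `n_low`.
#' @export
compare_extremes <- function(cohort, high_min = 240, low_min = 100,
                             model = NULL) {
  stopifnot(inherits(cohort, "wl_cohort"))
  hi <- cohort$operative_time >= high_min
  lo <- cohort$operative_time <= low_min
  if (!any(hi) || !any(lo))
    stop("empty extreme group (high n=", sum(hi), ", low n=", sum(lo), ")",
         call. = FALSE)
  reg <- variable_registry()

  one <- function(v, xh, xl) {
    kind <- reg$kind[match(v, reg$name)]
    if (identical(kind, "binary")) {
      tab <- rbind(high = c(sum(xh == 1), sum(xh == 0)),
                   low = c(sum(xl == 1), sum(xl == 0)))
      ft <- stats::fisher.test(tab)
      data.frame(variable = v, test = "fisher",
                 statistic = unname(ft$estimate %||% NA_real_),
                 p_value = ft$p.value,
                 median_high = mean(xh), median_low = mean(xl),
                 stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(xh, xl, alternative = "two.sided"))
      data.frame(variable = v, test = "mann-whitney",
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 median_high = stats::median(xh),
                 median_low = stats::median(xl),
                 stringsAsFactors = FALSE)
    }
  }

  rows <- lapply(predictor_names(), function(v)
    one(v, cohort[[v]][hi], cohort[[v]][lo]))
  if ("complication_rank" %in% names(cohort))
    rows <- c(rows, list(one("complication_rank",
                             cohort$complication_rank[hi],
                             cohort$complication_rank[lo])))
  if (!is.null(model)) {
    om <- discrimination_index(model, cohort)
    rows <- c(rows, list(one("discrimination_index", om[hi], om[lo])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_high") <- sum(hi)
  attr(out, "n_low") <- sum(lo)
  out
}

#' Complication frequency across quartiles of a predictor
#'
#' Splits the cohort at the 25th/50th/75th percentiles of a predictor
#' (perinephric fat area by default), counts donors with and without a
#' complication of grade 1 or higher in each quarter, and tests the 4x2
#' table for association with Fisher's exact test (the Freeman-Halton
#' extension to r x c tables, via [stats::fisher.test()]); when the exact
#' network algorithm is infeasible the p-value is estimated by Monte Carlo
#' with the given seed.
#'
#' @param cohort a `wl_cohort` carrying `complication_rank`.
#' @param variable predictor to quartile on (default `"area_pnf"`).
#' @param simulate force Monte-Carlo p (default `FALSE`: exact enumeration,
#'   with Monte-Carlo fallback on failure).
#' @param B Monte-Carlo replicates (default 1e5).
#' @param seed seed for the Monte-Carlo path.
#' @return List with `table` (4x2 counts), `p_value`, `method`,
#'   `boundaries` (the three percentile cut points).
#' @export
quartile_complication_test <- function(cohort, variable = "area_pnf",
                                       simulate = FALSE, B = 1e5,
                                       seed = 1) {
  stopifnot(inherits(cohort, "wl_cohort"))
  if (!"complication_rank" %in% names(cohort))
    stop("cohort has no complication data", call. = FALSE)
  x <- cohort[[variable]]
  comp <- cohort$complication_rank >= 1
  q <- stats::quantile(x, c(.25, .5, .75), type = 7, names = FALSE)
  grp <- cut(x, breaks = c(-Inf, q, Inf),
             labels = c("Q1", "Q2", "Q3", "Q4"))
  tab <- table(quartile = grp, complication = factor(comp,
                                                     c(FALSE, TRUE),
                                                     c("no", "yes")))
  res <- if (simulate) NULL else tryCatch(
    stats::fisher.test(tab, workspace = 2e7), error = function(e) NULL)
  if (is.null(res)) {
    res <- .with_seed(seed,
      stats::fisher.test(tab, simulate.p.value = TRUE, B = B))
    method <- sprintf("monte-carlo (B=%g, seed=%d)", B, seed)
  } else {
    method <- "exact enumeration"
  }
  list(table = tab, p_value = res$p.value, method = method,
       boundaries = q)
}
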