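# True-hit-rate estimation ----------------------------------------------------
#
# Apparent (training-data) rates are optimistic. Two estimators of the true
# rates on future donors are provided: leave-one-out cross-validation and
# the Efron .632 bootstrap. LOOCV folds reuse the full-data sufficient
# statistics through an exact rank-one downdate of the group mean and
# scatter, so a fold costs one k x k Cholesky rather than a full refit.

# run with a temporary RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# held-out predictions for every donor; exact downdated refits
.loocv_predict <- function(X, y1, mode = "pooled", ridge = 0,
                           ids = seq_len(nrow(X))) {
  n <- nrow(X); k <- ncol(X)
  n0 <- sum(!y1); n1 <- sum(y1)
  m0 <- colMeans(X[!y1, , drop = FALSE])
  m1 <- colMeans(X[y1, , drop = FALSE])
  S0 <- crossprod(sweep(X[!y1, , drop = FALSE], 2, m0))
  S1 <- crossprod(sweep(X[y1, , drop = FALSE], 2, m1))
  Tm <- colMeans(X)
  TT <- crossprod(sweep(X, 2, Tm))
  pred <- logical(n)
  for (i in seq_len(n)) {
    x <- X[i, ]
    if (y1[i]) {
      if (n1 - 1L < 2L)
        stop("fold for donor ", ids[i], " leaves the difficult group with ",
             n1 - 1L, " member(s); LOOCV needs >= 2 per class in every fold",
             call. = FALSE)
      d <- x - m1
      mm1 <- (n1 * m1 - x) / (n1 - 1); mm0 <- m0
      SS1 <- S1 - (n1 / (n1 - 1)) * tcrossprod(d); SS0 <- S0
      nn0 <- n0; nn1 <- n1 - 1L
    } else {
      if (n0 - 1L < 2L)
        stop("fold for donor ", ids[i], " leaves the easy group with ",
             n0 - 1L, " member(s); LOOCV needs >= 2 per class in every fold",
             call. = FALSE)
      d <- x - m0
      mm0 <- (n0 * m0 - x) / (n0 - 1); mm1 <- m1
      SS0 <- S0 - (n0 / (n0 - 1)) * tcrossprod(d); SS1 <- S1
      nn0 <- n0 - 1L; nn1 <- n1
    }
    Sig <- if (mode == "pooled") {
      (SS0 + SS1) / (nn0 + nn1 - 2)
    } else {
      dt <- x - Tm
      (TT - (n / (n - 1)) * tcrossprod(dt)) / (n - 2)
    }
    if (ridge > 0) Sig <- Sig + diag(ridge, k)
    R <- .safe_chol(Sig)
    if (is.null(R))
      stop("singular covariance in the fold holding out donor ", ids[i],
           call. = FALSE)
    z0 <- backsolve(R, x - mm0, transpose = TRUE)
    z1 <- backsolve(R, x - mm1, transpose = TRUE)
    om <- log(nn1 / nn0) - 0.5 * (sum(z1^2) - sum(z0^2))
    pred[i] <- om > 0
  }
  pred
}

#' Leave-one-out cross-validated hit rates
#'
#' For each donor, the rule is refitted on the remaining n-1 donors and the
#' held-out donor is classified; the n held-out predictions are pooled into
#' one 2x2 table whose [hit_rates()] estimate the true rates. Fully
#' deterministic (no resampling).
#'
#' @inheritParams fit_nldr
#' @return The five [hit_rates()] with the pooled confusion table attached
#'   as attribute `"confusion"`.
#' @examples
#' lab <- dichotomize(simulate_cohort(n = 128, seed = 1))
#' loocv_rates(lab, "E")["total"]
#' @export
loocv_rates <- function(labeled, subset, covariance = c("pooled", "total"),
                        ridge = 0) {
  stopifnot(inherits(labeled, "wl_labeled"))
  covariance <- match.arg(covariance)
  subset <- resolve_subset(subset)
  X <- .feature_matrix(labeled, subset)
  y1 <- labeled$workload == "difficult"
  pred <- .loocv_predict(X, y1, covariance, ridge, ids = labeled$donor_id)
  ct <- confusion_table(labeled$workload,
                        ifelse(pred, "difficult", "easy"))
  structure(hit_rates(ct), confusion = ct)
}

#' .632 bootstrap estimate of the true hit rates
#'
#' Draws `n_boot` bootstrap resamples of the cohort (size n, with
#' replacement; resamples leaving fewer than `min_group` members in either
#' class are redrawn, with the redraw count reported). The rule is fitted
#' on each resample and applied only to the donors absent from it
#' (out-of-bag); out-of-bag predictions are pooled across all replicates
#' into one 2x2 table, giving out-of-bag rates `r_oob`. Each of the five
#' rates is then combined with its apparent counterpart as
#' \deqn{r_{.632} = 0.368\, r_{apparent} + 0.632\, r_{oob},}
#' correcting the optimism of the apparent rates. Reproducible given
#' `seed`; the caller's RNG stream is left untouched.
#'
#' @inheritParams fit_nldr
#' @param n_boot number of bootstrap replicates (default 200).
#' @param seed integer seed (required).
#' @param min_group minimum per-class count in a valid resample
#'   (default 2).
#' @return Object of class `wl_boot632`: list with elements `est632`,
#'   `apparent`, `oob` (five [hit_rates()] each), `oob_confusion`,
#'   `n_boot`, `seed`, `redraws`.
#' @export
boot632_rates <- function(labeled, subset, n_boot = 200, seed,
                          min_group = 2, covariance = c("pooled", "total"),
                          ridge = 0) {
  stopifnot(inherits(labeled, "wl_labeled"))
  covariance <- match.arg(covariance)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is required for the bootstrap", call. = FALSE)
  if (!is.numeric(n_boot) || n_boot < 1)
    stop("n_boot must be >= 1", call. = FALSE)
  if (!is.numeric(min_group) || min_group < 2)
    stop("min_group must be >= 2", call. = FALSE)
  subset <- resolve_subset(subset)
  X <- .feature_matrix(labeled, subset)
  y1 <- labeled$workload == "difficult"
  n <- nrow(X)

  app <- apparent_rates(labeled, subset, covariance, ridge)

  counts <- c(A = 0L, B = 0L, C = 0L, D = 0L)
  redraws <- 0L
  max_attempts <- 100 * n_boot
  .with_seed(seed, {
    b <- 0L; attempts <- 0L
    while (b < n_boot) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("exceeded bootstrap redraw limit (", max_attempts,
             " attempts); use a larger cohort or smaller min_group",
             call. = FALSE)
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y1[idx]
      if (sum(yb) < min_group || sum(!yb) < min_group) {
        redraws <- redraws + 1L
        next
      }
      core <- .nldr_core(X[idx, , drop = FALSE], yb, covariance, ridge)
      if (is.null(core)) {          # singular resample: redraw, counted
        redraws <- redraws + 1L
        next
      }
      oob <- setdiff(seq_len(n), idx)
      if (length(oob)) {
        om <- .nldr_index(core, X[oob, , drop = FALSE])
        pd <- om > 0; td <- y1[oob]
        counts <- counts + c(A = sum(pd & td), B = sum(pd & !td),
                             C = sum(!pd & td), D = sum(!pd & !td))
      }
      b <- b + 1L
    }
  })

  ctoob <- structure(as.integer(counts), names = names(counts),
                     class = "wl_confusion")
  oob <- hit_rates(ctoob)
  est <- 0.368 * unclass(app)[1:5] + 0.632 * oob
  structure(list(est632 = est, apparent = unclass(app)[1:5], oob = oob,
                 oob_confusion = ctoob, n_boot = n_boot, seed = seed,
                 redraws = redraws, subset = subset),
            class = "wl_boot632")
}

#' @export
print.wl_boot632 <- function(x, ...) {
  cat(sprintf(".632 bootstrap (%d replicates, seed %s, %d redraws)\n",
              x$n_boot, format(x$seed), x$redraws))
  m <- rbind(apparent = x$apparent, oob = x$oob, est632 = x$est632)
  print(round(m, 1))
  invisible(x)
}

#' Two-stage final model selection funnel
#'
#' Reproduces the statistical selection pipeline for the final assessment
#' rule:
#' 1. **Stage 1** — exhaustive apparent-rate search over every non-empty
#'    subset; keep the best-apparent tier (identical 2x2 table by default).
#' 2. **Stage 2** — LOOCV on the tier; keep subsets whose CV total hit rate
#'    is within `cv_band` percentage points of the best CV total.
#' 3. **Stage 3** — .632 bootstrap on the survivors; the winner is the
#'    subset with the highest .632 total hit rate (ties broken by fewer
#'    variables, then by canonical mask order).
#'
#' @inheritParams boot632_rates
#' @param cv_band stage-2 band in percentage points below the best CV total
#'   (default 1.6).
#' @param predictors predictor universe to search (default: all 16).
#' @param tier stage-1 tier definition, see [best_tier()].
#' @return Object of class `wl_funnel`: list with the fitted winning
#'   `model`, `winner` (mask + members), and per-stage tables `stage1`
#'   (search result), `stage2` (CV rates of the tier), `stage3` (.632 rates
#'   of the survivors).
#' @examples
#' \donttest{
#' lab <- dichotomize(simulate_cohort(n = 128, seed = 7))
#' sel <- select_final_model(lab, seed = 7, n_boot = 100)
#' sel$winner$members
#' }
#' @export
select_final_model <- function(labeled, cv_band = 1.6, n_boot = 200, seed,
                               min_group = 2,
                               predictors = predictor_names(),
                               covariance = c("pooled", "total"),
                               ridge = 0, tier = c("table", "total")) {
  covariance <- match.arg(covariance)
  tier <- match.arg(tier)
  if (missing(seed)) stop("an integer `seed` is required", call. = FALSE)
  predictors <- resolve_subset(predictors)

  s1 <- search_subsets(labeled, predictors, covariance, ridge)
  tier_masks <- best_tier(s1, tier)

  cv <- lapply(tier_masks, function(m)
    loocv_rates(labeled, mask_members(m, predictors), covariance, ridge))
  stage2 <- data.frame(
    mask = tier_masks,
    members = vapply(tier_masks, function(m)
      paste(mask_members(m, predictors), collapse = ","), ""),
    k = vapply(tier_masks, function(m)
      length(mask_members(m, predictors)), 0L),
    t(vapply(cv, unclass, numeric(5))),
    stringsAsFactors = FALSE)
  best_cv <- max(stage2$total)
  keep <- stage2$total >= best_cv - cv_band
  survivors <- stage2$mask[keep]

  b6 <- lapply(seq_along(survivors), function(j)
    boot632_rates(labeled, mask_members(survivors[j], predictors),
                  n_boot = n_boot, seed = seed + j - 1L,
                  min_group = min_group, covariance = covariance,
                  ridge = ridge))
  stage3 <- data.frame(
    mask = survivors,
    members = vapply(survivors, function(m)
      paste(mask_members(m, predictors), collapse = ","), ""),
    k = vapply(survivors, function(m)
      length(mask_members(m, predictors)), 0L),
    t(vapply(b6, function(b) b$est632, numeric(5))),
    stringsAsFactors = FALSE)

  ord <- order(-stage3$total, stage3$k, stage3$mask)
  win <- stage3[ord[1], ]
  model <- fit_nldr(labeled, mask_members(win$mask, predictors),
                    covariance, ridge)
  structure(list(
    model = model,
    winner = list(mask = win$mask,
                  members = mask_members(win$mask, predictors),
                  est632 = unlist(win[c("hrdc", "hrec", "sensitivity",
                                        "specificity", "total")]),
                  cv_total = stage2$total[stage2$mask == win$mask],
                  apparent_total =
                    s1$total[s1$mask == win$mask]),
    stage1 = s1, stage2 = stage2, stage3 = stage3,
    cv_band = cv_band, n_boot = n_boot, seed = seed,
    covariance = covariance, tier = tier),
    class = "wl_funnel")
}

#' @export
print.wl_funnel <- function(x, ...) {
  cat("Final-model selection funnel\n")
  cat(sprintf("  stage 1: %d subsets searched, best tier (%s) of %d\n",
              nrow(x$stage1), x$tier, nrow(x$stage2)))
  cat(sprintf("  stage 2: LOOCV band %.1f pp -> %d survivor(s)\n",
              x$cv_band, nrow(x$stage3)))
  cat(sprintf("  stage 3: .632 (B=%d) winner: {%s}\n", x$n_boot,
              paste(x$winner$members, collapse = ", ")))
  cat(sprintf("  winner totals: apparent %.1f%%, CV %.1f%%, .632 %.1f%%\n",
              x$winner$apparent_total, x$winner$cv_total,
              x$winner$est632["total"]))
  invisible(x)
}
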