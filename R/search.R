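# Exhaustive best-subset search ----------------------------------------------
#
# Subsets are encoded as bit masks over the canonical registry order of the
# 16 predictors (bit 1 = first predictor). The full space for p = 16 is
# 65,535 non-empty subsets; both the pooled and total covariance of any
# subset are submatrices of the full-panel covariance, so the search
# pre-computes full-panel sufficient statistics once.

#' Enumerate all non-empty predictor subsets
#'
#' @param p number of predictors (1..24; the guard keeps the combinatorial
#'   space enumerable).
#' @return Integer vector of the `2^p - 1` subset bit masks, in ascending
#'   mask order.
#' @examples
#' length(enumerate_subsets(16)) # 65535
#' @export
enumerate_subsets <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p != trunc(p) || p < 1 || p > 24)
    stop("p must be an integer in 1..24", call. = FALSE)
  seq_len(2L^as.integer(p) - 1L)
}

#' Convert between subset masks and predictor names
#'
#' @param mask integer bit mask over `names` (bit i = `names[i]`).
#' @param names predictor universe, default the 16-variable registry order.
#' @return `mask_members`: character vector of member names;
#'   `subset_mask`: the integer mask of a set of names.
#' @export
mask_members <- function(mask, names = predictor_names()) {
  mask <- as.integer(mask)
  if (is.na(mask) || mask < 1 || mask > 2L^length(names) - 1L)
    stop("mask out of range for ", length(names), " predictors",
         call. = FALSE)
  names[bitwAnd(mask, bitwShiftL(1L, seq_along(names) - 1L)) != 0L]
}

#' @rdname mask_members
#' @param members character vector of predictor names.
#' @export
subset_mask <- function(members, names = predictor_names()) {
  idx <- match(members, names)
  if (anyNA(idx))
    stop("unknown predictor(s): ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  sum(bitwShiftL(1L, idx - 1L))
}

#' Apparent hit rates of one subset
#'
#' Fits the rule on the full labeled cohort and scores the same cohort (the
#' training-data or "apparent" rates, which are optimistic relative to
#' performance on future donors — see [loocv_rates()] and [boot632_rates()]
#' for corrected estimates).
#'
#' @inheritParams fit_nldr
#' @return The five [hit_rates()] with the confusion table attached as
#'   attribute `"confusion"`.
#' @export
apparent_rates <- function(labeled, subset, covariance = c("pooled", "total"),
                           ridge = 0) {
  model <- fit_nldr(labeled, subset, covariance, ridge)
  ct <- confusion_table(labeled$workload, classify(model, labeled))
  structure(hit_rates(ct), confusion = ct)
}

#' Exhaustive search over every non-empty predictor subset
#'
#' Evaluates the apparent hit rates of all `2^p - 1` subsets of the 16
#' candidate predictors (or of `predictors`, if given) on a labeled cohort,
#' and identifies the best-apparent tier. Two tier definitions are
#' reported: subsets sharing the identical 2x2 table with the best subset
#' (`tier_table`), and the looser set of all subsets attaining the maximum
#' total hit rate (`tier_total`). Singular subsets are recorded with status
#' `"singular"`, never dropped silently. Output order is canonical
#' ascending-mask order regardless of evaluation strategy, so identical
#' input yields a byte-identical table.
#'
#' @inheritParams fit_nldr
#' @param predictors predictor universe to search (default: all 16).
#' @return A data.frame of class `wl_search`, one row per subset: `mask`,
#'   `mask_hex`, `members`, `k`, counts `A`..`D`, the five rates, `status`
#'   (`ok`/`singular`). Attributes: `tier_table`, `tier_total` (integer
#'   masks), `best_mask`, `best_table`.
#' @examples
#' lab <- dichotomize(simulate_cohort(n = 60, seed = 2))
#' res <- search_subsets(lab, predictors = workload_sets()$A)
#' head(res)
#' @export
search_subsets <- function(labeled, predictors = predictor_names(),
                           covariance = c("pooled", "total"), ridge = 0) {
  stopifnot(inherits(labeled, "wl_labeled"))
  covariance <- match.arg(covariance)
  predictors <- resolve_subset(predictors)
  p <- length(predictors)
  masks <- enumerate_subsets(p)

  X <- .feature_matrix(labeled, predictors)
  y1 <- labeled$workload == "difficult"
  n0 <- sum(!y1); n1 <- sum(y1)
  if (n0 < 2L || n1 < 2L)
    stop("each workload group needs at least 2 members", call. = FALSE)

  # full-panel sufficient statistics; subset covariances are submatrices
  m0 <- colMeans(X[!y1, , drop = FALSE])
  m1 <- colMeans(X[y1, , drop = FALSE])
  SigFull <- if (covariance == "pooled") {
    (crossprod(sweep(X[!y1, , drop = FALSE], 2, m0)) +
       crossprod(sweep(X[y1, , drop = FALSE], 2, m1))) / (n0 + n1 - 2)
  } else {
    stats::cov(X)
  }
  if (ridge > 0) SigFull <- SigFull + diag(ridge, p)
  lpr <- log(n1 / n0)
  bits <- bitwShiftL(1L, seq_len(p) - 1L)
  tX <- t(X)

  nmask <- length(masks)
  A <- B <- C <- D <- rep(NA_integer_, nmask)
  status <- rep("ok", nmask)
  for (m in masks) {
    idx <- which(bitwAnd(m, bits) != 0L)
    R <- .safe_chol(SigFull[idx, idx, drop = FALSE])
    if (is.null(R)) { status[m] <- "singular"; next }
    Z0 <- backsolve(R, tX[idx, , drop = FALSE] - m0[idx], transpose = TRUE)
    Z1 <- backsolve(R, tX[idx, , drop = FALSE] - m1[idx], transpose = TRUE)
    om <- lpr - 0.5 * (colSums(Z1^2) - colSums(Z0^2))
    pd <- om > 0
    A[m] <- sum(pd & y1);  B[m] <- sum(pd & !y1)
    C[m] <- sum(!pd & y1); D[m] <- sum(!pd & !y1)
  }

  n <- n0 + n1
  pct <- function(num, den) {
    r <- 100 * num / den
    r[rep_len(den <= 0, length(r))] <- NA_real_
    r
  }
  out <- data.frame(
    mask = masks,
    mask_hex = sprintf("%04x", masks),
    members = vapply(masks, function(m)
      paste(predictors[bitwAnd(m, bits) != 0L], collapse = ","), ""),
    k = vapply(masks, function(m) sum(bitwAnd(m, bits) != 0L), 0L),
    A = A, B = B, C = C, D = D,
    hrdc = pct(A, A + B), hrec = pct(D, C + D),
    sensitivity = pct(A, A + C), specificity = pct(D, B + D),
    total = pct(A + D, n),
    status = status,
    stringsAsFactors = FALSE)

  ok <- status == "ok"
  if (!any(ok))
    stop("every subset produced a singular covariance matrix", call. = FALSE)
  best_total <- max(out$total[ok])
  tier_total <- out$mask[ok & out$total == best_total]
  best_mask <- tier_total[1]  # lowest mask among the best
  bt <- unlist(out[out$mask == best_mask, c("A", "B", "C", "D")])
  tier_table <- out$mask[ok & out$A == bt["A"] & out$B == bt["B"] &
                           out$C == bt["C"] & out$D == bt["D"]]
  structure(out, class = c("wl_search", "data.frame"),
            predictors = predictors, covariance = covariance,
            tier_table = tier_table, tier_total = tier_total,
            best_mask = best_mask, best_table = bt)
}

#' Best-apparent tier of a search result
#'
#' @param result a `wl_search` table from [search_subsets()].
#' @param by `"table"` — subsets sharing the identical 2x2 confusion table
#'   with the best subset (the strict tie definition) — or `"total"` — all
#'   subsets attaining the maximum total hit rate.
#' @return Integer vector of subset masks.
#' @export
best_tier <- function(result, by = c("table", "total")) {
  stopifnot(inherits(result, "wl_search"))
  by <- match.arg(by)
  attr(result, paste0("tier_", by))
}

#' Write a search result to CSV
#'
#' @param result a `wl_search` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_search <- function(result, path) {
  stopifnot(inherits(result, "wl_search"))
  utils::write.csv(as.data.frame(result), path, row.names = FALSE, na = "")
  invisible(path)
}
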