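# Internal fast core ---------------------------------------------------------
#
# The hot paths (65,535-subset search, leave-one-out folds, bootstrap
# replicates) work on plain matrices through these helpers; the exported
# fit_nldr()/predict() surface wraps them with validation and labels.

# Cholesky with a singularity guard: exact duplicates or constant columns
# make the numeric chol pivot collapse without always erroring, so factors
# whose diagonal spans more than ~7 orders of magnitude are treated as
# singular rather than silently inverted.
.safe_chol <- function(Sig) {
  R <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  d <- diag(R)
  if (min(d) <= 1e-7 * max(d)) return(NULL)
  R
}

# X: numeric matrix (n x k); y1: logical, TRUE = difficult (G1)
# mode: "pooled" (within-group, df n-2) or "total" (all vectors combined)
# Returns NULL when a group has < 2 members or the covariance is singular
# (unless ridge > 0 rescues it).
.nldr_core <- function(X, y1, mode = "pooled", ridge = 0) {
  n0 <- sum(!y1); n1 <- sum(y1)
  if (n0 < 2L || n1 < 2L) return(NULL)
  m0 <- colMeans(X[!y1, , drop = FALSE])
  m1 <- colMeans(X[y1, , drop = FALSE])
  if (mode == "pooled") {
    S0 <- crossprod(sweep(X[!y1, , drop = FALSE], 2, m0))
    S1 <- crossprod(sweep(X[y1, , drop = FALSE], 2, m1))
    Sig <- (S0 + S1) / (n0 + n1 - 2)
  } else {
    Sig <- stats::cov(X)
  }
  if (ridge > 0) Sig <- Sig + diag(ridge, ncol(X))
  R <- .safe_chol(Sig)
  if (is.null(R)) return(NULL)
  list(m0 = m0, m1 = m1, Sig = Sig, R = R,
       n0 = n0, n1 = n1, lpr = log(n1 / n0))
}

# discrimination index for rows of X given a core; vectorised over rows
.nldr_index <- function(core, X) {
  Z0 <- backsolve(core$R, t(X) - core$m0, transpose = TRUE)
  Z1 <- backsolve(core$R, t(X) - core$m1, transpose = TRUE)
  core$lpr - 0.5 * (colSums(Z1^2) - colSums(Z0^2))
}

# labeled cohort -> feature matrix on a canonical-name subset
.feature_matrix <- function(cohort, subset) {
  X <- as.matrix(as.data.frame(cohort)[, subset, drop = FALSE])
  if (anyNA(X)) {
    bad <- subset[colSums(is.na(X)) > 0]
    stop("missing predictor value(s) in: ", paste(bad, collapse = ", "),
         "; records with missing predictors cannot enter model fitting",
         call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

# Exported surface ------------------------------------------------------------

#' Fit the normal-based linear discriminant rule
#'
#' Fits the two-class Gaussian classifier with shared covariance: per-group
#' mean vectors mu_easy/mu_difficult, a shared covariance matrix Sigma, and
#' prior probabilities pi_i = n_i / (n_0 + n_1) taken from the group sizes.
#' A donor with feature vector x receives the discrimination index
#' \deqn{\Omega(x) = \log(\pi_1/\pi_0) - \tfrac12\{\Delta(x;\mu_1,\Sigma) -
#'   \Delta(x;\mu_0,\Sigma)\}}
#' where \eqn{\Delta} is the squared Mahalanobis distance; positive
#' \eqn{\Omega} means predicted difficult.
#'
#' @param labeled a `wl_labeled` cohort (see [dichotomize()]).
#' @param subset predictors to use: canonical names, published aliases, a
#'   comma-separated string, a named set letter (`"A"`..`"E"`), or a bit
#'   mask over the registry order.
#' @param covariance `"pooled"` (default) — pooled within-group covariance
#'   \eqn{[(n_0-1)S_0 + (n_1-1)S_1]/(n_0+n_1-2)} — or `"total"`, the
#'   covariance of all feature vectors from both groups combined.
#' @param ridge nonnegative ridge term added to the diagonal of Sigma
#'   (default 0: a singular covariance is an explicit error, never a silent
#'   pseudo-inverse).
#' @return An object of class `nldr` with components `subset`, `mu_easy`,
#'   `mu_difficult`, `sigma`, `prior_easy`, `prior_difficult`, `n_easy`,
#'   `n_difficult`, `covariance`, `ridge`, `threshold_min`.
#' @examples
#' lab <- dichotomize(simulate_cohort(n = 128, seed = 1))
#' fit <- fit_nldr(lab, "E")
#' fit
#' @export
fit_nldr <- function(labeled, subset, covariance = c("pooled", "total"),
                     ridge = 0) {
  stopifnot(inherits(labeled, "wl_labeled"))
  covariance <- match.arg(covariance)
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0)
    stop("ridge must be a single nonnegative number", call. = FALSE)
  subset <- resolve_subset(subset)
  X <- .feature_matrix(labeled, subset)
  y1 <- labeled$workload == "difficult"
  n0 <- sum(!y1); n1 <- sum(y1)
  if (n0 < 2L || n1 < 2L)
    stop("each workload group needs at least 2 members to fit (easy: ",
         n0, ", difficult: ", n1, ")", call. = FALSE)
  core <- .nldr_core(X, y1, covariance, ridge)
  if (is.null(core))
    stop("singular covariance matrix for subset {",
         paste(subset, collapse = ", "),
         "}; remove collinear/constant variables or set ridge > 0",
         call. = FALSE)
  structure(
    list(subset = subset,
         mu_easy = core$m0, mu_difficult = core$m1,
         sigma = core$Sig,
         prior_easy = n0 / (n0 + n1), prior_difficult = n1 / (n0 + n1),
         n_easy = n0, n_difficult = n1,
         covariance = covariance, ridge = ridge,
         threshold_min = attr(labeled, "threshold_min")),
    class = "nldr")
}

#' @export
print.nldr <- function(x, ...) {
  cat("Normal-based linear discriminant rule\n")
  cat(sprintf("  predictors (%d): %s\n", length(x$subset),
              paste(x$subset, collapse = ", ")))
  cat(sprintf("  groups: easy n=%d (prior %.4f), difficult n=%d (prior %.4f)\n",
              x$n_easy, x$prior_easy, x$n_difficult, x$prior_difficult))
  cat(sprintf("  covariance: %s%s; workload threshold %g min\n",
              x$covariance,
              if (x$ridge > 0) sprintf(" (ridge %g)", x$ridge) else "",
              x$threshold_min %||% NA))
  invisible(x)
}

#' Squared Mahalanobis distance
#'
#' \eqn{\Delta(x; \mu, \Sigma) = (x-\mu)' \Sigma^{-1} (x-\mu)}, the squared
#' statistical distance of a feature vector from a group mean. Zero iff
#' `x == mu`.
#'
#' @param x numeric vector, or matrix with one feature vector per row.
#' @param mu mean vector.
#' @param sigma positive-definite covariance matrix.
#' @return Nonnegative scalar (or vector, one per row of `x`).
#' @examples
#' mahalanobis_sq(c(3, 4), c(0, 0), diag(2)) # 25
#' @export
mahalanobis_sq <- function(x, mu, sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(mu) || !all(dim(sigma) == length(mu)))
    stop("dimension mismatch between x, mu and sigma", call. = FALSE)
  R <- tryCatch(chol(sigma), error = function(e)
    stop("sigma is not positive definite", call. = FALSE))
  Z <- backsolve(R, t(x) - mu, transpose = TRUE)
  colSums(Z^2)
}

#' Discrimination index of donors under a fitted rule
#'
#' The continuous workload score: log prior odds of the difficult group
#' minus half the difference of squared Mahalanobis distances to the two
#' group means. Positive values predict a difficult (heavy-workload) case;
#' the magnitude grades how far the donor sits from the decision boundary.
#'
#' @param model an `nldr` fit.
#' @param newdata a `wl_cohort`/data.frame with the model's predictors, or a
#'   named numeric vector for a single donor.
#' @return Numeric vector of indices.
#' @export
discrimination_index <- function(model, newdata) {
  stopifnot(inherits(model, "nldr"))
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    miss <- setdiff(model$subset, names(newdata))
    if (length(miss))
      stop("missing feature(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    newdata <- as.data.frame(as.list(newdata[model$subset]))
  }
  miss <- setdiff(model$subset, names(newdata))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  X <- .feature_matrix(newdata, model$subset)
  R <- chol(model$sigma)
  Z0 <- backsolve(R, t(X) - model$mu_easy, transpose = TRUE)
  Z1 <- backsolve(R, t(X) - model$mu_difficult, transpose = TRUE)
  log(model$prior_difficult / model$prior_easy) -
    0.5 * (colSums(Z1^2) - colSums(Z0^2))
}

#' Classify donors as difficult or easy
#'
#' Assigns `difficult` when the discrimination index is strictly positive
#' and `easy` otherwise (an exact zero — a measure-zero event — is assigned
#' `easy`, the fixed tie rule).
#'
#' @inheritParams discrimination_index
#' @return Factor with levels `easy`, `difficult`.
#' @export
classify <- function(model, newdata) {
  om <- discrimination_index(model, newdata)
  factor(ifelse(om > 0, "difficult", "easy"),
         levels = c("easy", "difficult"))
}

#' @rdname classify
#' @param object an `nldr` fit.
#' @param type `"class"`, `"index"`, or `"both"` (data.frame with both).
#' @param ... unused.
#' @export
predict.nldr <- function(object, newdata, type = c("class", "index", "both"),
                         ...) {
  type <- match.arg(type)
  switch(type,
    class = classify(object, newdata),
    index = discrimination_index(object, newdata),
    both  = {
      om <- discrimination_index(object, newdata)
      data.frame(index = om,
                 class = factor(ifelse(om > 0, "difficult", "easy"),
                                levels = c("easy", "difficult")))
    })
}

# Confusion table and hit rates ----------------------------------------------

#' Two-by-two discriminant table
#'
#' Cross-tabulates predictions against true workload labels using the
#' conventional layout: A = predicted difficult & truly difficult, B =
#' predicted difficult & easy, C = predicted easy & difficult, D = predicted
#' easy & easy.
#'
#' @param truth factor/character of true labels (`easy`/`difficult`).
#' @param predicted factor/character of predicted labels, same length.
#' @return Object of class `wl_confusion`: named integer vector
#'   `c(A=, B=, C=, D=)`.
#' @export
confusion_table <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length", call. = FALSE)
  truth <- factor(as.character(truth), levels = c("easy", "difficult"))
  predicted <- factor(as.character(predicted), levels = c("easy", "difficult"))
  if (anyNA(truth) || anyNA(predicted))
    stop("labels must be 'easy' or 'difficult'", call. = FALSE)
  td <- truth == "difficult"; pd <- predicted == "difficult"
  structure(c(A = sum(pd & td), B = sum(pd & !td),
              C = sum(!pd & td), D = sum(!pd & !td)),
            class = "wl_confusion")
}

#' @export
print.wl_confusion <- function(x, ...) {
  m <- matrix(c(x["A"], x["B"], x["C"], x["D"]), 2, byrow = TRUE,
              dimnames = list(c("predicted difficult", "predicted easy"),
                              c("difficult", "easy")))
  print(m)
  invisible(x)
}

#' Five hit rates of a discriminant table
#'
#' From the 2x2 counts (A, B, C, D) computes, as percentages:
#' * `hrdc` — hit rate of difficult cases, A/(A+B): how often a "difficult"
#'   call is right;
#' * `hrec` — hit rate of easy cases, D/(C+D);
#' * `sensitivity` — A/(A+C); `specificity` — D/(B+D);
#' * `total` — (A+D)/n, the total hit rate (accuracy).
#'
#' A rate whose denominator is zero is undefined and returned as `NA`.
#'
#' @param x a `wl_confusion`, or a numeric vector/list with elements
#'   A, B, C, D.
#' @return Named numeric vector of the five rates in percent (full
#'   precision; round for display).
#' @examples
#' hit_rates(c(A = 5, B = 1, C = 16, D = 106))
#' @export
hit_rates <- function(x) {
  x <- unlist(x)[c("A", "B", "C", "D")]
  if (anyNA(x) || any(x < 0))
    stop("x must contain nonnegative counts A, B, C, D", call. = FALSE)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(hrdc        = rate(x["A"], x["A"] + x["B"]),
    hrec        = rate(x["D"], x["C"] + x["D"]),
    sensitivity = rate(x["A"], x["A"] + x["C"]),
    specificity = rate(x["D"], x["B"] + x["D"]),
    total       = rate(x["A"] + x["D"], sum(x))) -> out
  names(out) <- c("hrdc", "hrec", "sensitivity", "specificity", "total")
  out
}

# Serialization ---------------------------------------------------------------

#' Save / load a fitted rule as JSON
#'
#' The model file is plain JSON holding the subset, group means, covariance,
#' priors, covariance mode and training metadata, written at full double
#' precision so that save/load round-trips exactly.
#'
#' @param model an `nldr` fit.
#' @param path file path for the JSON model file.
#' @return `save_nldr` returns `path` invisibly; `load_nldr` returns the
#'   `nldr` object.
#' @export
save_nldr <- function(model, path) {
  stopifnot(inherits(model, "nldr"))
  obj <- list(
    format = "surgworkload/nldr", version = 1L,
    subset = model$subset,
    mu_easy = unname(model$mu_easy),
    mu_difficult = unname(model$mu_difficult),
    sigma = unname(model$sigma),
    prior_easy = model$prior_easy, prior_difficult = model$prior_difficult,
    n_easy = model$n_easy, n_difficult = model$n_difficult,
    covariance = model$covariance, ridge = model$ridge,
    threshold_min = model$threshold_min)
  # 17 significant digits: JSON text reparses to bit-identical doubles
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname save_nldr
#' @export
load_nldr <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "surgworkload/nldr"))
    stop(path, " is not an nldr model file", call. = FALSE)
  k <- length(obj$subset)
  structure(
    list(subset = obj$subset,
         mu_easy = stats::setNames(obj$mu_easy, obj$subset),
         mu_difficult = stats::setNames(obj$mu_difficult, obj$subset),
         sigma = matrix(unlist(obj$sigma), k, k,
                        dimnames = list(obj$subset, obj$subset)),
         prior_easy = obj$prior_easy, prior_difficult = obj$prior_difficult,
         n_easy = obj$n_easy, n_difficult = obj$n_difficult,
         covariance = obj$covariance, ridge = obj$ridge,
         threshold_min = obj$threshold_min),
    class = "nldr")
}
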