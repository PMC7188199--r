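test_that("mahalanobis_sq matches trivial cases and a linear-solve oracle", {
  expect_equal(mahalanobis_sq(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(mahalanobis_sq(c(3, 4), c(0, 0), diag(2)), 25)
  set.seed(7)
  for (rep in 1:5) {
    k <- 5
    A <- matrix(rnorm(k * k), k)
    Sig <- crossprod(A) + diag(k)
    x <- rnorm(k); mu <- rnorm(k)
    oracle <- drop(t(x - mu) %*% solve(Sig, x - mu))
    expect_equal(mahalanobis_sq(x, mu, Sig), oracle,
                 tolerance = 1e-10)
  }
  expect_error(mahalanobis_sq(c(1, 2, 3), c(0, 0), diag(2)),
               "dimension mismatch")
})

test_that("fit_nldr stores group means, shared covariance and exact priors", {
  lab <- dichotomize(tiny_cohort(), 210)
  fit <- fit_nldr(lab, c("area_pnf", "number_ra"))
  expect_s3_class(fit, "nldr")
  expect_equal(fit$prior_difficult, 3 / 12)
  expect_equal(fit$prior_easy + fit$prior_difficult, 1)
  hard <- lab$workload == "difficult"
  expect_equal(unname(fit$mu_difficult["area_pnf"]),
               mean(lab$area_pnf[hard]))
  # pooled within-group covariance, df n-2, in the model's feature order
  M <- as.matrix(as.data.frame(lab)[, fit$subset])
  s0 <- cov(M[!hard, ]); s1 <- cov(M[hard, ])
  pooled <- ((sum(!hard) - 1) * s0 + (sum(hard) - 1) * s1) / (12 - 2)
  expect_equal(unname(fit$sigma), unname(pooled), tolerance = 1e-12)
  expect_true(isSymmetric(fit$sigma))
  expect_true(all(eigen(fit$sigma, only.values = TRUE)$values > 0))
})

test_that("degenerate fits error usefully; ridge rescues a constant column", {
  lab <- dichotomize(tiny_cohort(), 210)
  one_hard <- dichotomize(tiny_cohort(), 300)  # single difficult donor
  expect_error(suppressWarnings(fit_nldr(one_hard, "area_pnf")),
               "at least 2 members")
  cc <- as.data.frame(tiny_cohort())
  cc$thick_scf <- 5  # zero variance
  labc <- dichotomize(as_cohort(cc), 210)
  expect_error(fit_nldr(labc, c("area_pnf", "thick_scf")), "singular")
  expect_s3_class(fit_nldr(labc, c("area_pnf", "thick_scf"), ridge = 1e-6),
                  "nldr")
})

test_that("identical groups give a constant index equal to the log prior odds", {
  df <- as.data.frame(tiny_cohort())
  dup <- rbind(df, df)
  dup$donor_id <- sprintf("X%02d", seq_len(nrow(dup)))
  dup$operative_time <- rep(c(100, 250), each = nrow(df)) # label split only
  lab <- dichotomize(as_cohort(dup), 210)
  fit <- fit_nldr(lab, c("area_pnf", "age"))
  om <- discrimination_index(fit, lab)
  expect_equal(om, rep(log(fit$prior_difficult / fit$prior_easy),
                       nrow(dup)), tolerance = 1e-9)
})

test_that("index is zero at the equal-prior midpoint and negative at mu_easy", {
  lab <- dichotomize(tiny_cohort(), 160)  # 6 / 6 split -> equal priors
  fit <- fit_nldr(lab, c("area_pnf", "age", "body_weight"))
  expect_equal(fit$prior_easy, 0.5)
  mid <- (fit$mu_easy + fit$mu_difficult) / 2
  expect_equal(unname(discrimination_index(fit, mid)), 0,
               tolerance = 1e-10)
  at_mu0 <- discrimination_index(fit, fit$mu_easy)
  expect_equal(unname(at_mu0),
               -0.5 * unname(mahalanobis_sq(fit$mu_easy,
                                            fit$mu_difficult, fit$sigma)))
  expect_lt(at_mu0, 0)
})

test_that("classification follows the sign of the index with easy ties", {
  lab <- dichotomize(tiny_cohort(), 210)
  fit <- fit_nldr(lab, c("area_pnf", "number_ra"))
  om <- discrimination_index(fit, lab)
  cls <- classify(fit, lab)
  expect_equal(as.character(cls),
               ifelse(om > 0, "difficult", "easy"))
  # the tie rule: an index of exactly zero is assigned easy; a symmetric
  # hand-built model computes Omega = 0 exactly in floating point
  sym <- structure(list(subset = "area_pnf",
                        mu_easy = c(area_pnf = -1),
                        mu_difficult = c(area_pnf = 1),
                        sigma = matrix(1, dimnames =
                                         list("area_pnf", "area_pnf")),
                        prior_easy = 0.5, prior_difficult = 0.5,
                        n_easy = 10L, n_difficult = 10L,
                        covariance = "pooled", ridge = 0,
                        threshold_min = 210), class = "nldr")
  expect_identical(unname(discrimination_index(sym, c(area_pnf = 0))), 0)
  expect_equal(as.character(classify(sym, c(area_pnf = 0))), "easy")
  expect_error(discrimination_index(fit, c(area_pnf = 3)), "number_ra")
})

test_that("the rule is invariant to affine maps of the feature space", {
  lab <- dichotomize(simulate_cohort(n = 80, seed = 3), 210)
  vars <- c("area_pnf", "thick_scf", "age", "body_weight")
  fit <- fit_nldr(lab, vars)
  om <- discrimination_index(fit, lab)
  set.seed(1)
  L <- matrix(rnorm(16), 4); while (abs(det(L)) < 0.1)
    L <- matrix(rnorm(16), 4)
  b <- rnorm(4)
  df <- as.data.frame(lab)
  df[vars] <- sweep(as.matrix(df[vars]) %*% t(L), 2, b, "+")
  lab2 <- dichotomize(as_cohort(df), 210)
  fit2 <- fit_nldr(lab2, vars)
  om2 <- discrimination_index(fit2, lab2)
  expect_equal(om2, om, tolerance = 1e-8)
})

test_that("raising the difficult prior never flips a prediction to easy", {
  lab <- dichotomize(simulate_cohort(n = 80, seed = 4), 210)
  fit <- fit_nldr(lab, c("area_pnf", "number_ra", "age"))
  om <- discrimination_index(fit, lab)
  for (shift in c(0.2, 0.5, 0.8)) {
    fit2 <- fit
    p1 <- min(0.99, fit$prior_difficult + shift)
    fit2$prior_difficult <- p1
    fit2$prior_easy <- 1 - p1
    om2 <- discrimination_index(fit2, lab)
    expect_true(all(om2 >= om - 1e-12))
    expect_true(all(which(om > 0) %in% which(om2 > 0)))
  }
})

test_that("classify agrees with the reference shared-covariance LDA", {
  # dual route: our Mahalanobis-index rule vs MASS::lda posterior rule
  set.seed(20)
  n <- 200
  mu0 <- c(0, 0, 0); mu1 <- c(1, .5, -.7)
  A <- matrix(rnorm(9), 3); Sig <- crossprod(A) + diag(3)
  y <- rbinom(n, 1, 0.3)
  X <- t(vapply(y, function(yi)
    MASS::mvrnorm(1, if (yi) mu1 else mu0, Sig), numeric(3)))
  df <- data.frame(X)
  ref <- MASS::lda(X, grouping = y)
  ref_cls <- as.integer(as.character(predict(ref, X)$class))

  df_full <- as.data.frame(simulate_cohort(n = n, seed = 21))
  df_full$age <- X[, 1]; df_full$body_weight <- X[, 2]
  df_full$body_height <- X[, 3]
  df_full$operative_time <- ifelse(y == 1, 250, 150)
  lab <- dichotomize(as_cohort(df_full), 210)
  fit <- fit_nldr(lab, c("age", "body_weight", "body_height"))
  om <- discrimination_index(fit, lab)
  ours <- as.integer(om > 0)
  decided <- abs(om) > 1e-9
  expect_true(all(ours[decided] == ref_cls[decided]))
})

test_that("confusion table and the five hit rates match their definitions", {
  ct <- confusion_table(
    truth = c("difficult", "difficult", "easy", "easy", "easy"),
    predicted = c("difficult", "easy", "easy", "easy", "difficult"))
  expect_equal(unclass(ct), c(A = 1L, B = 1L, C = 1L, D = 2L))
  expect_error(confusion_table(c("easy"), c("easy", "easy")),
               "same length")

  hr <- hit_rates(c(A = 5, B = 1, C = 16, D = 106))
  expect_equal(unname(hr["hrdc"]), 100 * 5 / 6, tolerance = 1e-12)
  expect_equal(unname(hr["hrec"]), 100 * 106 / 122, tolerance = 1e-12)
  expect_equal(unname(hr["sensitivity"]), 100 * 5 / 21, tolerance = 1e-12)
  expect_equal(unname(hr["specificity"]), 100 * 106 / 107,
               tolerance = 1e-12)
  expect_equal(unname(hr["total"]), 100 * 111 / 128, tolerance = 1e-12)

  # perfect and degenerate tables
  expect_true(all(hit_rates(c(A = 21, B = 0, C = 0, D = 107)) == 100))
  hr0 <- hit_rates(c(A = 0, B = 0, C = 21, D = 107))
  expect_true(is.na(hr0["hrdc"]))
  expect_equal(unname(hr0["total"]), 100 * 107 / 128, tolerance = 1e-12)
})

test_that("perfect predictions give 100% total for any labeling", {
  set.seed(5)
  for (rep in 1:10) {
    lab <- sample(c("easy", "difficult"), 30, replace = TRUE)
    hr <- hit_rates(confusion_table(lab, lab))
    expect_equal(unname(hr["total"]), 100)
  }
})

test_that("model save/load round-trips exactly through JSON", {
  lab <- dichotomize(tiny_cohort(), 210)
  fit <- fit_nldr(lab, c("area_pnf", "number_ra", "age"))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  save_nldr(fit, f)
  fit2 <- load_nldr(f)
  expect_identical(fit2$subset, fit$subset)
  expect_identical(fit2$mu_easy, fit$mu_easy)
  expect_identical(fit2$mu_difficult, fit$mu_difficult)
  expect_identical(unname(fit2$sigma), unname(fit$sigma))
  expect_identical(fit2$prior_difficult, fit$prior_difficult)
  om1 <- discrimination_index(fit, lab)
  om2 <- discrimination_index(fit2, lab)
  expect_identical(om1, om2)
})
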