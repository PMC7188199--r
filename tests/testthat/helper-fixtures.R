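# Shared fixtures, all built in code at test time.

# A tiny hand-made cohort (12 donors) with all canonical columns; operative
# times straddle the 210-min boundary (3 difficult, 9 easy).
tiny_cohort <- function() {
  # hand-picked irregular values: no two columns are collinear
  df <- data.frame(
    donor_id = sprintf("T%02d", 1:12),
    operative_time = c(120, 150, 210, 95, 300, 140, 180, 160, 240, 130,
                       175, 155),
    sex_male = c(1, 0, 1, 0, 1, 0, 0, 1, 1, 0, 1, 0),
    age = c(34, 52, 61, 28, 66, 45, 57, 39, 63, 48, 55, 42),
    body_weight = c(52, 68, 75, 47, 88, 58, 71, 64, 81, 55, 62, 60),
    body_height = c(158, 171, 165, 152, 176, 160, 168, 173, 169, 155,
                    163, 161),
    total_protein = c(6.8, 7.2, 7.5, 6.5, 7.9, 7.0, 7.3, 6.9, 7.6, 6.7,
                      7.1, 7.4),
    albumin = c(4.1, 4.5, 4.0, 4.6, 3.8, 4.3, 4.2, 4.7, 3.9, 4.4, 4.0,
                4.5),
    triglyceride = c(88, 140, 210, 65, 320, 110, 175, 95, 260, 130, 150,
                     105),
    total_cholesterol = c(172, 205, 231, 158, 255, 190, 218, 180, 240,
                          198, 210, 165),
    number_ra = c(1, 1, 2, 1, 3, 1, 2, 1, 2, 1, 1, 1),
    maxthick_mpf = c(3.1, 6.4, 11.2, 2.2, 18.5, 4.8, 9.1, 5.5, 14.3,
                     3.9, 7.6, 6.0),
    medthick_mpf = c(2.0, 5.1, 9.8, 1.4, 16.2, 3.6, 7.9, 4.2, 12.5, 2.8,
                     6.3, 4.9),
    medthick_lpf = c(6.5, 11.0, 17.4, 4.2, 28.9, 8.8, 14.6, 10.1, 22.3,
                     7.4, 12.9, 9.5),
    area_pnf = c(3, 5, 25, 2, 40, 6, 15, 8, 30, 4, 10, 7),
    ctv_pnf = c(-96, -88, -74, -100, -62, -91, -80, -85, -70, -94, -83,
                -78),
    thick_scf = c(9.5, 18.2, 12.7, 22.4, 7.1, 15.8, 20.3, 11.4, 14.9,
                  24.6, 16.5, 10.8),
    area_scf = c(48, 95, 70, 122, 38, 84, 110, 62, 77, 135, 90, 55))
  as_cohort(df, provenance = "tiny fixture")
}

# Well-separated two-class Gaussian cohort on a small predictor panel:
# difficult cases shifted by `delta` on the panel variables.
separated_cohort <- function(n = 60, delta = 8, seed = 99) {
  set.seed(seed)
  base <- as.data.frame(simulate_cohort(n = n, seed = seed))
  hard <- base$operative_time >= stats::quantile(base$operative_time, .8)
  base$area_pnf <- rnorm(n) + delta * hard
  base$number_ra <- pmax(1, round(1 + rnorm(n, sd = .3) + 2 * hard))
  base$operative_time <- ifelse(hard, 260, 140) + rnorm(n, sd = 5)
  as_cohort(base, provenance = "separated fixture")
}

expect_rates_equal <- function(a, b, tol = 1e-10) {
  expect_equal(unclass(a)[1:5], unclass(b)[1:5], tolerance = tol)
}
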