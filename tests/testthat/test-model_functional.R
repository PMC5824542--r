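grid24 <- seq(0, 24, length.out = 101)

# an fpca_fit assembled by hand from a known rank-1 truth
manual_rank1_fit <- function(lambda = 3, sigma2 = 1e-6) {
  w <- growthsel:::trapezoid_weights(grid24)
  phi <- sin(pi * grid24 / 24)
  phi <- phi / sqrt(sum(w * phi^2))
  structure(list(grid = grid24,
                 mean_values = 50 + grid24,
                 cov_values = lambda * outer(phi, phi),
                 eigenfunctions = matrix(phi, ncol = 1),
                 eigenvalues = lambda, sigma2 = sigma2, pve = 0.99, K = 1L),
            class = "fpca_fit")
}

test_that("mean smoothing reproduces flat and linear signals and refuses to extrapolate", {
  d <- as_growth_dataset(tibble::tibble(
    subject_id = rep(sprintf("s%d", 1:10), each = 8),
    sex = 0L, age = rep(seq(0.5, 23.5, length.out = 8), 10), height = 60))
  expect_equal(smooth_mean(d, seq(1, 23, by = 1)), rep(60, 23), tolerance = 1e-8)
  d2 <- d
  d2$height <- 50 + 1.5 * d2$age
  expect_equal(smooth_mean(d2, seq(1, 23, by = 1)), 50 + 1.5 * (1:23),
               tolerance = 1e-6)
  expect_error(smooth_mean(d, c(0, 24)), "outside",
               class = "growthsel_domain_error")
})

test_that("mean smoothing recovers a curved growth mean from noisy data", {
  spec <- cohort_spec(n_subjects = 200, eigenfunctions = list(),
                      lambda = numeric(0), sex_effect = 0, noise_sd = 0.1,
                      seed = 3)
  sim <- simulate_cohort(spec)
  g <- seq(min(sim$data$age), max(sim$data$age), length.out = 60)
  expect_lt(max(abs(smooth_mean(sim$data, g) - spec$mean_curve(g))), 0.5)
})

test_that("covariance smoothing separates signal from noise", {
  # no subject deviations: surface ~ 0, sigma2 ~ noise variance
  spec0 <- cohort_spec(n_subjects = 300, eigenfunctions = list(),
                       lambda = numeric(0), sex_effect = 0, noise_sd = 0.5,
                       seed = 5)
  sim0 <- simulate_cohort(spec0)
  g <- seq(min(sim0$data$age), max(sim0$data$age), length.out = 41)
  mv <- smooth_mean(sim0$data, g)
  cv <- smooth_covariance(sim0$data, mv, g)
  expect_identical(cv$cov_values, t(cv$cov_values))
  expect_lt(max(abs(cv$cov_values)), 0.1)
  expect_gt(cv$sigma2, 0.15); expect_lt(cv$sigma2, 0.35)
  # rank-1 truth: leading eigenvalue of the surface near lambda1
  phi1 <- function(t) rep(1 / sqrt(24), length(t))
  spec1 <- cohort_spec(n_subjects = 300, eigenfunctions = list(phi1),
                       lambda = 4, sex_effect = 0, seed = 6)
  sim1 <- simulate_cohort(spec1)
  g1 <- seq(min(sim1$data$age), max(sim1$data$age), length.out = 41)
  mv1 <- smooth_mean(sim1$data, g1)
  cv1 <- smooth_covariance(sim1$data, mv1, g1)
  ed <- eigendecompose(cv1$cov_values, g1, pve = 0.99)
  expect_lt(abs(ed$eigenvalues[1] - 4) / 4, 0.2)
})

test_that("eigendecomposition recovers constructed spectra", {
  fitr <- manual_rank1_fit(lambda = 3)
  ed <- eigendecompose(fitr$cov_values, grid24, pve = 0.99)
  expect_equal(ed$eigenvalues[1], 3, tolerance = 1e-8)
  expect_lt(min(max(abs(ed$eigenfunctions[, 1] - fitr$eigenfunctions[, 1])),
                max(abs(ed$eigenfunctions[, 1] + fitr$eigenfunctions[, 1]))),
            1e-8)
  # sign convention: nonnegative integral
  w <- growthsel:::trapezoid_weights(grid24)
  expect_gte(sum(w * ed$eigenfunctions[, 1]), 0)
  # two-component surface and the pve boundary
  phi2 <- (grid24 - 12); phi2 <- phi2 / sqrt(sum(w * phi2^2))
  C2 <- 3 * outer(fitr$eigenfunctions[, 1], fitr$eigenfunctions[, 1]) +
    0.5 * outer(phi2, phi2)
  ed_all <- eigendecompose(C2, grid24, pve = 1.0)
  expect_equal(ed_all$eigenvalues[1:2], c(3, 0.5), tolerance = 1e-8)
  ed_small <- eigendecompose(C2, grid24, pve = 0.8)
  expect_equal(length(ed_small$eigenvalues), 1L)
  expect_error(eigendecompose(-C2, grid24, 0.99), "degenerate",
               class = "growthsel_fit_error")
})

test_that("conditional scoring shrinks, centers and recovers true scores", {
  fitr <- manual_rank1_fit(lambda = 3, sigma2 = 1e-6)
  ages <- seq(2, 22, length.out = 12)
  mu_o <- approx(grid24, fitr$mean_values, xout = ages)$y
  # data on the mean -> zero scores
  expect_equal(score_subject(fitr, list(age = ages, height = mu_o)), 0,
               tolerance = 1e-10, ignore_attr = TRUE)
  # noiseless single-component data -> score recovered within 2%
  phi_o <- approx(grid24, fitr$eigenfunctions[, 1], xout = ages)$y
  xi_true <- 1.7
  sc <- score_subject(fitr, list(age = ages, height = mu_o + xi_true * phi_o))
  expect_lt(abs(sc[1] - xi_true) / xi_true, 0.02)
  # huge noise variance -> shrink to zero
  noisy <- manual_rank1_fit(lambda = 3, sigma2 = 1e8)
  sc2 <- score_subject(noisy, list(age = ages, height = mu_o + xi_true * phi_o))
  expect_lt(abs(sc2[1]), 1e-4)
  # no observations -> population flag
  sc3 <- score_subject(fitr, list(age = numeric(0), height = numeric(0)))
  expect_true(attr(sc3, "population"))
  expect_equal(as.numeric(sc3), 0)
})

test_that("trajectory reconstruction is exact and linear in the scores", {
  fitr <- manual_rank1_fit(lambda = 3)
  expect_equal(predict_fpca(fitr, 0, grid24), fitr$mean_values)
  at <- grid24[c(10, 55)]
  expect_equal(predict_fpca(fitr, 2, at),
               fitr$mean_values[c(10, 55)] + 2 * fitr$eigenfunctions[c(10, 55), 1])
  d1 <- predict_fpca(fitr, 1.3, at) - fitr$mean_values[c(10, 55)]
  d2 <- predict_fpca(fitr, 2.6, at) - fitr$mean_values[c(10, 55)]
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_error(predict_fpca(fitr, 0, c(12, 25)), "outside",
               class = "growthsel_extrapolation_error")
})

test_that("a full fPCA fit is deterministic and reconstructs rank-2 truth", {
  spec <- cohort_spec(n_subjects = 215, sex_effect = 0, noise_sd = 1e-4,
                      seed = 17)
  sim <- simulate_cohort(spec)
  f1 <- fit_fpca(sim$data)
  f2 <- fit_fpca(sim$data)
  expect_identical(f1$eigenvalues, f2$eigenvalues)
  expect_identical(f1$scores, f2$scores)
  # near-noiseless rank-2 data: per-subject curves reproduced on their ages
  err <- vapply(sim$truth$subject_ids[1:50], function(id) {
    sv <- subject_view(sim$data, id)
    xi <- score_subject(f1, sv)
    max(abs(predict_fpca(f1, xi, sv$age) - sv$height))
  }, numeric(1))
  expect_lt(max(err), 0.2)
})

test_that("in training, conditional fPCA predictions beat the population mean", {
  sim <- small_cohort(n = 40, seed = 23, sex_effect = 0)
  fit <- fit_fpca(sim$data)
  per_subject <- vapply(unique(sim$data$subject_id), function(id) {
    sv <- subject_view(sim$data, id)
    xi <- score_subject(fit, sv)
    cond <- mean((predict_fpca(fit, xi, sv$age) - sv$height)^2)
    uncond <- mean((predict_fpca(fit, numeric(fit$K), sv$age) - sv$height)^2)
    cond <= uncond + 1e-10
  }, logical(1))
  expect_true(all(per_subject))
})

test_that("FCR reduces to fPCA structure and respects the sex contract", {
  sim <- small_cohort(n = 40, seed = 29, sex_effect = 1.2)
  fcr <- fit_fcr(sim$data)
  expect_true(fcr$converged)
  # sex = 0 predictions are exactly fPCA predictions of the adjusted fit
  sv <- subject_view(sim$data, sim$data$subject_id[1])
  xi <- score_subject(fcr$fpca, sv, sex_offset = 0)
  expect_equal(predict_fcr(fcr, sv, sex = 0, target_ages = c(5, 10)),
               predict_fpca(fcr$fpca, xi, c(5, 10)), tolerance = 1e-12)
  # empty observations, sex = 1 -> f0 + alpha1
  at <- c(6, 12)
  expect_equal(predict_fcr(fcr, NULL, sex = 1, target_ages = at),
               approx(fcr$fpca$grid, fcr$fpca$mean_values, xout = at)$y +
                 fcr$alpha1, tolerance = 1e-10)
  # two subjects with identical observations but different sex: algebraic oracle
  obs <- list(age = c(4, 8, 16), height = c(62, 69, 79))
  p0 <- predict_fcr(fcr, obs, sex = 0, target_ages = at)
  p1 <- predict_fcr(fcr, obs, sex = 1, target_ages = at)
  xi0 <- score_subject(fcr$fpca, obs, sex_offset = 0)
  xi1 <- score_subject(fcr$fpca, obs, sex_offset = fcr$alpha1)
  Phi_t <- vapply(seq_len(fcr$fpca$K), function(j)
    approx(fcr$fpca$grid, fcr$fpca$eigenfunctions[, j], xout = at)$y,
    numeric(2))
  expect_equal(p1 - p0, fcr$alpha1 + drop(Phi_t %*% (xi1 - xi0)),
               tolerance = 1e-10)
})

test_that("FCR needs both sexes and nulls out when the sexes are identical", {
  sim <- small_cohort(n = 20, seed = 31)
  d <- sim$data
  d$sex <- 1L
  expect_error(fit_fcr(as_growth_dataset(d)), "both sex",
               class = "growthsel_fit_error")
  # duplicate one noiseless cohort across both sexes: alpha must vanish
  spec <- cohort_spec(n_subjects = 12, sex_effect = 0, noise_sd = 0, seed = 33)
  sim0 <- simulate_cohort(spec)
  d0 <- sim0$data; d0$sex <- 0L
  d1 <- sim0$data; d1$sex <- 1L; d1$subject_id <- paste0(d1$subject_id, "m")
  both <- as_growth_dataset(dplyr::bind_rows(d0, d1))
  fcr0 <- fit_fcr(both)
  expect_lt(abs(fcr0$alpha1), 1e-6)
})

test_that("functional fits survive JSON serialization", {
  sim <- small_cohort(n = 25, seed = 37)
  fcr <- fit_fcr(sim$data)
  f <- withr::local_tempfile(fileext = ".json")
  write_fit(fcr, f)
  back <- read_fit(f)
  sv <- subject_view(sim$data, sim$data$subject_id[5])
  expect_equal(predict_fcr(back, sv, 1, c(3, 9, 21)),
               predict_fcr(fcr, sv, 1, c(3, 9, 21)), tolerance = 1e-10)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_fit(fcr$fpca, f2)
  back2 <- read_fit(f2)
  expect_equal(back2$eigenvalues, fcr$fpca$eigenvalues, tolerance = 1e-12)
})
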