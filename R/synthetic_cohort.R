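#' Specify a synthetic longitudinal growth cohort
#'
#' Builds the full description of a simulated cohort: how many children, how
#' visits are spaced, the population mean curve, a time-invariant sex effect,
#' a low-rank Gaussian-process model for subject-level curve deviations, and
#' the measurement-noise model. Defaults emulate a peri-urban birth-cohort
#' design with near-biweekly anthropometry over the first two years of life:
#' 215 children, up to 39 visits each, visit lags lognormal with median 14
#' days, 49% male.
#'
#' Heights are generated as
#' \deqn{Y_{ij} = f_0(t_{ij}) + \alpha_1 X_i + \sum_k \xi_{ik}\phi_k(t_{ij}) + \epsilon_{ij}}
#' with \eqn{\xi_{ik} \sim N(0, \lambda_k)} and Gaussian noise that is
#' independent (`residual_rho = 0`) or continuous-AR(1) correlated within
#' subject.
#'
#' @param n_subjects Number of children. Default 215.
#' @param target_obs_per_subject Maximum number of visits per child; visit
#'   sequences are also truncated at the end of `age_span`. Default 39.
#' @param visit_lag List describing the lag distribution between consecutive
#'   visits, in days: `list(dist = "lognormal", meanlog =, sdlog =)`.
#'   The default has median 14 days and quartile ratio matching an IQR of
#'   about 11–27 days.
#' @param male_fraction Probability a child is male. Default 0.49.
#' @param age_span Numeric length-2, months. Default `c(0, 24)`.
#' @param mean_curve Function of age (months) returning mean height (cm), or
#'   `NULL` for the default monotone infant-growth shape
#'   `a + b t + c log(1 + t)` anchored at 50 cm (birth), 74 cm (12 mo) and
#'   85 cm (24 mo).
#' @param sex_effect True time-invariant male–female mean difference, cm.
#'   Default 1.
#' @param eigenfunctions List of K functions of age, orthonormal in L2 on
#'   `age_span` (checked numerically to 1e-6), or `NULL` for the default
#'   pair: a level shift (constant) and a velocity contrast (centered
#'   linear).
#' @param lambda Eigenvalue (score variance) vector, cm^2, non-increasing
#'   and positive. Default `c(4, 1)`.
#' @param noise_sd Measurement noise standard deviation, cm. Default 0.5.
#' @param residual_rho Continuous-AR(1) correlation of the noise at lag one
#'   month, in `[0, 1)`. Default 0 (independent noise).
#' @param seed Integer master seed; each child has an independent stream
#'   derived from it, so changing `n_subjects` does not reshuffle existing
#'   children.
#' @return A `cohort_spec` object (a validated list).
#' @export
cohort_spec <- function(n_subjects = 215,
                        target_obs_per_subject = 39,
                        visit_lag = list(dist = "lognormal",
                                         meanlog = log(14), sdlog = 0.665),
                        male_fraction = 0.49,
                        age_span = c(0, 24),
                        mean_curve = NULL,
                        sex_effect = 1,
                        eigenfunctions = NULL,
                        lambda = c(4, 1),
                        noise_sd = 0.5,
                        residual_rho = 0,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, target_obs_per_subject >= 1,
            male_fraction >= 0, male_fraction <= 1,
            length(age_span) == 2, age_span[2] > age_span[1],
            noise_sd >= 0, residual_rho >= 0, residual_rho < 1)
  if (!identical(visit_lag$dist, "lognormal")) {
    abort("only lognormal visit lags are supported", class = "growthsel_spec_error")
  }
  span <- diff(age_span)
  # infeasibility guard: typical cumulative lag must not dwarf the span
  if ((target_obs_per_subject - 1) * exp(visit_lag$meanlog) / 30.4375 > 3 * span) {
    abort("visit-lag distribution cannot fit target_obs_per_subject in age_span",
          class = "growthsel_spec_error")
  }
  if (is.null(mean_curve)) mean_curve <- default_mean_curve()
  if (is.null(eigenfunctions)) {
    lo <- age_span[1]; hi <- age_span[2]; mid <- (lo + hi) / 2
    eigenfunctions <- list(
      function(t) rep(1 / sqrt(hi - lo), length(t)),
      function(t) (t - mid) / sqrt((hi - lo)^3 / 12)
    )
  }
  K <- length(eigenfunctions)
  lambda <- as.numeric(lambda)
  if (K > 0) {
    stopifnot(length(lambda) == K, all(lambda > 0), !is.unsorted(rev(lambda)))
    check_orthonormal(eigenfunctions, age_span)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    target_obs_per_subject = as.integer(target_obs_per_subject),
    visit_lag = visit_lag,
    male_fraction = male_fraction,
    age_span = age_span,
    mean_curve = mean_curve,
    sex_effect = sex_effect,
    eigenfunctions = eigenfunctions,
    lambda = lambda,
    noise_sd = noise_sd,
    residual_rho = residual_rho,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default cohort specification emulating a biweekly-visit birth cohort
#'
#' Convenience wrapper for [cohort_spec()] with its defaults: 215 children,
#' 49% male, up to 39 visits with lognormal lags of median 14 days, a
#' monotone mean curve from about 50 cm at birth to about 85 cm at 24
#' months, two eigenfunctions with variances (4, 1) cm^2, and 0.5 cm
#' measurement noise.
#'
#' @param ... Overrides passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
default_content_spec <- function(...) cohort_spec(...)

# a + b t + c log(1+t) through (0, 50), (12, 74), (24, 85) cm
default_mean_curve <- function() {
  anchors <- cbind(t = c(0, 12, 24), h = c(50, 74, 85))
  M <- cbind(1, anchors[, "t"], log1p(anchors[, "t"]))
  abc <- solve(M, anchors[, "h"])
  function(t) abc[1] + abc[2] * t + abc[3] * log1p(t)
}

check_orthonormal <- function(funs, span, tol = 1e-6) {
  g <- seq(span[1], span[2], length.out = 2001)
  w <- trapezoid_weights(g)
  Phi <- vapply(funs, function(f) f(g), numeric(length(g)))
  Gram <- t(Phi) %*% (w * Phi)
  if (max(abs(Gram - diag(ncol(Phi)))) > tol) {
    abort("eigenfunctions are not orthonormal on age_span (tolerance 1e-6)",
          class = "growthsel_spec_error")
  }
  invisible(TRUE)
}

trapezoid_weights <- function(grid) {
  h <- diff(grid)
  c(h / 2, 0) + c(0, h / 2)
}

subject_seed <- function(master, i) {
  as.integer((as.double(master) * 1000003 + 7919 * as.double(i)) %% 2147483629) + 1L
}

#' Simulate a cohort with known ground truth
#'
#' Draws, for each child independently: sex, a small uniform birth-age
#' jitter on (0, 0.5) months (so not all trajectories start at exactly
#' t = 0), visit ages by cumulative lognormal lags truncated at the end of
#' the age span and capped at `target_obs_per_subject` visits, latent scores
#' `xi_ik ~ N(0, lambda_k)`, and measurement noise (independent or CAR(1)
#' correlated). Fully reproducible from `spec$seed`; each child has its own
#' derived stream.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `data` (a [as_growth_dataset()] `growth_dataset`) and
#'   `truth` (per-subject true scores, sex, the mean curve and
#'   eigenfunctions, and the true `alpha1`, `lambda`, `sigma`, `rho`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lo <- spec$age_span[1]; hi <- spec$age_span[2]
  K <- length(spec$eigenfunctions)
  rows <- vector("list", spec$n_subjects)
  scores <- matrix(0, spec$n_subjects, max(K, 1))
  sexes <- integer(spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    set.seed(subject_seed(spec$seed, i))
    sexes[i] <- rbinom(1, 1, spec$male_fraction)
    ages <- lo + runif(1, 0, 0.5)
    while (length(ages) < spec$target_obs_per_subject) {
      lag_m <- rlnorm(1, spec$visit_lag$meanlog, spec$visit_lag$sdlog) / 30.4375
      nxt <- ages[length(ages)] + lag_m
      if (nxt > hi) break
      ages <- c(ages, nxt)
    }
    m <- length(ages)
    xi <- if (K > 0) rnorm(K, 0, sqrt(spec$lambda)) else numeric(0)
    if (K > 0) scores[i, seq_len(K)] <- xi
    dev <- if (K > 0) {
      Phi <- vapply(spec$eigenfunctions, function(f) f(ages), numeric(m))
      drop(Phi %*% xi)
    } else 0
    eps <- if (spec$noise_sd == 0) {
      numeric(m)
    } else if (spec$residual_rho > 0 && m > 1) {
      R <- spec$residual_rho^abs(outer(ages, ages, "-"))
      drop(crossprod(chol(R), rnorm(m))) * spec$noise_sd
    } else {
      rnorm(m, 0, spec$noise_sd)
    }
    h <- spec$mean_curve(ages) + spec$sex_effect * sexes[i] + dev + eps
    rows[[i]] <- tibble(subject_id = sprintf("S%04d", i), sex = sexes[i],
                        age = ages, height = h)
  }
  data <- as_growth_dataset(dplyr::bind_rows(rows), age_max = hi)
  truth <- list(
    subject_ids = sprintf("S%04d", seq_len(spec$n_subjects)),
    sex = sexes,
    scores = scores[, seq_len(max(K, 1)), drop = FALSE],
    mean_curve = spec$mean_curve,
    eigenfunctions = spec$eigenfunctions,
    alpha1 = spec$sex_effect,
    lambda = spec$lambda,
    sigma = spec$noise_sd,
    rho = spec$residual_rho
  )
  list(data = data, truth = truth)
}
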