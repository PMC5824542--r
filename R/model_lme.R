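#' Truncated cubic spline design row
#'
#' The fixed-effects design used by the growth LME: a cubic polynomial in
#' age plus truncated cubic terms \eqn{(t-k)_+^3} at each knot, plus the sex
#' indicator, i.e. `[1, t, t^2, t^3, (t-k1)+^3, ..., sex]`.
#'
#' @param t Age in months (scalar, non-negative).
#' @param sex 0/1 sex indicator.
#' @param knots Knot ages in months. Default `c(3, 6, 12, 18)`.
#' @return Numeric vector of length `4 + length(knots) + 1`.
#' @export
spline_design_row <- function(t, sex, knots = c(3, 6, 12, 18)) {
  stopifnot(length(t) == 1)
  drop(spline_design(t, sex, knots))
}

# vectorized design matrix; rows follow spline_design_row
spline_design <- function(t, sex, knots = c(3, 6, 12, 18)) {
  if (any(t < 0)) {
    abort("ages must be non-negative", class = "growthsel_domain_error")
  }
  X <- cbind(1, t, t^2, t^3,
             outer(t, knots, function(tt, k) pmax(tt - k, 0)^3),
             sex)
  colnames(X) <- c("(Intercept)", "t", "t2", "t3",
                   paste0("tk", knots), "sex")
  X
}

#' Continuous-AR(1) correlation matrix
#'
#' Correlation between two within-subject errors observed `|s - t|` months
#' apart is `rho^|s - t|`; the unit of `rho` is therefore per month.
#'
#' @param ages Strictly increasing ages, months.
#' @param rho Correlation at lag one month, in `[0, 1)`.
#' @return Symmetric matrix with unit diagonal, positive-definite for
#'   `rho` in `(0, 1)`.
#' @export
car1_correlation <- function(ages, rho) {
  if (rho < 0 || rho >= 1) {
    abort("rho must lie in [0, 1)", class = "growthsel_domain_error")
  }
  if (is.unsorted(ages, strictly = TRUE)) {
    abort("ages must be strictly increasing", class = "growthsel_domain_error")
  }
  rho^abs(outer(ages, ages, "-"))
}

#' Fit the growth linear mixed effects model
#'
#' Population mean: truncated cubic spline in age (knots default 3, 6, 12,
#' 18 months) plus a time-invariant sex effect. Subject level: random
#' intercept and slope with unstructured 2x2 covariance `G`. Within-subject
#' errors: continuous-AR(1) correlated Gaussian with variance `sigma2` and
#' correlation `rho^|s-t|` (ages in months). Estimated by REML via
#' [nlme::lme()]; subject BLUPs are recomputed from the frozen population
#' parameters with the same linear algebra used for held-out prediction.
#'
#' @param train A `growth_dataset` with at least two subjects.
#' @param knots Spline knot ages, months.
#' @param rho_fixed Optional value in `[0, 1)` at which to fix the CAR(1)
#'   correlation instead of estimating it (`0` gives independent
#'   within-subject errors). Default `NULL` (estimate `rho`).
#' @return An `lme_fit`: fixed effects (`beta`, `gamma`, `alpha1`) with
#'   standard errors, `G`, `sigma2`, `rho`, per-subject BLUPs, the REML
#'   log-likelihood, and a `converged` flag.
#' @export
fit_lme <- function(train, knots = c(3, 6, 12, 18), rho_fixed = NULL) {
  if (n_subjects(train) < 2) {
    abort("LME fitting needs at least 2 subjects (insufficient replication)",
          class = "growthsel_fit_error")
  }
  X <- spline_design(train$age, train$sex, knots)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    deficient <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("fixed-effects design is rank deficient; column(s): ",
                 paste(deficient, collapse = ", ")),
          class = "growthsel_fit_error")
  }
  d <- data.frame(.id = factor(train$subject_id), .y = train$height,
                  X[, -1, drop = FALSE], check.names = FALSE)
  terms <- colnames(X)[-1]
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", terms), collapse = " + ")))
  cor_struct <- if (is.null(rho_fixed)) {
    nlme::corCAR1(form = ~ t | .id)
  } else if (rho_fixed == 0) {
    NULL
  } else {
    nlme::corCAR1(value = rho_fixed, form = ~ t | .id, fixed = TRUE)
  }
  converged <- TRUE
  # optim is the faster path; nlme's default nlminb machinery is more robust
  # on ill-conditioned splits (e.g. many children missing their early ages),
  # so it serves as the fallback
  controls <- list(
    nlme::lmeControl(opt = "optim", maxIter = 200, msMaxIter = 200,
                     returnObject = TRUE),
    nlme::lmeControl(maxIter = 200, msMaxIter = 200, niterEM = 50,
                     returnObject = TRUE)
  )
  fit <- withCallingHandlers({
    f <- NULL
    last_err <- NULL
    for (ctl in controls) {
      f <- tryCatch(
        nlme::lme(fml, data = d, random = ~ 1 + t | .id,
                  correlation = cor_struct, method = "REML", control = ctl),
        error = function(e) e)
      if (!inherits(f, "error")) break
      last_err <- f
    }
    if (inherits(f, "error")) {
      abort(paste0("REML fit failed: ", conditionMessage(last_err)),
            class = "growthsel_fit_error")
    }
    f
  },
  warning = function(w) {
    converged <<- FALSE
    invokeRestart("muffleWarning")
  })
  fe <- nlme::fixef(fit)
  se <- sqrt(diag(vcov(fit)))
  G <- matrix(as.numeric(nlme::getVarCov(fit)), 2, 2)
  rho <- if (is.null(cor_struct)) 0 else
    unname(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  if (length(rho) == 0) rho <- rho_fixed  # fixed corCAR1 reports no coef
  coefs <- setNames(as.numeric(fe), colnames(X))
  out <- structure(list(
    beta = coefs[1:4],
    gamma = coefs[paste0("tk", knots)],
    alpha1 = unname(coefs["sex"]),
    se = setNames(as.numeric(se), colnames(X)),
    knots = knots,
    coefs = coefs,
    G = (G + t(G)) / 2,
    sigma2 = fit$sigma^2,
    rho = rho,
    reml_loglik = as.numeric(stats::logLik(fit)),
    converged = converged,
    n_subjects = n_subjects(train)
  ), class = "lme_fit")
  ids <- unique(train$subject_id)
  bl <- t(vapply(ids, function(id) {
    sv <- subject_view(train, id)
    lme_blup(out, sv$age, sv$height, sv$sex)
  }, numeric(2)))
  out$blups <- tibble(subject_id = ids, b0 = bl[, 1], b1 = bl[, 2])
  out
}

# BLUP of (b0, b1) for one subject under frozen population parameters:
# b = G Z' V^-1 (y - X beta), V = Z G Z' + sigma2 R(rho)
lme_blup <- function(fit, ages, heights, sex) {
  ord <- order(ages)
  ages <- ages[ord]; heights <- heights[ord]
  Z <- cbind(1, ages)
  R <- fit$rho^abs(outer(ages, ages, "-"))
  V <- Z %*% fit$G %*% t(Z) + fit$sigma2 * R
  resid <- heights - drop(spline_design(ages, sex, fit$knots) %*% fit$coefs)
  Vi <- tryCatch(solve(V, resid),
                 error = function(e) solve(V + 1e-10 * diag(nrow(V)), resid))
  drop(fit$G %*% t(Z) %*% Vi)
}

#' Predict heights from a fitted growth LME
#'
#' Population prediction is the spline mean plus the sex effect. When
#' `condition = TRUE` and observations for the subject are supplied, the
#' subject's random intercept and slope are first predicted (BLUP) from
#' those observations under the frozen population parameters, and added in.
#'
#' @param fit An `lme_fit`.
#' @param target_ages Ages (months) at which to predict.
#' @param sex 0/1 sex indicator of the subject.
#' @param subject_obs Optional list with `age` and `height` vectors — the
#'   observations to condition on (e.g. a subject's in-sample records).
#' @param condition If `FALSE`, ignore `subject_obs` and return the
#'   population prediction.
#' @return Numeric vector of predicted heights, cm.
#' @export
predict_lme <- function(fit, target_ages, sex, subject_obs = NULL,
                        condition = TRUE) {
  mu <- drop(spline_design(target_ages, sex, fit$knots) %*% fit$coefs)
  if (condition && !is.null(subject_obs) && length(subject_obs$age) > 0) {
    b <- lme_blup(fit, subject_obs$age, subject_obs$height, sex)
    mu <- mu + b[1] + b[2] * target_ages
  }
  mu
}
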