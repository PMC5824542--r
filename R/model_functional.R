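#' Smooth mean function of pooled growth data
#'
#' Penalized cubic regression spline of height on age over all pooled
#' observations ([mgcv::gam()], smoothness by REML), evaluated on a grid.
#'
#' @param train A `growth_dataset`.
#' @param grid Strictly increasing ages, months. Must lie inside the pooled
#'   observed age range.
#' @param k Spline basis dimension. Default 25. An adaptive penalty is used
#'   (curvature of infant growth concentrates near birth) whenever the data
#'   carry enough distinct ages; otherwise a cubic regression spline.
#' @return Numeric vector of mean heights on `grid`, cm.
#' @export
smooth_mean <- function(train, grid, k = 15) {
  rng <- range(train$age)
  if (min(grid) < rng[1] - 1e-8 || max(grid) > rng[2] + 1e-8) {
    abort("grid extends outside the observed age range", class = "growthsel_domain_error")
  }
  smooth_mean_fun(train, k)(grid)
}

#' Smooth the covariance operator of subject-level deviations
#'
#' Estimates `C(s, t) = Cov(b_i(s), b_i(t))` of the subject-specific curve
#' process from within-subject cross-products of mean-centered residuals.
#' Off-diagonal products `r_ij r_il` (j != l) are aggregated into age-pair
#' bins and smoothed with a tensor-product penalized spline; the result is
#' evaluated on the grid and symmetrized. The measurement-error variance is
#' the average positive gap along the diagonal between a one-dimensional
#' smooth of the squared residuals (which targets `C(t, t) + sigma^2`) and
#' the fitted surface (which targets `C(t, t)`), floored at 1e-8.
#'
#' @param train A `growth_dataset`.
#' @param mean_values Mean function on `grid` (from [smooth_mean()]).
#' @param grid Evaluation grid, months.
#' @param nbins Number of marginal age bins for cross-product aggregation.
#' @param k Marginal tensor-product basis dimension. Default 6.
#' @return List with `cov_values` (symmetric matrix on `grid` x `grid`) and
#'   `sigma2`.
#' @export
smooth_covariance <- function(train, mean_values, grid, nbins = 25, k = 6) {
  r <- train$height - approx(grid, mean_values, xout = train$age, rule = 2)$y
  sp <- split(data.frame(age = train$age, r = r), train$subject_id)
  sp <- sp[vapply(sp, nrow, 0L) >= 2]
  if (length(sp) == 0) {
    abort("covariance estimation needs at least one subject with >= 2 observations",
          class = "growthsel_fit_error")
  }
  cp <- dplyr::bind_rows(lapply(sp, function(d) {
    m <- nrow(d)
    idx <- which(upper.tri(matrix(NA, m, m)), arr.ind = TRUE)
    data.frame(s = d$age[idx[, 1]], t = d$age[idx[, 2]],
               p = d$r[idx[, 1]] * d$r[idx[, 2]])
  }))
  rng <- range(grid)
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  bs <- findInterval(cp$s, br, all.inside = TRUE)
  bt <- findInterval(cp$t, br, all.inside = TRUE)
  lo <- pmin(bs, bt); hi <- pmax(bs, bt)
  key <- (lo - 1) * nbins + hi
  mp <- tapply(cp$p, key, mean)
  nn <- tapply(cp$p, key, length)
  cell <- as.integer(names(mp))
  ctr <- (br[-1] + br[-(nbins + 1)]) / 2
  d1 <- data.frame(sa = ctr[(cell - 1) %/% nbins + 1],
                   ta = ctr[(cell - 1) %% nbins + 1],
                   p = as.numeric(mp), n = as.numeric(nn))
  off <- d1$sa != d1$ta
  dd <- rbind(d1, data.frame(sa = d1$ta[off], ta = d1$sa[off],
                             p = d1$p[off], n = d1$n[off]))
  k_use <- max(3, min(k, floor(sqrt(nrow(dd))) - 1))
  # mgcv's REML newton can report a benign step failure on very smooth
  # surfaces; the fit it returns is still usable and is validated downstream
  cg <- withCallingHandlers(
    mgcv::gam(p ~ te(sa, ta, k = c(k_use, k_use), bs = "cr"),
              weights = n, data = dd, method = "REML"),
    warning = function(w) {
      if (grepl("step failure", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  C <- matrix(predict(cg, newdata = expand.grid(sa = grid, ta = grid)),
              length(grid), length(grid))
  C <- (C + t(C)) / 2
  # diagonal: smooth of r^2 estimates C(t,t) + sigma^2
  k_diag <- min(10, max(3, length(unique(train$age)) - 1))
  dg <- mgcv::gam(I(r^2) ~ s(age, k = k_diag, bs = "cr"),
                  data = data.frame(age = train$age, r = r), method = "REML")
  Vdiag <- as.numeric(predict(dg, newdata = data.frame(age = grid)))
  sigma2 <- max(mean(pmax(Vdiag - diag(C), 0)), 1e-8)
  list(cov_values = C, sigma2 = sigma2)
}

#' Eigendecompose a covariance surface on a grid
#'
#' Solves the eigenproblem of the covariance operator using trapezoid
#' quadrature weights. Negative eigenvalues are dropped; `K` is the smallest
#' number of components whose eigenvalue sum reaches `pve` of the total
#' positive eigenvalue mass. Eigenfunctions have unit L2 norm on the grid
#' and are sign-fixed so each integrates to a nonnegative value (with a
#' positive leftmost value breaking exact ties).
#'
#' @param cov_values Symmetric matrix on `grid` x `grid`.
#' @param grid Strictly increasing ages, months.
#' @param pve Proportion of variance explained threshold in (0, 1].
#' @return List with `eigenfunctions` (grid-length x K matrix),
#'   `eigenvalues` (length K, positive, non-increasing).
#' @export
eigendecompose <- function(cov_values, grid, pve = 0.99) {
  stopifnot(isTRUE(all.equal(cov_values, t(cov_values), tolerance = 1e-8)))
  w <- trapezoid_weights(grid)
  sw <- sqrt(w)
  A <- sw * t(sw * cov_values)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  pos <- e$values > max(1e-12, 1e-10 * max(abs(e$values)))
  if (!any(pos)) {
    abort("covariance surface has no positive eigenvalues (degenerate process)",
          class = "growthsel_fit_error")
  }
  lam <- e$values[pos]
  K <- which(cumsum(lam) / sum(lam) >= pve - 1e-12)[1]
  lam <- lam[seq_len(K)]
  Phi <- e$vectors[, which(pos)[seq_len(K)], drop = FALSE] / sw
  for (j in seq_len(K)) {
    s <- sum(w * Phi[, j])
    if (abs(s) < 1e-10) s <- Phi[1, j]
    if (s < 0) Phi[, j] <- -Phi[, j]
  }
  list(eigenfunctions = Phi, eigenvalues = lam)
}

#' Conditional-expectation scores for one subject
#'
#' Best linear unbiased prediction of the subject's component scores given
#' sparse observations:
#' `xi = Lambda Phi_o' (Phi_o Lambda Phi_o' + sigma2 I)^-1 (y - f0(t) - offset)`
#' with eigenfunctions and mean linearly interpolated at the observed ages.
#'
#' @param fit An `fpca_fit`.
#' @param subject_obs List with `age` and `height`; may be empty.
#' @param sex_offset Constant offset, cm (0 for plain fPCA; `alpha1 * sex`
#'   for concurrent regression).
#' @return Numeric score vector of length `K`; all zeros (with attribute
#'   `population = TRUE`) when no observations are supplied.
#' @export
score_subject <- function(fit, subject_obs, sex_offset = 0) {
  K <- length(fit$eigenvalues)
  if (is.null(subject_obs) || length(subject_obs$age) == 0) {
    return(structure(numeric(K), population = TRUE))
  }
  check_in_grid(subject_obs$age, fit$grid)
  Phi_o <- vapply(seq_len(K), function(j)
    approx(fit$grid, fit$eigenfunctions[, j], xout = subject_obs$age)$y,
    numeric(length(subject_obs$age)))
  Phi_o <- matrix(Phi_o, nrow = length(subject_obs$age))
  mu_o <- approx(fit$grid, fit$mean_values, xout = subject_obs$age)$y
  resid <- subject_obs$height - mu_o - sex_offset
  Lam <- diag(fit$eigenvalues, K)
  M <- Phi_o %*% Lam %*% t(Phi_o) + fit$sigma2 * diag(length(resid))
  drop(Lam %*% t(Phi_o) %*% solve(M, resid))
}

#' Reconstruct a trajectory from fPCA scores
#'
#' `f0(t) + offset + sum_k xi_k phi_k(t)` with the mean and eigenfunctions
#' linearly interpolated at the target ages. Ages outside the grid raise an
#' extrapolation error (no silent clamping).
#'
#' @inheritParams score_subject
#' @param scores Score vector of length `K`.
#' @param target_ages Ages, months, inside the grid range.
#' @return Predicted heights, cm.
#' @export
predict_fpca <- function(fit, scores, target_ages, sex_offset = 0) {
  check_in_grid(target_ages, fit$grid)
  mu <- approx(fit$grid, fit$mean_values, xout = target_ages)$y
  K <- length(fit$eigenvalues)
  dev <- 0
  if (K > 0 && any(scores != 0)) {
    Phi_t <- vapply(seq_len(K), function(j)
      approx(fit$grid, fit$eigenfunctions[, j], xout = target_ages)$y,
      numeric(length(target_ages)))
    dev <- drop(matrix(Phi_t, nrow = length(target_ages)) %*% scores)
  }
  mu + sex_offset + dev
}

check_in_grid <- function(ages, grid) {
  if (min(ages) < grid[1] - 1e-8 || max(ages) > grid[length(grid)] + 1e-8) {
    abort(sprintf("age(s) outside the fitted grid range [%.3f, %.3f]; refit with a wider grid",
                  grid[1], grid[length(grid)]),
          class = "growthsel_extrapolation_error")
  }
  invisible(TRUE)
}

#' Fit sparse functional principal component analysis
#'
#' Composes [smooth_mean()], [smooth_covariance()], [eigendecompose()] and
#' [score_subject()] (with zero sex offset) over a regular age grid. The
#' model is `Y_ij = f0(t_ij) + b_i(t_ij) + e_ij` with `b_i` a zero-mean
#' Gaussian process of low effective rank; no covariates enter.
#'
#' @param train A `growth_dataset`.
#' @param grid_size Number of grid points. Default 101.
#' @param pve Proportion-of-variance threshold selecting `K`. Default 0.99.
#' @param grid_range Optional length-2 ages bounding the grid; defaults to
#'   the observed age range of `train`. Supply the full monitoring window
#'   when predictions outside the training range will be requested (the
#'   smoothers then extrapolate their penalized-spline fits marginally).
#' @return An `fpca_fit`: `grid`, `mean_values`, `cov_values`,
#'   `eigenfunctions`, `eigenvalues`, `sigma2`, `pve`, and per-subject
#'   `scores`.
#' @export
fit_fpca <- function(train, grid_size = 101, pve = 0.99, grid_range = NULL) {
  rng <- grid_range %||% range(train$age)
  grid <- seq(rng[1], rng[2], length.out = grid_size)
  mv <- smooth_mean_fun(train)(grid)
  cv <- smooth_covariance(train, mv, grid)
  ed <- eigendecompose(cv$cov_values, grid, pve)
  fit <- structure(list(
    grid = grid, mean_values = mv,
    cov_values = cv$cov_values, sigma2 = cv$sigma2,
    eigenfunctions = ed$eigenfunctions, eigenvalues = ed$eigenvalues,
    pve = pve, K = length(ed$eigenvalues)
  ), class = "fpca_fit")
  ids <- unique(train$subject_id)
  sc <- t(vapply(ids, function(id) {
    sv <- subject_view(train, id)
    score_subject(fit, sv, sex_offset = 0)
  }, numeric(fit$K)))
  sc <- matrix(sc, nrow = length(ids))
  colnames(sc) <- paste0("xi", seq_len(fit$K))
  fit$scores <- dplyr::bind_cols(tibble(subject_id = ids), as_tibble(sc))
  fit
}

# mean smoother as a function, so grids wider than the data can be filled
# by the spline's own extrapolation rather than erroring.
# An adaptive penalty is used because infant growth concentrates its
# curvature near birth: a single global smoothing parameter oversmooths the
# first months. Falls back to a plain cubic regression spline when the data
# carry too few distinct ages to support the adaptive basis.
smooth_mean_fun <- function(train, k = 25) {
  if (stats::var(train$height) < 1e-12) {
    h0 <- train$height[1]  # degenerate: constant response
    return(function(ages) rep(h0, length(ages)))
  }
  k_use <- min(k, max(3, length(unique(train$age)) - 1))
  bs <- if (k_use >= 15) "ad" else "cr"
  # penalty-null-space data (e.g. an exact line) drive the smoothing
  # parameter to its boundary and trip a benign mgcv step-failure warning
  gm <- withCallingHandlers(
    mgcv::gam(height ~ s(age, k = k_use, bs = bs), data = train,
              method = "REML"),
    warning = function(w) {
      if (grepl("step failure", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  function(ages) as.numeric(predict(gm, newdata = data.frame(age = ages)))
}

#' @export
print.fpca_fit <- function(x, ...) {
  cat(sprintf("<fpca_fit: K=%d (pve %.2f), lambda = %s, sigma2 = %.4g, grid %d pts on [%.2f, %.2f]>\n",
              x$K, x$pve, paste(signif(x$eigenvalues, 3), collapse = ", "),
              x$sigma2, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Fit functional concurrent regression with a time-invariant sex effect
#'
#' Model: `Y_ij = f0(t_ij) + alpha1 X_i + b_i(t_ij) + e_ij`, i.e. fPCA with
#' an added constant sex shift. Estimated by backfitting: `alpha1` is
#' initialized from the sex-group difference of residuals around a common
#' smooth mean, then alternated with a full fPCA fit of the sex-adjusted
#' heights until the change in `alpha1` falls below `tol`. Each child
#' carries equal weight (per-subject `1/m_i` observation weights) in the
#' `alpha1` update so heavily-sampled children do not dominate.
#'
#' @inheritParams fit_fpca
#' @param max_iter Maximum backfitting iterations. Default 20.
#' @param tol Convergence tolerance on `alpha1`, cm. Default 1e-4.
#' @return An `fcr_fit`: the final `fpca` fit of the sex-adjusted process,
#'   `alpha1`, `converged`, `n_iter`.
#' @export
fit_fcr <- function(train, grid_size = 101, pve = 0.99, grid_range = NULL,
                    max_iter = 20, tol = 1e-4) {
  if (length(unique(train$sex)) < 2) {
    abort("FCR needs both sex groups in the training data",
          class = "growthsel_fit_error")
  }
  m_i <- obs_counts(train)
  wts <- 1 / m_i[train$subject_id]
  mu0 <- smooth_mean_fun(train)(train$age)
  r0 <- train$height - mu0
  alpha <- unname(coef(lm(r0 ~ train$sex, weights = wts))[2])
  fp <- NULL
  converged <- FALSE
  iter <- 0
  prev_delta <- NA_real_
  delta <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1
    adj <- train
    adj$height <- train$height - alpha * train$sex
    fp <- fit_fpca(adj, grid_size = grid_size, pve = pve, grid_range = grid_range)
    # fitted subject deviations at observed ages
    bhat <- numeric(nrow(train))
    for (id in unique(train$subject_id)) {
      sel <- train$subject_id == id
      xi <- as.numeric(fp$scores[fp$scores$subject_id == id,
                                 -1, drop = FALSE][1, ])
      bhat[sel] <- predict_fpca(fp, xi, train$age[sel]) -
        approx(fp$grid, fp$mean_values, xout = train$age[sel])$y
    }
    r <- train$height - approx(fp$grid, fp$mean_values, xout = train$age)$y - bhat
    alpha_new <- unname(coef(lm(r ~ train$sex, weights = wts))[2])
    delta <- alpha_new - alpha
    if (abs(delta) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    # the BLUP step leaves a near-constant fraction of each alpha update in
    # the subject deviations, making the fixed-point iteration a slow linear
    # contraction; Aitken extrapolation jumps to its limit
    ratio <- delta / prev_delta
    if (is.finite(ratio) && ratio > 0 && ratio < 0.995) {
      alpha <- alpha_new + delta * ratio / (1 - ratio)
      prev_delta <- NA_real_
    } else {
      alpha <- alpha_new
      prev_delta <- delta
    }
  }
  if (!converged) {
    warn(sprintf("FCR backfitting did not converge in %d iterations (last step %.2g cm)",
                 max_iter, abs(delta)))
  }
  structure(list(fpca = fp, alpha1 = alpha, converged = converged,
                 n_iter = iter), class = "fcr_fit")
}

#' @export
print.fcr_fit <- function(x, ...) {
  cat(sprintf("<fcr_fit: alpha1 = %.3f cm (%s in %d iterations)>\n",
              x$alpha1, if (x$converged) "converged" else "not converged", x$n_iter))
  print(x$fpca)
  invisible(x)
}

#' Predict heights from a concurrent-regression fit
#'
#' Scores the subject with offset `alpha1 * sex` and reconstructs the
#' trajectory with the same offset; with `sex = 0` this reduces exactly to
#' the fPCA prediction of the sex-adjusted fit.
#'
#' @param fit An `fcr_fit`.
#' @param subject_obs List with `age`, `height` (may be `NULL` or empty for
#'   a population prediction).
#' @param sex 0/1 sex indicator.
#' @param target_ages Ages, months, inside the fitted grid.
#' @return Predicted heights, cm.
#' @export
predict_fcr <- function(fit, subject_obs, sex, target_ages) {
  off <- fit$alpha1 * sex
  xi <- score_subject(fit$fpca, subject_obs, sex_offset = off)
  predict_fpca(fit$fpca, xi, target_ages, sex_offset = off)
}
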