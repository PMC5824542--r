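# Fixtures are all built in code; tests that compare against "oracles" use
# the independent implementations below (naive loops / hand formulas), never
# the package's own code paths.

# small, fast cohort for unit tests
small_cohort <- function(n = 25, seed = 42, ...) {
  simulate_cohort(cohort_spec(n_subjects = n, seed = seed, ...))
}

# random prediction fixture: a few subjects, a few records each
random_prediction_fixture <- function(seed, n_subjects = 8, models = c("a", "b")) {
  set.seed(seed)
  rows <- list()
  for (id in sprintf("P%02d", seq_len(n_subjects))) {
    m <- sample(2:8, 1)
    ages <- sort(runif(m, 0, 24))
    obs <- runif(m, 45, 95)
    for (mod in models) {
      rows[[paste(id, mod)]] <- tibble::tibble(
        subject_id = id, age = ages, observed = obs,
        predicted = obs + rnorm(m, 0, 2), model = mod)
    }
  }
  prediction_set(dplyr::bind_rows(rows))
}

# --- brute-force metric oracles (double loops, no vectorization) ---------

oracle_mse <- function(preds) {
  out <- list()
  for (mod in unique(preds$model)) {
    for (id in unique(preds$subject_id[preds$model == mod])) {
      d <- preds[preds$model == mod & preds$subject_id == id, ]
      acc <- 0
      for (j in seq_len(nrow(d))) acc <- acc + (d$observed[j] - d$predicted[j])^2
      out[[paste(mod, id)]] <- tibble::tibble(model = mod, subject_id = id,
                                              value = acc / nrow(d))
    }
  }
  dplyr::bind_rows(out)
}

oracle_nmse <- function(preds) {
  out <- list()
  for (mod in unique(preds$model)) {
    for (id in unique(preds$subject_id[preds$model == mod])) {
      d <- preds[preds$model == mod & preds$subject_id == id, ]
      acc <- 0
      for (j in seq_len(nrow(d))) {
        acc <- acc + (d$observed[j] - d$predicted[j])^2 / d$observed[j]^2
      }
      out[[paste(mod, id)]] <- tibble::tibble(model = mod, subject_id = id,
                                              value = acc / nrow(d))
    }
  }
  dplyr::bind_rows(out)
}

oracle_amse <- function(preds, strata) {
  out <- list()
  nS <- length(strata) - 1
  for (mod in unique(preds$model)) {
    for (id in unique(preds$subject_id[preds$model == mod])) {
      d <- preds[preds$model == mod & preds$subject_id == id, ]
      for (s in seq_len(nS)) {
        acc <- 0
        for (j in seq_len(nrow(d))) {
          in_s <- d$age[j] >= strata[s] &
            (if (s < nS) d$age[j] < strata[s + 1] else d$age[j] <= strata[s + 1])
          if (in_s) acc <- acc + (d$observed[j] - d$predicted[j])^2
        }
        out[[paste(mod, id, s)]] <- tibble::tibble(
          model = mod, subject_id = id, stratum_index = s,
          value = acc / nrow(d))
      }
    }
  }
  dplyr::bind_rows(out)
}

# join package output against an oracle table and return max |difference|
max_metric_diff <- function(got, oracle, by = c("model", "subject_id")) {
  j <- dplyr::inner_join(got, oracle, by = by, suffix = c("", ".oracle"))
  stopifnot(nrow(j) == nrow(oracle))
  max(abs(j$value - j$value.oracle))
}

# --- independent LME-truth simulator (hand-rolled basis, not the package's)
sim_lme_truth <- function(n = 200, m_mean = 20, seed = 1,
                          beta = c(50, 4, -0.25, 0.006),
                          gamma = c(-0.01, 0.004, 0.0, 0.0),
                          alpha1 = 1, knots = c(3, 6, 12, 18),
                          G = matrix(c(4, 0.1, 0.1, 0.02), 2),
                          sigma = 0.7, rho = 0.5) {
  set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- max(rpois(1, m_mean), 4)
    ages <- sort(runif(m, 0, 24))
    sex <- rbinom(1, 1, 0.5)
    L <- chol(G + 1e-12 * diag(2))
    b <- drop(crossprod(L, rnorm(2)))
    R <- rho^abs(outer(ages, ages, "-"))
    eps <- drop(crossprod(chol(R), rnorm(m))) * sigma
    mu <- beta[1] + beta[2] * ages + beta[3] * ages^2 + beta[4] * ages^3
    for (k in seq_along(knots)) mu <- mu + gamma[k] * pmax(ages - knots[k], 0)^3
    y <- mu + alpha1 * sex + b[1] + b[2] * ages + eps
    rows[[i]] <- tibble::tibble(subject_id = sprintf("L%03d", i), sex = sex,
                                age = ages, height = y)
  }
  # suppress the rare dropped-row warning from extreme random-effect draws
  list(data = suppressWarnings(as_growth_dataset(dplyr::bind_rows(rows))),
       truth = list(beta = beta, gamma = gamma, alpha1 = alpha1,
                    G = G, sigma = sigma, rho = rho))
}
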