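test_that("hold-out counts follow the ceiling rule per scenario", {
  d <- as_growth_dataset(dplyr::bind_rows(lapply(1:4, function(i)
    tibble::tibble(subject_id = paste0("c", i), sex = i %% 2,
                   age = 1:10 * 2, height = 50 + 1:10))))
  sp <- scenario_spec("forward", holdout_fraction = 0.2, child_fraction = 1,
                      seed = 3)
  split <- make_split(d, sp)
  out <- d[split$out_of_sample, ]
  expect_equal(unname(table(out$subject_id)), rep(2L, 4), ignore_attr = TRUE)
  # forward: held-out ages are each child's last two
  for (id in unique(d$subject_id)) {
    expect_equal(out$age[out$subject_id == id], c(18, 20))
  }
  # backward mirrors it
  outb <- d[make_split(d, scenario_spec("backward", 0.2, 1, seed = 3))$out_of_sample, ]
  for (id in unique(d$subject_id)) {
    expect_equal(outb$age[outb$subject_id == id], c(2, 4))
  }
})

test_that("new-individual splits hold out whole children at the ceiling count", {
  d <- as_growth_dataset(dplyr::bind_rows(lapply(1:215, function(i)
    tibble::tibble(subject_id = sprintf("c%03d", i), sex = i %% 2,
                   age = c(2, 10, 20), height = c(55, 70, 83)))))
  split <- make_split(d, scenario_spec("new_individuals", holdout_fraction = 0.2,
                                       seed = 5))
  expect_length(split$affected_subjects, 43)  # ceiling(0.2 * 215)
  out_ids <- unique(d$subject_id[split$out_of_sample])
  expect_setequal(out_ids, split$affected_subjects)
  # every record of a held-out child is out of sample
  expect_equal(sum(d$subject_id %in% out_ids), length(split$out_of_sample))
})

test_that("splits are deterministic, partition the records, and respect age order", {
  sim <- small_cohort(n = 30, seed = 41)
  d <- sim$data
  for (sc in c("backward", "forward", "in_range", "new_individuals")) {
    sp <- scenario_spec(sc, holdout_fraction = 0.2, seed = 9)
    s1 <- make_split(d, sp)
    s2 <- make_split(d, sp)
    expect_identical(s1$out_of_sample, s2$out_of_sample)
    expect_setequal(c(s1$in_sample, s1$out_of_sample), seq_len(nrow(d)))
    expect_length(intersect(s1$in_sample, s1$out_of_sample), 0)
    for (id in s1$affected_subjects) {
      rows <- which(d$subject_id == id)
      ins <- d$age[intersect(rows, s1$in_sample)]
      outs <- d$age[intersect(rows, s1$out_of_sample)]
      if (sc == "forward") expect_true(max(ins) <= min(outs))
      if (sc == "backward") expect_true(min(ins) >= max(outs))
      if (sc == "in_range") {
        expect_false(d$age[rows[1]] %in% outs)
        expect_false(d$age[rows[length(rows)]] %in% outs)
      }
      if (sc == "new_individuals") expect_length(ins, 0)
    }
  }
})

test_that("degenerate split requests fail or warn as contracted", {
  d <- as_growth_dataset(tibble::tibble(
    subject_id = rep(c("a", "b"), each = 2), sex = rep(c(0L, 1L), each = 2),
    age = rep(c(1, 2), 2), height = rep(c(50, 52), 2)))
  expect_error(make_split(d, scenario_spec("forward", holdout_fraction = 0.99,
                                           child_fraction = 1, seed = 1)),
               "empty", class = "growthsel_split_error")
  expect_warning(make_split(d, scenario_spec("in_range", holdout_fraction = 0.2,
                                             child_fraction = 1, seed = 1)),
                 "skipped")
})

test_that("held-out records never influence model fitting", {
  sim <- small_cohort(n = 25, seed = 43)
  d <- sim$data
  sp <- scenario_spec("forward", holdout_fraction = 0.2, seed = 7)
  split <- make_split(d, sp)
  poisoned <- d
  poisoned$height[split$out_of_sample] <- 999  # absurd but valid heights
  poisoned <- as_growth_dataset(poisoned)
  res <- run_scenario(d, sp, models = c("lme", "fpca"), metrics = "mse",
                      split = split)
  resp <- run_scenario(poisoned, sp, models = c("lme", "fpca"), metrics = "mse",
                       split = split)
  expect_equal(resp$fits$lme$coefs, res$fits$lme$coefs, tolerance = 1e-12)
  expect_equal(resp$fits$lme$G, res$fits$lme$G, tolerance = 1e-12)
  expect_equal(resp$fits$fpca$mean_values, res$fits$fpca$mean_values,
               tolerance = 1e-12)
  expect_equal(resp$fits$fpca$eigenvalues, res$fits$fpca$eigenvalues,
               tolerance = 1e-12)
  # predictions at held-out points are unchanged too (only conditioning on
  # in-sample records); observed values differ by construction
  expect_equal(resp$predictions$predicted, res$predictions$predicted,
               tolerance = 1e-12)
})

test_that("a subject-aware model beats the population mean out of sample", {
  sim <- sim_lme_truth(n = 60, m_mean = 15, seed = 45)
  sp <- scenario_spec("in_range", holdout_fraction = 0.2, seed = 11)
  res <- run_scenario(sim$data, sp, models = "lme", metrics = "mse")
  fit <- res$fits$lme
  held <- sim$data[res$split$out_of_sample, ]
  base <- dplyr::bind_rows(lapply(unique(held$subject_id), function(id) {
    tgt <- held[held$subject_id == id, ]
    tibble::tibble(subject_id = id, age = tgt$age, observed = tgt$height,
                   predicted = predict_lme(fit, tgt$age, tgt$sex[1],
                                           condition = FALSE),
                   model = "population")
  }))
  m_lme <- median(res$metrics$value[res$metrics$metric == "mse"])
  m_base <- median(mse_per_subject(prediction_set(base))$value)
  expect_lte(m_lme, m_base)
})

test_that("conditioning on a new individual's observations helps prediction", {
  sim <- small_cohort(n = 40, seed = 47)
  sp <- scenario_spec("new_individuals", holdout_fraction = 0.2, seed = 13)
  cond <- run_scenario(sim$data, sp, models = "fpca", metrics = "mse")
  pop <- run_scenario(sim$data, sp, models = "fpca", metrics = "mse",
                      condition_new = FALSE)
  expect_lt(median(cond$metrics$value), median(pop$metrics$value))
})

test_that("the full comparison runs, summarises and reproduces byte-identically", {
  cfg <- list(scenarios = c("in_range", "new_individuals"),
              holdout_fractions = 0.2, models = "fpca",
              metrics = c("mse", "wmse"), seed = 3,
              cohort = list(n_subjects = 30))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- suppressMessages(run_comparison(cfg, out_dir = out1))
  r2 <- suppressMessages(run_comparison(cfg, out_dir = out2))
  expect_identical(readLines(file.path(out1, "summary.csv")),
                   readLines(file.path(out2, "summary.csv")))
  expect_length(r1$failures, 0)
  expect_setequal(unique(r1$summary$scenario), c("in_range", "new_individuals"))
  # one best model per scenario x metric
  best <- dplyr::filter(r1$summary, best, stratum == "all")
  expect_equal(nrow(best), 4)
  expect_true(file.exists(file.path(out1, "provenance.json")))
  expect_true(file.exists(file.path(out1, "sensitivity.csv")))
  prov <- jsonlite::fromJSON(file.path(out1, "provenance.json"))
  expect_equal(prov$seeds$master, 3)
})

test_that("invalid configurations fail before any computation", {
  expect_error(run_comparison(list(scenarios = "sideways")),
               "unknown scenario", class = "growthsel_config_error")
  expect_error(run_comparison(list(models = "deep_net")),
               "unknown model", class = "growthsel_config_error")
  expect_error(run_comparison(list(metriks = "mse")),
               "unknown config", class = "growthsel_config_error")
  expect_error(run_comparison(list(holdout_fractions = 1.2)),
               class = "growthsel_config_error")
})
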