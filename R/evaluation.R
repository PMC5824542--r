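#' Hold-out scenario specification
#'
#' Describes one pattern of induced missingness used to measure
#' out-of-sample error: `backward` (each affected child's earliest records
#' held out), `forward` (latest records), `in_range` (interior records,
#' never a child's first or last), or `new_individuals` (whole children).
#'
#' @param scenario One of `"backward"`, `"forward"`, `"in_range"`,
#'   `"new_individuals"`.
#' @param holdout_fraction Fraction of each affected child's records (or of
#'   children, for `new_individuals`) to hold out. Default 0.2, the primary
#'   analysis; 0.1 and 0.5 are the usual sensitivity settings.
#' @param child_fraction Fraction of children affected in the per-child
#'   scenarios. Default 0.5. Ignored for `new_individuals`.
#' @param seed Integer seed making the split reproducible.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("backward", "forward", "in_range",
                                       "new_individuals"),
                          holdout_fraction = 0.2, child_fraction = 0.5,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(holdout_fraction > 0, holdout_fraction < 1,
            child_fraction > 0, child_fraction <= 1)
  structure(list(scenario = scenario, holdout_fraction = holdout_fraction,
                 child_fraction = child_fraction, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Partition a dataset into in-sample and out-of-sample records
#'
#' Children are selected uniformly at random. For each affected child with
#' `m_i` records, `ceiling(h * m_i)` records are held out: the earliest by
#' age (`backward`), the latest (`forward`), or a uniform draw from the
#' interior records — never the child's first or last (`in_range`). For
#' `new_individuals`, `ceiling(h * n)` whole children are held out. Every
#' affected child retains at least one in-sample record in the per-child
#' scenarios (otherwise the split errors); `in_range` children with two or
#' fewer records are skipped with a warning.
#'
#' @param dataset A `growth_dataset`.
#' @param spec A [scenario_spec()].
#' @return An `evaluation_split`: integer row indices `in_sample` and
#'   `out_of_sample` (a partition of affected rows), the affected subject
#'   ids, and the scenario specification.
#' @export
make_split <- function(dataset, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  ids <- sort(unique(dataset$subject_id))
  n <- length(ids)
  h <- spec$holdout_fraction
  out <- integer(0)
  if (spec$scenario == "new_individuals") {
    held <- sample(ids, min(ceiling(h * n), n - 1))
    out <- which(dataset$subject_id %in% held)
    affected <- held
  } else {
    affected <- sample(ids, ceiling(spec$child_fraction * n))
    skipped <- character(0)
    for (id in affected) {
      idx <- which(dataset$subject_id == id)  # rows already age-ordered
      m <- length(idx)
      cnt <- ceiling(h * m)
      if (spec$scenario %in% c("backward", "forward") && cnt >= m) {
        abort(paste0("holding out ", cnt, " of ", m,
                     " records would empty subject ", id, "'s in-sample set"),
              class = "growthsel_split_error")
      }
      if (spec$scenario == "backward") {
        out <- c(out, idx[seq_len(cnt)])
      } else if (spec$scenario == "forward") {
        out <- c(out, idx[(m - cnt + 1):m])
      } else {  # in_range
        if (m <= 2) {
          skipped <- c(skipped, id)
          next
        }
        interior <- idx[2:(m - 1)]
        take <- min(cnt, length(interior))
        out <- c(out, sort(sample(interior, take)))
      }
    }
    if (length(skipped) > 0) {
      warn(paste0("in_range: skipped ", length(skipped),
                  " child(ren) with <= 2 records"))
      affected <- setdiff(affected, skipped)
    }
  }
  out <- sort(out)
  structure(list(in_sample = setdiff(seq_len(nrow(dataset)), out),
                 out_of_sample = out,
                 affected_subjects = sort(affected),
                 spec = spec),
            class = "evaluation_split")
}

#' @export
print.evaluation_split <- function(x, ...) {
  cat(sprintf("<evaluation_split: %s, h=%.2f, %d in-sample / %d out-of-sample records, %d affected subjects>\n",
              x$spec$scenario, x$spec$holdout_fraction, length(x$in_sample),
              length(x$out_of_sample), length(x$affected_subjects)))
  invisible(x)
}

model_registry <- function(knots, grid_size, pve, grid_range) {
  list(
    lme = list(
      fit = function(train) fit_lme(train, knots = knots),
      predict = function(fit, obs, sex, ages) predict_lme(fit, ages, sex, obs)
    ),
    fpca = list(
      fit = function(train) fit_fpca(train, grid_size = grid_size, pve = pve,
                                     grid_range = grid_range),
      predict = function(fit, obs, sex, ages) {
        xi <- score_subject(fit, obs, sex_offset = 0)
        predict_fpca(fit, xi, ages)
      }
    ),
    fcr = list(
      fit = function(train) fit_fcr(train, grid_size = grid_size, pve = pve,
                                    grid_range = grid_range),
      predict = function(fit, obs, sex, ages) predict_fcr(fit, obs, sex, ages)
    )
  )
}

#' Run one hold-out scenario across models and metrics
#'
#' Constructs (or accepts) a split, fits every requested model on the
#' in-sample records only, predicts the held-out heights, and computes the
#' requested per-subject metrics on the held-out points (so `m_i` is the
#' subject's out-of-sample count). Predictions for a partially observed
#' child condition on that child's in-sample records; for `new_individuals`
#' the held-out child's own observations are used for subject-level
#' conditioning under the frozen population fit (set
#' `condition_new = FALSE` for pure population predictions instead).
#' Velocity-quartile weights for wMSE are computed over all subjects of the
#' full dataset.
#'
#' @param dataset A `growth_dataset`.
#' @param spec A [scenario_spec()].
#' @param models Subset of `c("lme", "fpca", "fcr")`.
#' @param metrics Subset of `c("mse", "nmse", "amse", "wmse")`.
#' @param strata Age edges for aMSE. Default `c(0, 6, 12, 18, 24)` months.
#' @param knots LME spline knots, months.
#' @param grid_size,pve Functional-model settings (see [fit_fpca()]).
#' @param condition_new Condition on held-out children's own observations
#'   in `new_individuals` (default `TRUE`).
#' @param split Optional precomputed [make_split()] result.
#' @param velocity_weights Optional precomputed [velocity_quartiles()]
#'   table.
#' @return A list: `split`, `fits`, `predictions` (a [prediction_set()]),
#'   `metrics` (tidy per-subject values), `summary` (median/IQR per
#'   model/metric with best-model flags), `failures` (named character
#'   vector of model failures, empty when all fit).
#' @export
run_scenario <- function(dataset, spec,
                         models = c("lme", "fpca", "fcr"),
                         metrics = c("mse", "nmse", "amse", "wmse"),
                         strata = c(0, 6, 12, 18, 24),
                         knots = c(3, 6, 12, 18),
                         grid_size = 101, pve = 0.99,
                         condition_new = TRUE,
                         split = NULL, velocity_weights = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  split <- split %||% make_split(dataset, spec)
  train <- as_growth_dataset(dataset[split$in_sample, ],
                             age_max = attr(dataset, "age_max") %||% 24)
  heldout <- dataset[split$out_of_sample, ]
  registry <- model_registry(knots, grid_size, pve,
                             grid_range = range(dataset$age))
  new_ind <- spec$scenario == "new_individuals"
  failures <- character(0)
  fits <- list()
  pred_rows <- list()
  for (mod in models) {
    fit <- tryCatch(registry[[mod]]$fit(train), error = function(e) e)
    if (inherits(fit, "error")) {
      failures[mod] <- conditionMessage(fit)
      next
    }
    fits[[mod]] <- fit
    preds <- lapply(unique(heldout$subject_id), function(id) {
      tgt <- heldout[heldout$subject_id == id, ]
      obs_src <- if (new_ind) {
        if (condition_new) subject_view(dataset, id) else NULL
      } else {
        sv <- train[train$subject_id == id, ]
        list(age = sv$age, height = sv$height)
      }
      tibble(subject_id = id, age = tgt$age, observed = tgt$height,
             predicted = registry[[mod]]$predict(fit, obs_src, tgt$sex[1],
                                                 tgt$age),
             model = mod)
    })
    pred_rows[[mod]] <- dplyr::bind_rows(preds)
  }
  predictions <- prediction_set(dplyr::bind_rows(pred_rows))
  value_tabs <- list()
  if ("mse" %in% metrics) {
    value_tabs$mse <- dplyr::mutate(mse_per_subject(predictions),
                                    metric = "mse", stratum = "all")
  }
  if ("nmse" %in% metrics) {
    value_tabs$nmse <- dplyr::mutate(nmse_per_subject(predictions),
                                     metric = "nmse", stratum = "all")
  }
  if ("amse" %in% metrics) {
    value_tabs$amse <- amse_per_subject(predictions, strata = strata) |>
      dplyr::filter(!.data$empty) |>
      dplyr::mutate(metric = "amse") |>
      dplyr::select(!dplyr::any_of(c("n_stratum", "empty")))
  }
  if ("wmse" %in% metrics) {
    velocity_weights <- velocity_weights %||%
      velocity_quartiles(height_velocities(dataset))
    value_tabs$wmse <- dplyr::mutate(
      wmse_per_subject(predictions, velocity_weights),
      metric = "wmse", stratum = "all") |>
      dplyr::select(!dplyr::any_of("weight"))
  }
  vals <- dplyr::bind_rows(value_tabs) |>
    dplyr::mutate(scenario = spec$scenario,
                  holdout_fraction = spec$holdout_fraction) |>
    dplyr::select(dplyr::all_of(c("scenario", "holdout_fraction", "model",
                                  "metric", "stratum", "subject_id", "value")))
  list(split = split, fits = fits, predictions = predictions,
       metrics = vals, summary = summarize_metrics(vals),
       failures = failures)
}

default_config <- function() {
  list(
    scenarios = c("backward", "forward", "in_range", "new_individuals"),
    holdout_fractions = c(0.1, 0.2, 0.5),
    child_fraction = 0.5,
    models = c("lme", "fpca", "fcr"),
    metrics = c("mse", "nmse", "amse", "wmse"),
    strata = c(0, 6, 12, 18, 24),
    knots = c(3, 6, 12, 18),
    grid_size = 101,
    pve = 0.99,
    seed = 1L,
    data = NULL,
    cohort = list()
  )
}

child_seed <- function(master, k) {
  as.integer((as.double(master) + 10007 * as.double(k)) %% 2147483629) + 1L
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "growthsel_config_error")
  }
  cfg <- utils::modifyList(base, config)
  bad <- setdiff(cfg$scenarios,
                 c("backward", "forward", "in_range", "new_individuals"))
  if (length(bad) > 0) {
    abort(paste0("unknown scenario(s): ", paste(bad, collapse = ", ")),
          class = "growthsel_config_error")
  }
  bad <- setdiff(cfg$models, c("lme", "fpca", "fcr"))
  if (length(bad) > 0) {
    abort(paste0("unknown model(s): ", paste(bad, collapse = ", ")),
          class = "growthsel_config_error")
  }
  bad <- setdiff(cfg$metrics, c("mse", "nmse", "amse", "wmse"))
  if (length(bad) > 0) {
    abort(paste0("unknown metric(s): ", paste(bad, collapse = ", ")),
          class = "growthsel_config_error")
  }
  if (!all(cfg$holdout_fractions > 0 & cfg$holdout_fractions < 1)) {
    abort("holdout_fractions must lie in (0, 1)", class = "growthsel_config_error")
  }
  cfg
}

#' Run the full model comparison
#'
#' Runs every requested scenario at every hold-out fraction over every
#' model and metric, on either a data file or a simulated cohort, and
#' writes the comparison report. A master seed deterministically spawns a
#' named seed per scenario-by-fraction cell (and one for simulation), so
#' identical configurations reproduce byte-identical summaries.
#'
#' @param config Either a named list of settings or the path to a YAML file
#'   with the same flat keys: `scenarios`, `holdout_fractions`,
#'   `child_fraction`, `models`, `metrics`, `strata`, `knots`, `grid_size`,
#'   `pve`, `seed`, and one of `data` (a CSV readable by
#'   [read_growth_table()]) or `cohort` (overrides for [cohort_spec()];
#'   the default cohort is simulated when both are absent).
#' @param out_dir Optional output directory; when given, writes
#'   `metrics.csv`, `summary.csv`, `sensitivity.csv`, `run.log` and
#'   `provenance.json`.
#' @return A `comparison_report`: `metrics` (per-subject values),
#'   `summary` (median/IQR with best-model flags), `sensitivity` (medians
#'   across hold-out fractions), `failures`, `provenance`.
#' @export
run_comparison <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  sim_seed <- child_seed(cfg$seed, 0)
  if (!is.null(cfg$data)) {
    dataset <- read_growth_table(cfg$data)
    say("loaded %d subjects / %d records from %s", n_subjects(dataset),
        nrow(dataset), cfg$data)
  } else {
    spec <- do.call(cohort_spec, utils::modifyList(list(seed = sim_seed),
                                                   as.list(cfg$cohort)))
    dataset <- simulate_cohort(spec)$data
    say("simulated cohort: %d subjects / %d records (seed %d)",
        n_subjects(dataset), nrow(dataset), sim_seed)
  }
  vw <- if ("wmse" %in% cfg$metrics) {
    velocity_quartiles(height_velocities(dataset))
  } else NULL
  cells <- expand.grid(scenario = cfg$scenarios,
                       holdout_fraction = cfg$holdout_fractions,
                       stringsAsFactors = FALSE)
  all_metrics <- list()
  failures <- list()
  seeds <- list(master = cfg$seed, simulation = sim_seed)
  for (k in seq_len(nrow(cells))) {
    sc <- cells$scenario[k]
    h <- cells$holdout_fraction[k]
    sk <- child_seed(cfg$seed, k)
    seeds[[paste0(sc, "_h", h)]] <- sk
    spec <- scenario_spec(sc, holdout_fraction = h,
                          child_fraction = cfg$child_fraction, seed = sk)
    say("scenario %s, holdout %.0f%% (seed %d)", sc, 100 * h, sk)
    res <- run_scenario(dataset, spec, models = cfg$models,
                        metrics = cfg$metrics, strata = cfg$strata,
                        knots = cfg$knots, grid_size = cfg$grid_size,
                        pve = cfg$pve, velocity_weights = vw)
    all_metrics[[k]] <- res$metrics
    if (length(res$failures) > 0) {
      failures[[paste0(sc, "_h", h)]] <- res$failures
      for (mod in names(res$failures)) {
        say("  FAILED %s: %s", mod, res$failures[mod])
      }
    }
  }
  metrics <- dplyr::bind_rows(all_metrics)
  summary <- summarize_metrics(metrics)
  sensitivity <- summary |>
    dplyr::filter(.data$stratum == "all" | !.data$metric %in% "amse") |>
    dplyr::select(dplyr::all_of(c("scenario", "model", "metric", "stratum",
                                  "holdout_fraction", "median", "q25", "q75")))
  provenance <- list(
    package = "growthsel",
    version = as.character(utils::packageVersion("growthsel")),
    seeds = seeds,
    config = cfg[setdiff(names(cfg), c("data", "cohort"))],
    config_hash = rlang::hash(cfg[order(names(cfg))]),
    n_subjects = n_subjects(dataset),
    n_records = nrow(dataset)
  )
  report <- structure(list(metrics = metrics, summary = summary,
                           sensitivity = sensitivity,
                           failures = failures, provenance = provenance),
                      class = "comparison_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_csv(metrics, file.path(out_dir, "metrics.csv"))
    write_report_csv(summary, file.path(out_dir, "summary.csv"))
    write_report_csv(sensitivity, file.path(out_dir, "sensitivity.csv"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("report written to %s", out_dir)
  }
  report
}

# fixed-format CSV writer so identical runs are byte-identical
write_report_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report: %d scenario cells, %d models, %d per-subject values>\n",
              nrow(unique(x$summary[c("scenario", "holdout_fraction")])),
              length(unique(x$summary$model)), nrow(x$metrics)))
  best <- dplyr::filter(x$summary, .data$best, .data$stratum == "all")
  print(as_tibble(best), n = 30)
  invisible(x)
}
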