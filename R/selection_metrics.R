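#' Prediction sets
#'
#' A `prediction_set` pairs observed and predicted heights at held-out
#' (subject, age) points, per model. It is a tibble with columns
#' `subject_id`, `age`, `observed`, `predicted`, `model`; each
#' (subject, age, model) combination appears exactly once. The per-subject
#' denominators `m_i` used by all metrics are the counts of that subject's
#' evaluated records.
#'
#' @param x A data frame with the five columns above.
#' @return A validated `prediction_set`.
#' @export
prediction_set <- function(x) {
  need <- c("subject_id", "age", "observed", "predicted", "model")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("prediction set lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "growthsel_config_error")
  }
  d <- as_tibble(x)[need]
  d$subject_id <- as.character(d$subject_id)
  d$model <- as.character(d$model)
  if (anyNA(d$observed) || anyNA(d$predicted)) {
    abort("prediction set contains missing observed/predicted values",
          class = "growthsel_validation_error")
  }
  if (anyDuplicated(d[c("subject_id", "age", "model")]) > 0) {
    abort("duplicated (subject, age, model) rows in prediction set",
          class = "growthsel_validation_error")
  }
  structure(d, class = c("prediction_set", class(tibble())))
}

#' Subject-specific mean squared error
#'
#' `MSE_i = (1/m_i) sum_j (Y_ij - Yhat_ij)^2` over each subject's evaluated
#' records, per model.
#'
#' @param preds A [prediction_set()].
#' @return Tibble with `model`, `subject_id`, `m` (records evaluated) and
#'   `value` (cm^2).
#' @export
mse_per_subject <- function(preds) {
  preds |>
    dplyr::group_by(.data$model, .data$subject_id) |>
    dplyr::summarise(m = dplyr::n(),
                     value = mean((.data$observed - .data$predicted)^2),
                     .groups = "drop")
}

#' Subject-specific normalized mean squared error
#'
#' `nMSE_i = (1/m_i) sum_j (Y_ij - Yhat_ij)^2 / Y_ij^2` — squared relative
#' errors, unit-free, so trajectories measured on different scales compare
#' fairly.
#'
#' @inheritParams mse_per_subject
#' @return Tibble with `model`, `subject_id`, `m`, `value` (dimensionless).
#' @export
nmse_per_subject <- function(preds) {
  if (any(preds$observed <= 0)) {
    bad <- which(preds$observed <= 0)[1]
    abort(sprintf("nMSE needs positive observed values; subject %s at age %.3f is %.3f",
                  preds$subject_id[bad], preds$age[bad], preds$observed[bad]),
          class = "growthsel_domain_error")
  }
  preds |>
    dplyr::group_by(.data$model, .data$subject_id) |>
    dplyr::summarise(m = dplyr::n(),
                     value = mean(((.data$observed - .data$predicted) / .data$observed)^2),
                     .groups = "drop")
}

#' Subject-specific age-stratified mean squared error
#'
#' Splits each subject's squared errors by age stratum:
#' `aMSE_is = (1/m_i) sum_{j in stratum s} (Y_ij - Yhat_ij)^2`. The divisor
#' is the subject's total evaluated count `m_i` (not the per-stratum
#' count), so the strata values of a subject sum exactly to the subject's
#' MSE; set `per_stratum_mean = TRUE` for the within-stratum-mean variant.
#'
#' @inheritParams mse_per_subject
#' @param strata Increasing age edges, months; intervals are
#'   left-closed/right-open with the final interval closed. Default
#'   `c(0, 6, 12, 18, 24)`.
#' @param per_stratum_mean Divide by the per-stratum count instead of
#'   `m_i`. Default `FALSE`.
#' @return Tibble with `model`, `subject_id`, `stratum`, `m`, `n_stratum`,
#'   `value` and `empty` (no records in that stratum for the subject).
#' @export
amse_per_subject <- function(preds, strata = c(0, 6, 12, 18, 24),
                             per_stratum_mean = FALSE) {
  strata <- as.numeric(strata)
  if (length(strata) < 2 || is.unsorted(strata, strictly = TRUE)) {
    abort("strata edges must be strictly increasing (non-overlapping intervals)",
          class = "growthsel_config_error")
  }
  if (min(preds$age) < strata[1] || max(preds$age) > strata[length(strata)]) {
    abort("strata do not cover the evaluated age range",
          class = "growthsel_config_error")
  }
  nS <- length(strata) - 1
  labels <- paste0("[", strata[-length(strata)], ",", strata[-1],
                   c(rep(")", nS - 1), "]"))
  idx <- pmin(findInterval(preds$age, strata), nS)
  d <- preds
  d$stratum <- factor(labels[idx], levels = labels)
  per <- d |>
    dplyr::group_by(.data$model, .data$subject_id, .data$stratum, .drop = FALSE) |>
    dplyr::summarise(n_stratum = dplyr::n(),
                     sse = sum((.data$observed - .data$predicted)^2),
                     .groups = "drop")
  tot <- d |>
    dplyr::group_by(.data$model, .data$subject_id) |>
    dplyr::summarise(m = dplyr::n(), .groups = "drop")
  out <- dplyr::inner_join(per, tot, by = c("model", "subject_id"))
  out$value <- if (per_stratum_mean) {
    ifelse(out$n_stratum > 0, out$sse / out$n_stratum, 0)
  } else {
    out$sse / out$m
  }
  out$empty <- out$n_stratum == 0
  out$stratum <- as.character(out$stratum)
  out[c("model", "subject_id", "stratum", "m", "n_stratum", "value", "empty")]
}

#' Infancy height velocity of one subject
#'
#' Finite-difference growth rate between the subject's observation closest
#' to 3 months and the one closest to 12 months of age (ties broken toward
#' the earlier age). A warning is emitted when an anchor lies more than
#' `warn_window` months from its target.
#'
#' @param dataset A `growth_dataset`.
#' @param subject_id Subject to evaluate.
#' @param anchors Target anchor ages, months. Default `c(3, 12)`.
#' @param warn_window Proximity warning threshold, months. Default 1.5.
#' @return Velocity in cm/month.
#' @export
height_velocity <- function(dataset, subject_id, anchors = c(3, 12),
                            warn_window = 1.5) {
  sv <- subject_view(dataset, subject_id)
  pick <- function(target) {
    d <- abs(sv$age - target)
    which(d == min(d))[1]  # tie -> earlier age (ages sorted increasing)
  }
  i3 <- pick(anchors[1]); i12 <- pick(anchors[2])
  if (i3 == i12) {
    abort(paste0("height velocity undefined for subject ", subject_id,
                 ": both anchors resolve to the same observation"),
          class = "growthsel_domain_error")
  }
  if (abs(sv$age[i3] - anchors[1]) > warn_window ||
      abs(sv$age[i12] - anchors[2]) > warn_window) {
    warn(paste0("subject ", subject_id, ": velocity anchor more than ",
                warn_window, " months from its target age"))
  }
  (sv$height[i12] - sv$height[i3]) / (sv$age[i12] - sv$age[i3])
}

#' Infancy height velocities for every subject
#'
#' @inheritParams height_velocity
#' @return Tibble with `subject_id` and `velocity` (cm/month). Subjects for
#'   whom the velocity is undefined are dropped with a warning.
#' @export
height_velocities <- function(dataset, anchors = c(3, 12), warn_window = 1.5) {
  ids <- unique(dataset$subject_id)
  v <- vapply(ids, function(id) {
    tryCatch(suppressWarnings(height_velocity(dataset, id, anchors, warn_window)),
             growthsel_domain_error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(v)) {
    warn(paste0("velocity undefined for ", sum(is.na(v)), " subject(s); dropped"))
  }
  tibble(subject_id = ids[!is.na(v)], velocity = unname(v[!is.na(v)]))
}

#' Quartile weights from height velocities
#'
#' Each subject's velocity is ranked among all subjects (average ranks for
#' ties) and converted to a percentile `(rank - 1) / n * 100`; percentiles
#' in [0, 25), [25, 50), [50, 75) and [75, 100] receive weights 1, 2, 3 and
#' 4 respectively, so slower-growing children carry more weight (a smaller
#' divisor) in the weighted error.
#'
#' @param velocities Tibble with `subject_id` and `velocity` (from
#'   [height_velocities()]), or a named numeric vector.
#' @return A `VelocityTable` tibble: `subject_id`, `velocity`,
#'   `percentile`, `weight` (integer 1–4).
#' @export
velocity_quartiles <- function(velocities) {
  if (is.numeric(velocities)) {
    velocities <- tibble(subject_id = names(velocities),
                         velocity = unname(velocities))
  }
  n <- nrow(velocities)
  if (n < 4) {
    warn("fewer than 4 subjects: velocity quartiles degenerate, all weights set to 1")
    return(tibble(subject_id = velocities$subject_id,
                  velocity = velocities$velocity,
                  percentile = rep(NA_real_, n), weight = rep(1L, n)))
  }
  r <- rank(velocities$velocity, ties.method = "average")
  pct <- (r - 1) / n * 100
  weight <- 1L + (pct >= 25) + (pct >= 50) + (pct >= 75)
  tibble(subject_id = velocities$subject_id, velocity = velocities$velocity,
         percentile = pct, weight = as.integer(weight))
}

#' Subject-specific velocity-weighted mean squared error
#'
#' `wMSE_i = MSE_i / w_i` where `w_i` is the subject's height-velocity
#' quartile weight (1–4): errors on slower-growing children are divided by
#' less and so count for more.
#'
#' @inheritParams mse_per_subject
#' @param weights A [velocity_quartiles()] table covering every evaluated
#'   subject.
#' @return Tibble with `model`, `subject_id`, `m`, `weight`, `value`.
#' @export
wmse_per_subject <- function(preds, weights) {
  mse <- mse_per_subject(preds)
  missing_w <- setdiff(mse$subject_id, weights$subject_id)
  if (length(missing_w) > 0) {
    abort(paste0("no quartile weight for subject(s): ",
                 paste(missing_w, collapse = ", ")),
          class = "growthsel_config_error")
  }
  out <- dplyr::left_join(mse, weights[c("subject_id", "weight")],
                          by = "subject_id")
  out$value <- out$value / out$weight
  out[c("model", "subject_id", "m", "weight", "value")]
}

#' Median/IQR summary of per-subject metric values
#'
#' Summarises per-subject values by every grouping column present (any of
#' `scenario`, `holdout_fraction`, `model`, `metric`, `stratum`), reporting
#' the median and the 25th/75th percentiles (linear interpolation between
#' order statistics). Within each group defined by everything except
#' `model`, the model with the smallest median is flagged as best.
#'
#' @param values Tibble with a `value` column, a `model` column, and any of
#'   the grouping columns above.
#' @return Summary tibble with `median`, `q25`, `q75`, `n_subjects`,
#'   `best`.
#' @export
summarize_metrics <- function(values) {
  group_cols <- intersect(c("scenario", "holdout_fraction", "model",
                            "metric", "stratum"), names(values))
  out <- values |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(median = median(.data$value),
                     q25 = unname(quantile(.data$value, 0.25, type = 7)),
                     q75 = unname(quantile(.data$value, 0.75, type = 7)),
                     n_subjects = dplyr::n(),
                     .groups = "drop")
  rival_cols <- setdiff(group_cols, "model")
  out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(rival_cols))) |>
    dplyr::mutate(best = .data$median == min(.data$median)) |>
    dplyr::ungroup()
}
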