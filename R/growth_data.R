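#' Longitudinal growth datasets
#'
#' A `growth_dataset` is a tibble in long format with one row per
#' measurement and four canonical columns:
#'
#' * `subject_id` (character) — opaque child identifier,
#' * `sex` (integer 0/1; 1 = male by default),
#' * `age` (numeric, months),
#' * `height` (numeric, cm, strictly positive).
#'
#' Rows are ordered by subject and then by strictly increasing age; every
#' subject carries a single constant sex code. These invariants are what the
#' model-fitting and hold-out machinery rely on (the continuous-AR(1) error
#' model is degenerate at duplicated ages, and normalized errors need
#' positive heights), so construction always validates.
#'
#' @param x A data frame with the four canonical columns.
#' @param age_max Upper bound for valid ages, months. Default 24.
#' @param on_invalid How to treat rows violating row-level invariants
#'   (non-finite or out-of-range age, non-positive height, missing values):
#'   `"drop"` removes them with a warning and attaches the rejected rows as
#'   the `"validation"` attribute; `"error"` aborts.
#'
#' @return A validated `growth_dataset` (a tibble subclass).
#' @export
as_growth_dataset <- function(x, age_max = 24, on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  need <- c("subject_id", "sex", "age", "height")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
          class = "growthsel_config_error")
  }
  d <- as_tibble(x)[need]
  d$subject_id <- as.character(d$subject_id)
  d$sex <- as.integer(d$sex)
  d$age <- as.numeric(d$age)
  d$height <- as.numeric(d$height)
  d$.row <- seq_len(nrow(d))

  bad_sex <- !(d$sex %in% c(0L, 1L)) | is.na(d$sex)
  bad_age <- !is.finite(d$age) | d$age < 0 | d$age > age_max
  bad_height <- !is.finite(d$height) | d$height <= 0
  bad <- bad_sex | bad_age | bad_height | is.na(d$subject_id)
  rejected <- tibble()
  if (any(bad)) {
    reason <- dplyr::case_when(
      is.na(d$subject_id)[bad] ~ "missing subject id",
      bad_sex[bad] ~ "sex not codable as 0/1",
      bad_age[bad] ~ sprintf("age outside [0, %g] months or non-numeric", age_max),
      TRUE ~ "height not a positive number"
    )
    rejected <- tibble(row = d$.row[bad], reason = reason)
    if (on_invalid == "error") {
      abort(paste0(nrow(rejected), " row(s) violate growth-record invariants; first: row ",
                   rejected$row[1], " (", rejected$reason[1], ")"),
            class = "growthsel_validation_error")
    }
    warn(paste0("dropped ", nrow(rejected),
                " row(s) violating growth-record invariants (see attr(., 'validation'))"))
    d <- d[!bad, , drop = FALSE]
  }

  # constant sex within subject
  sex_n <- tapply(d$sex, d$subject_id, function(s) length(unique(s)))
  if (any(sex_n > 1)) {
    abort(paste0("subject(s) with inconsistent sex coding: ",
                 paste(names(sex_n)[sex_n > 1], collapse = ", ")),
          class = "growthsel_validation_error")
  }

  d <- d[order(d$subject_id, d$age, d$.row), , drop = FALSE]
  dup <- duplicated(d[c("subject_id", "age")])
  if (any(dup)) {
    warn(paste0("dropped ", sum(dup),
                " duplicated (subject, age) row(s); kept first occurrence"))
    d <- d[!dup, , drop = FALSE]
  }
  d$.row <- NULL
  structure(d, class = c("growth_dataset", class(tibble())),
            age_max = age_max, validation = rejected)
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf("<growth_dataset: %d subjects, %d measurements, ages %.2f-%.2f months>\n",
              n_subjects(x), nrow(x), min(x$age), max(x$age)))
  NextMethod()
}

#' Number of subjects in a growth dataset
#' @param dataset A `growth_dataset`.
#' @return Integer count of distinct subjects.
#' @export
n_subjects <- function(dataset) length(unique(dataset$subject_id))

#' Per-subject measurement counts
#' @param dataset A `growth_dataset`.
#' @return Named integer vector, one entry per subject (m_i).
#' @export
obs_counts <- function(dataset) {
  tab <- table(dataset$subject_id)
  setNames(as.integer(tab), names(tab))
}

#' Extract one subject's trajectory
#'
#' @param dataset A `growth_dataset`.
#' @param subject_id Identifier of the subject to extract.
#' @return A list with `age` (strictly increasing), `height` (same length)
#'   and scalar `sex`.
#' @export
subject_view <- function(dataset, subject_id) {
  d <- dataset[dataset$subject_id == subject_id, , drop = FALSE]
  if (nrow(d) == 0) {
    abort(paste0("unknown subject: ", subject_id), class = "growthsel_lookup_error")
  }
  list(age = d$age, height = d$height, sex = d$sex[1])
}

#' Read a long-format growth table
#'
#' Reads a delimited text file with one measurement per row. Column roles are
#' resolved through `col_map`, so files with arbitrary headers can be
#' ingested; sex may be coded 0/1 or with labels (e.g. `"M"`/`"F"`) declared
#' via `sex_codes`. Ages recorded in days are converted to months
#' (days / 30.4375) when `age_unit = "days"`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param col_map Named character vector mapping roles
#'   `c(subject_id=, sex=, age=, height=)` to column names in the file.
#' @param sex_codes Named vector giving the file's codes for
#'   `c(male=, female=)`. Default `c(male="1", female="0")`.
#' @param male_code Integer 0 or 1: internal code assigned to males.
#'   Default 1. Only the sign/interpretation of the fitted sex effect
#'   depends on this.
#' @param age_unit `"months"` (default) or `"days"`.
#' @param delim Field delimiter, default `","`.
#' @inheritParams as_growth_dataset
#' @return A validated `growth_dataset`.
#' @export
read_growth_table <- function(path,
                              col_map = c(subject_id = "subject_id", sex = "sex",
                                          age = "age_months", height = "height_cm"),
                              sex_codes = c(male = "1", female = "0"),
                              male_code = 1L,
                              age_unit = c("months", "days"),
                              delim = ",",
                              age_max = 24,
                              on_invalid = "drop") {
  age_unit <- match.arg(age_unit)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  need <- c("subject_id", "sex", "age", "height")
  if (!all(need %in% names(col_map))) {
    abort("col_map must name columns for subject_id, sex, age and height",
          class = "growthsel_config_error")
  }
  missing_cols <- setdiff(unname(col_map[need]), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "growthsel_config_error")
  }
  sex_raw <- trimws(raw[[col_map[["sex"]]]])
  sex <- rep(NA_integer_, length(sex_raw))
  sex[sex_raw %in% sex_codes[["male"]]] <- as.integer(male_code)
  sex[sex_raw %in% sex_codes[["female"]]] <- 1L - as.integer(male_code)
  age <- suppressWarnings(as.numeric(raw[[col_map[["age"]]]]))
  if (age_unit == "days") age <- age / 30.4375
  d <- tibble(
    subject_id = raw[[col_map[["subject_id"]]]],
    sex = sex,
    age = age,
    height = suppressWarnings(as.numeric(raw[[col_map[["height"]]]]))
  )
  as_growth_dataset(d, age_max = age_max, on_invalid = on_invalid)
}

#' Write a growth dataset to its canonical CSV form
#'
#' Writes the canonical header `subject_id,sex,age_months,height_cm` and one
#' row per measurement, with numeric fields at full double precision so that
#' `read_growth_table()` round-trips losslessly.
#'
#' @param dataset A `growth_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_growth_table <- function(dataset, path) {
  out <- data.frame(
    subject_id = dataset$subject_id,
    sex = dataset$sex,
    age_months = sprintf("%.12g", dataset$age),
    height_cm = sprintf("%.12g", dataset$height),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("cannot write to ", path, ": ", conditionMessage(ok)),
          class = "growthsel_io_error")
  }
  invisible(path)
}
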