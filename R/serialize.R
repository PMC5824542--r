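#' Serialize a model fit to JSON
#'
#' Writes the population-level parameters and per-subject effect tables of
#' an `lme_fit`, `fpca_fit` or `fcr_fit` as a flat JSON document, so a fit
#' can be stored and later reused for prediction without refitting.
#'
#' @param fit A fitted model object.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) UseMethod("write_fit")

#' @export
write_fit.lme_fit <- function(fit, path) {
  doc <- unclass(fit)
  # named vectors become JSON objects so coefficient names survive
  for (f in c("beta", "gamma", "se", "coefs")) doc[[f]] <- as.list(doc[[f]])
  doc$.class <- "lme_fit"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_fit.fpca_fit <- function(fit, path) {
  doc <- unclass(fit)
  doc$.class <- "fpca_fit"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_fit.fcr_fit <- function(fit, path) {
  doc <- unclass(fit)
  doc$fpca <- unclass(doc$fpca)
  doc$.class <- "fcr_fit"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model fit
#'
#' @param path Path to a JSON file written by [write_fit()].
#' @return The reconstructed fit object.
#' @export
read_fit <- function(path) {
  doc <- jsonlite::fromJSON(path)
  cls <- doc$.class
  doc$.class <- NULL
  rebuild <- function(d, cls) {
    if (cls == "lme_fit") {
      d$beta <- unlist(d$beta); d$gamma <- unlist(d$gamma)
      d$se <- unlist(d$se); d$coefs <- unlist(d$coefs)
      d$G <- matrix(unlist(d$G), 2, 2)
      d$blups <- as_tibble(d$blups)
    } else {
      d$eigenfunctions <- matrix(unlist(d$eigenfunctions),
                                 ncol = length(d$eigenvalues))
      d$cov_values <- matrix(unlist(d$cov_values), length(d$grid))
      d$scores <- as_tibble(d$scores)
    }
    structure(d, class = cls)
  }
  if (cls == "fcr_fit") {
    doc$fpca <- rebuild(doc$fpca, "fpca_fit")
    structure(doc, class = "fcr_fit")
  } else {
    rebuild(doc, cls)
  }
}
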