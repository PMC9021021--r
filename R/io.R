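.MODEL_SCHEMA <- "braincentile-model/1"

#' Serialize a fitted model to a portable JSON document
#'
#' The document is a language-neutral schema (version tag, specification,
#' named coefficients, study registries, random-effect variances, fit
#' metadata) written at full double precision, so write-read-write
#' round-trips are byte-identical and numerically lossless. Externally
#' produced parameter files that conform to the schema can be imported the
#' same way.
#'
#' @param object fitted `gg_gamlss` (training data is not serialized).
#' @param path output path.
#' @param overwrite logical; refuse to clobber an existing file unless
#'   TRUE.
#' @return the path, invisibly.
#' @export
write_gg_model <- function(object, path, overwrite = FALSE) {
  stopifnot(inherits(object, "gg_gamlss"))
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE", call. = FALSE)
  ser_formula <- function(f)
    list(powers = f$powers, covariates = f$covariates, random = f$random)
  doc <- list(
    schema = .MODEL_SCHEMA,
    phenotype = object$spec$phenotype,
    spec = list(mu = ser_formula(object$spec$mu),
                sigma = ser_formula(object$spec$sigma)),
    coefficients = list(
      beta_mu = as.list(object$beta_mu),
      beta_sigma = as.list(object$beta_sigma),
      alpha_nu = object$alpha_nu,
      gamma_mu = as.list(object$gamma_mu),
      gamma_sigma = as.list(object$gamma_sigma),
      delta2_mu = object$delta2_mu,
      delta2_sigma = object$delta2_sigma),
    levels = list(version = object$levels$version,
                  study = object$levels$study),
    fit = list(loglik = object$loglik, n_obs = object$n_obs,
               n_params = object$n_params, bic = object$bic,
               converged = object$converged,
               age_range = object$age_range))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gg_model
#' @export
read_gg_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || !identical(doc$schema, .MODEL_SCHEMA))
    stop("unsupported model schema '", doc$schema %||% "<missing>",
         "'; this build reads '", .MODEL_SCHEMA, "'", call. = FALSE)
  de_formula <- function(f)
    moment_formula(unlist(f$powers) %||% numeric(0),
                   unlist(f$covariates) %||% character(0),
                   isTRUE(f$random))
  spec <- gg_spec(doc$phenotype, mu = de_formula(doc$spec$mu),
                  sigma = de_formula(doc$spec$sigma))
  num <- function(x) {
    v <- unlist(x)
    if (is.null(v)) numeric(0) else v
  }
  co <- doc$coefficients
  obj <- list(
    spec = spec,
    beta_mu = num(co$beta_mu), beta_sigma = num(co$beta_sigma),
    alpha_nu = as.numeric(co$alpha_nu),
    gamma_mu = num(co$gamma_mu), gamma_sigma = num(co$gamma_sigma),
    delta2_mu = if (is.null(co$delta2_mu)) NA_real_ else
      as.numeric(co$delta2_mu),
    delta2_sigma = if (is.null(co$delta2_sigma)) NA_real_ else
      as.numeric(co$delta2_sigma),
    se_mu = NULL, se_sigma = NULL,
    loglik = as.numeric(doc$fit$loglik), penalized_loglik = NA_real_,
    n_obs = as.integer(doc$fit$n_obs),
    n_params = as.integer(doc$fit$n_params),
    bic = as.numeric(doc$fit$bic), converged = isTRUE(doc$fit$converged),
    cycles = NA_integer_,
    levels = list(version = unlist(doc$levels$version),
                  study = unlist(doc$levels$study) %||% character(0)),
    age_range = as.numeric(doc$fit$age_range),
    data = NULL, control = gg_control(), call = NULL)
  class(obj) <- "gg_gamlss"
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write centile scores or study offsets to disk
#'
#' `write_centiles` mirrors the input rows as CSV with the added `centile`,
#' `mu`, `sigma`, `nu`, `mode` columns; `write_offsets` emits the study
#' offsets as JSON.
#'
#' @param x a [centile_score()] table or [new_study_offset()] result.
#' @param path output path.
#' @param overwrite refuse to clobber unless TRUE.
#' @export
write_centiles <- function(x, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE", call. = FALSE)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centiles
#' @export
write_offsets <- function(x, path, overwrite = FALSE) {
  stopifnot(inherits(x, "study_offset"))
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE", call. = FALSE)
  json <- jsonlite::toJSON(as.data.frame(x), auto_unbox = TRUE,
                           digits = I(17), pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' Reads a YAML configuration describing a reproducible pipeline run and
#' validates the reproducibility contract: every stochastic stage must
#' carry an explicit integer seed (no wall-clock defaults).
#'
#' @param path YAML file with fields `phenotypes` (character),
#'   `seeds` (named list of integers), and optionally `input`, `output_dir`,
#'   `bootstrap_B`, `n_perm`.
#' @return validated named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$phenotypes) || !length(cfg$phenotypes))
    stop("config must list at least one phenotype", call. = FALSE)
  if (is.null(cfg$seeds) || !length(cfg$seeds))
    stop("config must carry explicit seeds (no wall-clock defaults)",
         call. = FALSE)
  bad <- names(cfg$seeds)[!vapply(cfg$seeds, function(s)
    is.numeric(s) && is.finite(s) && s == round(s), TRUE)]
  if (length(bad))
    stop("non-integer seed(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}
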