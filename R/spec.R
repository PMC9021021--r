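#' Moment formulas and model specifications
#'
#' A `moment_formula` describes the linear predictor of one distribution
#' parameter: an intercept, optional categorical fixed effects (`sex`,
#' `version`), a fractional-polynomial age trend, and an optional per-study
#' random intercept. `gg_spec` bundles the three moment formulas of a
#' generalized gamma model: \eqn{\log\mu} and \eqn{\log\sigma} carry
#' covariates and FP terms; \eqn{\nu} is intercept-only on the identity
#' scale (estimating age- or study-varying skewness reliably needs far more
#' data than the location and scale trends).
#'
#' @param powers FP power multiset (see [fp_powers()]); `numeric(0)` for no
#'   age trend.
#' @param covariates character vector of categorical covariates; subset of
#'   `c("sex", "version")`.
#' @param random logical; include a per-study random intercept.
#' @return `moment_formula`: a classed list; `gg_spec`: a classed list with
#'   elements `phenotype`, `mu`, `sigma`, `nu`.
#' @examples
#' gg_spec("gmv",
#'   mu = moment_formula(c(0, 0.5), covariates = "sex", random = TRUE),
#'   sigma = moment_formula(numeric(0), random = TRUE))
#' @export
moment_formula <- function(powers = numeric(0), covariates = character(0),
                           random = TRUE) {
  covariates <- as.character(covariates)
  bad <- setdiff(covariates, c("sex", "version"))
  if (length(bad))
    stop("unsupported covariates: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(powers = fp_powers(powers), covariates = covariates,
                 random = isTRUE(random)),
            class = "moment_formula")
}

#' @rdname moment_formula
#' @param phenotype name of the phenotype column the model applies to.
#' @param mu,sigma `moment_formula` objects for the location and scale
#'   linear predictors (log link). The `version` covariate, when used,
#'   belongs to the `mu` formula only.
#' @export
gg_spec <- function(phenotype, mu, sigma = moment_formula(numeric(0))) {
  stopifnot(is.character(phenotype), length(phenotype) == 1L,
            inherits(mu, "moment_formula"), inherits(sigma, "moment_formula"))
  if ("version" %in% sigma$covariates)
    stop("the 'version' covariate may appear only in the mu formula",
         call. = FALSE)
  structure(list(phenotype = phenotype, mu = mu, sigma = sigma,
                 nu = structure(list(powers = numeric(0),
                                     covariates = character(0),
                                     random = FALSE),
                                class = "moment_formula")),
            class = "gg_spec")
}

#' @export
print.gg_spec <- function(x, ...) {
  fmt <- function(f, name, link) {
    terms <- c("1",
               if (length(f$covariates)) f$covariates,
               if (length(f$powers))
                 paste0("fp{", paste(format(f$powers), collapse = ","), "}"),
               if (f$random) "(1 | study)")
    cat("  ", link, "(", name, ") ~ ", paste(terms, collapse = " + "),
        "\n", sep = "")
  }
  cat("Generalized gamma model specification for '", x$phenotype, "'\n",
      sep = "")
  fmt(x$mu, "mu", "log"); fmt(x$sigma, "sigma", "log")
  cat("   nu ~ 1\n")
  invisible(x)
}

#' Read and validate a phenotype table
#'
#' Reads a per-scan phenotype table from CSV or TSV (UTF-8, '.' decimal
#' separator, header required). Required columns: `participant_id`, `study`,
#' `age_days` (days post-conception), `sex` (F/M); optional: `version`,
#' `dx`, `session`, and one column per positive-valued phenotype.
#'
#' @param path file path; tab-separated when the extension is `.tsv`,
#'   otherwise comma-separated.
#' @param phenotypes optional character vector of phenotype columns that
#'   must be present and positive.
#' @return a validated `data.frame`.
#' @export
read_phenotypes <- function(path, phenotypes = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_phenotypes(tab, phenotypes)
}

#' @rdname read_phenotypes
#' @param tab a data frame in the per-scan layout.
#' @export
validate_phenotypes <- function(tab, phenotypes = NULL) {
  req <- c("participant_id", "study", "age_days", "sex")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("phenotype table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(tab$age_days) || any(!is.finite(tab$age_days)))
    stop("'age_days' must be numeric and finite", call. = FALSE)
  bad <- which(!tab$sex %in% c("F", "M"))
  if (length(bad))
    stop("'sex' must be 'F' or 'M'; offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  for (ph in phenotypes) {
    if (!ph %in% names(tab))
      stop("phenotype column '", ph, "' not found", call. = FALSE)
    if (any(!is.finite(tab[[ph]])) || any(tab[[ph]] <= 0))
      stop("phenotype '", ph, "' must be positive; offending rows: ",
           paste(utils::head(which(!(tab[[ph]] > 0)), 5L), collapse = ", "),
           call. = FALSE)
  }
  tab
}

#' Encode the design matrices of one moment formula
#'
#' Builds the fixed-effect matrix (intercept first, then indicator-coded
#' categorical covariates, then the FP age basis) and the study-indicator
#' matrix for the random intercept. Sex is coded as a single indicator with
#' female as the reference; `version` is one-hot against its first recorded
#' level. Level registries recorded at fit time are enforced at prediction
#' time: an unseen level is an error listing the known levels.
#'
#' @param tab phenotype table (see [read_phenotypes()]).
#' @param formula a [moment_formula()].
#' @param levels optional registry `list(version = ..., study = ...)` from a
#'   fitted model; when `NULL` the registry is built from `tab`.
#' @return list with `X` (fixed), `Z` (study indicators; zero columns when
#'   the formula has no random term) and `levels`.
#' @export
encode_design <- function(tab, formula, levels = NULL) {
  stopifnot(inherits(formula, "moment_formula"))
  n <- nrow(tab)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if ("sex" %in% formula$covariates) {
    bad <- setdiff(unique(tab$sex), c("F", "M"))
    if (length(bad))
      stop("unknown sex level(s) ", paste(bad, collapse = ", "),
           "; known levels: F, M", call. = FALSE)
    X <- cbind(X, sexM = as.numeric(tab$sex == "M"))
  }
  if ("version" %in% formula$covariates) {
    if (is.null(tab$version))
      stop("formula uses 'version' but the table has no version column",
           call. = FALSE)
    ver_levels <- if (!is.null(levels$version)) levels$version else
      sort(unique(as.character(tab$version)))
    bad <- setdiff(unique(as.character(tab$version)), ver_levels)
    if (length(bad))
      stop("unknown version level(s) ", paste(bad, collapse = ", "),
           "; known levels: ", paste(ver_levels, collapse = ", "),
           call. = FALSE)
    if (length(ver_levels) > 1L) {
      V <- sapply(ver_levels[-1L],
                  function(l) as.numeric(as.character(tab$version) == l))
      V <- matrix(V, nrow = n,
                  dimnames = list(NULL, paste0("version", ver_levels[-1L])))
      X <- cbind(X, V)
    }
  } else ver_levels <- NULL
  if (length(formula$powers)) {
    x <- transform_age(tab$age_days)$x
    X <- cbind(X, fp_basis(x, formula$powers))
  }
  study_levels <- if (!is.null(levels$study)) levels$study else
    sort(unique(as.character(tab$study)))
  if (formula$random) {
    Z <- sapply(study_levels,
                function(s) as.numeric(as.character(tab$study) == s))
    Z <- matrix(Z, nrow = n, dimnames = list(NULL, study_levels))
  } else {
    Z <- matrix(numeric(0), nrow = n, ncol = 0L)
  }
  list(X = X, Z = Z,
       levels = list(version = ver_levels, study = study_levels))
}
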