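#' Centile scores of observed scans under a fitted model
#'
#' The centile of a scan is the fitted generalized gamma CDF evaluated at
#' its observed phenotype value, i.e. the scan's rank within the age- and
#' sex-matched (and, in study/offset mode, study-adjusted) normative
#' population. Centiles are clamped to \[1e-6, 1 - 1e-6\] so downstream
#' transforms (for example the normal quantile) stay finite.
#'
#' @param object fitted `gg_gamlss`.
#' @param data phenotype table containing the model's phenotype column.
#' @param mode,offset as in [predict.gg_gamlss()].
#' @return `data.frame` mirroring the input rows with columns `centile`,
#'   `mu`, `sigma`, `nu` and `mode`.
#' @export
centile_score <- function(object, data,
                          mode = c("population", "study", "offset"),
                          offset = NULL) {
  mode <- match.arg(mode)
  data <- validate_phenotypes(data, object$spec$phenotype)
  par <- .predict_params(object, data, mode, offset)
  cent <- pgg(data[[object$spec$phenotype]], par$mu, par$sigma, par$nu)
  cent <- pmin(pmax(cent, 1e-6), 1 - 1e-6)
  out <- cbind(data, centile = cent, par, mode = mode)
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood study offsets for out-of-sample data
#'
#' Aligns each new (unseen) study to the normative model by maximizing its
#' log-likelihood over link-scale shifts `d_mu`, `d_sigma` and (optionally)
#' an identity-scale shift `d_nu`, with every population parameter frozen.
#' This is the out-of-sample harmonization step that lets scans from a new
#' scanner/protocol be centile-scored on the reference charts. Offsets are
#' estimated by plain (unpenalized) maximum likelihood; `d_nu` is bounded
#' to avoid degeneracy on small studies. Studies with fewer than 100 scans
#' are flagged: offset estimation below that size is unstable.
#'
#' @param object fitted `gg_gamlss`.
#' @param newdata phenotype table for one or more studies absent from the
#'   model's study registry.
#' @param estimate_nu logical; also estimate `d_nu`.
#' @param nu_bound bound on `|d_nu|`.
#' @return `data.frame` of class `study_offset`, one row per new study:
#'   `study`, `d_mu`, `d_sigma`, `d_nu`, `n_scans`, `small_sample_warning`,
#'   `loglik`, `converged`.
#' @export
new_study_offset <- function(object, newdata, estimate_nu = TRUE,
                             nu_bound = 2) {
  newdata <- validate_phenotypes(newdata, object$spec$phenotype)
  overlap <- intersect(unique(as.character(newdata$study)),
                       object$levels$study)
  if (length(overlap))
    stop("study (studies) already in the fitted registry: ",
         paste(overlap, collapse = ", "),
         "; use mode = 'study' for those", call. = FALSE)
  studies <- sort(unique(as.character(newdata$study)))
  res <- lapply(studies, function(s) {
    rows <- newdata[as.character(newdata$study) == s, , drop = FALSE]
    par0 <- .predict_params(object, rows, mode = "population")
    y <- rows[[object$spec$phenotype]]
    nll <- function(d) {
      nu <- par0$nu + if (estimate_nu) d[3] else 0
      nu <- sign(nu) * pmax(abs(nu), 1e-8)  # keep away from exact zero
      -sum(dgg(y, par0$mu * exp(d[1]), par0$sigma * exp(d[2]), nu,
               log = TRUE))
    }
    npar <- if (estimate_nu) 3L else 2L
    opt <- stats::optim(rep(0, npar), nll, method = "L-BFGS-B",
                        lower = c(-5, -5, -nu_bound)[seq_len(npar)],
                        upper = c(5, 5, nu_bound)[seq_len(npar)])
    if (opt$convergence != 0)
      warning("offset optimizer did not converge for study ", s,
              " (code ", opt$convergence, "); best point retained",
              call. = FALSE)
    data.frame(study = s, d_mu = opt$par[1], d_sigma = opt$par[2],
               d_nu = if (estimate_nu) opt$par[3] else 0,
               n_scans = nrow(rows),
               small_sample_warning = nrow(rows) < 100L,
               loglik = -opt$value, converged = opt$convergence == 0)
  })
  out <- do.call(rbind, res)
  class(out) <- c("study_offset", "data.frame")
  out
}

.grid_newdata <- function(ages_years, sex) {
  data.frame(participant_id = "grid", study = "grid",
             age_days = .age_years_to_x(ages_years) * 365.25, sex = sex,
             version = NA, stringsAsFactors = FALSE)
}

# prediction rows at the reference version level, if the model uses one
.grid_with_version <- function(object, ages_years, sex) {
  nd <- .grid_newdata(ages_years, sex)
  if (!is.null(object$levels$version))
    nd$version <- object$levels$version[1L]
  nd
}

#' Centile trajectories over an age grid
#'
#' Evaluates fitted quantile curves at the requested centile levels over an
#' age grid. Curves at distinct levels never cross (quantile monotonicity);
#' level 0.5 is the median trajectory. Ages outside the fitted age support
#' are flagged as extrapolation.
#'
#' @param object fitted `gg_gamlss`.
#' @param ages numeric vector of ages in years relative to birth.
#' @param sex `"F"` or `"M"`.
#' @param levels centile levels in (0, 1).
#' @param mode,offset as in [predict.gg_gamlss()].
#' @return long `data.frame`: `age_years`, `sex`, `level`, `value`,
#'   `extrapolated`.
#' @export
trajectory <- function(object, ages, sex = "F",
                       levels = c(0.025, 0.5, 0.975),
                       mode = "population", offset = NULL) {
  if (!length(ages)) stop("empty age grid", call. = FALSE)
  stopifnot(all(levels > 0 & levels < 1))
  nd <- .grid_with_version(object, ages, sex)
  par <- .predict_params(object, nd, mode, offset)
  rng <- transform_age(object$age_range)$age_years
  out <- do.call(rbind, lapply(levels, function(l)
    data.frame(age_years = ages, sex = sex, level = l,
               value = qgg(l, par$mu, par$sigma, par$nu),
               extrapolated = ages < rng[1] | ages > rng[2])))
  rownames(out) <- NULL
  out
}

#' Between-subject variability trajectory
#'
#' The between-subject standard deviation of the phenotype at each age,
#' computed in closed form from the fitted generalized gamma moments at the
#' population-mode parameters. With bootstrap replicate fits, a percentile
#' confidence band is added. Ages where the second moment does not exist
#' (strongly negative shape) yield NaN, not an error.
#'
#' @param object fitted `gg_gamlss`.
#' @param ages ages in years relative to birth.
#' @param sex `"F"` or `"M"`.
#' @param boot optional list of bootstrap replicate fits ([bootstrap_gg()]).
#' @param level confidence level of the percentile band.
#' @param mode,offset as in [predict.gg_gamlss()].
#' @return `data.frame`: `age_years`, `sex`, `sd` and, with `boot`,
#'   `ci_low`/`ci_high`.
#' @export
variability_trajectory <- function(object, ages, sex = "F", boot = NULL,
                                   level = 0.95, mode = "population",
                                   offset = NULL) {
  one <- function(fit) {
    nd <- .grid_with_version(fit, ages, sex)
    par <- .predict_params(fit, nd, mode, offset)
    gg_sd(par$mu, par$sigma, par$nu)
  }
  out <- data.frame(age_years = ages, sex = sex, sd = one(object))
  if (!is.null(boot)) {
    if (length(boot) < 20L)
      stop("percentile bands need at least 20 bootstrap replicates",
           call. = FALSE)
    reps <- sapply(boot, one)
    a <- (1 - level) / 2
    out$ci_low <- apply(reps, 1L, stats::quantile, probs = a, na.rm = TRUE)
    out$ci_high <- apply(reps, 1L, stats::quantile, probs = 1 - a,
                         na.rm = TRUE)
  }
  out
}

#' First derivative (velocity) of a sampled trajectory
#'
#' Central differences at interior grid points, one-sided differences at the
#' ends; units are phenotype units per year.
#'
#' @param age strictly increasing age grid (years).
#' @param value curve values on the grid (at least 3 points).
#' @return numeric vector of derivatives, same length as `age`.
#' @export
velocity <- function(age, value) {
  n <- length(age)
  stopifnot(length(value) == n)
  if (n < 3L) stop("velocity needs at least 3 grid points", call. = FALSE)
  if (any(diff(age) <= 0))
    stop("age grid must be strictly increasing (no duplicates)",
         call. = FALSE)
  v <- numeric(n)
  v[1L] <- (value[2L] - value[1L]) / (age[2L] - age[1L])
  v[n] <- (value[n] - value[n - 1L]) / (age[n] - age[n - 1L])
  i <- 2:(n - 1L)
  v[i] <- (value[i + 1L] - value[i - 1L]) / (age[i + 1L] - age[i - 1L])
  v
}
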