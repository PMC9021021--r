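#' @export
print.gg_gamlss <- function(x, ...) {
  cat("Generalized gamma distributional regression\n")
  print(x$spec)
  cat(sprintf("n = %d scans, %d studies; log-likelihood %.2f; BIC %.2f\n",
              x$n_obs, length(x$levels$study), x$loglik, x$bic))
  if (!x$converged)
    cat("WARNING: outer loop did not converge in", x$cycles, "cycles\n")
  invisible(x)
}

#' @export
summary.gg_gamlss <- function(object, ...) {
  ct <- function(b, se) cbind(Estimate = b, `Std. Error` = se,
                              `z value` = b / se)
  out <- list(spec = object$spec,
              mu = ct(object$beta_mu, object$se_mu),
              sigma = ct(object$beta_sigma, object$se_sigma),
              nu = object$alpha_nu,
              delta2_mu = object$delta2_mu,
              delta2_sigma = object$delta2_sigma,
              loglik = object$loglik, bic = object$bic,
              n_obs = object$n_obs, converged = object$converged,
              cycles = object$cycles)
  class(out) <- "summary.gg_gamlss"
  out
}

#' @export
print.summary.gg_gamlss <- function(x, digits = 4, ...) {
  print(x$spec)
  cat("\nlog(mu) coefficients:\n")
  print(round(x$mu, digits))
  cat("\nlog(sigma) coefficients:\n")
  print(round(x$sigma, digits))
  cat("\nnu (shape) intercept:", format(x$nu, digits = digits), "\n")
  if (!is.na(x$delta2_mu))
    cat("Study random-intercept variance, mu:   ",
        format(x$delta2_mu, digits = digits), "\n")
  if (!is.na(x$delta2_sigma))
    cat("Study random-intercept variance, sigma:",
        format(x$delta2_sigma, digits = digits), "\n")
  cat(sprintf("\nlog-likelihood %.2f on %d scans; BIC %.2f; %s in %d cycles\n",
              x$loglik, x$n_obs, x$bic,
              if (x$converged) "converged" else "NOT converged", x$cycles))
  invisible(x)
}

#' @export
coef.gg_gamlss <- function(object, ...) {
  list(mu = object$beta_mu, sigma = object$beta_sigma, nu = object$alpha_nu)
}

#' @export
logLik.gg_gamlss <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Predict distribution parameters, quantiles or means from a fitted model
#'
#' @param object a fitted `gg_gamlss` model.
#' @param newdata covariate table (columns `age_days`, `sex`, plus `version`
#'   and `study` as the model and mode require). Defaults to the training
#'   data when retained.
#' @param type `"parameters"` returns per-row (mu, sigma, nu);
#'   `"quantile"` returns the centile curve value at probability `p`;
#'   `"mean"` the distribution mean.
#' @param mode how study effects enter: `"population"` sets all random
#'   intercepts to zero; `"study"` adds the fitted intercepts of each row's
#'   study (error for studies unseen at fit time); `"offset"` adds the
#'   supplied link-scale shifts.
#' @param offset for `mode = "offset"`: a one-row [new_study_offset()]
#'   result or a named list/vector with `d_mu`, `d_sigma` and optionally
#'   `d_nu`.
#' @param p probability for `type = "quantile"`.
#' @param ... unused.
#' @return a data frame (`type = "parameters"`) or numeric vector.
#' @export
predict.gg_gamlss <- function(object, newdata = NULL,
                              type = c("parameters", "quantile", "mean"),
                              mode = c("population", "study", "offset"),
                              offset = NULL, p = 0.5, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  if (is.null(newdata)) stop("'newdata' required (fit kept no data)",
                             call. = FALSE)
  par <- .predict_params(object, newdata, match.arg(mode), offset)
  switch(type,
         parameters = par,
         quantile = qgg(p, par$mu, par$sigma, par$nu),
         mean = gg_mean(par$mu, par$sigma, par$nu))
}

.as_offset <- function(offset) {
  if (is.null(offset)) stop("mode = 'offset' requires an offset", call. = FALSE)
  if (is.data.frame(offset)) {
    if (nrow(offset) != 1L)
      stop("supply a single-study offset (one row)", call. = FALSE)
    offset <- as.list(offset)
  }
  offset <- as.list(offset)
  d_nu <- if (!is.null(offset$d_nu) && is.finite(offset$d_nu)) offset$d_nu else 0
  if (is.null(offset$d_mu) || is.null(offset$d_sigma))
    stop("offset must contain d_mu and d_sigma", call. = FALSE)
  list(d_mu = offset$d_mu, d_sigma = offset$d_sigma, d_nu = d_nu)
}

.predict_params <- function(object, newdata, mode = "population",
                            offset = NULL) {
  lvl <- object$levels
  Xm <- encode_design(newdata, object$spec$mu,
                      levels = list(version = lvl$version,
                                    study = lvl$study))$X
  Xs <- encode_design(newdata, object$spec$sigma,
                      levels = list(study = lvl$study))$X
  eta_mu <- drop(Xm %*% object$beta_mu)
  eta_sg <- drop(Xs %*% object$beta_sigma)
  nu <- rep_len(object$alpha_nu, nrow(newdata))
  if (mode == "study") {
    st <- as.character(newdata$study)
    unknown <- setdiff(unique(st), lvl$study)
    if (length(unknown))
      stop("study (studies) not in the fitted registry: ",
           paste(unknown, collapse = ", "),
           "; use mode = 'offset' with new_study_offset()", call. = FALSE)
    if (length(object$gamma_mu)) eta_mu <- eta_mu + object$gamma_mu[st]
    if (length(object$gamma_sigma)) eta_sg <- eta_sg + object$gamma_sigma[st]
  } else if (mode == "offset") {
    off <- .as_offset(offset)
    eta_mu <- eta_mu + off$d_mu
    eta_sg <- eta_sg + off$d_sigma
    nu <- nu + off$d_nu
  }
  data.frame(mu = exp(eta_mu), sigma = exp(eta_sg), nu = nu)
}

#' Randomized quantile (z-score) residuals
#'
#' Centile scores of the training data under the fitted model (study mode),
#' mapped through the standard normal quantile function; approximately
#' N(0, 1) when the model fits.
#'
#' @param object a fitted `gg_gamlss` with retained data.
#' @param ... unused.
#' @export
residuals.gg_gamlss <- function(object, ...) {
  if (is.null(object$data))
    stop("fit was created with keep_data = FALSE", call. = FALSE)
  ct <- centile_score(object, object$data, mode = "study")
  stats::qnorm(ct$centile)
}

#' @export
fitted.gg_gamlss <- function(object, ...) {
  if (is.null(object$data))
    stop("fit was created with keep_data = FALSE", call. = FALSE)
  .predict_params(object, object$data, mode = "study")$mu
}

#' Simulate phenotype values from a fitted model
#'
#' @param object fitted `gg_gamlss`.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed, applied via `set.seed` with RNG state restored.
#' @param newdata covariate table (defaults to training data).
#' @param mode,offset as in [predict.gg_gamlss()].
#' @param ... unused.
#' @return data frame with `nsim` columns of positive draws.
#' @export
simulate.gg_gamlss <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                               mode = "study", offset = NULL, ...) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  if (is.null(newdata)) newdata <- object$data
  par <- .predict_params(object, newdata, mode, offset)
  out <- replicate(nsim, rgg(nrow(par), par$mu, par$sigma, par$nu))
  as.data.frame(matrix(out, nrow = nrow(par),
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Plot fitted centile curves
#'
#' Draws the sex-specific median and outer centile curves over age (years
#' relative to birth, log-scaled offset axis), with the training data as
#' points when available.
#'
#' @param x fitted `gg_gamlss`.
#' @param sex sexes to draw.
#' @param levels centile levels.
#' @param n_grid grid resolution.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gg_gamlss <- function(x, sex = c("F", "M"),
                           levels = c(0.025, 0.5, 0.975), n_grid = 200, ...) {
  rng <- transform_age(x$age_range)$age_years
  ages <- seq(rng[1], rng[2], length.out = n_grid)
  cols <- c(F = "#c23b22", M = "#1f6fb2")
  first <- TRUE
  for (s in sex) {
    tr <- trajectory(x, ages, sex = s, levels = levels)
    wide <- sapply(levels, function(l) tr$value[tr$level == l])
    if (first) {
      graphics::matplot(ages, wide, type = "l", lty = c(2, 1, 2),
                        col = cols[[s]], xlab = "age (years from birth)",
                        ylab = x$spec$phenotype, ...)
      if (!is.null(x$data))
        graphics::points(transform_age(x$data$age_days)$age_years,
                         x$data[[x$spec$phenotype]], pch = ".",
                         col = "grey60")
      first <- FALSE
    } else {
      graphics::matlines(ages, wide, lty = c(2, 1, 2), col = cols[[s]])
    }
  }
  invisible(x)
}
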