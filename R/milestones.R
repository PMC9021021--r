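#' Developmental milestones of a fitted trajectory
#'
#' Extracts landmark ages from the fitted median (50th centile) trajectory:
#' the age and value of peak phenotype (argmax of the median curve) and the
#' age of peak growth rate (argmax of the curve's first derivative).
#' By default the female and male median curves are averaged pointwise
#' before taking argmax (headline, sex-agnostic milestones); per-sex
#' milestones are obtained by passing `sex = "F"` or `"M"`. Ages are
#' reported in years relative to birth, so prenatal milestones are
#' negative. A monotone curve yields the grid endpoint with
#' `interior = FALSE` rather than an error.
#'
#' @param object fitted `gg_gamlss`.
#' @param ages age grid in years relative to birth; defaults to a daily
#'   grid spanning the fitted age support.
#' @param sex `"average"` (default), `"F"` or `"M"`.
#' @param mode,offset as in [predict.gg_gamlss()].
#' @return `data.frame` of class `milestone_set` with one row per
#'   milestone (`peak` and `velocity_peak`): `phenotype`, `milestone`,
#'   `age_years`, `value`, `interior`.
#' @export
find_milestones <- function(object, ages = NULL, sex = "average",
                            mode = "population", offset = NULL) {
  if (is.null(ages)) {
    rng <- transform_age(object$age_range)$age_years
    ages <- seq(rng[1], rng[2], by = 1 / 365.25)
  }
  if (length(ages) < 3L) stop("age grid too short", call. = FALSE)
  med <- .median_curve(object, ages, sex, mode, offset)
  .milestones_from_curve(object$spec$phenotype, ages, med)
}

.median_curve <- function(object, ages, sex, mode = "population",
                          offset = NULL) {
  one <- function(s) trajectory(object, ages, sex = s, levels = 0.5,
                                mode = mode, offset = offset)$value
  if (identical(sex, "average")) (one("F") + one("M")) / 2 else one(sex)
}

.milestones_from_curve <- function(phenotype, ages, med) {
  i_pk <- which.max(med)
  vel <- velocity(ages, med)
  i_vp <- which.max(vel)
  n <- length(ages)
  out <- data.frame(
    phenotype = phenotype,
    milestone = c("peak", "velocity_peak"),
    age_years = c(ages[i_pk], ages[i_vp]),
    value = c(med[i_pk], vel[i_vp]),
    interior = c(i_pk > 1L && i_pk < n, i_vp > 1L && i_vp < n))
  class(out) <- c("milestone_set", "data.frame")
  out
}

#' Grey/white-matter differentiation epoch
#'
#' Locates the epoch bounded by the age at which the median grey-matter
#' volume first exceeds the median white-matter volume (the switch of the
#' proportionally dominant tissue compartment) and the later age at which
#' their absolute difference is maximal.
#'
#' @param model_gmv,model_wmv fitted `gg_gamlss` models on a shared unit.
#' @param ages age grid in years relative to birth (defaults to a daily
#'   grid over the intersection of the two fitted supports).
#' @param sex `"average"`, `"F"` or `"M"`.
#' @return list with `crossing_age`, `max_abs_diff_age` (NA plus
#'   `crossed = FALSE` when the curves never cross on the grid) and
#'   `direction` (+1 when the first model overtakes the second).
#' @export
gmv_wmv_differentiation <- function(model_gmv, model_wmv, ages = NULL,
                                    sex = "average") {
  if (is.null(ages)) {
    r1 <- transform_age(model_gmv$age_range)$age_years
    r2 <- transform_age(model_wmv$age_range)$age_years
    ages <- seq(max(r1[1], r2[1]), min(r1[2], r2[2]), by = 1 / 365.25)
  }
  g <- .median_curve(model_gmv, ages, sex)
  w <- .median_curve(model_wmv, ages, sex)
  d <- g - w
  s <- sign(d)
  flips <- which(s[-1L] != s[-length(s)] & s[-1L] != 0)
  if (!length(flips))
    return(list(crossing_age = NA_real_, max_abs_diff_age = NA_real_,
                crossed = FALSE, direction = NA_integer_))
  i_cross <- flips[1L] + 1L
  after <- seq(i_cross, length(ages))
  i_max <- after[which.max(abs(d[after]))]
  list(crossing_age = ages[i_cross], max_abs_diff_age = ages[i_max],
       crossed = TRUE, direction = as.integer(s[i_cross]))
}

#' Bootstrap confidence intervals for milestone ages
#'
#' Recomputes the milestones on each bootstrap replicate fit and returns
#' empirical percentile intervals of the replicate milestone ages.
#' Replicates whose maximum falls on a grid endpoint are excluded from the
#' interval and counted in the diagnostics.
#'
#' @param boot list of replicate fits from [bootstrap_gg()] (at least 20
#'   for 2.5/97.5 percentiles).
#' @param ages,sex as in [find_milestones()].
#' @param level confidence level.
#' @return `data.frame`: `milestone`, `ci_low`, `ci_high`, `n_used`,
#'   `n_endpoint_excluded`.
#' @export
milestone_ci <- function(boot, ages = NULL, sex = "average", level = 0.95) {
  if (length(boot) < 20L)
    stop("percentile intervals need at least 20 replicates", call. = FALSE)
  reps <- lapply(boot, find_milestones, ages = ages, sex = sex)
  a <- (1 - level) / 2
  out <- lapply(c("peak", "velocity_peak"), function(m) {
    rows <- lapply(reps, function(r) r[r$milestone == m, ])
    age <- sapply(rows, `[[`, "age_years")
    ok <- sapply(rows, `[[`, "interior")
    qs <- if (any(ok))
      stats::quantile(age[ok], c(a, 1 - a), type = 7, names = FALSE)
    else c(NA_real_, NA_real_)
    data.frame(milestone = m, ci_low = qs[1], ci_high = qs[2],
               n_used = sum(ok), n_endpoint_excluded = sum(!ok))
  })
  do.call(rbind, out)
}
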