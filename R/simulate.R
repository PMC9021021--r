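#' Ground-truth models for synthetic lifespan cohorts
#'
#' A `gg_truth` object couples a model specification with known coefficient
#' values, random-effect standard deviations and scenario knobs, so that
#' every pipeline stage can be exercised against a known answer. The
#' presets sketch the qualitative shape of the corresponding lifespan
#' phenotype trajectories (an interior peak at a configurable age over a
#' generalized gamma outcome); their coefficients are fixtures chosen for
#' realistic scale, between-subject spread and study heterogeneity, not
#' estimates of any real cohort.
#'
#' All preset location trajectories use the fractional-polynomial form
#' \eqn{\log\mu = c_0 + c_1 \log x - c_2 \sqrt{x}} (powers \{0, 0.5\}) in
#' years post-conception \eqn{x}, which has a single interior maximum at
#' \eqn{x^* = (2 c_1 / c_2)^2}.
#'
#' * `gmv_like`: cortical grey-matter-like volume, peak near 5.9 years
#'   from birth, scale ~7.7e5 mm^3, 12% between-subject spread.
#' * `wmv_like`: white-matter-like volume, peak near 28.7 years, scale
#'   ~4.8e5 mm^3.
#' * `ct_like`: cortical-thickness-like metric in mm, infancy peak near
#'   1.7 years, 4% spread.
#'
#' @param preset one of `"gmv_like"`, `"wmv_like"`, `"ct_like"`.
#' @param delta_mu,delta_sigma between-study SDs of the random intercepts
#'   on the log-mu and log-sigma scales.
#' @param ace named ACE variance components (`a2`, `c2`, `e2`, summing
#'   to 1) used by [simulate_twins()].
#' @param drift_per_year default longitudinal centile drift used by
#'   [simulate_longitudinal()].
#' @return object of class `gg_truth` with elements `spec`, `beta_mu`,
#'   `beta_sigma`, `alpha_nu`, `delta_mu`, `delta_sigma`, `ace`,
#'   `drift_per_year`.
#' @export
true_model <- function(preset = c("gmv_like", "wmv_like", "ct_like"),
                       delta_mu = 0.08, delta_sigma = 0.1,
                       ace = c(a2 = 0.6, c2 = 0.2, e2 = 0.2),
                       drift_per_year = 0.05) {
  preset <- match.arg(preset)
  stopifnot(delta_mu >= 0, delta_sigma >= 0)
  if (abs(sum(ace) - 1) > 1e-8 || any(ace < 0))
    stop("ACE variance components must be non-negative and sum to 1",
         call. = FALSE)
  par <- switch(preset,
    gmv_like = list(phen = "gmv", c0 = 13.80, c1 = 2.3649, c2 = 1.8319,
                    sex = 0.08, s0 = log(0.12), s1 = -0.002, nu = 1.5),
    wmv_like = list(phen = "wmv", c0 = 10.52, c1 = 1.8512, c2 = 0.6820,
                    sex = 0.10, s0 = log(0.13), s1 = -0.001, nu = 1.2),
    ct_like  = list(phen = "ct",  c0 = 1.10,  c1 = 0.15, c2 = 0.1908,
                    sex = 0.02, s0 = log(0.04), s1 = -0.001, nu = 2.0))
  spec <- gg_spec(par$phen,
                  mu = moment_formula(c(0, 0.5), covariates = "sex",
                                      random = delta_mu > 0),
                  sigma = moment_formula(1, random = delta_sigma > 0))
  beta_mu <- c("(Intercept)" = par$c0, sexM = par$sex,
               "fp(0)" = par$c1, "fp(0.5)" = -par$c2)
  beta_sigma <- c("(Intercept)" = par$s0, "fp(1)" = par$s1)
  structure(list(preset = preset, spec = spec, beta_mu = beta_mu,
                 beta_sigma = beta_sigma, alpha_nu = par$nu,
                 delta_mu = delta_mu, delta_sigma = delta_sigma,
                 ace = ace, drift_per_year = drift_per_year),
            class = "gg_truth")
}

# evaluate the true (mu, sigma, nu) for a covariate table, with per-study
# link-scale shifts given as named vectors (study -> shift)
.truth_params <- function(truth, tab, g_mu = NULL, g_sg = NULL) {
  Xm <- encode_design(tab, truth$spec$mu)$X
  Xs <- encode_design(tab, truth$spec$sigma)$X
  eta_mu <- drop(Xm %*% truth$beta_mu[colnames(Xm)])
  eta_sg <- drop(Xs %*% truth$beta_sigma[colnames(Xs)])
  st <- as.character(tab$study)
  if (!is.null(g_mu)) eta_mu <- eta_mu + g_mu[st]
  if (!is.null(g_sg)) eta_sg <- eta_sg + g_sg[st]
  data.frame(mu = exp(eta_mu), sigma = exp(eta_sg),
             nu = rep_len(truth$alpha_nu, nrow(tab)))
}

.draw_ages <- function(n, age_range_days) {
  # log-uniform sampling density over the lifespan: heavy early-life
  # coverage, mirroring how multi-study aggregates over-represent
  # development relative to a uniform age draw
  exp(stats::runif(n, log(age_range_days[1]), log(age_range_days[2])))
}

#' Simulate a multi-study lifespan reference cohort
#'
#' Draws a cross-sectional cohort from a known [true_model()]: log-uniform
#' ages over the requested range, Bernoulli sex, per-study Gaussian random
#' intercepts on the log-mu and log-sigma scales, and generalized gamma
#' outcomes at the implied parameters. Fully reproducible from the seed;
#' the RNG state of the session is restored on exit.
#'
#' @param truth a `gg_truth`.
#' @param n_studies number of primary studies (>= 2).
#' @param n_per_study scans per study; a scalar (equal sizes) or a vector
#'   of length `n_studies` (unequal sizes).
#' @param age_range_days age support in days post-conception.
#' @param sex_ratio probability of male.
#' @param seed integer seed.
#' @return phenotype table (`data.frame`) with the standard columns plus
#'   the truth's phenotype; attributes `gamma_mu`/`gamma_sigma` carry the
#'   realized study effects.
#' @export
simulate_cohort <- function(truth, n_studies = 20L, n_per_study = 200L,
                            age_range_days = c(115, 36525),
                            sex_ratio = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "gg_truth"), n_studies >= 2L)
  if (age_range_days[1] < 80 || diff(age_range_days) <= 0)
    stop("invalid age range", call. = FALSE)
  sizes <- rep_len(n_per_study, n_studies)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  studies <- sprintf("S%03d", seq_len(n_studies))
  g_mu <- stats::setNames(stats::rnorm(n_studies, 0, truth$delta_mu), studies)
  g_sg <- stats::setNames(stats::rnorm(n_studies, 0, truth$delta_sigma),
                          studies)
  n <- sum(sizes)
  tab <- data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    study = rep(studies, sizes),
    age_days = .draw_ages(n, age_range_days),
    sex = ifelse(stats::runif(n) < sex_ratio, "M", "F"),
    stringsAsFactors = FALSE)
  par <- .truth_params(truth, tab, g_mu, g_sg)
  tab[[truth$spec$phenotype]] <- rgg(n, par$mu, par$sigma, par$nu)
  attr(tab, "gamma_mu") <- g_mu
  attr(tab, "gamma_sigma") <- g_sg
  tab
}

#' Simulate one new study with fixed offsets
#'
#' Like [simulate_cohort()] for a single study, but with supplied
#' link-scale offsets instead of sampled random effects; used to validate
#' out-of-sample offset recovery.
#'
#' @param truth a `gg_truth`.
#' @param d_mu,d_sigma,d_nu fixed offsets (log-mu, log-sigma, identity-nu).
#' @param n number of scans.
#' @param study study label.
#' @inheritParams simulate_cohort
#' @export
simulate_new_study <- function(truth, d_mu = 0, d_sigma = 0, d_nu = 0,
                               n = 500L, age_range_days = c(115, 36525),
                               sex_ratio = 0.5, seed = 1L,
                               study = "NEW001") {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  tab <- data.frame(
    participant_id = sprintf("N%06d", seq_len(n)),
    study = study,
    age_days = .draw_ages(n, age_range_days),
    sex = ifelse(stats::runif(n) < sex_ratio, "M", "F"),
    stringsAsFactors = FALSE)
  par <- .truth_params(truth, tab)
  tab[[truth$spec$phenotype]] <- rgg(n, par$mu * exp(d_mu),
                                     par$sigma * exp(d_sigma),
                                     par$nu + d_nu)
  tab
}

#' Simulate a clinical group with shifted centiles
#'
#' Cases are drawn from the true model with the log-mu linear predictor
#' shifted by the amount that moves the group's median to the requested
#' centile of the normative distribution; the shift is solved by inverting
#' the generalized gamma CDF at the truth's reference scale/shape (it is
#' exact wherever sigma equals its reference-age value, and approximate
#' elsewhere to the extent sigma varies with age).
#'
#' @param truth a `gg_truth`.
#' @param target_median_centile normative centile at which the case median
#'   should sit (controls sit at 0.5).
#' @param n number of cases.
#' @param reference_age_days age at which the displacement is exact.
#' @inheritParams simulate_cohort
#' @export
simulate_clinical <- function(truth, target_median_centile = 0.3, n = 500L,
                              age_range_days = c(5840, 29220),
                              reference_age_days = 14610,
                              sex_ratio = 0.5, seed = 1L,
                              study = "CLIN01") {
  stopifnot(target_median_centile > 0, target_median_centile < 1)
  ref <- data.frame(participant_id = "r", study = "r",
                    age_days = reference_age_days, sex = "F")
  pr <- .truth_params(truth, ref)
  m50 <- qgg(0.5, pr$mu, pr$sigma, pr$nu)
  f <- function(s) pgg(exp(s) * m50, pr$mu, pr$sigma, pr$nu) -
    target_median_centile
  shift <- stats::uniroot(f, c(-3, 3), tol = 1e-10)$root
  out <- simulate_new_study(truth, d_mu = shift, n = n,
                            age_range_days = age_range_days,
                            sex_ratio = sex_ratio, seed = seed,
                            study = study)
  out$dx <- "CASE"
  attr(out, "d_mu") <- shift
  out
}

#' Simulate longitudinal repeat scans
#'
#' Each subject holds a latent base centile; session centiles add a linear
#' drift per year plus small session-to-session jitter, and observed values
#' are the corresponding quantiles of the true distribution at the session
#' age. Session ages increase strictly within subject.
#'
#' @param truth a `gg_truth`.
#' @param n_subjects subjects with repeat scans.
#' @param sessions scans per subject.
#' @param interval_years spacing between sessions.
#' @param drift_per_year centile drift per year (0 = stable subjects).
#' @param jitter SD of the session-level centile jitter.
#' @param baseline_age_range_days age range of the first session.
#' @inheritParams simulate_cohort
#' @export
simulate_longitudinal <- function(truth, n_subjects = 100L, sessions = 3L,
                                  interval_years = 1,
                                  drift_per_year = truth$drift_per_year,
                                  jitter = 0.02,
                                  baseline_age_range_days = c(3000, 25000),
                                  seed = 1L, study = "LONG01") {
  stopifnot(sessions >= 1L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  base_age <- .draw_ages(n_subjects, baseline_age_range_days)
  base_cent <- stats::runif(n_subjects, 0.05, 0.95)
  sexes <- ifelse(stats::runif(n_subjects) < 0.5, "M", "F")
  rows <- lapply(seq_len(n_subjects), function(i) {
    dt <- (seq_len(sessions) - 1L) * interval_years
    cent <- pmin(pmax(base_cent[i] + drift_per_year * dt +
                        stats::rnorm(sessions, 0, jitter), 1e-4), 1 - 1e-4)
    data.frame(participant_id = sprintf("L%05d", i), study = study,
               age_days = base_age[i] + dt * 365.25, sex = sexes[i],
               session = seq_len(sessions), true_centile = cent,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  par <- .truth_params(truth, tab)
  tab[[truth$spec$phenotype]] <- qgg(tab$true_centile, par$mu, par$sigma,
                                     par$nu)
  tab
}

#' Simulate twin pairs under an ACE model
#'
#' Latent liabilities follow the classical ACE decomposition: additive
#' genetic effects correlate 1 within monozygotic and 0.5 within dizygotic
#' pairs, the shared environment is common to a pair, and the unique
#' environment is independent. Observed values are the generalized gamma
#' quantiles of the normal-scores of the liabilities at the shared pair age
#' and sex, so the expected pair correlations on the centile scale are
#' \eqn{r_{MZ} = a^2 + c^2} and \eqn{r_{DZ} = a^2/2 + c^2}.
#'
#' @param truth a `gg_truth`.
#' @param n_pairs pairs per zygosity.
#' @param ace named ACE components (defaults to the truth's).
#' @param age_range_days shared pair age range (default: a narrow
#'   adolescent window, as in typical twin imaging cohorts).
#' @inheritParams simulate_cohort
#' @return `data.frame` with `pair_id`, `zygosity` ("MZ"/"DZ"), `twin`
#'   (1/2), `study`, `age_days`, `sex`, `true_centile` and the phenotype.
#' @export
simulate_twins <- function(truth, n_pairs = 300L, ace = truth$ace,
                           age_range_days = c(3560, 4290), seed = 1L,
                           study = "TWIN01") {
  if (abs(sum(ace) - 1) > 1e-8 || any(ace < 0))
    stop("ACE variance components must be non-negative and sum to 1",
         call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  a <- sqrt(ace[["a2"]]); cc <- sqrt(ace[["c2"]]); e <- sqrt(ace[["e2"]])
  one_zyg <- function(zyg) {
    A1 <- stats::rnorm(n_pairs)
    A2 <- if (zyg == "MZ") A1 else 0.5 * A1 +
      sqrt(0.75) * stats::rnorm(n_pairs)
    C <- stats::rnorm(n_pairs)
    z1 <- a * A1 + cc * C + e * stats::rnorm(n_pairs)
    z2 <- a * A2 + cc * C + e * stats::rnorm(n_pairs)
    age <- .draw_ages(n_pairs, age_range_days)
    sex <- ifelse(stats::runif(n_pairs) < 0.5, "M", "F")
    data.frame(
      pair_id = rep(sprintf("%s%04d", zyg, seq_len(n_pairs)), 2L),
      zygosity = zyg, twin = rep(1:2, each = n_pairs),
      participant_id = sprintf("%s%04d_%d", zyg,
                               rep(seq_len(n_pairs), 2L),
                               rep(1:2, each = n_pairs)),
      study = study, age_days = rep(age, 2L), sex = rep(sex, 2L),
      true_centile = stats::pnorm(c(z1, z2)), stringsAsFactors = FALSE)
  }
  tab <- rbind(one_zyg("MZ"), one_zyg("DZ"))
  par <- .truth_params(truth, tab)
  tab[[truth$spec$phenotype]] <- qgg(pmin(pmax(tab$true_centile, 1e-6),
                                          1 - 1e-6),
                                     par$mu, par$sigma, par$nu)
  tab
}

#' Reshape a twin table to per-pair matrices
#'
#' Utility for [twin_h2()]: turns the long [simulate_twins()] layout (or
#' its centile-scored counterpart) into the two-column per-pair matrices
#' expected by the heritability estimator.
#'
#' @param tab long table with `pair_id`, `zygosity`, `twin` and the value
#'   column.
#' @param value_col column to pair (e.g. the phenotype or `"centile"`).
#' @return list with `mz` and `dz` two-column matrices.
#' @export
pair_twins <- function(tab, value_col) {
  stopifnot(all(c("pair_id", "zygosity", "twin", value_col) %in% names(tab)))
  one <- function(zyg) {
    d <- tab[tab$zygosity == zyg, ]
    t1 <- d[d$twin == 1L, ]; t2 <- d[d$twin == 2L, ]
    t2 <- t2[match(t1$pair_id, t2$pair_id), ]
    cbind(twin1 = t1[[value_col]], twin2 = t2[[value_col]])
  }
  list(mz = one("MZ"), dz = one("DZ"))
}

#' Materialize a ground truth as a fitted-model object
#'
#' Wraps the exact coefficients of a [true_model()] in a `gg_gamlss`
#' object (empty study registry, zero random effects), so that prediction,
#' centile scoring, trajectories, milestones and out-of-sample offset
#' estimation can be run against the noise-free reference curves.
#'
#' @param truth a `gg_truth`.
#' @param age_range_days age support recorded on the object.
#' @return a `gg_gamlss` object.
#' @export
truth_as_model <- function(truth, age_range_days = c(115, 36525)) {
  stopifnot(inherits(truth, "gg_truth"))
  spec <- gg_spec(truth$spec$phenotype,
                  mu = moment_formula(truth$spec$mu$powers,
                                      truth$spec$mu$covariates,
                                      random = FALSE),
                  sigma = moment_formula(truth$spec$sigma$powers,
                                         truth$spec$sigma$covariates,
                                         random = FALSE))
  obj <- list(
    spec = spec, beta_mu = truth$beta_mu, beta_sigma = truth$beta_sigma,
    alpha_nu = truth$alpha_nu,
    gamma_mu = numeric(0), gamma_sigma = numeric(0),
    delta2_mu = NA_real_, delta2_sigma = NA_real_,
    se_mu = NULL, se_sigma = NULL,
    loglik = NA_real_, penalized_loglik = NA_real_,
    n_obs = 0L, n_params = length(truth$beta_mu) +
      length(truth$beta_sigma) + 1L,
    bic = NA_real_, converged = TRUE, cycles = 0L,
    levels = list(version = NULL, study = character(0)),
    age_range = as.numeric(age_range_days),
    data = NULL, control = gg_control(), call = NULL)
  class(obj) <- "gg_gamlss"
  obj
}

#' @export
print.gg_truth <- function(x, ...) {
  cat("Synthetic ground truth (preset '", x$preset, "')\n", sep = "")
  print(x$spec)
  cat("  delta_mu =", x$delta_mu, " delta_sigma =", x$delta_sigma,
      " nu =", x$alpha_nu, "\n")
  invisible(x)
}
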