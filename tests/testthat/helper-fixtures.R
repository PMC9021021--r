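# Shared fixtures, built once per test run.

tr_gmv <- true_model("gmv_like")
ref_gmv <- truth_as_model(tr_gmv)

# a small multi-study cohort and its fit, reused across files
small_cohort <- simulate_cohort(tr_gmv, n_studies = 8L, n_per_study = 120L,
                                seed = 202L)
small_fit <- gg_gamlss(small_cohort, tr_gmv$spec)

# analytic ground truth with a log-parabola median:
# log mu(x) = -(log x - log x_peak)^2 + h, built from FP powers {0, 0}
log_parabola_truth <- function(x_peak = 6.67, h = log(4e5), sigma = 0.1,
                               phenotype = "y") {
  tr <- true_model("gmv_like")
  tr$spec <- gg_spec(phenotype,
                     mu = moment_formula(c(0, 0), covariates = "sex",
                                         random = FALSE),
                     sigma = moment_formula(numeric(0), random = FALSE))
  tr$beta_mu <- c("(Intercept)" = h - log(x_peak)^2, sexM = 0,
                  "fp(0)" = 2 * log(x_peak), "fp(0).log1" = -1)
  tr$beta_sigma <- c("(Intercept)" = log(sigma))
  tr$alpha_nu <- 1
  tr
}
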