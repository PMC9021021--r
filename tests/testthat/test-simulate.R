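# Synthetic-data generators: reproducibility, moment structure,
# self-consistency with the scoring engine.

test_that("all generators are pure functions of their seed", {
  expect_identical(simulate_cohort(tr_gmv, 3, 40, seed = 5L),
                   simulate_cohort(tr_gmv, 3, 40, seed = 5L))
  expect_identical(simulate_new_study(tr_gmv, n = 50, seed = 6L),
                   simulate_new_study(tr_gmv, n = 50, seed = 6L))
  expect_identical(simulate_longitudinal(tr_gmv, 20, 3, seed = 7L),
                   simulate_longitudinal(tr_gmv, 20, 3, seed = 7L))
  expect_identical(simulate_twins(tr_gmv, 30, seed = 8L),
                   simulate_twins(tr_gmv, 30, seed = 8L))
  expect_false(identical(simulate_cohort(tr_gmv, 3, 40, seed = 5L),
                         simulate_cohort(tr_gmv, 3, 40, seed = 6L)))
})

test_that("per-study spread of log-residual means matches delta_mu", {
  dat <- simulate_cohort(tr_gmv, n_studies = 50L, n_per_study = 400L,
                         seed = 101L)
  par0 <- braincentile:::.truth_params(tr_gmv, dat)
  resid <- log(dat$gmv) - log(par0$mu)
  per_study <- tapply(resid, dat$study, mean)
  expect_lt(abs(sd(per_study) - tr_gmv$delta_mu), 0.025)
  # and the realized study effects are what the table reports
  expect_lt(abs(sd(attr(dat, "gamma_mu")) - tr_gmv$delta_mu), 0.03)
})

test_that("cohorts are self-consistent with the scoring engine", {
  dat <- simulate_cohort(tr_gmv, n_studies = 4L, n_per_study = 500L,
                         seed = 102L)
  g <- attr(dat, "gamma_mu"); gs <- attr(dat, "gamma_sigma")
  cents <- unlist(lapply(names(g), function(s) {
    rows <- dat[dat$study == s, ]
    centile_score(ref_gmv, rows, mode = "offset",
                  offset = list(d_mu = g[[s]], d_sigma = gs[[s]]))$centile
  }))
  expect_gt(ks.test(cents, "punif")$p.value, 0.01)
})

test_that("new-study offsets act as an exact scale family", {
  a <- simulate_new_study(tr_gmv, d_mu = 0, n = 300L, seed = 11L)
  b <- simulate_new_study(tr_gmv, d_mu = log(2), n = 300L, seed = 11L)
  expect_equal(b$gmv, 2 * a$gmv, tolerance = 1e-12)  # same seed, same draws
  # zero-offset studies score uniformly against the reference
  ct <- centile_score(ref_gmv, simulate_new_study(tr_gmv, n = 2000L,
                                                  seed = 12L))
  expect_gt(ks.test(ct$centile, "punif")$p.value, 0.01)
})

test_that("clinical cohorts land at the requested median centile", {
  cl <- simulate_clinical(tr_gmv, target_median_centile = 0.3, n = 1500L,
                          seed = 13L)
  ct <- centile_score(ref_gmv, cl)
  expect_equal(median(ct$centile), 0.3, tolerance = 0.03)
  expect_true(all(cl$dx == "CASE"))
})

test_that("longitudinal tables have ordered sessions and sane exclusions", {
  lg <- simulate_longitudinal(tr_gmv, n_subjects = 25L, sessions = 3L,
                              seed = 14L)
  by_subj <- split(lg$age_days, lg$participant_id)
  expect_true(all(vapply(by_subj, function(a) all(diff(a) > 0), TRUE)))
  one <- simulate_longitudinal(tr_gmv, n_subjects = 10L, sessions = 1L,
                               seed = 15L)
  out <- longitudinal_iqr(cbind(one, centile = one$true_centile))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_excluded"), 10L)
})

test_that("twin correlations follow the ACE expectations", {
  tw <- simulate_twins(tr_gmv, n_pairs = 500L,
                       ace = c(a2 = 0.6, c2 = 0.2, e2 = 0.2), seed = 16L)
  p <- pair_twins(tw, "true_centile")
  r_mz <- cor(p$mz[, 1], p$mz[, 2]); r_dz <- cor(p$dz[, 1], p$dz[, 2])
  # Gaussian-copula attenuation maps latent 0.8 / 0.5 to ~0.79 / 0.48
  expect_lt(abs(r_mz - 0.79), 0.05)
  expect_lt(abs(r_dz - 0.48), 0.07)
  # pure-A limit
  tw1 <- simulate_twins(tr_gmv, n_pairs = 400L,
                        ace = c(a2 = 1, c2 = 0, e2 = 0), seed = 17L)
  p1 <- pair_twins(tw1, "true_centile")
  expect_gt(cor(p1$mz[, 1], p1$mz[, 2]), 0.99)
  expect_lt(abs(cor(p1$dz[, 1], p1$dz[, 2]) - 0.48), 0.08)
  expect_error(true_model("gmv_like", ace = c(a2 = 0.5, c2 = 0.5,
                                              e2 = 0.5)), "sum to 1")
})

test_that("the default preset yields a positive, single-peaked trajectory", {
  ms <- find_milestones(ref_gmv)
  expect_true(ms$interior[ms$milestone == "peak"])
  rng <- transform_age(ref_gmv$age_range)$age_years
  tr <- trajectory(ref_gmv, seq(rng[1], rng[2], length.out = 2000),
                   sex = "M", levels = 0.5)
  expect_true(all(tr$value > 0))
  # single interior maximum: the curve rises then falls exactly once
  expect_equal(sum(diff(sign(diff(tr$value))) != 0), 1L)
})

test_that("invalid generator arguments are rejected", {
  expect_error(simulate_cohort(tr_gmv, n_studies = 1L), "n_studies")
  expect_error(simulate_cohort(tr_gmv, age_range_days = c(500, 100)),
               "age range")
})
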