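# Centile engine: prediction modes, scoring, trajectories, velocity.

test_that("a hand-computed linear predictor matches predict()", {
  m <- ref_gmv
  # x = 1 year post-conception, female: fp(0) = 0, fp(0.5) = 1
  nd <- data.frame(participant_id = "a", study = "s",
                   age_days = 365.25, sex = "F")
  par <- predict(m, nd, mode = "population")
  b <- tr_gmv$beta_mu
  expect_equal(par$mu, exp(b[["(Intercept)"]] + b[["fp(0.5)"]]),
               tolerance = 1e-12)
  bs <- tr_gmv$beta_sigma
  expect_equal(par$sigma, exp(bs[["(Intercept)"]] + bs[["fp(1)"]] * 1),
               tolerance = 1e-12)
  expect_equal(par$nu, tr_gmv$alpha_nu)
})

test_that("study and offset modes shift the population prediction exactly", {
  nd <- small_cohort[1:20, ]
  pop <- predict(small_fit, nd, mode = "population")
  stu <- predict(small_fit, nd, mode = "study")
  g <- small_fit$gamma_mu[as.character(nd$study)]
  expect_equal(stu$mu, pop$mu * exp(unname(g)), tolerance = 1e-12)
  off <- predict(small_fit, nd, mode = "offset",
                 offset = list(d_mu = log(2), d_sigma = 0))
  expect_equal(off$mu, 2 * pop$mu, tolerance = 1e-12)
  expect_error(predict(small_fit,
                       transform(nd, study = "UNSEEN"), mode = "study"),
               "offset")
})

test_that("centile scores are the CDF at the observation, clamped", {
  nd <- small_cohort[1:50, ]
  med <- predict(small_fit, nd, type = "quantile", p = 0.5, mode = "study")
  nd$gmv <- med
  ct <- centile_score(small_fit, nd, mode = "study")
  expect_equal(ct$centile, rep(0.5, 50), tolerance = 1e-9)
  # monotone in y: far above the 97.5th centile implies centile >= 0.975
  nd$gmv <- 10 * predict(small_fit, nd, type = "quantile", p = 0.975,
                         mode = "study")
  expect_true(all(centile_score(small_fit, nd,
                                mode = "study")$centile >= 0.975))
  # clamping keeps downstream transforms finite
  expect_true(all(is.finite(qnorm(centile_score(small_fit, nd,
                                                mode = "study")$centile))))
})

test_that("data simulated from the fitted model score uniformly", {
  nd <- small_cohort[sample.int(nrow(small_cohort), 500), ]
  nd$gmv <- simulate(small_fit, seed = 8, newdata = nd,
                     mode = "study")$sim_1
  ct <- centile_score(small_fit, nd, mode = "study")
  expect_gt(ks.test(ct$centile, "punif")$p.value, 0.01)
})

test_that("centiles are invariant to the measurement unit", {
  dat2 <- small_cohort
  dat2$gmv <- dat2$gmv / 1000  # mm^3 -> ml
  fit2 <- gg_gamlss(dat2, tr_gmv$spec)
  c1 <- centile_score(small_fit, small_cohort, mode = "study")$centile
  c2 <- centile_score(fit2, dat2, mode = "study")$centile
  expect_equal(c1, c2, tolerance = 1e-6)
})

test_that("trajectories are ordered, median-consistent and equivariant", {
  ages <- seq(0, 80, by = 0.5)
  tr <- trajectory(small_fit, ages, sex = "M",
                   levels = c(0.025, 0.5, 0.975))
  lo <- tr$value[tr$level == 0.025]
  md <- tr$value[tr$level == 0.5]
  hi <- tr$value[tr$level == 0.975]
  expect_true(all(lo < md & md < hi))
  nd <- braincentile:::.grid_with_version(small_fit, ages, "M")
  par <- predict(small_fit, nd, mode = "population")
  expect_equal(md, qgg(0.5, par$mu, par$sigma, par$nu), tolerance = 1e-12)
  tr2 <- trajectory(small_fit, ages, sex = "M", levels = 0.5,
                    mode = "offset", offset = list(d_mu = log(2),
                                                   d_sigma = 0))
  expect_equal(tr2$value, 2 * md, tolerance = 1e-12)
  expect_error(trajectory(small_fit, numeric(0)), "empty")
})

test_that("variability trajectory matches closed forms and sampling", {
  # sigma = 1, nu = 1 is exponential: SD equals the median-scale mu
  tr1 <- tr_gmv
  tr1$beta_sigma <- c("(Intercept)" = 0, "fp(1)" = 0)
  tr1$alpha_nu <- 1
  m1 <- truth_as_model(tr1)
  ages <- c(2, 10, 40)
  vt <- variability_trajectory(m1, ages, sex = "F")
  nd <- braincentile:::.grid_with_version(m1, ages, "F")
  expect_equal(vt$sd, predict(m1, nd, mode = "population")$mu,
               tolerance = 1e-12)
  # Monte Carlo oracle at one age on the realistic preset
  nd <- braincentile:::.grid_with_version(ref_gmv, 10, "F")
  par <- predict(ref_gmv, nd, mode = "population")
  set.seed(21)
  draws <- rgg(1e5, par$mu, par$sigma, par$nu)
  expect_equal(variability_trajectory(ref_gmv, 10, sex = "F")$sd, sd(draws),
               tolerance = 0.01 * sd(draws))
  # doubling mu scales the SD curve exactly (scale family)
  v2 <- variability_trajectory(ref_gmv, ages, sex = "F", mode = "offset",
                               offset = list(d_mu = log(2), d_sigma = 0))
  v1 <- variability_trajectory(ref_gmv, ages, sex = "F")
  expect_equal(v2$sd, 2 * v1$sd, tolerance = 1e-12)
})

test_that("velocity uses exact central differences", {
  x <- seq(1, 5, by = 0.5)
  expect_equal(velocity(x, rep(3, length(x))), rep(0, length(x)))
  v <- velocity(x, x^2)
  expect_equal(v[2:(length(x) - 1)], 2 * x[2:(length(x) - 1)])
  expect_error(velocity(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(velocity(c(1, 2), c(1, 2)), "3 grid points")
  # matches the analytic derivative of an FP median curve to O(h^2)
  # (constant sigma so the median multiplier is age-free)
  trc <- tr_gmv
  trc$beta_sigma <- c("(Intercept)" = log(0.12), "fp(1)" = 0)
  mc <- truth_as_model(trc)
  ages <- seq(2, 3, by = 1 / 365.25)
  md <- braincentile:::.median_curve(mc, ages, "F")
  v <- velocity(ages, md)
  x <- ages + 280 / 365.25
  b <- trc$beta_mu
  analytic <- md * (b[["fp(0)"]] / x + b[["fp(0.5)"]] * 0.5 / sqrt(x))
  i <- 50:300
  expect_equal(v[i], analytic[i], tolerance = 1e-5)
})
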