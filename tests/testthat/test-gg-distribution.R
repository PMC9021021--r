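# Generalized gamma kernel: closed forms, quadrature, inversion, sampling.

test_that("exponential and gamma special cases match closed forms", {
  # sigma = nu = 1 is the exponential with mean mu
  mu <- 3
  expect_equal(dgg(mu, mu, 1, 1, log = TRUE), -1 - log(mu))
  expect_equal(pgg(mu, mu, 1, 1), 1 - exp(-1))
  expect_equal(qgg(0.5, mu, 1, 1), mu * log(2))
  # nu = 1 is a gamma with shape 1/sigma^2 and mean mu
  y <- c(2, 8, 20); mu <- 10; s <- 0.4
  expect_equal(pgg(y, mu, s, 1),
               pgamma(y, shape = 1 / s^2, rate = 1 / (s^2 * mu)),
               tolerance = 1e-12)
  expect_equal(dgg(y, mu, s, 1),
               dgamma(y, shape = 1 / s^2, rate = 1 / (s^2 * mu)),
               tolerance = 1e-12)
})

test_that("density integrates to 1 across the parameter grid", {
  for (mu in c(2.5, 10, 1e4))
    for (s in c(0.1, 0.3, 1))
      for (nu in c(-1.2, -0.5, 0.8, 1, 2)) {
        lo <- qgg(1e-12, mu, s, nu); hi <- qgg(1 - 1e-12, mu, s, nu)
        # integrate in log space for numerical range control
        I <- integrate(function(u) dgg(exp(u), mu, s, nu) * exp(u),
                       log(lo), log(hi), rel.tol = 1e-10,
                       subdivisions = 400L)$value
        expect_lt(abs(I - 1), 1e-6)
      }
})

test_that("CDF matches quadrature of the density for negative shape", {
  mu <- 5; s <- 0.4; nu <- -1.2
  lo <- qgg(1e-14, mu, s, nu)
  for (y in c(2, 4, 5, 7, 12)) {
    I <- integrate(function(t) dgg(t, mu, s, nu), lo, y,
                   rel.tol = 1e-12, subdivisions = 400L)$value
    expect_lt(abs(pgg(y, mu, s, nu) - I), 1e-7)
  }
})

test_that("CDF and quantile are mutual inverses", {
  p <- c(1e-6, 0.01, 0.5, 0.975, 0.99, 1 - 1e-6)
  for (nu in c(-0.8, 1e-7, 1, 2)) {
    expect_equal(pgg(qgg(p, 8, 0.3, nu), 8, 0.3, nu), p, tolerance = 1e-8)
    y <- qgg(c(0.2, 0.5, 0.9), 8, 0.3, nu)
    expect_equal(qgg(pgg(y, 8, 0.3, nu), 8, 0.3, nu), y,
                 tolerance = 1e-8 * max(y))
  }
  # bisection oracle for an upper quantile
  target <- qgg(0.975, 1e4, 0.15, 2)
  bis <- uniroot(function(y) pgg(y, 1e4, 0.15, 2) - 0.975,
                 c(1e3, 1e5), tol = 1e-10)$root
  expect_equal(target, bis, tolerance = 1e-8)
})

test_that("small |nu| is continuous with the log-normal limit", {
  y <- c(5, 9, 12, 20)
  ln <- dlnorm(y, log(10), 0.3, log = TRUE)
  expect_equal(dgg(y, 10, 0.3, 1e-7, log = TRUE), ln, tolerance = 1e-4)
  for (nu in c(-1e-6, 1e-6))
    expect_equal(dgg(y, 10, 0.3, nu, log = TRUE), ln, tolerance = 1e-4)
  # just outside the switch the direct evaluation agrees too
  expect_equal(dgg(y, 10, 0.3, 2e-5, log = TRUE), ln, tolerance = 1e-3)
})

test_that("kernel agrees with the flexsurv parameterization", {
  # independent oracle: GG(mu, sigma, nu) == gengamma(log mu, sigma, Q = sigma*nu)
  y <- c(0.5, 2, 8, 30)
  for (par in list(c(5, 0.4, -1.2), c(10, 0.2, 1.7), c(2, 1, 0.5))) {
    expect_equal(dgg(y, par[1], par[2], par[3], log = TRUE),
                 flexsurv::dgengamma(y, mu = log(par[1]), sigma = par[2],
                                     Q = par[2] * par[3], log = TRUE),
                 tolerance = 1e-10)
    expect_equal(pgg(y, par[1], par[2], par[3]),
                 flexsurv::pgengamma(y, mu = log(par[1]), sigma = par[2],
                                     Q = par[2] * par[3]),
                 tolerance = 1e-10)
  }
})

test_that("sampling is reproducible and distributed as the CDF", {
  set.seed(11); a <- rgg(100, 8, 0.3, -0.8)
  set.seed(11); b <- rgg(100, 8, 0.3, -0.8)
  expect_identical(a, b)
  set.seed(12)
  x <- rgg(1e4, 20, 1, 1)  # exponential, mean 20, SE = 20/100
  expect_lt(abs(mean(x) - 20), 5 * 20 / sqrt(1e4))
  set.seed(13)
  x <- rgg(1e4, 8, 0.3, -0.8)
  expect_gt(ks.test(x, function(q) pgg(q, 8, 0.3, -0.8))$p.value, 0.01)
})

test_that("moments match closed forms and sampling", {
  expect_equal(gg_sd(7, 1, 1), 7)               # exponential SD = mean
  expect_equal(gg_mean(10, 0.3, 1e-8), exp(log(10) + 0.3^2 / 2))
  set.seed(14)
  x <- rgg(2e5, 300, 0.25, -0.6)
  expect_equal(gg_sd(300, 0.25, -0.6), sd(x), tolerance = 0.01)
  # second moment undefined for strongly negative shape
  expect_true(is.nan(gg_sd(10, 1, -1.5)))
})

test_that("domain errors name the offending argument", {
  expect_error(dgg(-1, 5, 1, 1), "'y'")
  expect_error(dgg(2, -5, 1, 1), "'mu'")
  expect_error(pgg(2, 5, 0, 1), "'sigma'")
  expect_error(qgg(0, 5, 1, 1), "'p'")
  expect_error(qgg(1, 5, 1, 1), "'p'")
  expect_error(rgg(0, 5, 1, 1), "'n'")
})
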