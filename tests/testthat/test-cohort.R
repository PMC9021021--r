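# Cohort statistics: CMD, case-control tests, longitudinal IQR, twins.

test_that("CMD reference and scores reproduce the diagonal hand example", {
  # CN sample engineered so cov = diag(0.04, 0.01) exactly
  k <- sqrt(11 / 12)
  cn <- cbind(rep(c(1, -1), 6) * 0.2 * k,
              rep(c(1, 1, -1, -1), 3) * 0.1 * k) + 0.5
  ref <- cmd_reference(cn)
  expect_equal(ref$sds, c(0.2, 0.1), tolerance = 1e-12)
  expect_equal(abs(ref$rotation), diag(2), tolerance = 1e-12)
  # subject offset (0.2, -0.2): components (1, 2), CMD 3
  sc <- cmd_score(ref, ref$center + c(0.2, -0.2))
  expect_equal(unname(sc$component_scores), c(1, 2), tolerance = 1e-10)
  expect_equal(sc$cmd, 3, tolerance = 1e-10)
  expect_equal(cmd_score(ref, ref$center)$cmd, 0)
  # Euclidean variant is the root sum of squares of the same components
  expect_equal(cmd_score(ref, ref$center + c(0.2, -0.2),
                         type = "euclidean")$cmd, sqrt(5),
               tolerance = 1e-10)
})

test_that("CMD axes are orthonormal, variance-complete and match prcomp", {
  set.seed(71)
  cn <- matrix(runif(200, 0.2, 0.8), 50, 4)
  cn[, 2] <- cn[, 2] + 0.5 * cn[, 1]
  ref <- cmd_reference(cn)
  expect_equal(crossprod(ref$rotation), diag(4), tolerance = 1e-10)
  expect_equal(sum(ref$sds^2), sum(diag(cov(cn))), tolerance = 1e-10)
  # independent route: prcomp axes and sdev give the same score
  subject <- runif(4)
  pc <- prcomp(cn, center = TRUE)
  oracle <- sum(abs(crossprod(pc$rotation, subject - colMeans(cn))) /
                  pc$sdev)
  expect_equal(cmd_score(ref, subject)$cmd, oracle, tolerance = 1e-8)
})

test_that("CMD is invariant under a common rotation", {
  set.seed(72)
  cn <- matrix(rnorm(200, 0.5, 0.12), 50, 4)
  subject <- rnorm(4, 0.5, 0.2)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  c1 <- cmd_score(cmd_reference(cn), subject)$cmd
  c2 <- cmd_score(cmd_reference(cn %*% Q), drop(subject %*% Q))$cmd
  expect_equal(c1, c2, tolerance = 1e-8)
})

test_that("rank-deficient CN covariance drops axes with a warning", {
  set.seed(73)
  cn <- matrix(rnorm(60, 0.5, 0.1), 20, 3)
  cn <- cbind(cn, cn[, 1])  # exactly dependent column
  expect_warning(ref <- cmd_reference(cn), "dropped")
  expect_equal(ncol(ref$rotation), 3L)
  expect_error(cmd_score(ref, rep(0.5, 3)), "expects 4")
})

test_that("permutation p-values are calibrated and super-uniform under the null", {
  set.seed(74)
  ps <- replicate(400, {
    x <- runif(60)
    g <- rep(c("CN", "CASE"), each = 30)
    case_control_tests(x, g, n_perm = 99L, n_boot = 0L + 50L,
                       seed = sample.int(1e6, 1))$pairwise$p_perm
  })
  rate <- mean(ps <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  # stochastic dominance: empirical CDF never far above the diagonal
  for (t in c(0.1, 0.25, 0.5))
    expect_lt(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 400))
})

test_that("a genuine group shift is detected with a sensible effect size", {
  set.seed(75)
  cn <- pnorm(rnorm(400))
  cs <- pnorm(rnorm(400, -0.85))
  res <- case_control_tests(c(cn, cs),
                            rep(c("CN", "AD"), c(400, 400)),
                            n_perm = 499L, seed = 2L)
  expect_lt(res$pairwise$p_perm, 0.01)
  expect_lt(res$pairwise$q_bh, 0.01)
  expect_gt(abs(res$pairwise$cohens_d), 0.5)
  expect_lt(res$omnibus$p_boot, 0.05)
  expect_true(all(c("median_diff", "cohens_d", "p_perm", "q_bh") %in%
                    names(res$pairwise)))
})

test_that("tiny groups are excluded with a warning", {
  expect_warning(
    res <- case_control_tests(runif(41), c(rep(c("A", "B"), each = 20), "C"),
                              n_perm = 99L, seed = 3L),
    "n < 2")
  expect_equal(nrow(res$pairwise), 1L)
})

test_that("longitudinal IQR follows the linear-interpolation rule", {
  tab <- data.frame(participant_id = c("a", "a", "a", "b", "b", "b", "b",
                                       "c"),
                    session = c(1:3, 1:4, 1),
                    centile = c(0.5, 0.5, 0.5, 0.2, 0.4, 0.6, 0.8, 0.9))
  out <- longitudinal_iqr(tab)
  expect_equal(out$iqr[out$participant_id == "a"], 0)
  expect_equal(out$iqr[out$participant_id == "b"], 0.3)
  expect_equal(attr(out, "n_excluded"), 1L)
  # session order is irrelevant
  tab2 <- tab[sample.int(nrow(tab)), ]
  expect_equal(longitudinal_iqr(tab2)$iqr[order(longitudinal_iqr(tab2)$participant_id)],
               out$iqr[order(out$participant_id)])
})

test_that("drifting subjects show larger centile IQR than stable ones", {
  stable <- simulate_longitudinal(tr_gmv, n_subjects = 80L, sessions = 4L,
                                  drift_per_year = 0, seed = 9L)
  drift <- simulate_longitudinal(tr_gmv, n_subjects = 80L, sessions = 4L,
                                 drift_per_year = 0.05, seed = 9L)
  cs <- centile_score(ref_gmv, stable)
  cd <- centile_score(ref_gmv, drift)
  i_s <- longitudinal_iqr(cbind(cs, session = stable$session))
  i_d <- longitudinal_iqr(cbind(cd, session = drift$session))
  expect_lt(median(i_s$iqr), median(i_d$iqr))
})

test_that("Falconer heritability is exact on stated correlations", {
  expect_equal(falconer_h2(0.8, 0.4), 0.8)
  expect_equal(falconer_h2(0.5, 0.5), 0)
  expect_equal(falconer_h2(0.9, 0.1), 1)  # clamped
})

test_that("twin heritability recovers the simulated ACE structure", {
  h2s <- sapply(1:3, function(s) {
    tw <- simulate_twins(tr_gmv, n_pairs = 300L, seed = 400L + s)
    ct <- centile_score(ref_gmv, tw)
    pairs <- pair_twins(cbind(tw[c("pair_id", "zygosity", "twin")],
                              centile = ct$centile), "centile")
    twin_h2(pairs$mz, pairs$dz, B = 100L, seed = s)$h2
  })
  expect_lt(abs(median(h2s) - 0.6), 0.15)
  # degenerate input errors
  expect_error(twin_h2(matrix(1, 20, 2), matrix(1:40, 20)), "degenerate")
  expect_error(twin_h2(matrix(rnorm(10), 5), matrix(rnorm(40), 20)),
               "10 pairs")
})
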