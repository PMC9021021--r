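#' Centile Mahalanobis distance (CMD) reference frame
#'
#' Summarizes the control (CN) group's multivariate centile distribution:
#' its mean vector, the principal axes of its covariance, and the standard
#' deviation along each axis. A subject's CMD is then the sum of the
#' absolute standardized distances of their centile vector from the CN mean
#' along every axis. Axes are ordered by decreasing variance with the sign
#' fixed so the largest-magnitude loading is positive; axes with numerically
#' zero variance (rank-deficient covariance) are dropped with a warning.
#'
#' @param cn_centiles numeric matrix, control subjects in rows and
#'   phenotype centiles in columns (at least 10 rows, 2 columns, no
#'   missing values).
#' @return list of class `cmd_reference`: `center`, `rotation` (columns =
#'   axes), `sds`, `n_dropped`.
#' @export
cmd_reference <- function(cn_centiles) {
  cn_centiles <- as.matrix(cn_centiles)
  if (ncol(cn_centiles) < 2L)
    stop("CMD needs at least 2 phenotypes", call. = FALSE)
  if (nrow(cn_centiles) < 10L)
    stop("CMD reference needs at least 10 CN subjects", call. = FALSE)
  if (any(!is.finite(cn_centiles)))
    stop("CN centile matrix must have no missing values", call. = FALSE)
  center <- colMeans(cn_centiles)
  eg <- eigen(stats::cov(cn_centiles), symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  tolv <- max(vals) * 1e-12
  keep <- vals > tolv
  if (any(!keep))
    warning(sum(!keep), " principal axis(es) with near-zero variance dropped",
            call. = FALSE)
  rot <- eg$vectors[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(center = center, rotation = rot, sds = sqrt(vals[keep]),
                 n_dropped = sum(!keep)),
            class = "cmd_reference")
}

#' @rdname cmd_reference
#' @param reference a `cmd_reference`.
#' @param centiles a subject centile vector, or a matrix of subjects in
#'   rows, matching the reference dimension.
#' @param type `"sum_abs"` (default): CMD is the sum of absolute
#'   standardized distances along the axes; `"euclidean"`: the classical
#'   Mahalanobis distance, i.e. the root sum of squares of the same
#'   standardized components.
#' @return `cmd_score`: for a vector, a list with `cmd` and
#'   `component_scores`; for a matrix, a `data.frame` with one `cmd` per
#'   row plus component columns.
#' @examples
#' ref <- cmd_reference(matrix(rnorm(100, 0.5, 0.1), 50, 2))
#' cmd_score(ref, ref$center)$cmd  # 0 at the CN mean
#' @export
cmd_score <- function(reference, centiles, type = c("sum_abs", "euclidean")) {
  stopifnot(inherits(reference, "cmd_reference"))
  type <- match.arg(type)
  agg <- function(comp) if (type == "sum_abs") sum(comp) else
    sqrt(sum(comp^2))
  if (is.matrix(centiles) || is.data.frame(centiles)) {
    m <- as.matrix(centiles)
    if (ncol(m) != length(reference$center))
      stop("centile matrix has ", ncol(m), " columns; reference expects ",
           length(reference$center), call. = FALSE)
    comp <- abs(sweep(m, 2L, reference$center) %*% reference$rotation)
    comp <- sweep(comp, 2L, reference$sds, "/")
    colnames(comp) <- paste0("axis", seq_len(ncol(comp)))
    return(data.frame(cmd = apply(comp, 1L, agg), comp))
  }
  if (length(centiles) != length(reference$center))
    stop("subject vector has length ", length(centiles),
         "; reference expects ", length(reference$center), call. = FALSE)
  proj <- drop(crossprod(reference$rotation, centiles - reference$center))
  comp <- abs(proj) / reference$sds
  list(cmd = agg(comp), component_scores = comp)
}

#' Case-control comparisons of centile scores
#'
#' For each sex stratum: pairwise two-sided Monte Carlo permutation tests on
#' the difference in group medians, with Benjamini-Hochberg FDR correction
#' across all pairs within the stratum, and Cohen's d from the pooled
#' standard deviation; plus an omnibus Welch-type one-way statistic whose
#' null distribution is generated by resampling from the pooled sample
#' (preserving group sizes).
#'
#' @param centile numeric vector of centile scores.
#' @param group group labels (diagnosis; must have >= 2 usable groups).
#' @param sex sex labels defining the strata (a single constant for an
#'   unstratified analysis).
#' @param n_perm permutations per pairwise test (>= 99).
#' @param n_boot omnibus bootstrap resamples.
#' @param seed integer seed (RNG state restored on exit).
#' @return list of class `case_control`: `pairwise` (tidy `data.frame`:
#'   sex, group1, group2, n1, n2, median_diff, cohens_d, p_perm, q_bh) and
#'   `omnibus` (`data.frame`: sex, welch_f, df1, df2, p_boot). Groups with
#'   fewer than 2 observations in a stratum are excluded with a warning.
#' @export
case_control_tests <- function(centile, group, sex = rep("all",
                                                         length(centile)),
                               n_perm = 10000L, n_boot = 500L, seed = 1L) {
  stopifnot(length(group) == length(centile), length(sex) == length(centile))
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  pw <- list(); om <- list()
  for (s in unique(sex)) {
    idx <- sex == s
    x <- centile[idx]; g <- as.character(group[idx])
    sizes <- table(g)
    small <- names(sizes)[sizes < 2L]
    if (length(small)) {
      warning("group(s) with n < 2 excluded in stratum ", s, ": ",
              paste(small, collapse = ", "), call. = FALSE)
      keep <- !g %in% small
      x <- x[keep]; g <- g[keep]
    }
    lev <- sort(unique(g))
    if (length(lev) < 2L) next
    # omnibus: Welch's F with a pooled-resampling null
    wt <- stats::oneway.test(x ~ factor(g), var.equal = FALSE)
    f_obs <- unname(wt$statistic)
    f_null <- replicate(n_boot, {
      xb <- sample(x, length(x), replace = TRUE)
      stats::oneway.test(xb ~ factor(g), var.equal = FALSE)$statistic
    })
    om[[length(om) + 1L]] <- data.frame(
      sex = s, welch_f = f_obs,
      df1 = unname(wt$parameter[1]), df2 = unname(wt$parameter[2]),
      p_boot = (1 + sum(f_null >= f_obs, na.rm = TRUE)) / (1 + n_boot))
    pairs <- utils::combn(lev, 2L, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      xi <- x[g == pr[1]]; xj <- x[g == pr[2]]
      t_obs <- stats::median(xi) - stats::median(xj)
      xx <- c(xi, xj); n1 <- length(xi); nn <- length(xx)
      t_perm <- replicate(n_perm, {
        p <- sample.int(nn, n1)
        stats::median(xx[p]) - stats::median(xx[-p])
      })
      sd_pool <- sqrt(((n1 - 1) * stats::var(xi) +
                         (length(xj) - 1) * stats::var(xj)) / (nn - 2))
      data.frame(sex = s, group1 = pr[1], group2 = pr[2],
                 n1 = n1, n2 = length(xj), median_diff = t_obs,
                 cohens_d = (mean(xi) - mean(xj)) / sd_pool,
                 p_perm = (1 + sum(abs(t_perm) >= abs(t_obs))) / (1 + n_perm))
    })
    tab <- do.call(rbind, rows)
    tab$q_bh <- stats::p.adjust(tab$p_perm, method = "BH")
    pw[[length(pw) + 1L]] <- tab
  }
  if (!length(pw)) stop("no stratum has >= 2 usable groups", call. = FALSE)
  structure(list(pairwise = do.call(rbind, pw),
                 omnibus = do.call(rbind, om)),
            class = "case_control")
}

#' Within-subject longitudinal stability of centile scores
#'
#' The subject-specific interquartile range of centiles across repeat
#' sessions, using linear-interpolation quantiles (R type 7); a fixed,
#' documented rule so IQRs are reproducible across environments. Subjects
#' with a single session are excluded and counted.
#'
#' @param tab `data.frame` with columns `participant_id`, `session` and the
#'   centile column.
#' @param centile_col name of the centile column.
#' @return `data.frame` with `participant_id`, `n_sessions`, `iqr`;
#'   attribute `n_excluded` counts single-session subjects.
#' @export
longitudinal_iqr <- function(tab, centile_col = "centile") {
  stopifnot(all(c("participant_id", "session", centile_col) %in% names(tab)))
  sp <- split(tab[[centile_col]], as.character(tab$participant_id))
  keep <- vapply(sp, length, 1L) >= 2L
  out <- data.frame(
    participant_id = names(sp)[keep],
    n_sessions = vapply(sp[keep], length, 1L),
    iqr = vapply(sp[keep], function(v)
      unname(diff(stats::quantile(v, c(0.25, 0.75), type = 7))), 1.0))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Falconer heritability from twin-pair correlations
#'
#' \eqn{h^2 = 2(r_{MZ} - r_{DZ})}, clamped to \[0, 1\].
#'
#' @param r_mz,r_dz monozygotic and dizygotic pair correlations.
#' @export
falconer_h2 <- function(r_mz, r_dz) pmin(pmax(2 * (r_mz - r_dz), 0), 1)

# double-entry (intraclass-style) Pearson pair correlation
.pair_cor <- function(pairs) {
  m <- as.matrix(pairs)
  stopifnot(ncol(m) == 2L)
  de <- rbind(m, m[, 2:1])
  if (stats::sd(de[, 1]) == 0 || stats::sd(de[, 2]) == 0)
    stop("degenerate (zero-variance) twin data", call. = FALSE)
  stats::cor(de[, 1], de[, 2])
}

#' Twin heritability of a phenotype or its centile scores
#'
#' Estimates the pair correlation within monozygotic and dizygotic twin
#' pairs (double-entry Pearson, so the estimate is symmetric in twin
#' order) and converts them to narrow-sense heritability with Falconer's
#' formula, with a percentile bootstrap over pairs for the confidence
#' interval.
#'
#' @param mz,dz two-column matrices or data frames (twin 1, twin 2 of each
#'   pair), at least 10 pairs each.
#' @param B bootstrap replicates.
#' @param seed integer seed (RNG state restored on exit).
#' @param level confidence level.
#' @return list of class `twin_h2`: `h2`, `r_mz`, `r_dz`, `ci_low`,
#'   `ci_high`, `n_mz`, `n_dz`.
#' @export
twin_h2 <- function(mz, dz, B = 1000L, seed = 1L, level = 0.95) {
  mz <- as.matrix(mz); dz <- as.matrix(dz)
  if (nrow(mz) < 10L || nrow(dz) < 10L)
    stop("need at least 10 pairs per zygosity", call. = FALSE)
  r_mz <- .pair_cor(mz); r_dz <- .pair_cor(dz)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  reps <- replicate(B, {
    falconer_h2(.pair_cor(mz[sample.int(nrow(mz), replace = TRUE), ]),
                .pair_cor(dz[sample.int(nrow(dz), replace = TRUE), ]))
  })
  a <- (1 - level) / 2
  qs <- stats::quantile(reps, c(a, 1 - a), names = FALSE)
  structure(list(h2 = falconer_h2(r_mz, r_dz), r_mz = r_mz, r_dz = r_dz,
                 ci_low = qs[1], ci_high = qs[2],
                 n_mz = nrow(mz), n_dz = nrow(dz)),
            class = "twin_h2")
}

#' @export
print.twin_h2 <- function(x, ...) {
  cat(sprintf(
    "Falconer h2 = %.3f (%.0f%% CI %.3f-%.3f); r_MZ = %.3f (n=%d), r_DZ = %.3f (n=%d)\n",
    x$h2, 100 * 0.95, x$ci_low, x$ci_high, x$r_mz, x$n_mz, x$r_dz, x$n_dz))
  invisible(x)
}
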