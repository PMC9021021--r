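#' BIC-guided staged selection of fractional-polynomial powers
#'
#' Searches the fractional-polynomial power multisets for the mu and sigma
#' age trends in two stages: first the mu powers with an intercept-only
#' sigma trend, then the sigma powers given the best mu. Candidates are
#' ranked by BIC (ascending); exact ties are broken by fewer parameters,
#' then lexicographically smaller powers. Candidates that fail to converge
#' are ranked last and flagged. The winning specification is refit at the
#' default (tighter) tolerance.
#'
#' BIC here is \eqn{-2\,\ell + k \log n} with \eqn{\ell} the unpenalized
#' log-likelihood at the posterior modes and \eqn{k} counting fixed
#' effects, the shape intercept and one variance per active random term.
#'
#' @param data phenotype table.
#' @param spec template [gg_spec()]: its covariates and random terms are
#'   kept, only the FP powers are searched.
#' @param mu_candidates,sigma_candidates lists of power multisets
#'   (default: all multisets up to order 3, including order 0).
#' @param control fit control for the search stage; a looser tolerance
#'   than the final fit, since only the ranking matters here.
#' @return list of class `gg_selection`: `stage_mu` and `stage_sigma`
#'   ranking tables (`powers`, `bic`, `n_params`, `converged`),
#'   `best_spec`, `best_fit`.
#' @export
select_gg_model <- function(data, spec,
                            mu_candidates = fp_candidates(3L),
                            sigma_candidates = fp_candidates(3L),
                            control = gg_control(tol = 1e-4,
                                                 max_cycles = 100L,
                                                 se = FALSE)) {
  stopifnot(inherits(spec, "gg_spec"))
  if (!length(mu_candidates) || !length(sigma_candidates))
    stop("candidate space is empty", call. = FALSE)

  fit_one <- function(mu_p, sg_p) {
    sp <- gg_spec(spec$phenotype,
                  mu = moment_formula(mu_p, spec$mu$covariates,
                                      spec$mu$random),
                  sigma = moment_formula(sg_p, spec$sigma$covariates,
                                         spec$sigma$random))
    fit <- tryCatch(gg_gamlss(data, sp, control, keep_data = FALSE),
                    error = function(e) NULL)
    if (is.null(fit))
      return(list(bic = Inf, n_params = NA_integer_, converged = FALSE))
    list(bic = fit$bic, n_params = fit$n_params, converged = fit$converged)
  }
  rank_table <- function(cands, results) {
    tab <- data.frame(
      powers = I(cands),
      bic = sapply(results, `[[`, "bic"),
      n_params = sapply(results, `[[`, "n_params"),
      converged = sapply(results, `[[`, "converged"))
    key <- sapply(cands, function(p) paste(format(p, nsmall = 1),
                                           collapse = ","))
    # non-converged last, then BIC, ties by parsimony then powers
    ord <- order(ifelse(tab$converged, 0L, 1L), tab$bic, tab$n_params, key)
    tab[ord, , drop = FALSE]
  }

  res_mu <- lapply(mu_candidates, fit_one, sg_p = numeric(0))
  stage_mu <- rank_table(mu_candidates, res_mu)
  best_mu <- stage_mu$powers[[1L]]

  res_sg <- lapply(sigma_candidates, function(p) fit_one(best_mu, p))
  stage_sg <- rank_table(sigma_candidates, res_sg)
  best_sg <- stage_sg$powers[[1L]]

  best_spec <- gg_spec(spec$phenotype,
                       mu = moment_formula(best_mu, spec$mu$covariates,
                                           spec$mu$random),
                       sigma = moment_formula(best_sg,
                                              spec$sigma$covariates,
                                              spec$sigma$random))
  structure(list(stage_mu = stage_mu, stage_sigma = stage_sg,
                 best_spec = best_spec,
                 best_fit = gg_gamlss(data, best_spec)),
            class = "gg_selection")
}

#' @export
print.gg_selection <- function(x, ...) {
  fmt <- function(p) paste0("{", paste(format(p), collapse = ","), "}")
  cat("Staged BIC selection\n",
      " best mu powers:    ", fmt(x$best_spec$mu$powers),
      "  (BIC ", format(x$stage_mu$bic[1L]), ")\n",
      " best sigma powers: ", fmt(x$best_spec$sigma$powers),
      "  (BIC ", format(x$stage_sigma$bic[1L]), ")\n", sep = "")
  invisible(x)
}

#' Stratified bootstrap refits
#'
#' Resamples participants with replacement within study-by-sex strata
#' (preserving each stratum's participant count, hence the per-study and
#' per-sex sample sizes) and refits the model on each replicate. Replicate
#' b is reproducible from `(seed, b)` alone. Non-convergent replicates are
#' retained and flagged.
#'
#' @param data phenotype table.
#' @param spec a [gg_spec()].
#' @param B number of replicates.
#' @param seed integer seed.
#' @param control fit control.
#' @return list of class `gg_boot`: `B` replicate `gg_gamlss` fits
#'   (without retained data) with attribute `converged` (logical vector).
#' @export
# draw a participant-level resample with replacement within each
# study-by-sex stratum; returns row indices into `data`
.resample_within_strata <- function(data) {
  strata <- split(seq_len(nrow(data)),
                  list(as.character(data$study), data$sex), drop = TRUE)
  unlist(lapply(strata, function(rows) {
    ids <- unique(data$participant_id[rows])
    pick <- sample(ids, length(ids), replace = TRUE)
    unlist(lapply(pick, function(p)
      rows[data$participant_id[rows] == p]), use.names = FALSE)
  }), use.names = FALSE)
}

bootstrap_gg <- function(data, spec, B = 199L, seed = 1L,
                         control = gg_control(tol = 1e-4,
                                              max_cycles = 100L,
                                              se = FALSE)) {
  stopifnot(B >= 1L)
  data <- validate_phenotypes(data, spec$phenotype)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  fits <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- .resample_within_strata(data)
    fits[[b]] <- gg_gamlss(data[idx, , drop = FALSE], spec, control,
                           keep_data = FALSE)
  }
  structure(fits, converged = vapply(fits, `[[`, TRUE, "converged"),
            class = "gg_boot")
}
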