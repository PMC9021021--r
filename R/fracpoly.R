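#' Fractional-polynomial age bases
#'
#' Construct the fractional-polynomial (FP) basis of a positive covariate for
#' a multiset of powers drawn from the standard set
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}. Power 0 denotes \eqn{\log x}; a power
#' repeated \eqn{k} times contributes the log-augmented columns
#' \eqn{x^p, x^p \log x, \dots, x^p (\log x)^{k-1}}.
#'
#' @param x positive numeric vector (here: age in years post-conception).
#' @param powers numeric vector (multiset) of length 0-3 from the standard
#'   power set; sorted internally. Length 0 gives a zero-column matrix
#'   (intercept-only age trend).
#' @return numeric matrix with one named column per FP term and
#'   `length(x)` rows.
#' @examples
#' fp_basis(c(1, 2, 10), c(-2, -2, -2))  # x^-2, x^-2 log x, x^-2 (log x)^2
#' @export
fp_basis <- function(x, powers) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("fractional polynomials require x > 0", call. = FALSE)
  powers <- fp_powers(powers)
  if (length(powers) == 0L)
    return(matrix(numeric(0), nrow = length(x), ncol = 0L))
  lx <- log(x)
  cols <- vector("list", length(powers))
  nms <- character(length(powers))
  rep_count <- 0L
  for (j in seq_along(powers)) {
    p <- powers[j]
    rep_count <- if (j > 1L && powers[j - 1L] == p) rep_count + 1L else 0L
    base <- if (p == 0) lx else x^p
    cols[[j]] <- base * lx^rep_count
    nms[j] <- paste0("fp(", format(p), ")",
                     if (rep_count > 0L) paste0(".log", rep_count) else "")
  }
  out <- do.call(cbind, cols)
  colnames(out) <- nms
  out
}

#' @rdname fp_basis
#' @export
fp_powers <- function(powers) {
  allowed <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  powers <- as.numeric(powers)
  if (length(powers) > 3L)
    stop("fractional polynomials of order > 3 are not supported", call. = FALSE)
  if (length(powers) && !all(powers %in% allowed))
    stop("powers must be drawn from {", paste(allowed, collapse = ", "), "}",
         call. = FALSE)
  sort(powers)
}

#' Enumerate candidate fractional-polynomial power multisets
#'
#' All multisets of the standard powers up to a maximum order, ordered by
#' order then lexicographically; used as the default model-selection search
#' space (order 0, i.e. no age trend, through order `max_order`).
#'
#' @param max_order maximum FP order (0-3).
#' @param min_order minimum FP order (default 0 = intercept-only).
#' @return list of numeric power vectors.
#' @export
fp_candidates <- function(max_order = 3L, min_order = 0L) {
  stopifnot(max_order >= min_order, max_order <= 3L, min_order >= 0L)
  allowed <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  out <- list()
  for (ord in seq(min_order, max_order)) {
    if (ord == 0L) { out <- c(out, list(numeric(0))); next }
    idx <- utils::combn(length(allowed) + ord - 1L, ord, simplify = FALSE)
    # combinations with repetition via the stars-and-bars bijection
    for (cc in idx) out <- c(out, list(allowed[cc - seq_len(ord) + 1L]))
  }
  out
}

#' Age conversion between days post-conception and years
#'
#' Internal model age is years post-conception, strictly positive so that
#' logs and negative powers are defined for foetal scans; ages are reported
#' relative to birth using the 40-week (280-day) convention, allowing
#' negative prenatal ages.
#'
#' @param age_days age in days post-conception.
#' @param floor smallest admissible age in days post-conception.
#' @return data frame with `x` (years post-conception, the model covariate)
#'   and `age_years` (years relative to birth, the reporting scale).
#' @examples
#' transform_age(280)  # birth: x = 0.7666, age_years = 0
#' @export
transform_age <- function(age_days, floor = 80) {
  age_days <- as.numeric(age_days)
  if (any(!is.finite(age_days)) || any(age_days < floor))
    stop("age_days must be >= ", floor, " days post-conception", call. = FALSE)
  data.frame(x = age_days / 365.25, age_years = (age_days - 280) / 365.25)
}

# inverse of the reporting convention
.age_years_to_x <- function(age_years) age_years + 280 / 365.25
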