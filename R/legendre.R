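#' Normalized Legendre basis for random-regression covariables
#'
#' Evaluates the normalized Legendre polynomials
#' \eqn{\phi_l(x) = \sqrt{(2l+1)/2}\, P_l(x)} on the standardized scale
#' \eqn{x \in [-1, 1]}, the conventional basis for longitudinal animal
#' models. Order 1 (intercept + slope) is the package default.
#'
#' @param x numeric vector of standardized ages in \[-1, 1\].
#' @param order highest polynomial degree (basis has `order + 1` columns).
#' @return matrix with `length(x)` rows and `order + 1` columns.
#' @examples
#' legendre_basis(c(-1, 0, 1), order = 1)
#' @export
legendre_basis <- function(x, order = 1) {
  stopifnot(is.numeric(x), order >= 0)
  if (any(x < -1 - 1e-9 | x > 1 + 1e-9)) {
    stop("standardized ages must lie in [-1, 1]")
  }
  n <- length(x)
  P <- matrix(0, n, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (l in 2:order) {
      # Bonnet recursion: l P_l = (2l-1) x P_{l-1} - (l-1) P_{l-2}
      P[, l + 1] <- ((2 * l - 1) * x * P[, l] - (l - 1) * P[, l - 1]) / l
    }
  }
  norm <- sqrt((2 * seq(0, order) + 1) / 2)
  sweep(P, 2, norm, `*`)
}

#' Map ages to the standardized basis scale
#'
#' @param age numeric ages in years.
#' @param age_range length-2 numeric, ages mapped linearly to \[-1, 1\].
#' @return numeric vector of standardized ages.
#' @export
standardize_age <- function(age, age_range = c(2, 8)) {
  stopifnot(length(age_range) == 2, age_range[2] > age_range[1])
  if (any(age < age_range[1] - 1e-9 | age > age_range[2] + 1e-9)) {
    stop("age outside standardization bounds [", age_range[1], ", ",
         age_range[2], "]")
  }
  2 * (age - age_range[1]) / (age_range[2] - age_range[1]) - 1
}
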