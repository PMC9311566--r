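#' Variance components of a fitted random-regression model
#'
#' @param fit an `rrgreml` object.
#' @return list with the coefficient covariance matrices (`K$a`, `K$d`,
#'   `K$pe` when fitted) and `sigma2_e`.
#' @export
varcomps <- function(fit) {
  stopifnot(inherits(fit, "rrgreml"))
  list(K = fit$K, sigma2_e = fit$sigma2_e)
}

#' Animal coefficient BLUPs
#'
#' Solutions of the mixed-model equations at the estimated variance
#' components, one q x (order+1) matrix per random term, including
#' animals without records that are connected through the GRMs.
#'
#' @param fit an `rrgreml` object.
#' @return named list of coefficient matrices.
#' @export
blup_effects <- function(fit) {
  stopifnot(inherits(fit, "rrgreml"))
  fit$u
}

#' Project animal effects to an age
#'
#' Evaluates \eqn{\hat u(t) = \phi(t)' c} for each animal's additive and
#' dominance coefficient vectors; the total is their sum.
#'
#' @param fit an `rrgreml` object (or a list of coefficient matrices with
#'   attributes `order`, `age_range`).
#' @param age projection age in years (default 8).
#' @return data.frame with `id`, `u_a`, `u_d` (0 when no dominance term),
#'   `u_pe` (if fitted), `total` = `u_a + u_d`.
#' @export
project_to_age <- function(fit, age = 8) {
  stopifnot(inherits(fit, "rrgreml"))
  phi <- drop(legendre_basis(standardize_age(age, fit$age_range),
                             fit$order))
  pr <- lapply(fit$u, function(U) as.numeric(U %*% phi))
  u_a <- pr$a
  u_d <- if (!is.null(pr$d)) pr$d else rep(0, length(u_a))
  out <- data.frame(id = fit$ids, u_a = u_a, u_d = u_d,
                    total = u_a + u_d, stringsAsFactors = FALSE)
  if (!is.null(pr$pe)) out$u_pe <- pr$pe
  out
}

#' Age-wise variance fractions (heritability curve)
#'
#' At each age t: \eqn{v_a(t) = \phi(t)' K_a \phi(t)}, similarly for the
#' dominance and permanent-environment terms, and
#' \eqn{h^2_a(t) = v_a / (v_a + v_d + v_{pe} + \sigma^2_e)},
#' \eqn{h^2_d(t)} analogous.
#'
#' @param fit an `rrgreml` object.
#' @param ages numeric vector of ages.
#' @return data.frame with ages, variances and variance fractions.
#' @export
heritability_curve <- function(fit, ages = seq(2, 8, by = 0.5)) {
  stopifnot(inherits(fit, "rrgreml"))
  phi <- legendre_basis(standardize_age(ages, fit$age_range), fit$order)
  qf <- function(K) rowSums((phi %*% K) * phi)
  v_a <- qf(fit$K$a)
  v_d <- if (!is.null(fit$K$d)) qf(fit$K$d) else rep(0, length(ages))
  v_pe <- if (!is.null(fit$K$pe)) qf(fit$K$pe) else rep(0, length(ages))
  tot <- v_a + v_d + v_pe + fit$sigma2_e
  data.frame(age = ages, v_a = v_a, v_d = v_d, v_pe = v_pe,
             sigma2_e = fit$sigma2_e, v_total = tot,
             h2_a = v_a / tot, h2_d = v_d / tot)
}

#' @export
print.rrgreml <- function(x, digits = 4, ...) {
  cat("Random-regression GREML fit",
      if (!is.null(x$trait)) paste0("(", x$trait, ")"), "\n")
  cat("  records:", x$N, " animals:", length(x$ids),
      " basis order:", x$order, "\n")
  cat("  restricted logL:", format(x$logLik, digits = 10),
      if (x$converged) " (converged" else " (NOT converged",
      paste0("in ", x$n_iter, " iterations)"), "\n")
  cat("  sigma2_e:", format(x$sigma2_e, digits = digits), "\n")
  for (nm in names(x$K)) {
    cat("  K_", nm, ":\n", sep = "")
    print(round(x$K[[nm]], digits))
  }
  h8 <- heritability_curve(x, 8)
  cat(sprintf("  age-8 variance fractions: h2_a = %.3f, h2_d = %.3f\n",
              h8$h2_a, h8$h2_d))
  invisible(x)
}

#' @export
summary.rrgreml <- function(object, ages = seq(2, 8, by = 1), ...) {
  out <- list(trait = object$trait, curve = heritability_curve(object, ages),
              K = object$K, sigma2_e = object$sigma2_e,
              logLik = object$logLik, converged = object$converged,
              n_iter = object$n_iter, N = object$N,
              n_animals = length(object$ids))
  class(out) <- "summary.rrgreml"
  out
}

#' @export
print.summary.rrgreml <- function(x, ...) {
  cat("Random-regression GREML",
      if (!is.null(x$trait)) paste0("(", x$trait, ")"), "\n")
  cat(" ", x$N, "records on", x$n_animals, "animals; restricted logL",
      format(x$logLik, digits = 10), "\n\n")
  cat("Variance fractions by age:\n")
  print(round(x$curve, 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.rrgreml <- function(object, ...) object$beta

#' @export
logLik.rrgreml <- function(object, ...) {
  structure(object$logLik, df = length(object$beta), class = "logLik")
}

#' @export
fitted.rrgreml <- function(object, ...) object$fitted

#' @export
residuals.rrgreml <- function(object, ...) object$residuals

#' Predict projected animal effects
#'
#' @param object an `rrgreml` fit.
#' @param age projection age (years), default 8.
#' @param ... unused.
#' @return see [project_to_age()].
#' @export
predict.rrgreml <- function(object, age = 8, ...) {
  project_to_age(object, age = age)
}

#' Plot the heritability curve of a fit
#'
#' @param x an `rrgreml` fit.
#' @param ages ages at which to evaluate the curve.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rrgreml <- function(x, ages = seq(2, 8, by = 0.25), ...) {
  cv <- heritability_curve(x, ages)
  graphics::matplot(cv$age, cbind(cv$h2_a, cv$h2_d), type = "l", lty = 1,
                    col = c("black", "red3"), xlab = "Age (years)",
                    ylab = "Variance fraction", ...)
  graphics::legend("topleft", legend = c("additive", "dominance"),
                   col = c("black", "red3"), lty = 1, bty = "n")
  invisible(cv)
}

#' Simulate response vectors from a fitted model
#'
#' Draws new phenotype vectors at the fitted variance components and fixed
#' effects, with coefficient effects sampled from `K kron` structure.
#' Mainly useful for parametric-bootstrap checks.
#'
#' @param object an `rrgreml` fit.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param G,D the relationship matrices used in the fit (not stored in the
#'   object to keep it small).
#' @param records the record table used in the fit.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.rrgreml <- function(object, nsim = 1, seed = NULL, G, D = NULL,
                             records, ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- build_design(records, object$ids, order = object$order,
                      age_range = object$age_range)
  q <- length(object$ids)
  chG <- chol_ridge(G, "G")$chol
  chD <- if (!is.null(object$K$d) && !is.null(D)) chol_ridge(D, "D")$chol
  mu <- as.numeric(des$X %*% object$beta)
  out <- matrix(0, length(mu), nsim)
  for (s in seq_len(nsim)) {
    ua <- sample_kron_coefs(object$K$a, chG, q)
    vec <- as.numeric(ua)
    if (!is.null(chD)) vec <- vec + as.numeric(
      sample_kron_coefs(object$K$d, chD, q))
    if (!is.null(object$K$pe)) vec <- vec + as.numeric(
      sample_kron_coefs(object$K$pe, diag(q), q))
    out[, s] <- mu + as.numeric(des$Z %*% vec) +
      stats::rnorm(length(mu), 0, sqrt(object$sigma2_e))
  }
  as.data.frame(out)
}
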