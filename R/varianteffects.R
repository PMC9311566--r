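#' Back-solve variant effects from projected animal effects
#'
#' Solves \eqn{\hat\alpha = M'(MM')^{-1}\hat u} where `coeff` is the
#' centered additive coefficient matrix M (or the dominance coefficient
#' matrix H) and `gram * scale = coeff %*% t(coeff)` is its Gram matrix
#' (c_a G or c_d D), so the Gram product never has to be re-formed. The
#' solution is the minimum-norm vector reproducing
#' \eqn{M\hat\alpha = \hat u}.
#'
#' @param coeff n x m coefficient matrix (M or H) over the animals in `u`.
#' @param u projected animal effects (kg), length n.
#' @param gram n x n relationship matrix (G or D).
#' @param scale scaling denominator (c_a or c_d) with
#'   `gram * scale == tcrossprod(coeff)` up to tolerance.
#' @param check verify the Gram identity (skipped inside permutation
#'   loops).
#' @return numeric vector of m variant effects (kg).
#' @details Centered coefficient matrices have column sums of zero, so
#'   their Gram matrix is always singular (the all-ones vector is in its
#'   null space). Singular systems are solved with an eigen-truncated
#'   pseudoinverse, which preserves the minimum-norm reconstruction
#'   identity for any `u` in the row space of `coeff` (as projected
#'   animal effects are).
#' @export
backsolve_effects <- function(coeff, u, gram, scale, check = TRUE) {
  n <- nrow(coeff)
  stopifnot(length(u) == n, nrow(gram) == n, ncol(gram) == n)
  if (check) {
    GG <- tcrossprod(coeff)
    rel <- max(abs(GG - gram * scale)) / max(abs(GG), 1e-12)
    if (rel > 1e-6) {
      stop("gram * scale does not match coeff %*% t(coeff) ",
           "(relative error ", format(rel, digits = 3), ")")
    }
  }
  as.numeric(crossprod(coeff, gram_solve(gram * scale) %*% u))
}

# inverse (or eigen-truncated pseudoinverse) of a symmetric PSD Gram
# matrix
gram_solve <- function(A, tol = 1e-10) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch) && min(diag(ch))^2 > tol * mean(diag(A))) {
    return(chol2inv(ch))
  }
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  if (!any(pos)) stop("Gram matrix is numerically zero")
  V <- e$vectors[, pos, drop = FALSE]
  V %*% (t(V) / e$values[pos])
}

#' Z-standardize a vector of variant effects
#'
#' \eqn{z_j = (e_j - \bar e) / s} with the sample SD (denominator m - 1).
#'
#' @param effects numeric vector (length >= 2).
#' @return numeric z vector.
#' @export
zscore <- function(effects) {
  if (length(effects) < 2) stop("need at least two variant effects")
  s <- stats::sd(effects)
  if (s == 0) stop("zero spread: z-scores undefined")
  (effects - mean(effects)) / s
}

#' Permutation-based significance of variant effects
#'
#' Back-solves effects and z-scores for `B` random permutations of the
#' entries of the animal-effect vector; the per-variant standard error of
#' the permuted z-scores approximates the null scale, and
#' \eqn{p_j = 2\Phi(-|z_j|/SE_j)} (two-sided standard-normal tail).
#' Variants with zero permutation SE get p = 1 and are flagged.
#'
#' @inheritParams backsolve_effects
#' @param B number of permutations (>= 100; the analysis default is 5000).
#' @param seed integer seed for the permutations.
#' @return list with `effects`, `z`, `se_z`, `p`, `zero_se` (logical),
#'   `B`, `seed`.
#' @export
permutation_pvalues <- function(coeff, u, gram, scale, B = 5000, seed = 1) {
  if (B < 100) stop("B must be at least 100")
  n <- nrow(coeff)
  # m x n back-solve operator, reused for observed and permuted vectors
  Aop <- crossprod(coeff, gram_solve(gram * scale))
  eff <- as.numeric(Aop %*% u)
  z <- zscore(eff)
  set.seed(seed)
  P <- matrix(0, n, B)
  for (b in seq_len(B)) P[, b] <- u[sample.int(n)]
  Ez <- Aop %*% P               # m x B permuted effects
  Ez <- scale(Ez, center = TRUE, scale = apply(Ez, 2, stats::sd))
  se <- apply(Ez, 1, stats::sd)
  zero_se <- !is.finite(se) | se == 0
  p <- rep(1, length(z))
  p[!zero_se] <- 2 * stats::pnorm(-abs(z[!zero_se]) / se[!zero_se])
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(effects = eff, z = z, se_z = se, p = p, zero_se = zero_se,
       B = B, seed = seed)
}

#' Bonferroni selection of significant variants
#'
#' A variant is flagged when `p * m_tests < alpha`.
#'
#' @param p numeric p-values.
#' @param alpha family-wise level (default 0.05).
#' @param m_tests number of tests corrected for (defaults to `length(p)`).
#' @return logical vector.
#' @export
bonferroni_select <- function(p, alpha = 0.05, m_tests = length(p)) {
  if (m_tests < length(p)) stop("m_tests must be >= length(p)")
  if (length(p) == 0) return(logical(0))
  p * m_tests < alpha
}

#' Propagate significance to pruned redundant variants
#'
#' Variants removed from M and H because of redundancy inherit the effect,
#' p-value and significance flag of the retained variant they were pruned
#' against.
#'
#' @param table data.frame of tested variants with a `variant` name column
#'   plus statistics columns.
#' @param redundancy_map data.frame with columns `pruned`,
#'   `representative` (variant names).
#' @return `table` extended with the pruned variants (column `representative`
#'   names each variant's source; tested variants point to themselves).
#' @export
propagate_redundant <- function(table, redundancy_map) {
  stopifnot("variant" %in% names(table))
  table$representative <- table$variant
  if (is.null(redundancy_map) || nrow(redundancy_map) == 0) return(table)
  idx <- match(redundancy_map$representative, table$variant)
  if (anyNA(idx)) {
    stop("redundancy map references variants absent from the tested set")
  }
  extra <- table[idx, , drop = FALSE]
  extra$variant <- redundancy_map$pruned
  extra$representative <- redundancy_map$representative
  out <- rbind(table, extra)
  rownames(out) <- NULL
  out
}

#' Per-variant effect table for one trait
#'
#' Convenience wrapper running the back-solve, z-scores, permutation
#' p-values, and Bonferroni selection for the additive and dominance
#' components of one trait, then propagating results to pruned variants.
#'
#' @param grm_add result of [additive_grm()] (supplies M, G, c_a).
#' @param grm_dom result of [dominance_grm()] (supplies H, D, c_d).
#' @param proj projection data.frame from [project_to_age()] restricted to
#'   the animals the GRMs are built on (matched by `id`).
#' @param genotypes the `geno_matrix` the GRMs came from (for chrom/pos).
#' @param B permutations.
#' @param seed integer seed.
#' @param alpha Bonferroni family-wise level.
#' @param redundancy_map optional map from [ld_prune()].
#' @return data.frame with per-variant chrom, pos, effects, z, p and
#'   significance flags for both components.
#' @export
variant_effect_table <- function(grm_add, grm_dom, proj, genotypes,
                                 B = 5000, seed = 1, alpha = 0.05,
                                 redundancy_map = NULL) {
  ids <- rownames(grm_add$M)
  pr <- proj[match(ids, proj$id), ]
  stopifnot(!anyNA(pr$id))
  m_tests <- ncol(grm_add$M)  # tests performed; pruned variants inherit
  pa <- permutation_pvalues(grm_add$M, pr$u_a, grm_add$G, grm_add$c_a,
                            B = B, seed = seed)
  pd <- permutation_pvalues(grm_dom$H, pr$u_d, grm_dom$D, grm_dom$c_d,
                            B = B, seed = seed + 1)
  tab <- data.frame(
    variant = variant_names(genotypes),
    chrom = genotypes$map$chrom, pos = genotypes$map$pos,
    alpha_kg = pa$effects, d_kg = pd$effects,
    z_a = pa$z, z_d = pd$z, p_a = pa$p, p_d = pd$p,
    sig_a = bonferroni_select(pa$p, alpha, m_tests),
    sig_d = bonferroni_select(pd$p, alpha, m_tests),
    stringsAsFactors = FALSE)
  propagate_redundant(tab, redundancy_map)
}
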