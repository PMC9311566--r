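#' Coefficient covariance matrices with target age-8 variance ratios
#'
#' Builds `K_a` and `K_d` proportional to a fixed well-conditioned
#' intercept/slope pattern, scaled so the age-8 genetic variances are the
#' requested fractions of the total phenotypic variance at age 8
#' (additive + dominance + residual).
#'
#' @param ratio_a,ratio_d target age-8 additive and dominance variance
#'   fractions (sum < 1).
#' @param sigma2_e residual variance (kg^2).
#' @param order basis order (default 1).
#' @param age_range standardization bounds.
#' @return list with `K_a`, `K_d`, `sigma2_e`.
#' @export
ratio_kmatrices <- function(ratio_a, ratio_d, sigma2_e = 900, order = 1,
                            age_range = c(2, 8)) {
  stopifnot(ratio_a >= 0, ratio_d >= 0, ratio_a + ratio_d < 1)
  kdim <- order + 1
  base <- diag(c(1, rep(0.25, kdim - 1)))
  if (kdim >= 2) base[1, 2] <- base[2, 1] <- 0.1
  phi8 <- drop(legendre_basis(standardize_age(age_range[2], age_range),
                              order))
  v8 <- drop(t(phi8) %*% base %*% phi8)
  tot <- sigma2_e / (1 - ratio_a - ratio_d)
  list(K_a = base * (ratio_a * tot / v8),
       K_d = base * (ratio_d * tot / v8),
       sigma2_e = sigma2_e)
}

#' Simulate a complete herd study under known variance ratios
#'
#' Convenience wrapper reproducing the package's standard study
#' conditions: a 3-breed panel (Fst 0.1), two generations of purebred,
#' F1, backcross and three-way matings, gene-dropped genotypes, genomic
#' G and D over the phenotyped cows, and longitudinal records generated
#' under the breeding/culling regime with coefficient-sampled genetic
#' values at the requested age-8 variance ratios.
#'
#' @param seed integer seed (drives every stage).
#' @param n_cows number of phenotyped cows.
#' @param n_variants number of variants.
#' @param ratio_a,ratio_d true age-8 additive and dominance variance
#'   fractions.
#' @param sigma2_e residual variance (kg^2).
#' @param n_founders founders per breed group.
#' @param herd optional herd from [build_study_herd()] to reuse across
#'   trait regimes.
#' @return list with `records` (CW-type trait records), `G`, `D`,
#'   `events` (the `herd_events` object with the truth), `pedigree`,
#'   `genotypes`, `herd`.
#' @export
simulate_herd_study <- function(seed, n_cows = 1000, n_variants = 1000,
                                ratio_a = 0.5, ratio_d = 0.05,
                                sigma2_e = 900, n_founders = 20,
                                herd = NULL) {
  if (is.null(herd)) {
    herd <- build_study_herd(seed, n_cows = n_cows,
                             n_variants = n_variants,
                             n_founders = n_founders)
  }
  km <- ratio_kmatrices(ratio_a, ratio_d, sigma2_e)
  pars <- true_params(K_a = km$K_a, K_d = km$K_d, sigma2_e = sigma2_e,
                      order = 1)
  ev <- simulate_events(herd$pedigree, herd$full_genotypes, pars,
                        mode = "coefficient",
                        seed = seed + 3000L + round(1e4 * ratio_d),
                        cows = herd$cows,
                        rel = list(G = herd$G, D = herd$D))
  recs <- build_records(ev, herd$pedigree)$cw
  list(records = recs, G = herd$G, D = herd$D, events = ev,
       pedigree = herd$pedigree, genotypes = herd$genotypes, herd = herd)
}

#' @rdname simulate_herd_study
#' @export
build_study_herd <- function(seed, n_cows = 1000, n_variants = 1000,
                             n_founders = 20) {
  per_mating <- ceiling(n_cows / 5)  # ~2 generations x 5+ groups, half F
  panel <- simulate_breed_panel(3, n_variants, n_chromosomes = 5,
                                fst = 0.1, seed = seed)
  plan <- default_cross_plan(panel$breeds, n_generations = 2,
                             n_per_mating = per_mating)
  ped <- simulate_pedigree(plan, n_founders, 2, seed = seed + 1000L)
  geno <- drop_genotypes(ped, panel, 1, seed = seed + 2000L)
  cows <- ped$id[ped$sex == "F" & ped$gen > 0]
  if (length(cows) < n_cows) {
    stop("plan produced too few cows; increase n_per_mating")
  }
  cows <- cows[seq_len(n_cows)]
  sub <- geno_matrix(geno$calls[cows, , drop = FALSE], geno$map)
  list(panel = panel, pedigree = ped, full_genotypes = geno,
       genotypes = sub, cows = cows,
       G = additive_grm(sub)$G, D = dominance_grm(sub)$D)
}
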