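#' True simulation parameters for longitudinal herd data
#'
#' Bundles the generating values for the random-regression model on the
#' basis scale: coefficient covariance matrices `K_a` (additive), `K_d`
#' (dominance) and optionally `K_pe` (permanent environment), all in kg^2,
#' the residual variance `sigma2_e` (kg^2), a directional dominance mean
#' (kg per heterozygous locus, used in variant-effects mode), and the
#' conception model (baseline probability plus a heterosis shift on the
#' logit scale).
#'
#' @param K_a,K_d,K_pe symmetric PSD coefficient covariance matrices
#'   ((order+1) x (order+1)); `K_d` may be a zero matrix, `K_pe` may be
#'   NULL.
#' @param sigma2_e residual variance, > 0.
#' @param dom_mean directional dominance mean, kg per heterozygous causal
#'   locus (variant-effects mode).
#' @param conception_base baseline per-exposure conception probability.
#' @param conception_het additive shift on the conception logit per unit of
#'   centered genomic heterozygosity.
#' @param order Legendre basis order the K matrices refer to.
#' @param age_range standardization bounds in years.
#' @param max_age last intended calving age simulated.
#' @param cw_base mean cow weight (kg) at the first record age.
#' @param cw_gain mean cow-weight gain (kg) per year of age.
#' @param calf_base mean calf weaning weight (kg).
#' @param calf_sex_effect male minus female weaning-weight difference (kg).
#' @param calf_sd residual SD of calf weaning weight (kg).
#' @param wean_prob probability a calf born is weaned.
#' @param miss_cw probability a cow weight is missing at a test.
#' @param causal_frac fraction of variants causal (variant-effects mode).
#' @param var_a,var_d target age-8 additive and dominance variances
#'   (variant-effects mode).
#' @return object of class `true_params`.
#' @export
true_params <- function(K_a, K_d = NULL, K_pe = NULL, sigma2_e,
                        dom_mean = 0, conception_base = 0.85,
                        conception_het = 0, order = 1,
                        age_range = c(2, 8), max_age = 8,
                        cw_base = 450, cw_gain = 25,
                        calf_base = 220, calf_sex_effect = 14,
                        calf_sd = 25, wean_prob = 0.95, miss_cw = 0.02,
                        causal_frac = 0.1, var_a = NULL, var_d = NULL) {
  kdim <- order + 1
  K_a <- as.matrix(K_a)
  if (is.null(K_d)) K_d <- matrix(0, kdim, kdim)
  K_d <- as.matrix(K_d)
  check_psd <- function(K, nm) {
    if (!isTRUE(all.equal(K, t(K), tolerance = 1e-8))) {
      stop(nm, " must be symmetric")
    }
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) stop(nm, " must be PSD")
  }
  check_psd(K_a, "K_a"); check_psd(K_d, "K_d")
  if (!is.null(K_pe)) check_psd(as.matrix(K_pe), "K_pe")
  stopifnot(sigma2_e > 0, nrow(K_a) == kdim, nrow(K_d) == kdim)
  structure(list(K_a = K_a, K_d = K_d, K_pe = K_pe, sigma2_e = sigma2_e,
                 dom_mean = dom_mean, conception_base = conception_base,
                 conception_het = conception_het, order = order,
                 age_range = age_range, max_age = max_age,
                 cw_base = cw_base, cw_gain = cw_gain,
                 calf_base = calf_base, calf_sex_effect = calf_sex_effect,
                 calf_sd = calf_sd, wean_prob = wean_prob,
                 miss_cw = miss_cw, causal_frac = causal_frac,
                 var_a = var_a, var_d = var_d),
            class = "true_params")
}

# sample q x k coefficient matrix with cov(vec) = K (k x k) kron A (q x q),
# coefficient-major vec ordering; uses a (possibly ridged) chol of A
sample_kron_coefs <- function(K, chA, q) {
  k <- nrow(K)
  if (all(K == 0)) return(matrix(0, q, k))
  ek <- eigen(K, symmetric = TRUE)
  Rk <- diag(sqrt(pmax(ek$values, 0)), k) %*% t(ek$vectors)  # Rk'Rk = K
  Z <- matrix(stats::rnorm(q * k), q, k)
  t(chA) %*% Z %*% Rk
}

chol_ridge <- function(A, label = "matrix") {
  md <- mean(diag(A))
  ridge <- 0
  for (trial in 0:6) {
    ch <- tryCatch(chol(A + diag(ridge, nrow(A))), error = function(e) NULL)
    # escalate on failure or on a numerically singular factor (tiny pivot),
    # which would make the inverse explode
    if (!is.null(ch) && min(diag(ch))^2 > 1e-10 * md) {
      return(list(chol = ch, ridge = ridge))
    }
    ridge <- if (ridge == 0) 1e-6 * md else ridge * 10
  }
  stop(label, " is not positive definite even after ridging")
}

#' Simulate longitudinal breeding, weaning, and weighing events
#'
#' Runs each cow through the breeding/culling regime: exposures start at
#' the breeding intended to calve at age 2; conception is Bernoulli with a
#' logit shifted by heterosis (centered genomic heterozygosity); after a
#' first non-pregnant diagnosis the next intended calving age moves by 0.5
#' years (season shift), after a second consecutive non-pregnant diagnosis
#' the cow is culled; a pregnancy moves the next intended calving age by a
#' full year. Cow weight is recorded at every pregnancy test; a weaned calf
#' contributes its weaning weight (base + sex effect + the cow's
#' weaning-trait genetic value + noise).
#'
#' True genetic values come in two modes. In `"coefficient"` mode, each
#' cow's additive and dominance coefficient vectors are drawn with
#' covariance `K_a` kron `G` and `K_d` kron `D` (GRMs built from the
#' supplied genotypes, or passed via `rel`). In `"variant"` mode,
#' per-variant additive effects are Normal and dominance effects Normal
#' with positive mean `dom_mean` (directional dominance), building
#' age-constant animal values from centered allele counts and
#' heterozygosity codes, rescaled to the target variances `var_a`, `var_d`.
#'
#' @param pedigree a `herd_pedigree`.
#' @param genotypes a [geno_matrix()] covering at least the phenotyped cows.
#' @param params a [true_params()].
#' @param mode `"coefficient"` or `"variant"`.
#' @param seed integer seed.
#' @param cows character ids of phenotyped cows; default all non-founder
#'   females present in the genotypes.
#' @param rel optional list with precomputed `G` and `D` for `cows`
#'   (coefficient mode) to avoid rebuilding.
#' @return object of class `herd_events`: list with `events` (data.frame
#'   `cow_id`, `age`, `preg`, `calf_sex`, `wean_wt`, `cow_wt`), `truth`
#'   (per-cow coefficient matrices `a`, `d`, `pe`, age-8 values `u8_a`,
#'   `u8_d`, genomic heterozygosity `ghet`), and `params`.
#' @export
simulate_events <- function(pedigree, genotypes, params,
                            mode = c("coefficient", "variant"), seed = 1,
                            cows = NULL, rel = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "true_params"))
  set.seed(seed)
  if (is.null(cows)) {
    cows <- pedigree$id[pedigree$sex == "F" & pedigree$gen > 0]
    cows <- intersect(cows, rownames(genotypes$calls))
  }
  q <- length(cows)
  if (q == 0) stop("no phenotyped cows")
  kdim <- params$order + 1

  calls <- genotypes$calls[cows, , drop = FALSE]
  ghet <- rowMeans(calls == 1L, na.rm = TRUE)

  if (mode == "coefficient") {
    if (is.null(rel)) {
      sub <- geno_matrix(calls, genotypes$map)
      rel <- list(G = additive_grm(sub)$G, D = dominance_grm(sub)$D)
    }
    chG <- chol_ridge(rel$G, "G")$chol
    a_coef <- sample_kron_coefs(params$K_a, chG, q)
    if (all(params$K_d == 0)) {
      d_coef <- matrix(0, q, kdim)
    } else {
      chD <- chol_ridge(rel$D, "D")$chol
      d_coef <- sample_kron_coefs(params$K_d, chD, q)
    }
  } else {
    m <- ncol(calls)
    p <- colMeans(calls, na.rm = TRUE) / 2
    causal <- sort(sample.int(m, max(1, round(params$causal_frac * m))))
    alpha <- stats::rnorm(length(causal))
    delta <- stats::rnorm(length(causal), mean = params$dom_mean, sd = 1)
    Mc <- sweep(calls[, causal, drop = FALSE], 2, 2 * p[causal], `-`)
    Mc[is.na(Mc)] <- 0
    het <- (calls[, causal, drop = FALSE] == 1L) * 1
    het[is.na(het)] <- 0
    a_val <- as.numeric(Mc %*% alpha)
    d_val <- as.numeric(het %*% delta)
    rescale <- function(v, target) {
      s <- stats::sd(v)
      if (is.null(target) || s == 0) return(v)
      (v - 0) * sqrt(target) / s
    }
    a_val <- rescale(a_val, params$var_a)
    d_val <- rescale(d_val, params$var_d)
    a_coef <- cbind(a_val / legendre_basis(1, 0)[1],
                    matrix(0, q, kdim - 1))
    d_coef <- cbind(d_val / legendre_basis(1, 0)[1],
                    matrix(0, q, kdim - 1))
  }
  rownames(a_coef) <- rownames(d_coef) <- cows
  pe_coef <- if (!is.null(params$K_pe)) {
    pc <- sample_kron_coefs(params$K_pe, diag(q), q)
    rownames(pc) <- cows
    pc
  } else NULL

  phi8 <- drop(legendre_basis(standardize_age(8, params$age_range),
                              params$order))
  u8_a <- as.numeric(a_coef %*% phi8)
  u8_d <- as.numeric(d_coef %*% phi8)
  names(u8_a) <- names(u8_d) <- cows

  het_c <- ghet - mean(ghet)
  se <- sqrt(params$sigma2_e)

  out <- vector("list", q)
  for (i in seq_len(q)) {
    age <- 2
    open_streak <- 0L
    recs <- list()
    while (age <= params$max_age + 1e-9) {
      x <- standardize_age(age, params$age_range)
      phi <- drop(legendre_basis(x, params$order))
      gval <- sum(phi * a_coef[i, ]) + sum(phi * d_coef[i, ]) +
        if (is.null(pe_coef)) 0 else sum(phi * pe_coef[i, ])
      p_conc <- stats::plogis(stats::qlogis(params$conception_base) +
                                params$conception_het * het_c[i])
      preg <- stats::rbinom(1, 1, p_conc)
      calf_sex <- NA_character_
      wean_wt <- 0
      if (preg == 1 && stats::runif(1) < params$wean_prob) {
        calf_sex <- sample(c("M", "F"), 1)
        # cow's genetic value enters her calves' weaning weights
        wean_wt <- max(1, params$calf_base +
                         (calf_sex == "M") * params$calf_sex_effect -
                         params$calf_sex_effect / 2 +
                         gval + stats::rnorm(1, 0, params$calf_sd))
      }
      cow_wt <- params$cw_base + params$cw_gain * (age - 2) +
        gval + stats::rnorm(1, 0, se)
      if (stats::runif(1) < params$miss_cw) cow_wt <- NA_real_
      recs[[length(recs) + 1]] <- data.frame(
        cow_id = cows[i], age = age, preg = preg, calf_sex = calf_sex,
        wean_wt = wean_wt, cow_wt = cow_wt, stringsAsFactors = FALSE)
      if (preg == 1) {
        open_streak <- 0L
        age <- age + 1
      } else {
        open_streak <- open_streak + 1L
        if (open_streak >= 2L) break
        age <- age + 0.5
      }
    }
    out[[i]] <- do.call(rbind, recs)
  }
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  structure(list(events = events,
                 truth = list(a = a_coef, d = d_coef, pe = pe_coef,
                              u8_a = u8_a, u8_d = u8_d, ghet = ghet),
                 params = params),
            class = "herd_events")
}

#' @export
print.herd_events <- function(x, ...) {
  cat("Herd event log:", length(unique(x$events$cow_id)), "cows,",
      nrow(x$events), "breeding exposures\n")
  invisible(x)
}
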