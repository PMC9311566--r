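#' Call-rate and minor-allele-frequency filtering
#'
#' Applies, in order: variant call-rate filter, animal call-rate filter,
#' then MAF filter. A variant is kept only when its minor allele frequency
#' is strictly greater than `min_maf` (so MAF exactly at the threshold is
#' removed). Removal counts are attached as the `qc_log` attribute.
#'
#' @param genotypes a [geno_matrix()].
#' @param min_call_rate minimum call rate for variants and animals.
#' @param min_maf variants kept when MAF > this value.
#' @return filtered `geno_matrix` with attribute `qc_log`.
#' @export
qc_filter <- function(genotypes, min_call_rate = 0.95, min_maf = 0.005) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1,
            min_maf >= 0, min_maf < 0.5)
  calls <- genotypes$calls
  map <- genotypes$map

  vcr <- 1 - colMeans(is.na(calls))
  keep_v1 <- vcr >= min_call_rate
  calls <- calls[, keep_v1, drop = FALSE]
  map <- map[keep_v1, , drop = FALSE]

  acr <- 1 - rowMeans(is.na(calls))
  keep_a <- acr >= min_call_rate
  calls <- calls[keep_a, , drop = FALSE]

  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_v2 <- !is.na(maf) & maf > min_maf
  calls <- calls[, keep_v2, drop = FALSE]
  map <- map[keep_v2, , drop = FALSE]

  if (ncol(calls) == 0) stop("all variants removed by QC")
  if (nrow(calls) == 0) stop("all animals removed by QC")
  out <- geno_matrix(calls, map)
  attr(out, "qc_log") <- list(
    variants_call_rate = sum(!keep_v1),
    animals_call_rate = sum(!keep_a),
    variants_maf = sum(!keep_v2))
  out
}

#' Remove close, nearly redundant variants
#'
#' Scans each chromosome left to right; a variant is dropped and mapped to
#' the earlier retained variant when the two are within `window_bp` and the
#' absolute Pearson correlation of their call vectors (over animals
#' non-missing at both) exceeds `r_thresh`. Zero-variance comparisons have
#' undefined r and never prune. Pruning is idempotent.
#'
#' @param genotypes a [geno_matrix()].
#' @param window_bp window in base pairs (distance `<= window_bp` counts
#'   as close).
#' @param r_thresh correlation threshold (strictly greater prunes).
#' @return list with `genotypes` (retained set) and `map` (data.frame
#'   `pruned`, `representative` of dropped variant indices by name).
#' @export
ld_prune <- function(genotypes, window_bp = 50000, r_thresh = 0.98) {
  calls <- genotypes$calls
  map <- genotypes$map
  m <- ncol(calls)
  vname <- variant_names(genotypes)
  keep <- logical(m)
  rep_of <- character(0)
  pruned <- character(0)

  for (ch in unique(map$chrom)) {
    ix <- which(map$chrom == ch)
    retained <- integer(0)
    for (j in ix) {
      close_idx <- retained[map$pos[j] - map$pos[retained] <= window_bp]
      dropped <- FALSE
      for (i in rev(close_idx)) {
        r <- suppressWarnings(stats::cor(calls[, i], calls[, j],
                                         use = "complete.obs"))
        if (!is.na(r) && abs(r) > r_thresh) {
          pruned <- c(pruned, vname[j])
          rep_of <- c(rep_of, vname[i])
          dropped <- TRUE
          break
        }
      }
      if (!dropped) {
        retained <- c(retained, j)
        keep[j] <- TRUE
      }
    }
  }
  out <- geno_matrix(calls[, keep, drop = FALSE], map[keep, , drop = FALSE])
  list(genotypes = out,
       map = data.frame(pruned = pruned, representative = rep_of,
                        stringsAsFactors = FALSE))
}

#' Variant names (chrom_pos) for a genotype matrix
#' @param genotypes a `geno_matrix`.
#' @return character vector.
#' @export
variant_names <- function(genotypes) {
  paste0(genotypes$map$chrom, "_", genotypes$map$pos)
}

impute_mean <- function(calls, p) {
  nmiss <- sum(is.na(calls))
  if (nmiss > 0) {
    idx <- which(is.na(calls), arr.ind = TRUE)
    calls[idx] <- (2 * p)[idx[, 2]]
  }
  list(calls = calls, n_imputed = nmiss)
}

#' Additive genomic relationship matrix
#'
#' VanRaden's first method: with per-variant alternate-allele frequency
#' \eqn{p_j} computed from the analyzed animals, the centered coefficient
#' matrix is \eqn{M_{ij} = m_{ij} - 2p_j} and
#' \deqn{G = M M' / (2 \sum_j p_j (1 - p_j)).}
#' Missing calls are mean-imputed (to \eqn{2p_j}) before centering.
#'
#' @param genotypes a [geno_matrix()].
#' @return list with `G`, `M`, `c_a` (the scaling denominator), `p`, and
#'   `n_imputed`.
#' @export
additive_grm <- function(genotypes) {
  p <- allele_freq(genotypes)
  imp <- impute_mean(genotypes$calls, p)
  M <- sweep(imp$calls, 2, 2 * p, `-`)
  c_a <- 2 * sum(p * (1 - p))
  if (c_a <= 0) stop("all variants monomorphic; additive scaling is zero")
  G <- tcrossprod(M) / c_a
  dimnames(G) <- list(rownames(M), rownames(M))
  list(G = G, M = M, c_a = c_a, p = p, n_imputed = imp$n_imputed)
}

#' Dominance genomic relationship matrix
#'
#' Dominance-deviation coding (Vitezica-style): with alternate-allele
#' frequency \eqn{p_j} and \eqn{q_j = 1 - p_j}, calls 0/1/2 are coded
#' \eqn{-2p_j^2}, \eqn{2p_jq_j}, \eqn{-2q_j^2}, and
#' \deqn{D = H H' / \sum_j (2 p_j q_j)^2.}
#' Under exact Hardy-Weinberg proportions each column of `H` sums to zero.
#' Missing calls are mean-imputed on the allele-count scale first; their
#' dominance code is interpolated between the flanking genotype codes.
#'
#' @inheritParams additive_grm
#' @param coding `"deviation"` (default) for the centered dominance
#'   deviations above, `"indicator"` for centered 0/1 heterozygosity calls.
#' @return list with `D`, `H`, `c_d`, `p`, `n_imputed`.
#' @export
dominance_grm <- function(genotypes, coding = c("deviation", "indicator")) {
  coding <- match.arg(coding)
  p <- allele_freq(genotypes)
  q <- 1 - p
  calls <- genotypes$calls
  n_imputed <- sum(is.na(calls))
  if (coding == "deviation") {
    c0 <- -2 * p^2; c1 <- 2 * p * q; c2 <- -2 * q^2
    H <- matrix(0, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
    for (code in 0:2) {
      cc <- switch(code + 1L, c0, c1, c2)
      idx <- which(calls == code, arr.ind = TRUE)
      H[idx] <- cc[idx[, 2]]
    }
    if (n_imputed > 0) {
      # expected dominance code at the imputed (HWE) genotype distribution
      emiss <- q^2 * c0 + 2 * p * q * c1 + p^2 * c2
      idx <- which(is.na(calls), arr.ind = TRUE)
      H[idx] <- emiss[idx[, 2]]
    }
    c_d <- sum((2 * p * q)^2)
  } else {
    het <- (calls == 1L) * 1
    if (n_imputed > 0) {
      idx <- which(is.na(calls), arr.ind = TRUE)
      het[idx] <- (2 * p * q)[idx[, 2]]
    }
    H <- sweep(het, 2, 2 * p * q, `-`)
    c_d <- sum(2 * p * q * (1 - 2 * p * q))
  }
  if (c_d <= 0) stop("dominance scaling denominator is zero")
  D <- tcrossprod(H) / c_d
  dimnames(D) <- list(rownames(calls), rownames(calls))
  list(D = D, H = H, c_d = c_d, p = p, n_imputed = n_imputed)
}

#' Genomic inbreeding coefficients
#'
#' \eqn{F_{g,i} = G_{ii} - 1}, the diagonal of the additive GRM minus one.
#'
#' @param G additive genomic relationship matrix.
#' @return named numeric vector.
#' @export
genomic_inbreeding <- function(G) {
  diag(G) - 1
}
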