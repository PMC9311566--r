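#' Genotype matrix container
#'
#' Thin S3 wrapper around an animals x variants call matrix (0/1/2/NA)
#' plus variant metadata. Alternate-allele frequencies are computed from
#' non-missing calls on demand by [allele_freq()].
#'
#' @param calls integer matrix, rows = animals (rownames = ids),
#'   columns = variants, entries 0/1/2/NA.
#' @param map data.frame with columns chrom, pos (1-based), class.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)),
            nrow(map) == ncol(calls),
            all(c("chrom", "pos") %in% names(map)))
  if (is.null(map$class)) map$class <- "unknown"
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("calls must be 0/1/2 or NA")
  # positions must be sorted within chromosome
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p)) stop("positions must be sorted within chromosome")
  }
  structure(list(calls = calls, map = map, ids = rownames(calls)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$calls), "animals x", ncol(x$calls),
      "variants;", sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' Alternate-allele frequencies from non-missing calls
#' @param genotypes a `geno_matrix`.
#' @return numeric vector p_j per variant.
#' @export
allele_freq <- function(genotypes) {
  colMeans(genotypes$calls, na.rm = TRUE) / 2
}

#' Per-variant and per-animal call rates
#' @param genotypes a `geno_matrix`.
#' @return list with `variant` and `animal` call-rate vectors.
#' @export
call_rates <- function(genotypes) {
  miss <- is.na(genotypes$calls)
  list(variant = 1 - colMeans(miss), animal = 1 - rowMeans(miss))
}

#' Drop genotypes through a pedigree with recombination
#'
#' Founder haplotypes are drawn per locus from the founder's breed-mixture
#' allele frequencies (a composite founder uses its composition-weighted
#' frequency). Each meiosis recombines the parental haplotypes with a
#' Haldane crossover process (Poisson number of crossovers per chromosome
#' at `map_cm_per_mb` cM per Mb, uniform positions, no interference), so
#' identical-by-descent segments -- and hence runs of homozygosity -- arise
#' naturally in closed lines.
#'
#' @param pedigree a `herd_pedigree` (parents listed before offspring).
#' @param panel a `breed_panel` whose breeds cover the pedigree's
#'   composition columns.
#' @param map_cm_per_mb recombination rate, centimorgans per megabase.
#' @param seed integer seed.
#' @param missing_rate fraction of calls masked to NA (genotyping noise).
#' @return a [geno_matrix()] over all pedigree animals.
#' @export
drop_genotypes <- function(pedigree, panel, map_cm_per_mb = 1, seed = 1,
                           missing_rate = 0) {
  stopifnot(inherits(pedigree, "herd_pedigree"),
            inherits(panel, "breed_panel"), map_cm_per_mb > 0)
  comp <- breed_composition(pedigree)
  if (!all(colnames(comp) %in% rownames(panel$freq))) {
    stop("panel does not cover the pedigree's breeds")
  }
  set.seed(seed)
  m <- nrow(panel$map)
  n <- nrow(pedigree)
  ids <- pedigree$id
  chroms <- unique(panel$map$chrom)
  chr_idx <- lapply(chroms, function(ch) which(panel$map$chrom == ch))
  chr_pos <- lapply(chr_idx, function(ix) panel$map$pos[ix])
  L <- panel$chrom_length
  exp_xo <- L / 1e6 * map_cm_per_mb / 100  # expected crossovers / meiosis

  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  si <- match(pedigree$sire, ids)
  di <- match(pedigree$dam, ids)

  gamete <- function(parent_row) {
    g <- integer(m)
    for (k in seq_along(chroms)) {
      ix <- chr_idx[[k]]
      nxo <- stats::rpois(1, exp_xo)
      xo <- if (nxo > 0) sort(stats::runif(nxo, 0, L)) else numeric(0)
      phase <- (sample.int(2, 1) - 1 + findInterval(chr_pos[[k]], xo)) %% 2
      g[ix] <- ifelse(phase == 0, H1[parent_row, ix], H2[parent_row, ix])
    }
    g
  }

  for (i in seq_len(n)) {
    if (is.na(si[i]) || is.na(di[i])) {
      pmix <- as.numeric(comp[i, , drop = FALSE] %*%
                           panel$freq[colnames(comp), , drop = FALSE])
      H1[i, ] <- stats::rbinom(m, 1L, pmix)
      H2[i, ] <- stats::rbinom(m, 1L, pmix)
    } else {
      H1[i, ] <- gamete(si[i])
      H2[i, ] <- gamete(di[i])
    }
  }
  calls <- H1 + H2
  rownames(calls) <- ids
  if (missing_rate > 0) {
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  }
  geno_matrix(calls, panel$map)
}
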