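#' Simulate a multibreed allele-frequency panel
#'
#' Draws per-breed alternate-allele frequencies around a shared ancestral
#' frequency under the Balding-Nichols model: for ancestral frequency
#' \eqn{p_0} and divergence \eqn{F_{ST}}, breed frequencies are
#' Beta\eqn{(p_0(1-F)/F, (1-p_0)(1-F)/F)}, so the across-breed variance of
#' a variant's frequency is \eqn{F\,p_0(1-p_0)}. `fst = 0` gives identical
#' frequencies in every breed. Variant positions are uniform without
#' duplicates, sorted within chromosome.
#'
#' @param n_breeds number of breeds (>= 1).
#' @param n_variants total number of biallelic variants.
#' @param n_chromosomes number of chromosomes the variants are spread over.
#' @param chrom_length chromosome length in base pairs.
#' @param fst divergence parameter in \[0, 1).
#' @param seed integer seed.
#' @param breed_names optional character vector of breed names.
#' @return an object of class `breed_panel`: list with `breeds`, `freq`
#'   (breeds x variants matrix), `map` (data.frame chrom/pos/class), `fst`,
#'   `chrom_length`.
#' @examples
#' pan <- simulate_breed_panel(2, 50, fst = 0.1, seed = 1)
#' range(pan$freq)
#' @export
simulate_breed_panel <- function(n_breeds, n_variants, n_chromosomes = 5,
                                 chrom_length = 1e8, fst = 0.1, seed = 1,
                                 breed_names = NULL) {
  if (n_breeds < 1 || n_variants < 1 || n_chromosomes < 1) {
    stop("counts must be positive")
  }
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (is.null(breed_names)) {
    breed_names <- paste0("Breed", seq_len(n_breeds))
  }
  stopifnot(length(breed_names) == n_breeds)
  set.seed(seed)

  # spread variants as evenly as possible over chromosomes
  per_chr <- rep(n_variants %/% n_chromosomes, n_chromosomes)
  extra <- n_variants %% n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1
  chrom <- rep(seq_len(n_chromosomes), per_chr)
  pos <- unlist(lapply(per_chr, function(k) {
    sort(sample.int(chrom_length, k, replace = FALSE))
  }))

  p0 <- stats::runif(n_variants, 0.05, 0.95)
  if (fst == 0) {
    freq <- matrix(rep(p0, each = n_breeds), n_breeds, n_variants)
  } else {
    a <- p0 * (1 - fst) / fst
    b <- (1 - p0) * (1 - fst) / fst
    freq <- matrix(stats::rbeta(n_breeds * n_variants,
                                rep(a, each = n_breeds),
                                rep(b, each = n_breeds)),
                   n_breeds, n_variants)
  }
  rownames(freq) <- breed_names
  map <- data.frame(chrom = chrom, pos = pos,
                    class = rep("functional", n_variants),
                    stringsAsFactors = FALSE)
  structure(list(breeds = breed_names, freq = freq, map = map, fst = fst,
                 chrom_length = chrom_length),
            class = "breed_panel")
}

#' @export
print.breed_panel <- function(x, ...) {
  cat("Breed allele-frequency panel:", length(x$breeds), "breeds,",
      nrow(x$map), "variants on", length(unique(x$map$chrom)),
      "chromosomes (Fst =", x$fst, ")\n")
  invisible(x)
}
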