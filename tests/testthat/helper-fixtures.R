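# shared fixture builders for the test suite

# small genotype matrix with explicit calls
make_geno <- function(calls, pos = NULL, chrom = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("a", seq_len(nrow(calls)))
  }
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep(1L, m)
  geno_matrix(calls, data.frame(chrom = chrom, pos = pos,
                                class = "functional"))
}

# full-sib line pedigree: two founders, then n_gen generations of
# full-sib pairs mated to each other
fullsib_pedigree <- function(n_gen) {
  ids <- c("F0_s", "F0_d")
  sire <- c(NA, NA); dam <- c(NA, NA)
  sex <- c("M", "F"); gen <- c(0L, 0L)
  for (g in seq_len(n_gen)) {
    s_prev <- ids[length(ids) - 1]
    d_prev <- ids[length(ids)]
    ids <- c(ids, paste0("G", g, "_s"), paste0("G", g, "_d"))
    sire <- c(sire, s_prev, s_prev)
    dam <- c(dam, d_prev, d_prev)
    sex <- c(sex, "M", "F")
    gen <- c(gen, g, g)
  }
  comp <- matrix(1, length(ids), 1, dimnames = list(ids, "Angus"))
  herd_pedigree(data.frame(id = ids, sire = sire, dam = dam, sex = sex,
                           gen = gen, season = gen, group = "Angus",
                           stringsAsFactors = FALSE), comp)
}

# event data.frame builder: one cow, given (age, preg, sex, wean, cw)
make_events <- function(cow = "c1", age, preg = NULL, sex = NULL,
                        wean = NULL, cw = NULL) {
  n <- length(age)
  data.frame(cow_id = rep(cow, n), age = age,
             preg = if (is.null(preg)) rep(1, n) else preg,
             calf_sex = if (is.null(sex)) rep(NA_character_, n) else sex,
             wean_wt = if (is.null(wean)) rep(0, n) else wean,
             cow_wt = if (is.null(cw)) rep(500, n) else cw,
             stringsAsFactors = FALSE)
}

# dense reference for the restricted log-likelihood (independent of the
# MME-based engine): direct V-based evaluation
dense_restricted_logL <- function(y, X, Z, covs, s2e) {
  N <- length(y); p <- ncol(X)
  V <- diag(s2e, N)
  for (cv in covs) V <- V + Z %*% cv %*% t(Z)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  -0.5 * ((N - p) * log(2 * pi) + determinant(V)$modulus[1] +
          determinant(XVX)$modulus[1] + drop(t(y) %*% P %*% y))
}

# brute-force consecutive-run oracle: for each feasible start compute the
# maximal feasible end by checking every window explicitly, then apply
# the same greedy left-most selection the scanner documents
oracle_runs <- function(calls, pos, state, min_len, min_snp, max_gap,
                        max_opp, max_miss) {
  m <- length(calls)
  good <- if (state == "het") calls == 1L else calls %in% c(0L, 2L)
  good[is.na(calls)] <- FALSE
  miss <- is.na(calls)
  opp <- !good & !miss
  feasible_end <- function(i) {
    if (!good[i]) return(NA_integer_)
    best <- i
    for (j in i:m) {
      win <- i:j
      if (j > i && any(diff(pos[win]) > max_gap)) break
      if (sum(opp[win]) > max_opp) break
      if (sum(miss[win]) > max_miss) break
      if (good[j]) best <- j
    }
    best
  }
  segs <- list()
  i <- 1L
  while (i <= m) {
    j <- feasible_end(i)
    if (is.na(j)) { i <- i + 1L; next }
    span <- pos[j] - pos[i]
    if (span >= min_len && (j - i + 1L) >= min_snp) {
      segs[[length(segs) + 1]] <- c(start = pos[i], end = pos[j],
                                    n = j - i + 1L)
    }
    i <- j + 1L
  }
  if (length(segs)) do.call(rbind, segs) else NULL
}
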