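#' Pedigree-expected retained heterozygosity
#'
#' Fraction of F1 heterozygosity expected in the offspring of parents with
#' base-breed compositions s and d: \eqn{pHet = 1 - \sum_b s_b d_b}.
#' Compositions must already be decomposed to base breeds (composites
#' expanded); Angus and Red Angus are treated as one breed first.
#'
#' @param sire_comp,dam_comp named numeric breed-fraction vectors summing
#'   to 1.
#' @return pHet in \[0, 1\].
#' @export
pedigree_retained_heterozygosity <- function(sire_comp, dam_comp) {
  s <- merge_red_angus(sire_comp)
  d <- merge_red_angus(dam_comp)
  if (abs(sum(s) - 1) > 1e-9 || abs(sum(d) - 1) > 1e-9) {
    stop("compositions must sum to 1")
  }
  breeds <- union(names(s), names(d))
  sv <- stats::setNames(numeric(length(breeds)), breeds)
  dv <- sv
  sv[names(s)] <- s
  dv[names(d)] <- d
  1 - sum(sv * dv)
}

merge_red_angus <- function(comp) {
  nm <- names(comp)
  if (is.null(nm)) stop("composition must be named by breed")
  ra <- nm %in% c("Red Angus", "RedAngus", "Red_Angus")
  if (any(ra)) {
    ang <- sum(comp[nm == "Angus"]) + sum(comp[ra])
    comp <- comp[!ra & nm != "Angus"]
    comp <- c(comp, Angus = unname(ang))
  }
  comp[comp > 0]
}

#' Per-animal retained heterozygosity from a pedigree
#'
#' Applies [pedigree_retained_heterozygosity()] to each animal's sire and
#' dam compositions; animals with an unknown parent get NA.
#'
#' @param pedigree a `herd_pedigree`.
#' @return named numeric vector.
#' @export
retained_heterozygosity <- function(pedigree) {
  comp <- breed_composition(pedigree)
  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  out <- rep(NA_real_, nrow(pedigree))
  for (i in seq_len(nrow(pedigree))) {
    if (!is.na(si[i]) && !is.na(di[i])) {
      out[i] <- pedigree_retained_heterozygosity(comp[si[i], ], comp[di[i], ])
    }
  }
  stats::setNames(out, pedigree$id)
}

#' Genomic heterozygosity
#'
#' Fraction of each animal's non-missing genotype calls that are
#' heterozygous.
#'
#' @param genotypes a [geno_matrix()].
#' @return named numeric vector gHet in \[0, 1\].
#' @export
genomic_heterozygosity <- function(genotypes) {
  nm <- rowSums(!is.na(genotypes$calls))
  if (any(nm == 0)) stop("animal with zero non-missing calls")
  stats::setNames(rowSums(genotypes$calls == 1L, na.rm = TRUE) / nm,
                  rownames(genotypes$calls))
}

# generic consecutive-method run scan; state = "hom" or "het"
run_scan <- function(genotypes, state, min_length_bp, min_snp, max_gap_bp,
                     max_opp, max_miss) {
  calls <- genotypes$calls
  map <- genotypes$map
  n <- nrow(calls)
  segs <- vector("list", n)
  for (a in seq_len(n)) {
    seg_rows <- list()
    for (ch in unique(map$chrom)) {
      ix <- which(map$chrom == ch)
      pos <- map$pos[ix]
      g <- calls[a, ix]
      st <- ifelse(is.na(g), "miss",
                   ifelse(g == 1L, if (state == "het") "good" else "opp",
                          if (state == "het") "opp" else "good"))
      i <- 1L
      m <- length(ix)
      while (i <= m) {
        if (st[i] != "good") { i <- i + 1L; next }
        # greedy extension from i with interruption budgets
        j <- i
        opp_used <- 0L; miss_used <- 0L
        last_good <- i
        k <- i + 1L
        while (k <= m) {
          if (pos[k] - pos[k - 1L] > max_gap_bp) break
          if (st[k] == "good") {
            last_good <- k
          } else if (st[k] == "opp") {
            if (opp_used + 1L > max_opp) break
            opp_used <- opp_used + 1L
          } else {
            if (miss_used + 1L > max_miss) break
            miss_used <- miss_used + 1L
          }
          k <- k + 1L
        }
        j <- last_good
        span <- pos[j] - pos[i]
        nv <- j - i + 1L
        if (span >= min_length_bp && nv >= min_snp) {
          seg_rows[[length(seg_rows) + 1]] <- data.frame(
            id = rownames(calls)[a], chrom = ch,
            start = pos[i], end = pos[j], n_variants = nv,
            stringsAsFactors = FALSE)
        }
        i <- j + 1L
      }
    }
    segs[[a]] <- if (length(seg_rows)) do.call(rbind, seg_rows) else NULL
  }
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(id = character(0), chrom = integer(0),
                      start = integer(0), end = integer(0),
                      n_variants = integer(0), stringsAsFactors = FALSE)
  }
  total <- stats::setNames(rep(0, n), rownames(calls))
  if (nrow(out)) {
    tt <- tapply(out$end - out$start, out$id, sum)
    total[names(tt)] <- tt
  }
  list(segments = out, total_bases = total)
}

#' Runs of homozygosity (consecutive method)
#'
#' Scans each animal's sorted variants chromosome by chromosome. A run
#' grows greedily from the left-most homozygous call while inter-variant
#' gaps stay within `max_gap_bp`, at most `max_het` heterozygous and
#' `max_miss` missing calls interrupt it, and is trimmed to end on a
#' homozygous call; it is reported when its span (end - start position)
#' reaches `min_length_bp` and it covers at least `min_snp` variants.
#'
#' @param genotypes a [geno_matrix()].
#' @param min_length_bp minimum span (default 1 Mb).
#' @param min_snp minimum variants in a run.
#' @param max_gap_bp maximum gap between consecutive variants in a run.
#' @param max_het allowed heterozygous interruptions.
#' @param max_miss allowed missing interruptions.
#' @return list with `segments` (id, chrom, start, end, n_variants) and
#'   `total_bases` per animal.
#' @export
detect_roh <- function(genotypes, min_length_bp = 1e6, min_snp = 15,
                       max_gap_bp = 1e6, max_het = 0, max_miss = 1) {
  run_scan(genotypes, "hom", min_length_bp, min_snp, max_gap_bp,
           max_het, max_miss)
}

#' Heterozygosity-rich regions (consecutive method)
#'
#' Same scan as [detect_roh()] with heterozygous calls as the run state
#' and homozygous calls as interruptions; default minimum length 100 kb.
#'
#' @inheritParams detect_roh
#' @param max_hom allowed homozygous interruptions.
#' @export
detect_hrr <- function(genotypes, min_length_bp = 1e5, min_snp = 3,
                       max_gap_bp = 1e6, max_hom = 0, max_miss = 1) {
  run_scan(genotypes, "het", min_length_bp, min_snp, max_gap_bp,
           max_hom, max_miss)
}

#' Heterosis profile of a herd
#'
#' Per-animal pedigree retained heterozygosity, genomic heterozygosity,
#' genomic inbreeding, and total bases in heterozygosity-rich regions and
#' runs of homozygosity.
#'
#' @param genotypes a [geno_matrix()] (post-QC).
#' @param G additive GRM over the same animals.
#' @param pedigree a `herd_pedigree` covering the animals.
#' @param roh_args,hrr_args named lists overriding scan defaults.
#' @return data.frame with columns id, phet, ghet, fg, hrr_bases,
#'   roh_bases; segments attached as attributes `roh` and `hrr`.
#' @export
heterosis_profile <- function(genotypes, G, pedigree,
                              roh_args = list(), hrr_args = list()) {
  ids <- rownames(genotypes$calls)
  phet <- retained_heterozygosity(pedigree)[ids]
  ghet <- genomic_heterozygosity(genotypes)
  fg <- genomic_inbreeding(G)[ids]
  roh <- do.call(detect_roh, c(list(genotypes), roh_args))
  hrr <- do.call(detect_hrr, c(list(genotypes), hrr_args))
  out <- data.frame(id = ids, phet = unname(phet), ghet = unname(ghet),
                    fg = unname(fg),
                    hrr_bases = unname(hrr$total_bases[ids]),
                    roh_bases = unname(roh$total_bases[ids]),
                    stringsAsFactors = FALSE)
  attr(out, "roh") <- roh$segments
  attr(out, "hrr") <- hrr$segments
  out
}

#' Group cows by projected merit
#'
#' Splits phenotyped cows into halves above and below the mean total merit
#' (additive + dominance projections) for each trait, and into quadrants
#' by both traits: low CW/low WtW (LL), low CW/high WtW (LH), high CW/high
#' WtW (HH), high CW/low WtW (HL). Ties at a mean go to the Low half.
#'
#' @param proj_cw,proj_wtw projection data.frames from
#'   [project_to_age()] restricted to the same cow set.
#' @return data.frame with id, cw_half, wtw_half, quadrant.
#' @export
group_cows <- function(proj_cw, proj_wtw) {
  ids <- intersect(proj_cw$id, proj_wtw$id)
  if (length(ids) == 0) stop("empty cow set")
  cw <- proj_cw$total[match(ids, proj_cw$id)]
  ww <- proj_wtw$total[match(ids, proj_wtw$id)]
  cw_half <- ifelse(cw > mean(cw), "High", "Low")
  wtw_half <- ifelse(ww > mean(ww), "High", "Low")
  quad <- paste0(ifelse(cw_half == "Low", "L", "H"),
                 ifelse(wtw_half == "Low", "L", "H"))
  data.frame(id = ids, cw_half = cw_half, wtw_half = wtw_half,
             quadrant = quad, stringsAsFactors = FALSE)
}

#' Variance in projected effects explained by heterosis metrics
#'
#' Regresses each projected effect column on each heterosis metric with a
#' simple least-squares line and reports R-squared x 100 per
#' (effect, metric) pair. Zero-variance metrics give NA.
#'
#' @param effects data.frame of per-cow effect columns (e.g. dominance and
#'   total projections for each trait), plus an `id` column.
#' @param metrics data.frame from [heterosis_profile()] (id + metric
#'   columns).
#' @return data.frame: rows = effect columns, columns = metrics, entries
#'   R^2 x 100.
#' @export
regress_metrics <- function(effects, metrics) {
  stopifnot("id" %in% names(effects), "id" %in% names(metrics))
  ids <- intersect(effects$id, metrics$id)
  if (length(ids) < 3) stop("need at least 3 cows")
  ef <- effects[match(ids, effects$id), setdiff(names(effects), "id"),
                drop = FALSE]
  mt <- metrics[match(ids, metrics$id), setdiff(names(metrics), "id"),
                drop = FALSE]
  out <- matrix(NA_real_, ncol(ef), ncol(mt),
                dimnames = list(names(ef), names(mt)))
  for (i in seq_len(ncol(ef))) for (j in seq_len(ncol(mt))) {
    x <- mt[[j]]
    if (stats::var(x) > 0) {
      out[i, j] <- 100 * summary(stats::lm(ef[[i]] ~ x))$r.squared
    }
  }
  as.data.frame(out)
}

#' Group means and standard errors of heterosis metrics
#'
#' For each group (All, Low/High by trait, and the four quadrants):
#' group size, mean and SE (SD / sqrt(n)) of each metric. Single-cow
#' groups report NA SE.
#'
#' @param metrics data.frame from [heterosis_profile()].
#' @param groups data.frame from [group_cows()].
#' @return long-format data.frame: group, n, then mean_/se_ per metric.
#' @export
summarize_groups <- function(metrics, groups) {
  ids <- intersect(metrics$id, groups$id)
  mt <- metrics[match(ids, metrics$id), , drop = FALSE]
  gr <- groups[match(ids, groups$id), , drop = FALSE]
  sel <- list(
    All = rep(TRUE, length(ids)),
    `Low CW` = gr$cw_half == "Low", `High CW` = gr$cw_half == "High",
    `Low WtW` = gr$wtw_half == "Low", `High WtW` = gr$wtw_half == "High",
    LL = gr$quadrant == "LL", LH = gr$quadrant == "LH",
    HH = gr$quadrant == "HH", HL = gr$quadrant == "HL")
  cols <- setdiff(names(mt), "id")
  rows <- lapply(names(sel), function(g) {
    k <- sel[[g]]
    n <- sum(k)
    row <- data.frame(group = g, n = n, stringsAsFactors = FALSE)
    for (cn in cols) {
      v <- mt[[cn]][k]
      row[[paste0("mean_", cn)]] <- if (n > 0) mean(v, na.rm = TRUE) else NA
      row[[paste0("se_", cn)]] <- if (n > 1) {
        stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
      } else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export run segments as BED
#'
#' Converts 1-based inclusive segment coordinates to BED's 0-based
#' half-open convention and writes a tab-separated file.
#'
#' @param segments segment data.frame (id, chrom, start, end, n_variants).
#' @param path output file.
#' @export
write_segments_bed <- function(segments, path) {
  if (nrow(segments) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start - 1L,
                    end = segments$end,
                    name = paste0(segments$id, ":", segments$n_variants))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
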