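test_that("retained heterozygosity matches the worked breed examples", {
  expect_equal(pedigree_retained_heterozygosity(c(Angus = 1),
                                                c(Hereford = 1)), 1)
  expect_equal(pedigree_retained_heterozygosity(c(Angus = 1),
                                                c(Angus = 1)), 0)
  brangus <- c(Brahman = 0.375, Angus = 0.625)
  expect_equal(pedigree_retained_heterozygosity(brangus, brangus),
               0.46875)
  # symmetry
  mixed <- c(Angus = 0.25, Hereford = 0.75)
  expect_equal(pedigree_retained_heterozygosity(mixed, brangus),
               pedigree_retained_heterozygosity(brangus, mixed))
  # Angus and Red Angus are one breed for this computation
  expect_equal(pedigree_retained_heterozygosity(c(Angus = 1),
                                                c(`Red Angus` = 1)), 0)
  expect_error(pedigree_retained_heterozygosity(c(Angus = 0.5),
                                                c(Angus = 1)), "sum to 1")
})

test_that("per-animal retained heterozygosity uses parent compositions", {
  df <- data.frame(id = c("s", "d", "k"), sire = c(NA, NA, "s"),
                   dam = c(NA, NA, "d"), sex = c("M", "F", "F"),
                   gen = c(0L, 0L, 1L), season = 0L, group = "x",
                   stringsAsFactors = FALSE)
  comp <- rbind(s = c(1, 0), d = c(0, 1), k = c(0.5, 0.5))
  colnames(comp) <- c("Angus", "Hereford")
  ped <- herd_pedigree(df, comp)
  ph <- retained_heterozygosity(ped)
  expect_true(is.na(ph["s"]))
  expect_equal(unname(ph["k"]), 1)
})

test_that("genomic heterozygosity counts heterozygous call fractions", {
  g <- make_geno(rbind(c(0L, 1L, 1L, 2L)))
  expect_equal(unname(genomic_heterozygosity(g)), 0.5)
  g2 <- make_geno(rbind(c(0L, 2L, 0L)))
  expect_equal(unname(genomic_heterozygosity(g2)), 0)
  g3 <- make_geno(rbind(c(1L, NA, 1L)))
  expect_equal(unname(genomic_heterozygosity(g3)), 1)
  # no missing calls: heterozygous + homozygous fractions sum to one
  set.seed(2)
  calls <- matrix(rbinom(40, 2, 0.5), 4, 10)
  g4 <- make_geno(calls)
  gh <- genomic_heterozygosity(g4)
  expect_equal(gh + rowMeans(calls != 1L), rep(1, 4), ignore_attr = TRUE)
})

test_that("runs of homozygosity respect span and count minima", {
  pos <- as.integer(seq(1e6, by = 1e5, length.out = 20))
  g <- make_geno(matrix(2L, 1, 20), pos = pos)
  res <- detect_roh(g)
  expect_equal(nrow(res$segments), 1)
  expect_equal(res$segments$start, 1e6)
  expect_equal(res$segments$end, 2.9e6)
  expect_equal(res$segments$n_variants, 20)
  expect_equal(unname(res$total_bases), 1.9e6)

  het <- make_geno(matrix(1L, 1, 20), pos = pos)
  expect_equal(unname(detect_roh(het)$total_bases), 0)

  # 0.8 Mb homozygous span falls below the 1 Mb minimum
  pos2 <- as.integer(seq(1e6, by = 4e4, length.out = 21))  # span 0.8 Mb
  g2 <- make_geno(matrix(0L, 1, 21), pos = pos2)
  expect_equal(nrow(detect_roh(g2)$segments), 0)
})

test_that("heterozygosity-rich regions respect their minima", {
  pos <- as.integer(seq(5e5, by = 3.75e4, length.out = 5))  # span 150 kb
  g <- make_geno(matrix(1L, 1, 5), pos = pos)
  res <- detect_hrr(g)
  expect_equal(nrow(res$segments), 1)
  expect_equal(res$segments$end - res$segments$start, 1.5e5)

  hom <- make_geno(matrix(2L, 1, 5), pos = pos)
  expect_equal(nrow(detect_hrr(hom)$segments), 0)

  pos2 <- as.integer(seq(5e5, by = 2.25e4, length.out = 5))  # span 90 kb
  g2 <- make_geno(matrix(1L, 1, 5), pos = pos2)
  expect_equal(nrow(detect_hrr(g2)$segments), 0)
})

test_that("consecutive scans match the exhaustive window oracle", {
  set.seed(77)
  for (rep in 1:25) {
    m <- sample(20:50, 1)
    pos <- sort(sample.int(5e6, m))
    calls <- matrix(sample(c(0L, 1L, 2L, NA), m, replace = TRUE,
                           prob = c(0.4, 0.25, 0.3, 0.05)), 1, m)
    g <- make_geno(calls, pos = pos)
    args <- list(min_length_bp = 5e5, min_snp = 4, max_gap_bp = 8e5)
    roh <- do.call(detect_roh, c(list(g), args, max_het = 1, max_miss = 1))
    ora <- oracle_runs(calls[1, ], pos, "hom", 5e5, 4, 8e5, 1, 1)
    if (is.null(ora)) {
      expect_equal(nrow(roh$segments), 0)
    } else {
      expect_equal(nrow(roh$segments), nrow(ora))
      expect_equal(roh$segments$start, unname(ora[, "start"]))
      expect_equal(roh$segments$end, unname(ora[, "end"]))
      expect_equal(roh$segments$n_variants, unname(ora[, "n"]))
    }
    hrr <- do.call(detect_hrr, c(list(g), args, max_hom = 1, max_miss = 1))
    orh <- oracle_runs(calls[1, ], pos, "het", 5e5, 4, 8e5, 1, 1)
    expect_equal(nrow(hrr$segments), if (is.null(orh)) 0 else nrow(orh))
    if (!is.null(orh)) {
      expect_equal(hrr$segments$start, unname(orh[, "start"]))
      expect_equal(hrr$segments$end, unname(orh[, "end"]))
    }
    # segments never overlap within an animal
    seg <- roh$segments
    if (nrow(seg) > 1) {
      expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))
    }
  }
})

test_that("merit groups split at means with ties going low", {
  pcw <- data.frame(id = c("a", "b", "c", "d"),
                    total = c(10, -10, 10, -10))
  pww <- data.frame(id = c("a", "b", "c", "d"),
                    total = c(5, 5, -5, -5))
  gr <- group_cows(pcw, pww)
  expect_equal(gr$quadrant, c("HH", "LH", "HL", "LL"))

  same <- data.frame(id = c("a", "b"), total = c(1, 1))
  gr2 <- group_cows(same, same)
  expect_equal(gr2$cw_half, c("Low", "Low"))  # ties at the mean go low

  sym <- data.frame(id = c("a", "b"), total = c(-1, 1))
  gr3 <- group_cows(sym, sym)
  expect_equal(gr3$cw_half, c("Low", "High"))
  expect_error(group_cows(data.frame(id = character(0), total = numeric(0)),
                          pww), "empty")
})

test_that("regression R-squared behaves like a coefficient of
           determination", {
  set.seed(10)
  eff <- data.frame(id = paste0("c", 1:50), val = rnorm(50))
  mt <- data.frame(id = eff$id, same = eff$val,
                   noise = rnorm(50), flat = rep(1, 50))
  r2 <- regress_metrics(eff, mt)
  expect_equal(r2["val", "same"], 100, tolerance = 1e-8)
  expect_lt(r2["val", "noise"], 15)
  expect_true(is.na(r2["val", "flat"]))
  # affine rescaling of the metric leaves R^2 unchanged
  mt2 <- mt; mt2$noise <- 3 * mt$noise - 7
  r2b <- regress_metrics(eff, mt2)
  expect_equal(r2b["val", "noise"], r2["val", "noise"])
  expect_error(regress_metrics(eff[1:2, ], mt[1:2, ]), "at least 3")
})

test_that("group summaries report means, SEs and the partition identity", {
  mt <- data.frame(id = paste0("c", 1:6), phet = c(1, 2, 3, 4, 5, 6))
  gr <- data.frame(id = mt$id,
                   cw_half = c("Low", "Low", "Low", "High", "High", "High"),
                   wtw_half = c("Low", "High", "Low", "High", "Low", "High"),
                   quadrant = c("LL", "LH", "LL", "HH", "HL", "HH"))
  sm <- summarize_groups(mt, gr)
  all_row <- sm[sm$group == "All", ]
  lo <- sm[sm$group == "Low CW", ]; hi <- sm[sm$group == "High CW", ]
  expect_equal(all_row$mean_phet,
               (lo$mean_phet * lo$n + hi$mean_phet * hi$n) / all_row$n)
  expect_equal(lo$se_phet, sd(c(1, 2, 3)) / sqrt(3))
  # single-cow group reports NA SE
  gr1 <- gr; gr1$quadrant[5] <- "HL"
  sm1 <- summarize_groups(mt, gr1)
  expect_true(is.na(sm1$se_phet[sm1$group == "HL"]))
})

test_that("segments export as zero-based half-open BED", {
  seg <- data.frame(id = "a", chrom = 1L, start = 1000L, end = 5000L,
                    n_variants = 7L)
  path <- tempfile(fileext = ".bed")
  write_segments_bed(seg, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 999)
  expect_equal(bed$V3, 5000)
})
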