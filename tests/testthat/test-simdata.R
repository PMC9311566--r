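test_that("zero divergence gives identical breed frequencies", {
  pan <- simulate_breed_panel(2, 100, fst = 0, seed = 1)
  expect_equal(pan$freq[1, ], pan$freq[2, ])
  expect_true(all(pan$freq >= 0 & pan$freq <= 1))
})

test_that("across-breed frequency variance follows the divergence model", {
  pan <- simulate_breed_panel(10, 5000, fst = 0.1, seed = 7)
  p0 <- colMeans(pan$freq)
  v <- apply(pan$freq, 2, stats::var)
  keep <- p0 > 0.1 & p0 < 0.9
  ratio <- mean(v[keep]) / mean((p0 * (1 - p0))[keep])
  expect_lt(abs(ratio - 0.1), 0.02)
})

test_that("panel positions are strictly increasing within chromosome", {
  pan <- simulate_breed_panel(1, 10, n_chromosomes = 1, seed = 3)
  expect_true(all(diff(pan$map$pos) > 0))
  expect_true(all(pan$freq >= 0 & pan$freq <= 1))
  expect_error(simulate_breed_panel(0, 10), "positive")
  expect_error(simulate_breed_panel(2, 10, fst = 1), "fst")
})

test_that("offspring breed composition is the parental average", {
  expect_error(cross_plan(c("A"), composites = list(), matings =
    data.frame(gen = 1, group = "x", sire_group = "B", dam_group = "A",
               n = 1)), "unknown group")
  # Brahman is referenced by the composite but is not a founder breed
  expect_error(
    cross_plan(c("Angus"),
               composites = list(Brangus = c(Brahman = 0.375, Angus = 0.625)),
               matings = data.frame(gen = 1, group = "B", sire_group = "Brangus",
                                    dam_group = "Angus", n = 1)),
    "unknown breeds")

  plan2 <- cross_plan(
    c("Angus", "Hereford", "Charolais", "Brahman"),
    composites = list(Brangus = c(Brahman = 0.375, Angus = 0.625)),
    matings = data.frame(
      gen = c(1, 2),
      group = c("AxH", "F1xC"),
      sire_group = c("Angus", "AxH"),
      dam_group = c("Hereford", "Charolais"),
      n = c(10, 10)))
  ped <- simulate_pedigree(plan2, n_founders_per_breed = 6,
                           n_generations = 2, seed = 1)
  comp <- breed_composition(ped)
  expect_true(all(abs(rowSums(comp) - 1) < 1e-9))

  f1 <- comp[ped$group == "AxH", , drop = FALSE]
  expect_true(all(f1[, "Angus"] == 0.5 & f1[, "Hereford"] == 0.5))

  # declared composite founders carry the decomposed composition
  br <- comp[ped$group == "Brangus", , drop = FALSE]
  expect_true(all(br[, "Brahman"] == 0.375 & br[, "Angus"] == 0.625))

  # F1 x purebred third breed -> 1/4, 1/4, 1/2
  bc <- comp[ped$group == "F1xC", , drop = FALSE]
  expect_true(all(bc[, "Angus"] == 0.25 & bc[, "Hereford"] == 0.25 &
                    bc[, "Charolais"] == 0.5))

  # parental average holds for every non-founder
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  nf <- which(!is.na(si))
  expect_equal(unname(comp[nf, ]),
               unname((comp[si[nf], ] + comp[di[nf], ]) / 2))
})

test_that("gene dropping respects fixed and opposite-fixed founders", {
  pan <- simulate_breed_panel(2, 50, n_chromosomes = 2, fst = 0.2, seed = 5)
  pan$freq[1, ] <- 1   # breed 1 fixed for the alternate allele
  pan$freq[2, ] <- 0   # breed 2 fixed for the reference allele
  df <- data.frame(id = c("s", "d", "kid"), sire = c(NA, NA, "s"),
                   dam = c(NA, NA, "d"), sex = c("M", "F", "F"),
                   gen = c(0L, 0L, 1L), season = c(0L, 0L, 1L),
                   group = c("B1", "B2", "F1"), stringsAsFactors = FALSE)
  comp <- rbind(s = c(1, 0), d = c(0, 1), kid = c(0.5, 0.5))
  colnames(comp) <- pan$breeds
  ped <- herd_pedigree(df, comp)
  g <- drop_genotypes(ped, pan, seed = 2)
  expect_true(all(g$calls["s", ] == 2L))
  expect_true(all(g$calls["d", ] == 0L))
  expect_true(all(g$calls["kid", ] == 1L))
})

test_that("full-sib lines accumulate homozygosity tracking pedigree F", {
  pan <- simulate_breed_panel(1, 600, n_chromosomes = 3,
                              chrom_length = 1e8, fst = 0, seed = 9,
                              breed_names = "Angus")
  ped <- fullsib_pedigree(5)
  Fped <- pedigree_inbreeding(ped)
  expect_equal(unname(Fped["G1_s"]), 0)
  expect_equal(unname(Fped["G2_s"]), 0.25)
  # mean over replicate gene drops: heterozygosity loss tracks F
  hets <- sapply(1:12, function(s) {
    g <- drop_genotypes(ped, pan, map_cm_per_mb = 1, seed = s)
    rowMeans(g$calls == 1L)
  })
  h <- rowMeans(hets)
  exp_het <- mean(2 * pan$freq[1, ] * (1 - pan$freq[1, ]))
  gens <- paste0("G", 1:5, "_s")
  # observed heterozygosity declines with generation as (1 - F) E[2pq]
  expect_true(all(diff(h[gens]) < 0.02))
  expect_lt(max(abs(h[gens] - (1 - Fped[gens]) * exp_het)), 0.06)
})

test_that("event simulation enforces the two-strike culling rule", {
  pan <- simulate_breed_panel(1, 40, fst = 0, seed = 1,
                              breed_names = "Angus")
  ped <- fullsib_pedigree(2)
  g <- drop_genotypes(ped, pan, seed = 3)
  km <- ratio_kmatrices(0.3, 0.1, sigma2_e = 400)
  pars <- true_params(K_a = km$K_a, K_d = km$K_d, sigma2_e = 400,
                      conception_base = 0.4)  # many failures
  cows <- ped$id[ped$sex == "F"]
  ev <- simulate_events(ped, g, pars, mode = "coefficient", seed = 5,
                        cows = cows)
  for (cid in unique(ev$events$cow_id)) {
    d <- ev$events[ev$events$cow_id == cid, ]
    streak <- 0
    for (i in seq_len(nrow(d))) {
      expect_lt(streak, 2)  # no exposure after two consecutive open tests
      streak <- if (d$preg[i] == 0) streak + 1 else 0
    }
    # ages advance by 1 after conception, 0.5 after a first open test
    if (nrow(d) > 1) {
      inc <- diff(d$age)
      expect_true(all(inc %in% c(0.5, 1)))
      expect_equal(inc == 0.5, d$preg[-nrow(d)] == 0)
    }
  }
})

test_that("null dominance parameters give zero dominance values", {
  pan <- simulate_breed_panel(1, 40, fst = 0, seed = 1,
                              breed_names = "Angus")
  ped <- fullsib_pedigree(2)
  g <- drop_genotypes(ped, pan, seed = 3)
  pars <- true_params(K_a = diag(100, 2), K_d = matrix(0, 2, 2),
                      sigma2_e = 400)
  ev <- simulate_events(ped, g, pars, mode = "coefficient", seed = 5,
                        cows = ped$id[ped$sex == "F"])
  expect_true(all(ev$truth$d == 0))
  expect_true(all(ev$truth$u8_d == 0))
})

test_that("coefficient sampling reproduces the target covariance scale", {
  set.seed(31)
  q <- 400
  calls <- matrix(rbinom(q * 500, 2, runif(q * 500, 0.2, 0.8)), q, 500)
  rownames(calls) <- paste0("c", 1:q)
  gm <- make_geno(calls)
  G <- additive_grm(gm)$G
  km <- ratio_kmatrices(0.4, 0, sigma2_e = 600)
  # empirical variance of age-8 additive values over animals matches
  # phi8' K_a phi8 scaled by the mean diagonal of G
  phi8 <- drop(legendre_basis(1, 1))
  target <- drop(t(phi8) %*% km$K_a %*% phi8) * mean(diag(G))
  reps <- sapply(1:8, function(s) {
    chG <- crossherd:::chol_ridge(G)$chol
    set.seed(s)
    a <- crossherd:::sample_kron_coefs(km$K_a, chG, q)
    stats::var(as.numeric(a %*% phi8))
  })
  expect_lt(abs(mean(reps) / target - 1), 0.15)
})
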