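test_that("normalized Legendre basis takes its textbook values", {
  phi <- legendre_basis(c(-1, 0, 1), order = 1)
  expect_equal(phi[, 1], rep(sqrt(1 / 2), 3))
  expect_equal(phi[, 2], sqrt(3 / 2) * c(-1, 0, 1))
  phi2 <- legendre_basis(0.5, order = 2)
  expect_equal(phi2[1, 3], sqrt(5 / 2) * 0.5 * (3 * 0.25 - 1))
  expect_error(legendre_basis(1.5, 1), "\\[-1, 1\\]")
  expect_equal(standardize_age(c(2, 5, 8)), c(-1, 0, 1))
  expect_error(standardize_age(9), "bounds")
})

test_that("design matrices place basis values in cow coefficient columns", {
  recs <- data.frame(cow_id = c("c1", "c1"), value_kg = c(400, 500),
                     age_yr = c(2, 8))
  ids <- c("c1", "c2")
  des <- build_design(recs, ids, order = 1)
  Z <- as.matrix(des$Z)
  phi <- legendre_basis(c(-1, 1), 1)
  expect_equal(Z[1, c(1, 3)], unname(phi[1, ]))
  expect_equal(Z[2, c(1, 3)], unname(phi[2, ]))
  expect_equal(Z[, c(2, 4)], matrix(0, 2, 2))  # c2 has no records

  # order 0 collapses to scaled cow incidence
  des0 <- build_design(recs, ids, order = 0)
  expect_equal(as.matrix(des0$Z),
               cbind(rep(sqrt(0.5), 2), 0), ignore_attr = TRUE)

  expect_error(build_design(data.frame(cow_id = "zz", value_kg = 1,
                                       age_yr = 3), ids), "missing")
})

test_that("restricted likelihood matches a dense reference evaluation", {
  set.seed(2)
  q <- 15
  calls <- matrix(rbinom(q * 80, 2, 0.5), q, 80)
  rownames(calls) <- paste0("c", seq_len(q))
  g <- make_geno(calls)
  G <- additive_grm(g)$G + diag(1e-3, q)
  D <- dominance_grm(g)$D + diag(1e-3, q)
  rownames(G) <- colnames(G) <- rownames(D) <- colnames(D) <-
    rownames(calls)
  recs <- do.call(rbind, lapply(seq_len(q), function(i) {
    data.frame(cow_id = rownames(calls)[i], value_kg = rnorm(4, 500, 30),
               age_yr = c(2, 4, 6, 8))
  }))
  Ka <- matrix(c(120, 15, 15, 50), 2)
  Kd <- matrix(c(40, 5, 5, 25), 2)
  s2e <- 500
  fit <- rr_greml(recs, G, D, max_iter = 1,
                  start = list(K = list(Ka, Kd), sigma2_e = s2e))
  des <- build_design(recs, rownames(G), order = 1)
  ref <- dense_restricted_logL(des$y, des$X, as.matrix(des$Z),
                               list(kronecker(Ka, G), kronecker(Kd, D)),
                               s2e)
  expect_equal(fit$logLik_trace[1], ref, tolerance = 1e-8)
})

test_that("restricted logL is monotone and components recover signal", {
  set.seed(8)
  h <- simulate_herd_study(21, n_cows = 220, n_variants = 400,
                           ratio_a = 0.45, ratio_d = 0.05,
                           n_founders = 12)
  fit <- rr_greml(h$records, h$G, h$D, trait = "CW", tol = 1e-4,
                  max_iter = 25)
  expect_true(all(diff(fit$logLik_trace) > -1e-7))
  h8 <- heritability_curve(fit, 8)
  # loose single-run check; the tight multi-seed recovery bound lives in
  # the acceptance suite
  expect_gt(h8$h2_a, 0.2)
  expect_lt(h8$h2_d, 0.35)
  # BLUPs correlate positively with the simulated truth
  pr <- project_to_age(fit, 8)
  tr <- h$events$truth
  cc <- cor(pr$u_a[match(names(tr$u8_a), pr$id)], tr$u8_a)
  expect_gt(cc, 0.3)
  # additive BLUP intercepts sum to ~0 under a centered GRM
  expect_lt(abs(sum(blup_effects(fit)$a[, 1])),
            0.01 * sum(abs(blup_effects(fit)$a[, 1])) + 1e-6)
})

test_that("constant records at fixed variance components give zero BLUPs", {
  q <- 12
  set.seed(3)
  calls <- matrix(rbinom(q * 50, 2, 0.5), q, 50)
  rownames(calls) <- paste0("c", seq_len(q))
  g <- make_geno(calls)
  G <- additive_grm(g)$G + diag(1e-3, q)
  recs <- do.call(rbind, lapply(seq_len(q), function(i) {
    data.frame(cow_id = rownames(calls)[i], value_kg = 500,
               age_yr = c(2, 5, 8))
  }))
  fit <- rr_greml(recs, G, max_iter = 1,
                  start = list(K = list(diag(50, 2)), sigma2_e = 100))
  expect_lt(max(abs(blup_effects(fit)$a)), 1e-8)
  expect_lt(max(abs(project_to_age(fit, 8)$total)), 1e-8)
})

test_that("BLUP accuracy grows with herd size", {
  cors <- sapply(c(120, 420), function(n) {
    h <- simulate_herd_study(33, n_cows = n, n_variants = 300,
                             ratio_a = 0.5, ratio_d = 0, n_founders = 12)
    fit <- rr_greml(h$records, h$G, trait = "CW", tol = 1e-3,
                    max_iter = 15)
    pr <- project_to_age(fit, 8)
    tr <- h$events$truth$u8_a
    cor(pr$u_a[match(names(tr), pr$id)], tr)
  })
  expect_gt(cors[1], 0)
  expect_gt(cors[2], cors[1])
})

test_that("projection evaluates the basis at the requested age", {
  U <- list(a = rbind(c(1, 2), c(0, 0)), d = rbind(c(0.5, 0), c(0, 0)))
  rownames(U$a) <- rownames(U$d) <- c("c1", "c2")
  fit <- structure(list(u = U, ids = c("c1", "c2"), order = 1,
                        age_range = c(2, 8)), class = "rrgreml")
  pr <- project_to_age(fit, 8)
  phi <- drop(legendre_basis(1, 1))
  expect_equal(pr$u_a[1], sum(phi * c(1, 2)))
  expect_equal(pr$u_d[1], 0.5 * phi[1])
  expect_equal(pr$total, pr$u_a + pr$u_d)
  expect_equal(pr$u_a[2], 0)
  # order-0 projection is age-constant
  fit0 <- structure(list(u = list(a = matrix(2, 1, 1,
                                             dimnames = list("c1", NULL))),
                         ids = "c1", order = 0, age_range = c(2, 8)),
                    class = "rrgreml")
  expect_equal(project_to_age(fit0, 3)$u_a,
               project_to_age(fit0, 7.5)$u_a)
})

test_that("heritability curves follow the coefficient covariances", {
  fit <- structure(list(K = list(a = diag(c(100, 20)),
                                 d = matrix(0, 2, 2)),
                        sigma2_e = 300, order = 1, age_range = c(2, 8)),
                   class = "rrgreml")
  cv <- heritability_curve(fit, c(2, 5, 8))
  phi <- legendre_basis(c(-1, 0, 1), 1)
  va <- rowSums((phi %*% diag(c(100, 20))) * phi)
  expect_equal(cv$v_a, va)
  expect_equal(cv$h2_d, rep(0, 3))
  expect_true(all(cv$h2_a + cv$h2_d <= 1))
  expect_equal(cv$h2_a, va / (va + 300))

  fit0 <- structure(list(K = list(a = matrix(80, 1, 1)), sigma2_e = 100,
                         order = 0, age_range = c(2, 8)),
                    class = "rrgreml")
  cv0 <- heritability_curve(fit0, c(2, 8))
  expect_equal(cv0$h2_a[1], cv0$h2_a[2])
})

test_that("rescaling the response rescales variance components only", {
  h <- simulate_herd_study(55, n_cows = 120, n_variants = 250,
                           ratio_a = 0.4, ratio_d = 0.1, n_founders = 10)
  f1 <- rr_greml(h$records, h$G, h$D, tol = 1e-4, max_iter = 20)
  r2 <- h$records
  r2$value_kg <- r2$value_kg * 3
  f2 <- rr_greml(r2, h$G, h$D, tol = 1e-4, max_iter = 20)
  expect_equal(f2$sigma2_e / f1$sigma2_e, 9, tolerance = 0.05)
  expect_equal(unname(f2$K$a / f1$K$a), matrix(9, 2, 2),
               tolerance = 0.08)
  c1 <- heritability_curve(f1, c(3, 8))
  c2 <- heritability_curve(f2, c(3, 8))
  expect_equal(c1$h2_a, c2$h2_a, tolerance = 0.01)
})

test_that("fit methods expose the expected summaries", {
  h <- simulate_herd_study(66, n_cows = 80, n_variants = 200,
                           ratio_a = 0.4, ratio_d = 0, n_founders = 8)
  fit <- rr_greml(h$records, h$G, h$D, trait = "CW", tol = 1e-3,
                  max_iter = 10)
  expect_s3_class(fit, "rrgreml")
  expect_output(print(fit), "Random-regression GREML")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.rrgreml")
  expect_output(print(sm), "Variance fractions")
  expect_named(varcomps(fit), c("K", "sigma2_e"))
  expect_equal(length(coef(fit)), fit$p)
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  expect_equal(length(residuals(fit)), fit$N)
  expect_equal(fitted(fit) + residuals(fit),
               build_design(h$records, fit$ids)$y)
  pr <- predict(fit, age = 8)
  expect_equal(nrow(pr), length(fit$ids))
})
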