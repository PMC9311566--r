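#' Design matrices for the random-regression model
#'
#' Builds the fixed-effect matrix X (intended-calving-age classes,
#' opportunity groups when present, cumulative-calf-sex covariate when
#' present) and the random-regression covariable matrix Z whose row r
#' carries the normalized Legendre values \eqn{\phi(t_r)} in the record's
#' cow's coefficient columns (coefficient-major: all animals' intercepts,
#' then all slopes, ...). Rank-deficient fixed-effect columns are dropped
#' (logged in the `dropped` attribute).
#'
#' @param records trait-record data.frame (`cow_id`, `value_kg`, `age_yr`,
#'   optionally `opp_group`, `cum_calf_sex`).
#' @param ids animal ids defining the coefficient columns (row order of
#'   the relationship matrices).
#' @param order Legendre basis order.
#' @param age_range standardization bounds mapped to \[-1, 1\].
#' @return list with `X` (dense), `Z` (sparse `Matrix`), `y`, `phi`,
#'   `cow_index`.
#' @export
build_design <- function(records, ids, order = 1, age_range = c(2, 8)) {
  stopifnot(all(c("cow_id", "value_kg", "age_yr") %in% names(records)))
  if (!all(records$cow_id %in% ids)) {
    stop("records reference cows missing from the relationship matrices")
  }
  N <- nrow(records)
  q <- length(ids)
  kdim <- order + 1
  x <- standardize_age(records$age_yr, age_range)
  phi <- legendre_basis(x, order)

  fixed <- list(age = factor(records$age_yr))
  if (!is.null(records$opp_group) && length(unique(records$opp_group)) > 1) {
    fixed$opp <- factor(records$opp_group)
  }
  df <- as.data.frame(fixed)
  form <- ~age
  if (!is.null(fixed$opp)) form <- ~ age + opp
  if (!is.null(records$cum_calf_sex)) {
    df$ccs <- records$cum_calf_sex
    form <- stats::update(form, ~ . + ccs)
  }
  X <- stats::model.matrix(form, df)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }

  ci <- match(records$cow_id, ids)
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(N), kdim),
    j = as.integer(rep((seq_len(kdim) - 1) * q, each = N) + ci),
    x = as.numeric(phi),
    dims = c(N, kdim * q))
  structure(list(X = X, Z = Z, y = records$value_kg, phi = phi,
                 cow_index = ci),
            dropped = dropped, class = "rr_design")
}

# chol-solve helper for a (upper) Cholesky factor
chol_solve <- function(ch, b) {
  backsolve(ch, backsolve(ch, b, transpose = TRUE))
}

# pack/unpack symmetric K matrices + residual into a parameter vector
pack_theta <- function(Ks, s2e) {
  c(unlist(lapply(Ks, function(K) K[lower.tri(K, diag = TRUE)])), s2e)
}
unpack_theta <- function(theta, kdim, nt) {
  nk <- kdim * (kdim + 1) / 2
  Ks <- vector("list", nt)
  for (t in seq_len(nt)) {
    K <- matrix(0, kdim, kdim)
    K[lower.tri(K, diag = TRUE)] <- theta[(t - 1) * nk + seq_len(nk)]
    K <- K + t(K) - diag(diag(K), kdim)
    Ks[[t]] <- K
  }
  list(Ks = Ks, s2e = theta[nt * nk + 1])
}

# eigenvalue floor so K stays invertible along the EM/AI path
psd_floor <- function(K, floor_val) {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) >= floor_val) return(K)
  v <- pmax(e$values, floor_val)
  e$vectors %*% diag(v, length(v)) %*% t(e$vectors)
}

#' Random-regression GREML for one trait
#'
#' Fits the univariate mixed model
#' \deqn{y = X\beta + Z u_a + Z u_d + (Z u_{pe}) + e}
#' where the coefficient vectors have covariance \eqn{K_a \otimes G}
#' (additive, genomic), \eqn{K_d \otimes D} (dominance, genomic) and
#' optionally \eqn{K_{pe} \otimes I} (permanent environment), with
#' \eqn{e \sim N(0, \sigma^2_e I)}. Variance components are estimated by
#' restricted maximum likelihood: monotone EM steps with an
#' average-information (AI) Newton step taken whenever it is admissible
#' (PSD `K`s, positive residual variance) and increases the restricted
#' log-likelihood. Animals present in `G` without records are carried and
#' receive coefficient BLUPs through their genomic relationships.
#'
#' @param records trait-record data.frame (see [build_design()]).
#' @param G additive GRM with dimnames = animal ids.
#' @param D optional dominance GRM over the same ids.
#' @param order Legendre basis order (default 1: intercept + slope).
#' @param age_range age standardization bounds, years.
#' @param include_pe add a permanent-environment random regression.
#' @param trait optional trait label (e.g. "CW", "WtW") carried in output.
#' @param tol convergence tolerance on the change in restricted logL.
#' @param max_iter maximum iterations.
#' @param start optional list(K = list(...), sigma2_e =) of starting values.
#' @param verbose print the iteration trace.
#' @return object of class `rrgreml`; see [varcomps()], [blup_effects()],
#'   [project_to_age()], [heritability_curve()] and the `print`, `summary`,
#'   `coef`, `logLik`, `predict`, `residuals`, `fitted`, `plot` methods.
#' @export
rr_greml <- function(records, G, D = NULL, order = 1, age_range = c(2, 8),
                     include_pe = FALSE, trait = NULL, tol = 1e-6,
                     max_iter = 200, start = NULL, verbose = FALSE) {
  ids <- rownames(G)
  stopifnot(!is.null(ids), nrow(G) == ncol(G))
  des <- build_design(records, ids, order = order, age_range = age_range)
  X <- des$X; Z <- des$Z; y <- des$y
  N <- length(y); p <- ncol(X); q <- length(ids); kdim <- order + 1
  kq <- kdim * q

  term_names <- c("a", if (!is.null(D)) "d", if (include_pe) "pe")
  nt <- length(term_names)
  structs <- list(a = G)
  if (!is.null(D)) {
    stopifnot(identical(rownames(D), ids))
    structs$d <- D
  }
  # permanent environment has identity structure: structs[["pe"]] is NULL

  ridge_log <- list()
  Ainv <- vector("list", nt); logdetA <- numeric(nt)
  for (t in seq_len(nt)) {
    A <- structs[[term_names[t]]]
    if (is.null(A)) {          # identity structure (permanent environment)
      Ainv[[t]] <- NULL
      logdetA[t] <- 0
    } else {
      cr <- chol_ridge(A, term_names[t])
      if (cr$ridge > 0) ridge_log[[term_names[t]]] <- cr$ridge
      Ainv[[t]] <- chol2inv(cr$chol)
      logdetA[t] <- 2 * sum(log(diag(cr$chol)))
    }
  }

  # constant cross-product blocks; W = [X, Z, Z, ...] (Z shared by terms)
  XtX <- crossprod(X)
  XtZ <- as.matrix(Matrix::crossprod(X, Z))
  ZtZ <- as.matrix(Matrix::crossprod(Z))
  Xty <- crossprod(X, y)
  Zty <- as.numeric(Matrix::crossprod(Z, y))
  yty <- sum(y^2)
  ntot <- p + nt * kq
  CWW <- matrix(0, ntot, ntot)
  CWW[1:p, 1:p] <- XtX
  tidx <- lapply(seq_len(nt), function(t) p + (t - 1) * kq + seq_len(kq))
  for (t in seq_len(nt)) {
    CWW[1:p, tidx[[t]]] <- XtZ
    CWW[tidx[[t]], 1:p] <- t(XtZ)
    for (s in seq_len(nt)) CWW[tidx[[t]], tidx[[s]]] <- ZtZ
  }
  WtY <- c(as.numeric(Xty), rep(Zty, nt))

  vy <- stats::var(y)
  floor_val <- 1e-10 * vy
  if (is.null(start)) {
    # start the residual at the pooled within-cow variance of age-adjusted
    # records (method of moments); split the rest across the genetic terms
    ydev <- y - stats::ave(y, records$age_yr)
    within <- stats::ave(ydev, records$cow_id,
                         FUN = function(v) v - mean(v))
    ncow <- length(unique(records$cow_id))
    dfree <- max(N - ncow, 1)
    s2e <- max(sum(within^2) / dfree, 0.05 * vy)
    s2e <- min(s2e, 0.95 * vy)
    scale_phi <- mean(rowSums(des$phi^2))
    Ks <- replicate(nt, diag(max(vy - s2e, 0.05 * vy) / (nt * scale_phi),
                             kdim), simplify = FALSE)
  } else {
    Ks <- lapply(start$K, as.matrix)
    s2e <- start$sigma2_e
  }

  # precomputed linear indices of each term's diagonal block (and, for
  # identity-structured terms, of the block diagonals only) make the
  # per-iteration assembly a single vectorized subassignment
  blk_idx <- lapply(seq_len(nt), function(t) {
    rows <- tidx[[t]]
    if (is.null(Ainv[[t]])) {
      idx <- integer(0)
      for (l in seq_len(kdim)) for (m in seq_len(kdim)) {
        i <- p + (t - 1) * kq + (l - 1) * q + seq_len(q)
        j <- p + (t - 1) * kq + (m - 1) * q + seq_len(q)
        idx <- c(idx, (j - 1) * ntot + i)
      }
      as.integer(idx)
    } else {
      as.integer(outer(rows, (rows - 1) * ntot, `+`))
    }
  })

  add_kron <- function(C, Kinv, t) {
    if (is.null(Ainv[[t]])) {
      C[blk_idx[[t]]] <- C[blk_idx[[t]]] +
        rep(as.vector(t(Kinv)), each = q)
    } else {
      C[blk_idx[[t]]] <- C[blk_idx[[t]]] +
        as.vector(kronecker(Kinv, Ainv[[t]]))
    }
    C
  }

  eval_theta <- function(Ks, s2e, want_chol = FALSE) {
    Kinv <- vector("list", nt); logdetK <- numeric(nt)
    for (t in seq_len(nt)) {
      chK <- tryCatch(chol(Ks[[t]]), error = function(e) NULL)
      if (is.null(chK)) return(NULL)
      Kinv[[t]] <- chol2inv(chK)
      logdetK[t] <- 2 * sum(log(diag(chK)))
    }
    C <- CWW / s2e
    for (t in seq_len(nt)) C <- add_kron(C, Kinv[[t]], t)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    sol <- chol_solve(ch, WtY / s2e)
    yPy <- (yty - sum(sol * WtY)) / s2e
    logdetC <- 2 * sum(log(diag(ch)))
    m2ll <- (N - p) * log(2 * pi) + N * log(s2e) +
      sum(q * logdetK + kdim * logdetA) + logdetC + yPy
    out <- list(logL = -0.5 * m2ll, sol = sol, yPy = yPy, Kinv = Kinv)
    if (want_chol) out$ch <- ch
    out
  }

  trace_hist <- numeric(0)
  converged <- FALSE
  iter <- 0
  em_info <- NULL
  logL_prev <- -Inf
  step_type <- character(0)
  ev_cache <- NULL
  ai_ok <- TRUE   # retry AI only periodically after a rejection
  gam <- 4        # adaptive over-relaxation factor for EM extrapolation

  repeat {
    iter <- iter + 1
    ev <- if (!is.null(ev_cache)) ev_cache else
      eval_theta(Ks, s2e, want_chol = TRUE)
    ev_cache <- NULL
    if (is.null(ev)) stop("coefficient matrix not positive definite")
    logL <- ev$logL
    trace_hist <- c(trace_hist, logL)
    if (verbose) {
      cat(sprintf("iter %3d  logL %.6f  s2e %.4f\n", iter, logL, s2e))
    }
    converged <- iter > 1 && abs(logL - logL_prev) < tol
    done <- converged || iter >= max_iter
    sol <- ev$sol
    beta <- sol[1:p]
    U <- lapply(seq_len(nt), function(t) {
      matrix(sol[tidx[[t]]], q, kdim,
             dimnames = list(ids, paste0("phi", 0:(kdim - 1))))
    })
    r <- y - as.numeric(X %*% beta) -
      as.numeric(Z %*% Reduce(`+`, lapply(U, as.numeric)))
    if (done) {
      em_info <- list(beta = beta, U = U, r = r, Kinv = ev$Kinv)
      break
    }
    logL_prev <- logL

    Cinv <- chol2inv(ev$ch)
    # per-term kdim x kdim trace matrices T2[l,m] = tr(Ainv %*% Cinv_block)
    T2 <- vector("list", nt)
    for (t in seq_len(nt)) {
      Tm <- matrix(0, kdim, kdim)
      for (l in seq_len(kdim)) for (m in l:kdim) {
        rows <- p + (t - 1) * kq + (l - 1) * q + seq_len(q)
        cols <- p + (t - 1) * kq + (m - 1) * q + seq_len(q)
        blk <- Cinv[rows, cols]
        Tm[l, m] <- Tm[m, l] <-
          if (is.null(Ainv[[t]])) sum(diag(blk)) else sum(Ainv[[t]] * blk)
      }
      T2[[t]] <- Tm
    }

    # --- EM proposal (monotone) ---
    Ks_em <- vector("list", nt)
    for (t in seq_len(nt)) {
      Ai <- Ainv[[t]]
      AU <- if (is.null(Ai)) U[[t]] else Ai %*% U[[t]]
      Ks_em[[t]] <- psd_floor((crossprod(U[[t]], AU) + T2[[t]]) / q,
                              floor_val)
    }
    s2e_em <- (sum(r^2) + s2e * (ntot - sum_kron_trace(ev$Kinv, T2,
                                                       kdim, q, nt))) / N

    # --- AI proposal (skipped during the short EM warmup, where the
    # Newton step nearly always overshoots) ---
    prop <- NULL
    try_ai <- ai_ok || iter %% 4 == 0
    ai <- if (!try_ai) NULL else tryCatch(
      ai_step(Ks, s2e, ev, Cinv, T2, r, X, Z, structs, term_names,
              p, q, kdim, nt, N, CWW, WtY, tidx),
      error = function(e) NULL)
    th0 <- pack_theta(Ks, s2e)
    try_cand <- function(th, type) {
      cand <- unpack_theta(th, kdim, nt)
      if (cand$s2e <= 0) return(NULL)
      # grossly indefinite proposals are rejected; mildly negative
      # eigenvalues (boundary overshoot) are floored to the PSD cone
      ok <- all(vapply(cand$Ks, function(K) {
        ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
        min(ev) > -0.1 * max(abs(ev), 1e-12)
      }, logical(1)))
      if (!ok) return(NULL)
      Ks_c <- lapply(cand$Ks, psd_floor, floor_val = floor_val)
      ev_c <- eval_theta(Ks_c, cand$s2e, want_chol = TRUE)
      if (is.null(ev_c) || ev_c$logL <= logL) return(NULL)
      list(Ks = Ks_c, s2e = cand$s2e, type = type, ev = ev_c)
    }
    # try the full AI Newton step, then over-relaxed EM, then the plain
    # EM step, which is monotone by theory
    if (!is.null(ai)) prop <- try_cand(th0 + ai$delta, "AI")
    if (try_ai) ai_ok <- !is.null(prop)
    if (is.null(prop)) {
      th_em <- pack_theta(Ks_em, s2e_em)
      if (gam > 1) prop <- try_cand(th0 + gam * (th_em - th0), "EMx")
      if (is.null(prop)) {
        gam <- max(gam / 2, 1)
        prop <- list(Ks = Ks_em, s2e = s2e_em, type = "EM")
      } else {
        gam <- min(gam * 1.5, 32)
      }
    }
    Ks <- prop$Ks; s2e <- prop$s2e
    ev_cache <- prop$ev
    step_type <- c(step_type, prop$type)
  }

  K_out <- stats::setNames(lapply(Ks, function(K) {
    dimnames(K) <- rep(list(paste0("phi", 0:(kdim - 1))), 2)
    K
  }), term_names)
  fit <- structure(list(
    K = K_out, sigma2_e = s2e, logLik = trace_hist[iter],
    logLik_trace = trace_hist, step_type = step_type,
    converged = converged, n_iter = iter,
    beta = stats::setNames(em_info$beta, colnames(X)),
    u = stats::setNames(em_info$U, term_names),
    residuals = em_info$r, fitted = y - em_info$r,
    ids = ids, order = order, age_range = age_range, trait = trait,
    N = N, p = p, dropped_fixed = attr(des, "dropped"),
    ridge_log = ridge_log,
    cows = unique(records$cow_id)),
    class = "rrgreml")
  fit
}

# tr(Cinv %*% blkdiag(0, Kinv kron Ainv)) summed over terms, via T2
sum_kron_trace <- function(Kinv, T2, kdim, q, nt) {
  tot <- 0
  for (t in seq_len(nt)) tot <- tot + sum(Kinv[[t]] * T2[[t]])
  tot
}

# one average-information Newton proposal
ai_step <- function(Ks, s2e, ev, Cinv, T2, r, X, Z, structs, term_names,
                    p, q, kdim, nt, N, CWW, WtY, tidx) {
  Py <- r / s2e
  ZtPy <- as.numeric(Matrix::crossprod(Z, Py))
  Uq <- matrix(ZtPy, q, kdim)
  nk <- kdim * (kdim + 1) / 2
  npar <- nt * nk + 1

  Es <- list()
  for (l in seq_len(kdim)) for (m in l:kdim) {
    S <- matrix(0, kdim, kdim)
    S[l, m] <- S[m, l] <- 1
    Es[[length(Es) + 1]] <- S
  }

  fs <- vector("list", npar)
  grad <- numeric(npar)
  i <- 0
  for (t in seq_len(nt)) {
    A <- structs[[term_names[t]]]
    AU <- if (is.null(A)) Uq else A %*% Uq
    Kinv <- ev$Kinv[[t]]
    for (e in seq_len(nk)) {
      S <- Es[[e]]
      i <- i + 1
      fs[[i]] <- as.numeric(Z %*% as.numeric(AU %*% S))
      trPV <- q * sum(S * Kinv) -
        sum(diag(S %*% Kinv %*% T2[[t]] %*% Kinv))
      grad[i] <- -0.5 * (trPV - sum(fs[[i]] * Py))
    }
  }
  # residual variance
  i <- i + 1
  fs[[i]] <- Py
  qtot <- nt * kdim * q
  trP <- (N - p - qtot + sum(vapply(seq_len(nt), function(t) {
    sum(ev$Kinv[[t]] * T2[[t]])
  }, numeric(1)))) / s2e
  grad[i] <- -0.5 * (trP - sum(Py^2))

  # P f_j via the mixed-model equations
  Pf <- vector("list", npar)
  for (j in seq_len(npar)) {
    f <- fs[[j]]
    Wtf <- c(as.numeric(crossprod(X, f)),
             rep(as.numeric(Matrix::crossprod(Z, f)), nt))
    g <- chol_solve(ev$ch, Wtf / s2e)
    Wg <- as.numeric(X %*% g[1:p])
    for (t in seq_len(nt)) {
      Wg <- Wg + as.numeric(Z %*% g[tidx[[t]]])
    }
    Pf[[j]] <- (f - Wg) / s2e
  }
  AI <- matrix(0, npar, npar)
  for (a in seq_len(npar)) for (b in a:npar) {
    AI[a, b] <- AI[b, a] <- 0.5 * sum(fs[[a]] * Pf[[b]])
  }
  # Levenberg-style ridge keeps the Newton direction finite when the
  # average information is nearly singular (small data, boundary K)
  lam <- 1e-6 * mean(diag(AI))
  delta <- tryCatch(solve(AI + diag(lam, npar), grad),
                    error = function(e) grad / max(diag(AI), 1e-12))
  list(delta = delta, grad = grad, AI = AI)
}
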