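# Restricted-likelihood machinery shared by the GBLUP fitting front-ends.
#
# All balanced fits exploit two diagonalizations: the eigendecomposition
# G = U D U' of the relationship matrix (one rotation of the data), and the
# simultaneous diagonalization of (T, R) in the multi-trait case, which turns
# every n x t covariance block d_m T + R into a diagonal form. Likelihood
# evaluations then cost O(n t) flops, so a derivative-free optimizer over a
# log-Cholesky parameterization is fast and cannot leave the
# positive-definite cone. Unbalanced (missing-record) fits fall back on a
# dense multivariate-normal restricted likelihood.

# ---- log-Cholesky packing ---------------------------------------------------

logchol_pack <- function(M) {
  L <- t(chol(M))
  d <- log(diag(L))
  c(d, L[lower.tri(L)])
}

logchol_unpack <- function(par, t) {
  L <- matrix(0, t, t)
  diag(L) <- exp(par[seq_len(t)])
  L[lower.tri(L)] <- par[-seq_len(t)]
  tcrossprod(L)
}

n_logchol <- function(t) t * (t + 1L) / 2L

lowtri_from_par <- function(par, t) {
  L <- matrix(0, t, t)
  diag(L) <- exp(par[seq_len(t)])
  L[lower.tri(L)] <- par[-seq_len(t)]
  L
}

# REML log-likelihood constant convention used throughout:
#   ll = -0.5 * ( log|V| + log|X'V^-1 X| + y'Py + (N - p) log(2*pi) )

# ---- balanced multi-trait likelihood ---------------------------------------

# Analytic gradient of the NEGATIVE restricted log-likelihood with respect to
# the log-Cholesky parameters of (T, R), in the rotated representation.
# Derivation: dl/dθ = -0.5( tr(P dV) - y'P dV P y ) with V_m = d_m T + R and
# P the REML projection; in the W basis every term reduces to inner products
# of W' dV W with three t x t accumulators, and for a single-entry dL the
# inner product collapses to one element of W M P_L.
mt_balanced_grad <- function(Ytil, xtil, d, L_T, L_R, diagonal = FALSE) {
  t <- ncol(Ytil)
  Tm <- tcrossprod(L_T); Rm <- tcrossprod(L_R)
  Rc <- chol(Rm)
  Ui <- backsolve(Rc, diag(t))
  S <- crossprod(Ui, Tm %*% Ui); S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  W <- Ui %*% es$vectors
  Zt <- Ytil %*% W
  Dl <- outer(d, lam)
  Wts <- 1 / (Dl + 1)
  Dx <- colSums(xtil^2 * Wts)
  cz <- colSums(xtil * (Wts * Zt))
  beta_w <- cz / Dx
  zres <- Zt - outer(xtil, beta_w)
  wz <- Wts * zres

  c1 <- colSums(d * Wts)
  c0 <- colSums(Wts)
  C1d <- colSums(xtil^2 * d * Wts^2)
  C0d <- colSums(xtil^2 * Wts^2)
  U1 <- crossprod(wz * sqrt(d))
  U0 <- crossprod(wz)
  M_T <- diag(c1 - C1d / Dx, t) - U1
  M_R <- diag(c0 - C0d / Dx, t) - U0

  if (diagonal) {
    # parameters p_j with T_jj = exp(2 p_j): dT = 2 T_jj e_j e_j', so the
    # gradient of -l is T_jj (W M_T W')_jj (and likewise for R)
    wmwT <- rowSums((W %*% M_T) * W)
    wmwR <- rowSums((W %*% M_R) * W)
    return(c(diag(Tm) * wmwT, diag(Rm) * wmwR))
  }
  pack_grad <- function(M, L) {
    # for a single lower-tri entry dL = v e_i e_j': grad = v (W M W'L)[i, j];
    # v = L_ii on the log-scaled diagonal, 1 elsewhere
    G <- W %*% M %*% crossprod(W, L)
    c(diag(G) * diag(L), G[lower.tri(G)])
  }
  c(pack_grad(M_T, L_T), pack_grad(M_R, L_R))
}

# Ytil = U'Y (n x t), xtil = U'1 (n), d = eigenvalues of G.
mt_balanced_eval <- function(Ytil, xtil, d, Tm, Rm, want_blup = FALSE) {
  t <- ncol(Ytil); n <- nrow(Ytil)
  Rc <- tryCatch(chol(Rm), error = function(e) NULL)
  if (is.null(Rc)) return(NULL)
  Ui <- backsolve(Rc, diag(t))            # R^{-1/2} (upper-tri inverse)
  S <- crossprod(Ui, Tm %*% Ui)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  W <- Ui %*% es$vectors                  # W'RW = I, W'TW = diag(lam)
  ldetR <- 2 * sum(log(diag(Rc)))

  Zt <- Ytil %*% W
  Dl <- outer(d, lam)                     # n x t
  Wts <- 1 / (Dl + 1)
  Dx <- colSums(xtil^2 * Wts)
  if (any(Dx <= 0)) return(NULL)
  cz <- colSums(xtil * (Wts * Zt))
  beta_w <- cz / Dx
  quad_full <- sum(Wts * Zt^2)
  yPy <- quad_full - sum(cz^2 / Dx)
  logV <- sum(log1p(Dl)) + n * ldetR
  logXVX <- sum(log(Dx)) - ldetR
  N <- n * t; p <- t
  ll <- -0.5 * (logV + logXVX + yPy + (N - p) * log(2 * pi))
  if (!want_blup) return(list(loglik = ll))
  beta <- solve(t(W), beta_w)             # trait means
  Zres <- Zt - outer(xtil, beta_w)
  M <- sweep(Wts * Zres, 2, lam, "*") * d # d_m * lam_l * w * z_res
  Gtil <- M %*% solve(W)
  list(loglik = ll, beta = as.vector(beta), gebv_rot = Gtil)
}

mt_reml_balanced <- function(Y, G, diagonal = FALSE, init = NULL,
                             maxit = 4000, restarts = 1L) {
  # standardize traits internally so the optimization problem (and thus the
  # optimum found in finitely many steps) is exactly invariant to trait
  # rescaling; components are mapped back afterwards
  sds <- apply(Y, 2, stats::sd)
  sds[!is.finite(sds) | sds <= 0] <- 1
  if (!is.null(init)) {
    init <- list(T = t(init$T / sds) / sds, R = t(init$R / sds) / sds)
  }
  fit <- mt_reml_balanced_std(scale(Y, center = FALSE, scale = sds), G,
                              diagonal = diagonal, init = init,
                              maxit = maxit, restarts = restarts)
  D <- diag(sds, length(sds))
  fit$T <- D %*% fit$T %*% D
  fit$R <- D %*% fit$R %*% D
  fit$beta <- fit$beta * sds
  fit$gebv <- sweep(fit$gebv, 2, sds, "*")
  dimnames(fit$gebv) <- dimnames(Y)
  # restore the restricted log-likelihood on the original scale: the data
  # Jacobian contributes -n log sd_j per trait and the profiled trait-mean
  # fixed effects give back +log sd_j each
  fit$loglik <- fit$loglik - (nrow(Y) - 1) * sum(log(sds))
  fit$loglik_init <- fit$loglik_init - (nrow(Y) - 1) * sum(log(sds))
  fit
}

mt_reml_balanced_std <- function(Y, G, diagonal = FALSE, init = NULL,
                                 maxit = 4000, restarts = 1L) {
  t <- ncol(Y); n <- nrow(Y)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  U <- eg$vectors
  Ytil <- crossprod(U, Y)
  xtil <- as.vector(crossprod(U, rep(1, n)))

  C0 <- stats::cov(Y)
  C0 <- C0 + diag(mean(diag(C0)) * 1e-4, t)
  if (is.null(init)) init <- list(T = 0.5 * C0, R = 0.5 * C0)
  if (diagonal) {
    pack <- function(Tm, Rm) c(log(diag(Tm)) / 2, log(diag(Rm)) / 2)
    unpack <- function(par) list(T = diag(exp(2 * par[seq_len(t)]), t),
                                 R = diag(exp(2 * par[t + seq_len(t)]), t))
  } else {
    pack <- function(Tm, Rm) c(logchol_pack(Tm), logchol_pack(Rm))
    unpack <- function(par) {
      k <- n_logchol(t)
      list(T = logchol_unpack(par[seq_len(k)], t),
           R = logchol_unpack(par[k + seq_len(k)], t))
    }
  }
  fn <- function(par) {
    vc <- unpack(par)
    ev <- mt_balanced_eval(Ytil, xtil, d, vc$T, vc$R)
    if (is.null(ev) || !is.finite(ev$loglik)) return(1e10)
    -ev$loglik
  }
  gr <- function(par) {
    if (diagonal) {
      L_T <- diag(exp(par[seq_len(t)]), t)
      L_R <- diag(exp(par[t + seq_len(t)]), t)
    } else {
      k <- n_logchol(t)
      L_T <- lowtri_from_par(par[seq_len(k)], t)
      L_R <- lowtri_from_par(par[k + seq_len(k)], t)
    }
    mt_balanced_grad(Ytil, xtil, d, L_T, L_R, diagonal = diagonal)
  }
  par <- pack(init$T, init$R)
  ll0 <- -fn(par)
  # short simplex phase for robustness, then quasi-Newton with the analytic
  # gradient, which pins the optimum to near machine precision
  op <- stats::optim(par, fn, method = "Nelder-Mead",
                     control = list(maxit = min(maxit, 500), reltol = 1e-8))
  op2 <- tryCatch(stats::optim(op$par, fn, gr = gr, method = "BFGS",
                               control = list(maxit = maxit, reltol = 1e-15)),
                  error = function(e) NULL)
  if (!is.null(op2) && op2$value <= op$value) op <- op2
  for (r in seq_len(restarts)) {
    op3 <- tryCatch(stats::optim(op$par, fn, gr = gr, method = "BFGS",
                                 control = list(maxit = maxit, reltol = 1e-15)),
                    error = function(e) NULL)
    if (!is.null(op3) && op3$value < op$value) op <- op3 else break
  }
  vc <- unpack(op$par)
  ev <- mt_balanced_eval(Ytil, xtil, d, vc$T, vc$R, want_blup = TRUE)
  gebv <- U %*% ev$gebv_rot
  dimnames(gebv) <- dimnames(Y)
  list(T = vc$T, R = vc$R, loglik = ev$loglik, loglik_init = ll0,
       beta = ev$beta, gebv = gebv, eigen = list(U = U, d = d),
       counts = op$counts)
}

# ---- dense (unbalanced) multi-trait likelihood ------------------------------

# records: data.frame(acc_idx, trait_idx, value); G over accessions.
mt_dense_V <- function(records, G, Tm, Rm) {
  ai <- records$acc_idx; ti <- records$trait_idx
  V <- Tm[ti, ti] * G[ai, ai]
  same <- outer(ai, ai, "==")
  V[same] <- V[same] + Rm[cbind(ti[row(same)[same]], ti[col(same)[same]])]
  V
}

mt_dense_eval <- function(records, G, Tm, Rm, want_beta = FALSE) {
  y <- records$value
  t_all <- sort(unique(records$trait_idx))
  X <- outer(records$trait_idx, t_all, "==") + 0
  V <- mt_dense_V(records, G, Tm, Rm)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Ki <- backsolve(ch, forwardsolve(t(ch), cbind(y, X)))
  Viy <- Ki[, 1]; ViX <- Ki[, -1, drop = FALSE]
  XtViX <- crossprod(X, ViX)
  ch2 <- chol(XtViX)
  beta <- backsolve(ch2, forwardsolve(t(ch2), crossprod(X, Viy)))
  yPy <- sum(y * Viy) - sum(crossprod(X, Viy) * beta)
  logV <- 2 * sum(log(diag(ch)))
  logXVX <- 2 * sum(log(diag(ch2)))
  N <- length(y); p <- ncol(X)
  ll <- -0.5 * (logV + logXVX + yPy + (N - p) * log(2 * pi))
  out <- list(loglik = ll)
  if (want_beta) {
    out$beta <- as.vector(beta)
    out$trait_levels <- t_all
    out$resid <- y - X %*% beta
    out$chol_V <- ch
  }
  out
}

mt_reml_dense <- function(records, G, t, diagonal = FALSE, init = NULL,
                          maxit = 4000) {
  if (is.null(init)) {
    v <- stats::aggregate(value ~ trait_idx, records, stats::var)
    vv <- rep(mean(v$value), t); vv[v$trait_idx] <- v$value
    init <- list(T = diag(vv / 2, t), R = diag(vv / 2, t))
  }
  if (diagonal) {
    pack <- function(Tm, Rm) c(log(diag(Tm)) / 2, log(diag(Rm)) / 2)
    unpack <- function(par) list(T = diag(exp(2 * par[seq_len(t)]), t),
                                 R = diag(exp(2 * par[t + seq_len(t)]), t))
  } else {
    pack <- function(Tm, Rm) c(logchol_pack(Tm), logchol_pack(Rm))
    unpack <- function(par) {
      k <- n_logchol(t)
      list(T = logchol_unpack(par[seq_len(k)], t),
           R = logchol_unpack(par[k + seq_len(k)], t))
    }
  }
  fn <- function(par) {
    vc <- unpack(par)
    ev <- mt_dense_eval(records, G, vc$T, vc$R)
    if (is.null(ev) || !is.finite(ev$loglik)) return(1e10)
    -ev$loglik
  }
  par <- pack(init$T, init$R)
  ll0 <- -fn(par)
  op <- stats::optim(par, fn, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-12))
  op2 <- stats::optim(op$par, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
  if (op2$value < op$value) op <- op2
  vc <- unpack(op$par)
  list(T = vc$T, R = vc$R, loglik = -op$value, loglik_init = ll0,
       counts = op$counts)
}

# Conditional GEBVs for all accessions x traits given observed records and
# fixed variance components: ghat = Cov(g, y) V^-1 (y - X beta).
mt_dense_predict <- function(records, G, Tm, Rm) {
  ev <- mt_dense_eval(records, G, Tm, Rm, want_beta = TRUE)
  if (is.null(ev)) stop("singular covariance in conditional prediction")
  n <- nrow(G); t <- nrow(Tm)
  ai <- records$acc_idx; ti <- records$trait_idx
  Vi_r <- backsolve(ev$chol_V, forwardsolve(t(ev$chol_V), ev$resid))
  gebv <- matrix(0, n, t)
  for (j in seq_len(t)) {
    Cj <- Tm[j, ti] * G[, ai, drop = FALSE]   # Cov(g_{., j}, y)
    gebv[, j] <- as.vector(Cj %*% Vi_r)
  }
  list(gebv = gebv, beta = ev$beta, trait_levels = ev$trait_levels,
       loglik = ev$loglik)
}

# ---- balanced single-trait (univariate) profile REML ------------------------

uv_reml_eigen <- function(y, G, floor_frac = 1e-8) {
  n <- length(y)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  U <- eg$vectors
  ytil <- as.vector(crossprod(U, y))
  xtil <- as.vector(crossprod(U, rep(1, n)))
  vary <- stats::var(y)
  floorv <- floor_frac * max(vary, .Machine$double.eps)

  if (!is.finite(vary) || vary < 1e-12) {
    return(list(sigma2_A = floorv, sigma2_e = floorv, h2 = 0,
                loglik = NA_real_, beta = mean(y), gebv = rep(0, n),
                eigen = list(U = U, d = d)))
  }
  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    Dx <- sum(xtil^2 * w)
    bw <- sum(xtil * w * ytil) / Dx
    rss <- sum(w * (ytil - xtil * bw)^2)
    s2e <- rss / (n - 1)
    ll <- -0.5 * ((n - 1) * log(s2e) + sum(log(lam * d + 1)) + log(Dx) +
                    (n - 1) + (n - 1) * log(2 * pi))
    ll
  }
  op <- stats::optimize(function(z) -prof(z), c(-16, 16), tol = 1e-9)
  lam <- exp(op$minimum)
  w <- 1 / (lam * d + 1)
  Dx <- sum(xtil^2 * w)
  bw <- sum(xtil * w * ytil) / Dx
  res <- ytil - xtil * bw
  s2e <- sum(w * res^2) / (n - 1)
  s2a <- lam * s2e
  gtil <- lam * d * w * res
  gebv <- as.vector(U %*% gtil)
  list(sigma2_A = max(s2a, floorv), sigma2_e = max(s2e, floorv),
       h2 = lam / (1 + lam), loglik = prof(op$minimum),
       beta = bw / 1, beta_mean = NA, gebv = gebv,
       lambda = lam, eigen = list(U = U, d = d))
}

# Univariate prediction into new accessions with fixed components:
# ghat_new = s2a * G[new, obs] * (s2a G[obs, obs] + s2e I)^-1 (y - mu).
uv_predict <- function(y_obs, G, obs_idx, new_idx, sigma2_A, sigma2_e) {
  Vo <- sigma2_A * G[obs_idx, obs_idx] + diag(sigma2_e, length(obs_idx))
  ch <- chol(Vo)
  one <- rep(1, length(obs_idx))
  Vi <- backsolve(ch, forwardsolve(t(ch), cbind(y_obs, one)))
  mu <- sum(one * Vi[, 1]) / sum(one * Vi[, 2])
  r <- y_obs - mu
  Vir <- backsolve(ch, forwardsolve(t(ch), r))
  as.vector(sigma2_A * G[new_idx, obs_idx, drop = FALSE] %*% Vir)
}

# ---- balanced g x E likelihood ----------------------------------------------

# Y: n x S (one trait, S sites, same accessions throughout).
gxe_eval <- function(Ytil, xtil, d, s2a, s2g, s2e, want_blup = FALSE) {
  n <- nrow(Ytil); S <- ncol(Ytil)
  alpha <- d * s2g + s2e
  beta <- d * s2a
  tot <- alpha + S * beta
  if (any(alpha <= 0) || any(tot <= 0)) return(NULL)
  rs <- rowSums(Ytil)
  logV <- (S - 1) * sum(log(alpha)) + sum(log(tot))
  A1 <- sum(xtil^2 / alpha)
  A2 <- sum(xtil^2 * beta / (alpha * tot))
  if (A1 <= 0 || A1 - S * A2 <= 0) return(NULL)
  logXVX <- (S - 1) * log(A1) + log(A1 - S * A2)
  cvec <- colSums(xtil * Ytil / alpha) - sum(xtil * beta * rs / (alpha * tot))
  # (A1 I - A2 J)^-1 = (1/A1)(I + A2/(A1 - S A2) J)
  bhat <- (cvec + A2 / (A1 - S * A2) * sum(cvec)) / A1
  yVy <- sum(Ytil^2 / alpha) - sum(beta * rs^2 / (alpha * tot))
  yPy <- yVy - sum(cvec * bhat)
  N <- n * S; p <- S
  ll <- -0.5 * (logV + logXVX + yPy + (N - p) * log(2 * pi))
  if (!want_blup) return(list(loglik = ll))
  Rres <- Ytil - outer(xtil, bhat)
  rs_r <- rowSums(Rres)
  g_til <- beta * rs_r / tot
  gE_til <- s2g * d * (Rres / alpha - beta * rs_r / (alpha * tot))
  list(loglik = ll, beta = bhat, g_rot = g_til, gE_rot = gE_til)
}

gxe_reml_balanced <- function(Y, G, fix_s2g = NULL, maxit = 2000) {
  n <- nrow(Y); S <- ncol(Y)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  U <- eg$vectors
  Ytil <- crossprod(U, Y)
  xtil <- as.vector(crossprod(U, rep(1, n)))
  v0 <- mean(apply(Y, 2, stats::var))
  floorv <- 1e-8 * v0

  if (is.null(fix_s2g)) {
    fn <- function(par) {
      ev <- gxe_eval(Ytil, xtil, d, exp(par[1]), exp(par[2]), exp(par[3]))
      if (is.null(ev) || !is.finite(ev$loglik)) return(1e10)
      -ev$loglik
    }
    par0 <- log(c(v0 / 3, v0 / 3, v0 / 3))
    op <- stats::optim(par0, fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-12))
    op2 <- stats::optim(op$par, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (op2$value < op$value) op <- op2
    s2 <- exp(op$par)
  } else {
    fn <- function(par) {
      ev <- gxe_eval(Ytil, xtil, d, exp(par[1]), fix_s2g, exp(par[2]))
      if (is.null(ev) || !is.finite(ev$loglik)) return(1e10)
      -ev$loglik
    }
    par0 <- log(c(v0 / 2, v0 / 2))
    op <- stats::optim(par0, fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-12))
    s2 <- c(exp(op$par[1]), fix_s2g, exp(op$par[2]))
  }
  ev <- gxe_eval(Ytil, xtil, d, s2[1], s2[2], s2[3], want_blup = TRUE)
  g <- as.vector(U %*% ev$g_rot)
  gE <- U %*% ev$gE_rot
  dimnames(gE) <- dimnames(Y)
  list(sigma2_A = max(s2[1], floorv), sigma2_gxe = max(s2[2], floorv),
       sigma2_e = max(s2[3], floorv), loglik = ev$loglik,
       beta = ev$beta, gebv_main = g, gebv_site = gE)
}

# ---- plot-level multi-trait likelihood with row/column random terms ---------

# records: data.frame(acc_idx, trait_idx, plot_idx, row_idx, col_idx,
# rep_idx, value). Random row/column effects are i.i.d. per trait with
# variances s2row[t], s2col[t]; the residual has trait covariance R at the
# same plot and independence across plots (spatial trend is stage 1's job).
# Dense; intended for modest trial sizes.
mt_plot_dense_eval <- function(records, G, Tm, Rm, s2row, s2col,
                               want_blup = FALSE) {
  ai <- records$acc_idx; ti <- records$trait_idx
  m <- nrow(records)
  V <- Tm[ti, ti] * G[ai, ai]
  same_trait <- outer(ti, ti, "==")
  pair_tt <- cbind(rep(ti, times = m), rep(ti, each = m))
  same_plot <- outer(records$plot_idx, records$plot_idx, "==")
  V <- V + matrix(Rm[pair_tt], m, m) * same_plot
  V <- V + outer(sqrt(s2row[ti]), sqrt(s2row[ti])) * same_trait *
    outer(records$row_idx, records$row_idx, "==")
  V <- V + outer(sqrt(s2col[ti]), sqrt(s2col[ti])) * same_trait *
    outer(records$col_idx, records$col_idx, "==")

  t_all <- sort(unique(ti))
  X <- outer(ti, t_all, "==") + 0
  reps <- sort(unique(records$rep_idx))
  if (length(reps) > 1L) {
    for (r in reps[-1]) {
      X <- cbind(X, outer(ti, t_all, "==") * (records$rep_idx == r))
    }
  }
  y <- records$value
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Ki <- backsolve(ch, forwardsolve(t(ch), cbind(y, X)))
  Viy <- Ki[, 1]; ViX <- Ki[, -1, drop = FALSE]
  XtViX <- crossprod(X, ViX)
  ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch2)) return(NULL)
  beta <- backsolve(ch2, forwardsolve(t(ch2), crossprod(X, Viy)))
  yPy <- sum(y * Viy) - sum(crossprod(X, Viy) * beta)
  N <- length(y); p <- ncol(X)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) + yPy +
                  (N - p) * log(2 * pi))
  if (!want_blup) return(list(loglik = ll))
  resid <- y - as.vector(X %*% beta)
  Vir <- backsolve(ch, forwardsolve(t(ch), resid))
  n <- nrow(G); t <- nrow(Tm)
  gebv <- matrix(0, n, t)
  for (j in seq_len(t)) {
    Cj <- Tm[j, ti] * G[, ai, drop = FALSE]
    gebv[, j] <- as.vector(Cj %*% Vir)
  }
  list(loglik = ll, beta = as.vector(beta), gebv = gebv)
}

mt_reml_plot <- function(records, G, t, maxit = 3000) {
  v <- stats::aggregate(value ~ trait_idx, records, stats::var)
  vv <- rep(mean(v$value), t); vv[v$trait_idx] <- v$value
  k <- n_logchol(t)
  unpack <- function(par) {
    list(T = logchol_unpack(par[seq_len(k)], t),
         R = logchol_unpack(par[k + seq_len(k)], t),
         s2row = exp(par[2 * k + seq_len(t)]),
         s2col = exp(par[2 * k + t + seq_len(t)]))
  }
  par0 <- c(logchol_pack(diag(vv / 3, t)), logchol_pack(diag(vv / 3, t)),
            log(vv / 6), log(vv / 6))
  fn <- function(par) {
    vc <- unpack(par)
    ev <- mt_plot_dense_eval(records, G, vc$T, vc$R, vc$s2row, vc$s2col)
    if (is.null(ev) || !is.finite(ev$loglik)) return(1e10)
    -ev$loglik
  }
  op <- stats::optim(par0, fn, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-10))
  op2 <- stats::optim(op$par, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  if (op2$value < op$value) op <- op2
  vc <- unpack(op$par)
  ev <- mt_plot_dense_eval(records, G, vc$T, vc$R, vc$s2row, vc$s2col,
                           want_blup = TRUE)
  c(vc, list(loglik = ev$loglik, beta = ev$beta, gebv = ev$gebv))
}
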