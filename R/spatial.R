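#' AR1 correlation matrix
#'
#' @param n Dimension.
#' @param rho Autocorrelation, |rho| < 1.
#' @return `n x n` matrix with entries `rho^|i - j|`.
#' @export
ar1_correlation <- function(n, rho) {
  if (n < 1) stop("n must be >= 1")
  if (abs(rho) >= 1) stop("AR1 rho must satisfy |rho| < 1")
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

# Tridiagonal AR1 precision (inverse of ar1_correlation), sparse.
ar1_precision <- function(n, rho) {
  if (abs(rho) >= 1) stop("AR1 rho must satisfy |rho| < 1")
  if (n == 1L) return(Matrix::sparseMatrix(i = 1, j = 1, x = 1))
  main <- c(1, rep(1 + rho^2, n - 2L), 1) / (1 - rho^2)
  off <- rep(-rho / (1 - rho^2), n - 1L)
  Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                     diagonals = list(off, main, off), symmetric = FALSE)
}

# Log-determinant of ar1_correlation(n, rho): (n - 1) * log(1 - rho^2).
ar1_logdet <- function(n, rho) (n - 1) * log(1 - rho^2)

# REML criterion and GLS fit for fixed (rho_row, rho_col).
# Returns -2 * restricted log-likelihood pieces plus the GLS solution.
spatial_gls <- function(y, X, idx_obs, nr, nc, rho_r, rho_c) {
  n <- length(y); p <- ncol(X)
  Q <- Matrix::kronecker(ar1_precision(nc, rho_c), ar1_precision(nr, rho_r))
  ntot <- nr * nc
  logdet_full <- nc * ar1_logdet(nr, rho_r) + nr * ar1_logdet(nc, rho_c)
  if (length(idx_obs) < ntot) {
    mis <- setdiff(seq_len(ntot), idx_obs)
    Qmm <- as.matrix(Q[mis, mis, drop = FALSE])
    Qom <- Q[idx_obs, mis, drop = FALSE]
    ch <- chol(Qmm)
    # Sigma_obs^-1 = Q_oo - Q_om Q_mm^-1 Q_mo ; log|Sigma_obs| = log|Sigma| + log|Q_mm|
    Qmm_inv <- chol2inv(ch)
    Qoo <- Q[idx_obs, idx_obs, drop = FALSE]
    logdetC <- logdet_full + 2 * sum(log(diag(ch)))
    Ay <- as.vector(Qoo %*% y) - as.vector(Qom %*% (Qmm_inv %*% as.vector(Matrix::crossprod(Qom, y))))
    AX <- as.matrix(Qoo %*% X) - as.matrix(Qom %*% (Qmm_inv %*% as.matrix(Matrix::crossprod(Qom, X))))
  } else {
    logdetC <- logdet_full
    Ay <- as.vector(Q %*% y)
    AX <- as.matrix(Q %*% X)
  }
  XtAX <- as.matrix(crossprod(X, AX))
  XtAX <- (XtAX + t(XtAX)) / 2
  XtAy <- as.vector(crossprod(X, Ay))
  ch2 <- tryCatch(chol(XtAX), error = function(e) NULL)
  if (is.null(ch2)) return(NULL)
  beta <- backsolve(ch2, forwardsolve(t(ch2), XtAy))
  r <- y - as.vector(X %*% beta)
  rss <- sum(r * (Ay - AX %*% beta))
  sigma2 <- rss / (n - p)
  logdetXtAX <- 2 * sum(log(diag(ch2)))
  # restricted loglik with sigma2 profiled out
  ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + logdetC + logdetXtAX)
  list(beta = as.vector(beta), sigma2 = sigma2, loglik = ll,
       XtAX_chol = ch2)
}

#' Stage-one spatial analysis of a single trial: accession BLUEs
#'
#' Fits, by restricted maximum likelihood, a model with fixed accession and
#' replicate effects and a separable AR1(rho_row) x AR1(rho_col) residual
#' over the plot grid. The two autocorrelations are profiled on a grid
#' (default step 0.05 over (-0.9, 0.9)) and refined by Nelder-Mead on the
#' atanh scale; fixed effects are estimated by generalized least squares at
#' the optimum. Missing grid cells are handled by observed-submatrix GLS
#' (rows of the Kronecker covariance are dropped, not imputed). Replicate
#' effects use sum-to-zero contrasts, so an accession's BLUE is its estimated
#' mean averaged over replicates.
#'
#' @param plots A `trial_table` (single site) with columns
#'   `site, rep, row, col, accession` and the trait.
#' @param trait Trait column name to analyse.
#' @param grid_step Grid step for the profile search over the AR1 parameters.
#' @param rho_limit Grid extent (search over `[-rho_limit, rho_limit]`).
#' @param fix_rho Optional length-2 vector to skip estimation and fit at the
#'   given (rho_row, rho_col).
#' @param refine Logical: run Nelder-Mead refinement after the grid search.
#' @return List with `blues` (data.frame `site, accession, trait, estimate,
#'   se`) and `fit` (list `rho_row, rho_col, sigma2_spatial, log_likelihood`).
#' @export
fit_trial_blues <- function(plots, trait, grid_step = 0.05, rho_limit = 0.9,
                            fix_rho = NULL, refine = TRUE) {
  stopifnot(is.data.frame(plots), trait %in% names(plots))
  if (length(unique(plots$site)) != 1L) stop("fit_trial_blues expects a single site")
  keep <- is.finite(plots[[trait]])
  plots <- plots[keep, , drop = FALSE]
  acc <- factor(plots$accession)
  if (nlevels(acc) < 2L) stop("need at least 2 accessions")
  nr <- max(plots$row); nc <- max(plots$col)
  idx_obs <- (plots$col - 1L) * nr + plots$row
  if (anyDuplicated(idx_obs)) stop("duplicate (row, col) plot positions")
  y <- plots[[trait]]

  X <- stats::model.matrix(~ 0 + acc)
  if (length(unique(plots$rep)) > 1L) {
    repf <- factor(plots$rep)
    Xr <- stats::model.matrix(~ repf, contrasts.arg = list(repf = "contr.sum"))[, -1, drop = FALSE]
    X <- cbind(X, Xr)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: an accession is confounded with replicate structure")
  }

  obj <- function(rho) {
    f <- spatial_gls(y, X, idx_obs, nr, nc, rho[1], rho[2])
    if (is.null(f)) return(Inf)
    -f$loglik
  }

  if (!is.null(fix_rho)) {
    best <- fix_rho
  } else {
    grid <- seq(-rho_limit, rho_limit, by = grid_step)
    best <- c(0, 0); best_val <- obj(c(0, 0))
    for (rr in grid) for (rc in grid) {
      v <- obj(c(rr, rc))
      if (v < best_val - 1e-12) { best_val <- v; best <- c(rr, rc) }
    }
    if (refine) {
      tr <- function(z) tanh(z) * 0.99
      op <- stats::optim(atanh(pmin(pmax(best / 0.99, -0.999), 0.999)),
                         function(z) obj(tr(z)), method = "Nelder-Mead",
                         control = list(reltol = 1e-10, maxit = 400))
      cand <- tr(op$par)
      if (obj(cand) <= best_val) best <- cand
    }
  }

  fit <- spatial_gls(y, X, idx_obs, nr, nc, best[1], best[2])
  na <- nlevels(acc)
  est <- fit$beta[seq_len(na)]
  covb <- chol2inv(fit$XtAX_chol) * fit$sigma2
  se <- sqrt(diag(covb)[seq_len(na)])
  blues <- data.frame(site = plots$site[1], accession = levels(acc),
                      trait = trait, estimate = est, se = se,
                      stringsAsFactors = FALSE)
  class(blues) <- c("blue_table", "data.frame")
  list(blues = blues,
       fit = list(site = plots$site[1], trait = trait,
                  rho_row = best[1], rho_col = best[2],
                  sigma2_spatial = fit$sigma2,
                  log_likelihood = fit$loglik))
}
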