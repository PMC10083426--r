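# Small fixture builders shared across test files. Everything is generated
# in code; no stored data.

# Tiny genotype panel with hand-picked dosages (lines x markers).
toy_geno <- function(dosages, line_ids = NULL, marker_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(line_ids)) line_ids <- sprintf("L%02d", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- sprintf("M%02d", seq_len(ncol(dosages)))
  genotype_matrix(line_ids, marker_ids, dosages)
}

# One-site bivariate simulation with the trait covariances implied by
# heritabilities and a genetic correlation (unit phenotypic variance).
bivar_params <- function(h2, rA, n_lines = 300, n_markers = 2000, seed,
                         traits = c("GY", "PH"), ...) {
  Tm <- diag(h2)
  Tm[1, 2] <- Tm[2, 1] <- rA * sqrt(prod(h2))
  Rm <- diag(1 - h2)
  sim_params(n_lines = n_lines, n_markers = n_markers, missing_rate = 0,
             n_sites = 1, site_means = matrix(c(3, 100), 1),
             T_target = Tm, R_target = Rm, sigma2_gxe = 0,
             traits = traits, seed = seed, ...)
}

# Simulate accession-level phenotypes and the conditioned GRM in one go.
sim_blues_grm <- function(params) {
  g <- simulate_genotypes(params)
  ef <- simulate_true_effects(g, params)
  grm <- condition_grm(vanraden_grm(impute_missing(g)))
  list(blues = simulate_blues(g, ef, params), grm = grm, effects = ef,
       geno = g)
}

# Dense-matrix REML profile log-likelihood for the univariate GBLUP model,
# used as an independent oracle (no eigendecomposition, no profiling tricks
# shared with the implementation under test).
dense_uv_reml_ll <- function(lambda, y, G) {
  n <- length(y)
  X <- matrix(1, n, 1)
  C <- lambda * G + diag(n)
  Ci <- solve(C)
  XtCiX <- t(X) %*% Ci %*% X
  b <- solve(XtCiX, t(X) %*% Ci %*% y)
  r <- y - X %*% b
  s2e <- as.numeric(t(r) %*% Ci %*% r) / (n - 1)
  as.numeric(-0.5 * ((n - 1) * log(s2e) + determinant(C)$modulus +
                       log(det(XtCiX)) + (n - 1) + (n - 1) * log(2 * pi)))
}
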