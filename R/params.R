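#' Simulation parameters for a multi-site, multi-trait trial series
#'
#' Bundles every knob of the synthetic-data generator: genotype panel
#' dimensions, the additive genetic covariance `T_target` and residual
#' covariance `R_target` among traits, per-site trait means, row/column and
#' genotype-by-site (g`\eqn{\times}`E) variances, and the AR1
#' autocorrelations of the separable spatial error field.
#'
#' @param n_lines Number of accessions (lines).
#' @param n_markers Number of biallelic SNP markers.
#' @param maf_range Length-2 numeric, allele-frequency range in (0, 0.5] from
#'   which per-marker frequencies are drawn uniformly.
#' @param missing_rate Probability that any one genotype call is missing.
#' @param n_sites Number of trial sites (environments).
#' @param site_means `n_sites x n_traits` matrix of trait means (trait units);
#'   rows are sites.
#' @param T_target Additive genetic covariance matrix among traits
#'   (trait units squared); symmetric positive-definite.
#' @param R_target Residual covariance matrix among traits; symmetric
#'   positive-definite. At plot level this is the marginal covariance of the
#'   spatial error field.
#' @param rho_row,rho_col AR1 autocorrelations along rows/columns, in (-1, 1).
#' @param sigma2_row,sigma2_col Per-trait variances of the random row and
#'   column effects (recycled if scalar).
#' @param sigma2_gxe Per-trait variance of the site-by-accession interaction
#'   deviations (recycled if scalar).
#' @param n_reps Replicates per site (complete blocks).
#' @param layout_rows,layout_cols Field grid dimensions per site. Replicates
#'   occupy contiguous column blocks, so `layout_rows * layout_cols / n_reps`
#'   must be at least `n_lines`.
#' @param traits Character vector of trait names.
#' @param seed Integer seed; mandatory, drives every random draw.
#'
#' @return An object of class `sim_params` (a validated list).
#' @seealso [default_sim_params()] for study-scale defaults,
#'   [simulate_genotypes()], [simulate_true_effects()], [simulate_trial()].
#' @export
sim_params <- function(n_lines, n_markers, maf_range = c(0.05, 0.5),
                       missing_rate = 0.2, n_sites = 1L,
                       site_means, T_target, R_target,
                       rho_row = 0.4, rho_col = 0.4,
                       sigma2_row = NULL, sigma2_col = NULL,
                       sigma2_gxe = 0,
                       n_reps = 2L, layout_rows = NULL, layout_cols = NULL,
                       traits = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory in sim_params()")
  n_lines <- as.integer(n_lines); n_markers <- as.integer(n_markers)
  if (n_lines < 2L || n_markers < 1L) {
    stop("need n_lines >= 2 and n_markers >= 1")
  }
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5] with min <= max")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")

  T_target <- as.matrix(T_target); R_target <- as.matrix(R_target)
  n_traits <- nrow(T_target)
  check_spd(T_target, "T_target")
  check_spd(R_target, "R_target")
  if (!all(dim(R_target) == n_traits)) stop("T_target and R_target dimensions differ")

  if (is.null(traits)) {
    traits <- colnames(T_target)
    if (is.null(traits)) traits <- paste0("trait", seq_len(n_traits))
  }
  dimnames(T_target) <- dimnames(R_target) <- list(traits, traits)

  site_means <- matrix(as.numeric(site_means), nrow = n_sites, ncol = n_traits,
                       dimnames = list(paste0("S", seq_len(n_sites)), traits))

  if (abs(rho_row) >= 1 || abs(rho_col) >= 1) stop("AR1 rho must be in (-1, 1)")

  if (is.null(sigma2_row)) sigma2_row <- 0.25 * diag(R_target)
  if (is.null(sigma2_col)) sigma2_col <- 0.25 * diag(R_target)
  sigma2_row <- rep_len(as.numeric(sigma2_row), n_traits)
  sigma2_col <- rep_len(as.numeric(sigma2_col), n_traits)
  sigma2_gxe <- rep_len(as.numeric(sigma2_gxe), n_traits)
  if (any(c(sigma2_row, sigma2_col, sigma2_gxe) < 0)) {
    stop("variance components must be non-negative")
  }

  n_reps <- as.integer(n_reps)
  if (is.null(layout_rows)) layout_rows <- max(2L, as.integer(ceiling(sqrt(n_lines * n_reps))))
  if (is.null(layout_cols)) {
    layout_cols <- as.integer(n_reps * ceiling(n_lines / layout_rows))
  }
  cols_per_rep <- layout_cols %/% n_reps
  if (cols_per_rep * n_reps != layout_cols) {
    stop("layout_cols must be divisible by n_reps (replicates are contiguous column blocks)")
  }
  if (layout_rows * cols_per_rep < n_lines) {
    stop(sprintf("layout too small: %d rows x %d columns per replicate < %d lines",
                 layout_rows, cols_per_rep, n_lines))
  }

  structure(list(
    n_lines = n_lines, n_markers = n_markers, maf_range = maf_range,
    missing_rate = missing_rate, n_sites = as.integer(n_sites),
    site_means = site_means, T_target = T_target, R_target = R_target,
    rho_row = rho_row, rho_col = rho_col,
    sigma2_row = sigma2_row, sigma2_col = sigma2_col, sigma2_gxe = sigma2_gxe,
    n_reps = n_reps, layout_rows = as.integer(layout_rows),
    layout_cols = as.integer(layout_cols), traits = traits,
    seed = as.integer(seed)
  ), class = "sim_params")
}

check_spd <- function(M, name) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop(name, " must be a square matrix")
  if (max(abs(M - t(M))) > 1e-8) stop(name, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop(name, " must be positive-definite")
  invisible(TRUE)
}

#' Study-scale default simulation parameters
#'
#' Returns a [sim_params()] object emulating a diverse safflower collection
#' evaluated over four environments: 349 accessions genotyped at 6,911 SNPs
#' and phenotyped for eight agronomic traits (days to flowering DF, days to
#' maturity DM, flowering time FT, plant height PH in cm, seed weight SW in
#' g/500 achenes, grain yield GY in t/ha, seed protein PC in %, oil content
#' OL in %) in replicated row-column field trials. Genetic and residual trait
#' variances follow published estimates for such a collection at an optimal
#' (irrigated) site; genetic correlations encode the reported qualitative
#' structure (moderate GY-PH, weak GY-DF and GY-OL, negative SW-OL/SW-PC and
#' PC-GY, positive OL-PC). Site means step grain yield down from the optimal
#' to the water-stressed environments.
#'
#' @param n_lines,n_markers,n_sites,seed Overrides for the study-scale
#'   defaults (349 lines, 6911 markers, 4 sites).
#' @param ... Further overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
default_sim_params <- function(n_lines = 349L, n_markers = 6911L,
                               n_sites = 4L, seed = 20170349L, ...) {
  traits <- c("DF", "DM", "FT", "PH", "SW", "GY", "PC", "OL")
  sigA <- c(DF = 9.621, DM = 13.534, FT = 4.546, PH = 176.286,
            SW = 9.726, GY = 0.682, PC = 0.342, OL = 11.730)
  sigE <- c(DF = 3.594, DM = 6.163, FT = 3.898, PH = 61.840,
            SW = 2.297, GY = 0.557, PC = 0.294, OL = 3.067)
  corT <- diag(8); dimnames(corT) <- list(traits, traits)
  set_cor <- function(a, b, v) {
    corT[a, b] <<- v; corT[b, a] <<- v
  }
  set_cor("DF", "DM", 0.60); set_cor("DF", "FT", -0.30); set_cor("DM", "FT", 0.45)
  set_cor("GY", "PH", 0.45); set_cor("GY", "DF", 0.10); set_cor("GY", "OL", 0.19)
  set_cor("GY", "PC", -0.30); set_cor("SW", "OL", -0.45); set_cor("SW", "PC", -0.45)
  set_cor("OL", "PC", 0.30)
  Tm <- diag(sqrt(sigA)) %*% corT %*% diag(sqrt(sigA))
  Rm <- diag(sigE)
  dimnames(Tm) <- dimnames(Rm) <- list(traits, traits)

  means <- rbind(
    c(100, 140, 40, 110, 35, 3.0, 16.0, 27.0),  # optimal irrigated
    c( 95, 132, 37, 100, 34, 1.7, 16.2, 26.0),  # rainfed, flowering stress
    c( 90, 125, 35,  70, 32, 1.0, 15.8, 25.0),  # low-rainfall stress
    c( 92, 128, 36,  75, 33, 1.1, 16.0, 25.5)   # high-rainfall zone
  )
  means <- means[seq_len(n_sites), , drop = FALSE]

  args <- list(n_lines = n_lines, n_markers = n_markers,
               maf_range = c(0.05, 0.5), missing_rate = 0.2,
               n_sites = n_sites, site_means = means,
               T_target = Tm, R_target = Rm,
               rho_row = 0.4, rho_col = 0.4,
               sigma2_row = 0.25 * sigE, sigma2_col = 0.25 * sigE,
               sigma2_gxe = 0.4 * sigA,
               n_reps = 2L, layout_rows = 25L, layout_cols = 28L,
               traits = traits, seed = seed)
  over <- list(...)
  if (any(!nzchar(names(over)))) stop("overrides must be named")
  args[names(over)] <- over
  if (!"layout_rows" %in% names(over) && args$n_lines != 349L) {
    args$layout_rows <- NULL
    if (!"layout_cols" %in% names(over)) args$layout_cols <- NULL
  }
  do.call(sim_params, args)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("sim_params: %d lines x %d markers, %d site(s), %d trait(s), %d rep(s)\n",
              x$n_lines, x$n_markers, x$n_sites, length(x$traits), x$n_reps))
  cat(sprintf("  traits: %s\n", paste(x$traits, collapse = ", ")))
  cat(sprintf("  field: %d rows x %d cols, AR1 rho (row, col) = (%.2f, %.2f), seed %d\n",
              x$layout_rows, x$layout_cols, x$rho_row, x$rho_col, x$seed))
  invisible(x)
}
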