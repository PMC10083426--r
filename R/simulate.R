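#' Simulate a biallelic SNP genotype panel
#'
#' Draws per-marker allele frequencies uniformly from `params$maf_range` and
#' genotype dosages as two binomial draws per line (Hardy-Weinberg sampling),
#' then masks calls completely at random at `params$missing_rate`. Markers are
#' unlinked; linkage disequilibrium is deliberately not modelled.
#'
#' @param params A [sim_params()] object.
#' @return A `genotype_matrix`: list with `line_ids`, `marker_ids`, `dosages`
#'   (lines x markers, values 0/1/2 with `NA` for missing) and `missing_mask`.
#' @export
simulate_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_lines; m <- params$n_markers
  p <- stats::runif(m, params$maf_range[1], params$maf_range[2])
  dos <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  miss <- matrix(stats::runif(n * m) < params$missing_rate, nrow = n, ncol = m)
  dos[miss] <- NA_integer_
  line_ids <- sprintf("L%04d", seq_len(n))
  marker_ids <- sprintf("M%05d", seq_len(m))
  dimnames(dos) <- dimnames(miss) <- list(line_ids, marker_ids)
  genotype_matrix(line_ids, marker_ids, dos, miss)
}

#' Construct a genotype matrix object
#'
#' @param line_ids,marker_ids Unique identifiers.
#' @param dosages Lines x markers matrix with values in \{0, 1, 2\} or `NA`.
#' @param missing_mask Optional logical matrix; derived from `NA`s if omitted.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(line_ids, marker_ids, dosages, missing_mask = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (anyDuplicated(line_ids)) stop("line ids must be unique")
  if (anyDuplicated(marker_ids)) stop("marker ids must be unique")
  if (nrow(dosages) != length(line_ids) || ncol(dosages) != length(marker_ids)) {
    stop("dosage dimensions inconsistent with id lengths")
  }
  if (is.null(missing_mask)) missing_mask <- is.na(dosages)
  rng <- range(dosages, na.rm = TRUE)
  # continuous values in [0, 2] are allowed (mean-imputed panels)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9) stop("dosages must lie in [0, 2]")
  dimnames(dosages) <- dimnames(missing_mask) <- list(line_ids, marker_ids)
  structure(list(line_ids = as.character(line_ids),
                 marker_ids = as.character(marker_ids),
                 dosages = dosages,
                 missing_mask = missing_mask),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers, %.1f%% missing\n",
              length(x$line_ids), length(x$marker_ids),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' Simulate true additive and site-interaction genetic effects
#'
#' Additive values are built as sums of i.i.d. normal marker effects over the
#' (mean-imputed, centred) dosage matrix and then linearly rescaled so that
#' the in-sample covariance of the true breeding values equals `T_target`
#' exactly; this removes Monte-Carlo drift so that downstream
#' parameter-recovery checks are sharp. Site-interaction deviations gE are
#' drawn independently per site and per trait and rescaled to their target
#' variance `sigma2_gxe` the same way.
#'
#' @param genotypes A `genotype_matrix`.
#' @param params A [sim_params()] object (`T_target` must be positive-definite).
#' @return List with `g` (lines x traits additive values, in-sample covariance
#'   exactly `T_target`) and `gE` (list per site of lines x traits deviations).
#' @export
simulate_true_effects <- function(genotypes, params) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(params, "sim_params"))
  check_spd(params$T_target, "T_target")
  set.seed(params$seed + 1L)
  W <- impute_missing(genotypes, method = "mean_dosage")$dosages
  W <- scale(W, center = TRUE, scale = FALSE)
  n <- nrow(W); t <- length(params$traits)
  B <- matrix(stats::rnorm(ncol(W) * t), ncol = t)
  g <- W %*% B
  g <- scale(g, center = TRUE, scale = FALSE)
  C <- crossprod(g) / (n - 1)
  # map sample covariance C onto the target exactly: g %*% Uc^-1 %*% Ut
  g <- g %*% solve(chol(C)) %*% chol(params$T_target)
  dimnames(g) <- list(genotypes$line_ids, params$traits)

  # interaction deviations are additive-by-site: marker-effect sums drawn
  # independently per site, so within a site they carry the same genomic
  # covariance structure G as the main effects
  gE <- vector("list", params$n_sites)
  names(gE) <- rownames(params$site_means)
  for (s in seq_len(params$n_sites)) {
    E <- W %*% matrix(stats::rnorm(ncol(W) * t), ncol = t)
    E <- scale(E, center = TRUE, scale = FALSE)
    sdev <- apply(E, 2, stats::sd)
    E <- sweep(E, 2, pmax(sdev, .Machine$double.eps), "/")
    E <- sweep(E, 2, sqrt(params$sigma2_gxe), "*")
    dimnames(E) <- list(genotypes$line_ids, params$traits)
    gE[[s]] <- E
  }
  list(g = g, gE = gE)
}

rep_column_block <- function(params, rep) {
  cpr <- params$layout_cols %/% params$n_reps
  ((rep - 1L) * cpr + 1L):(rep * cpr)
}

#' Simulate plot-level phenotypes for a multi-site trial series
#'
#' Each site is an independent row-column field of `layout_rows x layout_cols`
#' plots in which every replicate occupies a contiguous block of columns and
#' accessions are completely randomized within replicate. A plot value is
#'
#' site mean + additive effect + site interaction + random row effect +
#' random column effect + spatial residual,
#'
#' where the residual field is separable AR1(rho_row) x AR1(rho_col) with
#' marginal trait covariance `R_target`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param effects Output of [simulate_true_effects()].
#' @param params A [sim_params()] object.
#' @return A `trial_table` data.frame with columns
#'   `site, rep, row, col, accession` and one column per trait.
#' @export
simulate_trial <- function(genotypes, effects, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 2L)
  n <- params$n_lines; t <- length(params$traits)
  cpr <- params$layout_cols %/% params$n_reps
  if (params$layout_rows * cpr < n) {
    stop("layout too small for n_lines plots per replicate")
  }
  Lr <- chol(ar1_correlation(params$layout_rows, params$rho_row))
  Lc <- chol(ar1_correlation(params$layout_cols, params$rho_col))
  Lt <- chol(params$R_target)
  out <- vector("list", params$n_sites)
  for (s in seq_len(params$n_sites)) {
    site_id <- rownames(params$site_means)[s]
    row_eff <- sweep(matrix(stats::rnorm(params$layout_rows * t),
                            params$layout_rows, t), 2,
                     sqrt(params$sigma2_row), "*")
    col_eff <- sweep(matrix(stats::rnorm(params$layout_cols * t),
                            params$layout_cols, t), 2,
                     sqrt(params$sigma2_col), "*")
    # separable field: (Lr' Z Lc) has covariance AR1_row (x) AR1_col per trait
    eps <- array(0, c(params$layout_rows, params$layout_cols, t))
    Z <- matrix(stats::rnorm(params$layout_rows * params$layout_cols * t),
                params$layout_rows * params$layout_cols, t)
    Z <- Z %*% Lt
    for (j in seq_len(t)) {
      Zj <- matrix(Z[, j], params$layout_rows, params$layout_cols)
      eps[, , j] <- crossprod(Lr, Zj) %*% Lc
    }
    recs <- vector("list", params$n_reps)
    for (r in seq_len(params$n_reps)) {
      ord <- sample.int(n)
      cols <- rep_column_block(params, r)
      grid <- expand.grid(row = seq_len(params$layout_rows), col = cols)
      grid <- grid[seq_len(n), , drop = FALSE]
      acc <- genotypes$line_ids[ord]
      vals <- matrix(NA_real_, n, t)
      for (j in seq_len(t)) {
        vals[, j] <- params$site_means[s, j] +
          effects$g[ord, j] + effects$gE[[s]][ord, j] +
          row_eff[grid$row, j] + col_eff[grid$col, j] +
          eps[cbind(grid$row, grid$col, j)]
      }
      colnames(vals) <- params$traits
      recs[[r]] <- data.frame(site = site_id, rep = r,
                              row = grid$row, col = grid$col,
                              accession = acc, vals,
                              stringsAsFactors = FALSE)
    }
    out[[s]] <- do.call(rbind, recs)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  key <- paste(tab$site, tab$row, tab$col)
  stopifnot(!anyDuplicated(key))
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Simulate accession-level phenotypes (BLUE-like records)
#'
#' Generates one phenotype per accession, trait and site directly at the
#' accession level: site mean + additive effect + site interaction + an
#' independent residual with trait covariance `R_target`. This is the
#' generative counterpart of the stage-two models fitted to spatially
#' adjusted accession means, and is the input of choice for
#' parameter-recovery and cross-validation experiments where the stage-one
#' spatial adjustment is not under study.
#'
#' @param genotypes A `genotype_matrix`.
#' @param effects Output of [simulate_true_effects()].
#' @param params A [sim_params()] object.
#' @param sites Site indices to generate (default all).
#' @return A long-format `blue_table` data.frame with columns
#'   `site, accession, trait, estimate, se` (`se` is `NA`; these are
#'   synthetic noise-added values, not model estimates).
#' @export
simulate_blues <- function(genotypes, effects, params,
                           sites = seq_len(params$n_sites)) {
  set.seed(params$seed + 3L)
  n <- params$n_lines; t <- length(params$traits)
  Lt <- chol(params$R_target)
  out <- vector("list", length(sites))
  for (k in seq_along(sites)) {
    s <- sites[k]
    e <- matrix(stats::rnorm(n * t), n, t) %*% Lt
    vals <- sweep(effects$g + effects$gE[[s]] + e, 2,
                  params$site_means[s, ], "+")
    out[[k]] <- data.frame(
      site = rownames(params$site_means)[s],
      accession = rep(genotypes$line_ids, t),
      trait = rep(params$traits, each = n),
      estimate = as.vector(vals),
      se = NA_real_, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("blue_table", "data.frame")
  tab
}
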